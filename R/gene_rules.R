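#' Parse a gene-protein-reaction (GPR) rule string
#'
#' Rules are boolean expressions over gene identifiers with `and` / `or`
#' operators (case-insensitive; `&&`/`&` and `||`/`|` are accepted) and
#' parentheses. `and` binds tighter than `or`, as in COBRA-style model
#' files. The empty string denotes a spontaneous or orphan reaction.
#'
#' @param rule character scalar, e.g. `"G1 and (G2 or G3)"`.
#' @return A rule tree: `NULL` for the empty rule, a character scalar for a
#'   single gene leaf, or a list with elements `op` (`"and"` or `"or"`) and
#'   `args` (list of subtrees).
#' @export
#' @examples
#' parse_gene_rule("BCKDHA and BCKDHB")
#' rule_genes(parse_gene_rule("G1 and (G2 or G3)"))
parse_gene_rule <- function(rule) {
  stopifnot(is.character(rule), length(rule) == 1L)
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- tokenize_rule(rule)
  st <- list(toks = toks, pos = 1L)
  res <- parse_or(st)
  if (res$st$pos <= length(toks)) {
    stop("malformed gene rule near '", toks[res$st$pos], "': ", rule)
  }
  res$node
}

tokenize_rule <- function(rule) {
  rule <- gsub("&&|&", " and ", rule)
  rule <- gsub("\\|\\||\\|", " or ", rule)
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

parse_or <- function(st) {
  left <- parse_and(st)
  st <- left$st
  args <- list(left$node)
  while (!is.na(peek(st)) && tolower(peek(st)) == "or") {
    st$pos <- st$pos + 1L
    nxt <- parse_and(st)
    st <- nxt$st
    args <- c(args, list(nxt$node))
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  list(node = node, st = st)
}

parse_and <- function(st) {
  left <- parse_atom(st)
  st <- left$st
  args <- list(left$node)
  while (!is.na(peek(st)) && tolower(peek(st)) == "and") {
    st$pos <- st$pos + 1L
    nxt <- parse_atom(st)
    st <- nxt$st
    args <- c(args, list(nxt$node))
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  list(node = node, st = st)
}

parse_atom <- function(st) {
  tok <- peek(st)
  if (is.na(tok)) stop("malformed gene rule: unexpected end of expression")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- parse_or(st)
    st <- inner$st
    if (is.na(peek(st)) || peek(st) != ")") stop("malformed gene rule: missing ')'")
    st$pos <- st$pos + 1L
    return(list(node = inner$node, st = st))
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop("malformed gene rule: unexpected token '", tok, "'")
  }
  st$pos <- st$pos + 1L
  list(node = tok, st = st)
}

#' Extract the gene leaves of a rule
#'
#' @param rule a rule string or a parsed rule tree.
#' @return Character vector of unique gene ids (empty for the empty rule).
#' @export
rule_genes <- function(rule) {
  if (is.character(rule)) rule <- parse_gene_rule(rule)
  leaves <- function(node) {
    if (is.null(node)) return(character(0))
    if (is.character(node)) return(node)
    unlist(lapply(node$args, leaves), use.names = FALSE)
  }
  unique(leaves(rule))
}

#' Serialize a rule tree back to a string
#'
#' @param node rule tree as returned by [parse_gene_rule()].
#' @return Character scalar; `""` for the empty rule.
#' @export
rule_to_string <- function(node) {
  if (is.null(node)) return("")
  if (is.character(node)) return(node)
  parts <- vapply(node$args, function(a) {
    s <- rule_to_string(a)
    # parenthesize an OR nested under AND to preserve precedence
    if (identical(node$op, "and") && is.list(a) && identical(a$op, "or")) {
      s <- paste0("(", s, ")")
    }
    s
  }, character(1))
  paste(parts, collapse = paste0(" ", node$op, " "))
}
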
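#' Construct a metabolic model
#'
#' The container mirrors a COBRA-style genome-scale model: an ordered table
#' of metabolites, an ordered table of reactions with flux bounds, GPR rule
#' strings and subsystem labels, and a stoichiometry list mapping each
#' reaction to its signed metabolite coefficients (negative = consumed,
#' positive = produced). A reaction touching exactly one metabolite is a
#' system-boundary exchange pseudo-reaction.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   and optionally `formula`.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gene_rule`, `subsystem`.
#' @param stoichiometry named list (names = reaction ids) of named numeric
#'   vectors (names = metabolite ids, values = signed coefficients).
#' @param genes character vector of gene ids; defaults to the union of all
#'   rule leaves.
#' @param compartments character vector of compartment tokens; defaults to
#'   those used by the metabolites.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            genes = NULL, compartments = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(reactions$gene_rule)) reactions$gene_rule <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (is.null(compartments)) compartments <- unique(metabolites$compartment)
  rule_leaves <- unique(unlist(lapply(reactions$gene_rule, rule_genes),
                               use.names = FALSE))
  if (is.null(genes)) genes <- rule_leaves
  genes <- unique(as.character(genes))
  stoichiometry <- stoichiometry[reactions$id]
  reactions$is_exchange <- vapply(stoichiometry, length, 1L) == 1L
  m <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, genes = genes,
         compartments = unique(compartments)),
    class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, referential integrity of stoichiometries and gene
#' rules, bound ordering, nonzero coefficients and the exchange convention.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly; stops on the first violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met <- model$metabolites; rxn <- model$reactions
  if (anyDuplicated(met$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) stop("duplicate reaction ids")
  if (any(!nzchar(met$id))) stop("empty metabolite id")
  if (any(!nzchar(rxn$id))) stop("empty reaction id")
  if (!all(met$compartment %in% model$compartments)) {
    stop("metabolite compartment not among declared compartments")
  }
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    bad <- rxn$id[rxn$lower_bound > rxn$upper_bound][1]
    stop("lower_bound > upper_bound for reaction ", bad)
  }
  if (!identical(names(model$stoichiometry), rxn$id)) {
    stop("stoichiometry list must be named by reaction id in reaction order")
  }
  for (rid in rxn$id) {
    sto <- model$stoichiometry[[rid]]
    if (length(sto) == 0) stop("reaction ", rid, " has empty stoichiometry")
    if (any(sto == 0)) stop("zero stoichiometric coefficient in reaction ", rid)
    missing_met <- setdiff(names(sto), met$id)
    if (length(missing_met)) {
      stop("reaction ", rid, " references unknown metabolite ",
           missing_met[1])
    }
  }
  for (i in seq_len(nrow(rxn))) {
    gs <- rule_genes(rxn$gene_rule[i])
    missing_g <- setdiff(gs, model$genes)
    if (length(missing_g)) {
      stop("reaction ", rxn$id[i], " references unknown gene ", missing_g[1])
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "'\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), " exchange)",
      "  genes: ", length(x$genes), "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @param sparse return a `Matrix::sparseMatrix` (default) or a dense matrix.
#' @return Matrix of shape metabolites x reactions; entry (i, j) is the
#'   coefficient of metabolite i in reaction j, 0 if absent. Row and column
#'   order follow model order; dimnames carry the ids.
#' @export
stoichiometric_matrix <- function(model, sparse = TRUE) {
  validate_model(model)
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxn_ids)) {
    sto <- model$stoichiometry[[j]]
    ii <- c(ii, match(names(sto), met_ids))
    jj <- c(jj, rep.int(j, length(sto)))
    xx <- c(xx, unname(sto))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))
  if (sparse) S else as.matrix(S)
}

#' Reactions associated with a gene
#'
#' Association is leaf membership in the reaction's GPR rule, regardless of
#' AND/OR context: any reaction whose rule mentions the gene is returned.
#' This matches bound-scaling knockdown semantics, which perturb every
#' associated reaction wholesale rather than evaluating isozyme redundancy.
#'
#' @param model a `metabolic_model`.
#' @param gene_id gene identifier present in `model$genes`.
#' @return Character vector of reaction ids (possibly empty), in model order.
#' @export
reactions_for_gene <- function(model, gene_id) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!gene_id %in% model$genes) {
    stop("unknown gene id '", gene_id, "' (not in model gene list)")
  }
  hit <- vapply(model$reactions$gene_rule,
                function(r) gene_id %in% rule_genes(r), logical(1))
  model$reactions$id[hit]
}

#' Effective flux bounds after overrides
#'
#' @param model a `metabolic_model`.
#' @param overrides named list (reaction id -> c(lb, ub)) replacing the
#'   model bounds for those reactions only; may be empty.
#' @return data.frame with columns `id`, `lower_bound`, `upper_bound`.
#' @export
effective_bounds <- function(model, overrides = list()) {
  b <- model$reactions[, c("id", "lower_bound", "upper_bound")]
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), b$id)
    if (length(unknown)) stop("override for unknown reaction ", unknown[1])
    for (rid in names(overrides)) {
      o <- overrides[[rid]]
      if (length(o) != 2 || o[1] > o[2]) {
        stop("invalid override bounds for reaction ", rid)
      }
      k <- match(rid, b$id)
      b$lower_bound[k] <- o[1]
      b$upper_bound[k] <- o[2]
    }
  }
  b
}
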
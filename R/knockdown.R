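#' Specify a fractional gene knockdown
#'
#' Knockdown is modelled as scaling the flux bounds of every reaction
#' associated with the gene toward zero by `scale_factor`: a factor of 0.5
#' halves the maximum attainable flux through those reactions, 0 deletes
#' them, 1 leaves the model unchanged.
#'
#' @param gene_id gene identifier to perturb.
#' @param scale_factor fraction of the original bound magnitude retained,
#'   in `[0, 1]`; default 0.5 (a 50% change in maximum flux).
#' @param target_reactions optional explicit reaction-id set overriding the
#'   gene-rule lookup.
#' @return A `knockdown_spec` object.
#' @export
knockdown_spec <- function(gene_id, scale_factor = 0.5,
                           target_reactions = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!is.numeric(scale_factor) || length(scale_factor) != 1L ||
      scale_factor < 0 || scale_factor > 1) {
    stop("scale_factor must be a single number in [0, 1]")
  }
  structure(list(gene_id = gene_id, scale_factor = scale_factor,
                 target_reactions = target_reactions),
            class = "knockdown_spec")
}

#' Translate a knockdown into bound overrides
#'
#' For every reaction associated with the gene (leaf membership in its GPR
#' rule, or the explicit `target_reactions`), each bound is scaled toward
#' zero: `ub' = f * ub` when `ub > 0`, `lb' = f * lb` when `lb < 0`; bounds
#' already at or across zero are untouched, so an irreversible reaction
#' keeps its zero lower bound and a reversible reaction shrinks
#' symmetrically in both directions. All other reactions are unaffected.
#'
#' @param model a `metabolic_model`.
#' @param spec a [knockdown_spec()] (or a gene id, which uses defaults).
#' @return Named list (reaction id -> `c(lb, ub)`) suitable for the
#'   `overrides` argument of [maximize_flux()].
#' @export
#' @examples
#' m <- make_linear_chain(ubs = c(100, 10, 100), genes = c(NA, "G1", NA))
#' apply_knockdown(m, knockdown_spec("G1", 0.5))
apply_knockdown <- function(model, spec) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.character(spec)) spec <- knockdown_spec(spec)
  stopifnot(inherits(spec, "knockdown_spec"))
  targets <- spec$target_reactions
  if (is.null(targets)) {
    targets <- reactions_for_gene(model, spec$gene_id)
    if (!length(targets)) {
      stop("gene '", spec$gene_id, "' maps to no reactions")
    }
  } else {
    unknown <- setdiff(targets, model$reactions$id)
    if (length(unknown)) stop("unknown target reaction '", unknown[1], "'")
    if (!length(targets)) stop("gene '", spec$gene_id,
                               "' maps to no reactions")
  }
  f <- spec$scale_factor
  overrides <- list()
  for (rid in targets) {
    k <- match(rid, model$reactions$id)
    lb <- model$reactions$lower_bound[k]
    ub <- model$reactions$upper_bound[k]
    overrides[[rid]] <- c(if (lb < 0) f * lb else lb,
                          if (ub > 0) f * ub else ub)
  }
  overrides
}

#' Ensemble-objective knockdown screen
#'
#' Runs the screen at the heart of the package: every objective reaction is
#' maximized by FBA twice, under wild-type bounds and under knockdown
#' bounds, and the reduction in its maximal attainable flux is recorded.
#' Reactions losing at least `threshold` of their wild-type maximum are
#' classified as compromised and tallied per metabolic subsystem.
#'
#' Objectives whose wild-type maximum is at tolerance zero are flagged
#' `blocked` (reduction defined as 0: a blocked reaction cannot be
#' compromised). Objectives with a non-optimal solver status in either
#' condition are flagged `excluded` and removed from classification with a
#' warning rather than aborting the screen.
#'
#' @param model a `metabolic_model`.
#' @param spec a [knockdown_spec()] or gene id.
#' @param objective_set reaction ids to screen; default all non-exchange
#'   reactions (boundary pseudo-reactions are not meaningful objectives).
#' @param threshold reduction fraction at or above which a reaction counts
#'   as compromised; default 0.25.
#' @param tol LP tolerance; also the zero cutoff for `blocked`.
#' @param verbose emit a census and warnings to stderr.
#' @return A `screen_result`: list with `spec`, `threshold`, `records`
#'   (data.frame: `reaction_id`, `subsystem`, `wt_status`, `kd_status`,
#'   `wt_max`, `kd_max`, `reduction_fraction`, `blocked`, `excluded`,
#'   `compromised`), `compromised_ids` and `subsystem_counts`.
#' @export
#' @examples
#' m <- make_valine_pathway_model()
#' res <- ensemble_screen(m, knockdown_spec("HIBCH", 0.5))
#' subsystem_summary(res)
ensemble_screen <- function(model, spec, objective_set = NULL,
                            threshold = 0.25, tol = 1e-9, verbose = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.character(spec)) spec <- knockdown_spec(spec)
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]")
  }
  if (is.null(objective_set)) {
    objective_set <- model$reactions$id[!model$reactions$is_exchange]
  }
  overrides <- apply_knockdown(model, spec)
  if (verbose) {
    message("model '", model$id, "': ", nrow(model$metabolites),
            " metabolites, ", nrow(model$reactions), " reactions; screening ",
            length(objective_set), " objectives (", 2 * length(objective_set),
            " LPs), knockdown of ", length(overrides), " reaction(s)")
  }
  wt <- max_over_all(model, objective_set)
  kd <- max_over_all(model, objective_set, overrides = overrides)
  stopifnot(identical(wt$reaction_id, kd$reaction_id))

  subsys <- model$reactions$subsystem[match(wt$reaction_id,
                                            model$reactions$id)]
  excluded <- wt$status != "optimal" | kd$status != "optimal"
  blocked <- !excluded & wt$max_flux <= tol
  red <- numeric(nrow(wt))
  ok <- !excluded & !blocked
  red[ok] <- 1 - kd$max_flux[ok] / wt$max_flux[ok]
  # solver tolerance can leave a vanishing negative reduction; clamp it
  red[ok & red < 0 & red > -1e-6] <- 0
  red[abs(red) < 1e-12] <- 0
  if (any(excluded)) {
    warning(sum(excluded), " objective(s) excluded with non-optimal status: ",
            paste(wt$reaction_id[excluded], collapse = ", "))
  }
  compromised <- classify_compromised(
    data.frame(reaction_id = wt$reaction_id, reduction_fraction = red,
               blocked = blocked, excluded = excluded,
               stringsAsFactors = FALSE),
    threshold)
  records <- data.frame(
    reaction_id = wt$reaction_id, subsystem = subsys,
    wt_status = wt$status, kd_status = kd$status,
    wt_max = wt$max_flux, kd_max = kd$max_flux,
    reduction_fraction = red, blocked = blocked, excluded = excluded,
    compromised = wt$reaction_id %in% compromised,
    stringsAsFactors = FALSE)
  counts <- table(records$subsystem[records$compromised])
  structure(list(spec = spec, threshold = threshold, records = records,
                 compromised_ids = compromised,
                 subsystem_counts = stats::setNames(as.integer(counts),
                                                    names(counts))),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Knockdown screen: gene ", x$spec$gene_id,
      ", scale factor ", x$spec$scale_factor,
      ", threshold ", x$threshold, "\n", sep = "")
  cat("  objectives: ", nrow(x$records),
      "  compromised: ", length(x$compromised_ids),
      "  blocked: ", sum(x$records$blocked),
      "  excluded: ", sum(x$records$excluded), "\n", sep = "")
  invisible(x)
}

#' Classify compromised reactions
#'
#' A reaction is compromised when it is neither excluded nor blocked and
#' its reduction fraction reaches `threshold` (up to a 1e-6 tolerance on
#' the comparison).
#'
#' @param records data.frame with columns `reaction_id`,
#'   `reduction_fraction`, `blocked`, `excluded`.
#' @param threshold reduction cutoff in `(0, 1]`.
#' @return Character vector of compromised reaction ids.
#' @export
classify_compromised <- function(records, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  hit <- !records$excluded & !records$blocked &
    records$reduction_fraction >= threshold - 1e-6
  records$reaction_id[hit]
}

#' Summarize compromised reactions per subsystem
#'
#' @param result a `screen_result` from [ensemble_screen()].
#' @return data.frame with columns `subsystem`, `n_compromised`,
#'   `reaction_ids` (comma-separated), one row per subsystem with at least
#'   one compromised reaction, sorted by descending count then subsystem.
#' @export
subsystem_summary <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  rec <- result$records[result$records$compromised, , drop = FALSE]
  if (!nrow(rec)) {
    return(data.frame(subsystem = character(0), n_compromised = integer(0),
                      reaction_ids = character(0), stringsAsFactors = FALSE))
  }
  sp <- split(rec$reaction_id, rec$subsystem)
  out <- data.frame(subsystem = names(sp),
                    n_compromised = vapply(sp, length, 1L),
                    reaction_ids = vapply(sp, paste, "", collapse = ","),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_compromised, out$subsystem), , drop = FALSE]
}
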
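#' Maximize flux through one reaction (flux balance analysis)
#'
#' Solves `max v_obj` subject to steady-state mass balance `S v = 0` and the
#' model's flux bounds, optionally modified by per-reaction bound overrides.
#' Exchange bounds are taken verbatim from the model: the medium is whatever
#' the model's boundary reactions allow, and this function never opens or
#' closes exchanges on its own.
#'
#' @param model a `metabolic_model`.
#' @param objective_reaction reaction id to maximize.
#' @param overrides named list (reaction id -> `c(lb, ub)`) of bound
#'   replacements, e.g. from [apply_knockdown()].
#' @param tol feasibility/pivot tolerance of the LP solver.
#' @return An `fba_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value` (optimal flux; `NA`
#'   unless optimal) and `fluxes` (named vector, one feasible optimal flux
#'   distribution; optimal in value only -- alternate optima may exist).
#' @export
#' @examples
#' m <- make_linear_chain(ubs = c(100, 10, 100), genes = c(NA, "G1", NA))
#' maximize_flux(m, "R2")$objective_value  # bottleneck bound: 10
maximize_flux <- function(model, objective_reaction, overrides = list(),
                          tol = 1e-9) {
  stopifnot(inherits(model, "metabolic_model"))
  rxn_ids <- model$reactions$id
  if (!objective_reaction %in% rxn_ids) {
    stop("unknown reaction id '", objective_reaction, "'")
  }
  bounds <- effective_bounds(model, overrides)
  S <- stoichiometric_matrix(model, sparse = FALSE)
  obj <- as.numeric(rxn_ids == objective_reaction)
  res <- solve_lp(obj, S, bounds$lower_bound, bounds$upper_bound,
                  maximize = TRUE, tol = tol)
  fluxes <- if (identical(res$status, "optimal")) {
    stats::setNames(res$x, rxn_ids)
  } else NA
  structure(list(status = res$status,
                 objective_value = if (identical(res$status, "optimal"))
                   res$value else NA_real_,
                 fluxes = fluxes),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("FBA solution: status =", x$status)
  if (identical(x$status, "optimal")) {
    cat(", objective =", format(x$objective_value))
  }
  cat("\n")
  invisible(x)
}

#' Maximize every requested reaction in turn
#'
#' The ensemble-objective primitive: each listed reaction is treated as the
#' objective of an independent FBA maximization under the same bounds.
#' Results are reported in model reaction order regardless of request order.
#'
#' @inheritParams maximize_flux
#' @param reaction_ids reaction ids to maximize; default all reactions.
#' @return data.frame with columns `reaction_id`, `status`, `max_flux`
#'   (`NA` unless optimal), one row per requested reaction in model order.
#' @export
max_over_all <- function(model, reaction_ids = NULL, overrides = list(),
                         tol = 1e-9) {
  stopifnot(inherits(model, "metabolic_model"))
  all_ids <- model$reactions$id
  if (is.null(reaction_ids)) reaction_ids <- all_ids
  unknown <- setdiff(reaction_ids, all_ids)
  if (length(unknown)) stop("unknown reaction id '", unknown[1], "'")
  ids <- all_ids[all_ids %in% reaction_ids]
  # the constraint system is shared across objectives; build it once
  bounds <- effective_bounds(model, overrides)
  S <- stoichiometric_matrix(model, sparse = FALSE)
  status <- character(length(ids))
  maxv <- rep(NA_real_, length(ids))
  for (k in seq_along(ids)) {
    obj <- as.numeric(all_ids == ids[k])
    res <- tryCatch(
      solve_lp(obj, S, bounds$lower_bound, bounds$upper_bound,
               maximize = TRUE, tol = tol),
      error = function(e) {
        stop("FBA failed for objective reaction '", ids[k], "': ",
             conditionMessage(e))
      })
    status[k] <- res$status
    if (identical(res$status, "optimal")) maxv[k] <- res$value
  }
  data.frame(reaction_id = ids, status = status, max_flux = maxv,
             stringsAsFactors = FALSE)
}
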
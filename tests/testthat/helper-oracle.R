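# Independent oracles for flux maxima, deliberately avoiding the package's
# LP solver.
#
# oracle_max_flux: brute-force vertex enumeration of the bounded polytope
# {S v = 0, lb <= v <= ub}. A linear objective attains its maximum at a
# vertex, and at a vertex at least n - rank(S) coordinates sit on a bound;
# enumerating all bound assignments and solving the equality system for the
# rest visits every vertex. Exponential, so only for fixtures with few
# reactions.
oracle_max_flux <- function(model, reaction_id, overrides = list(),
                            tol = 1e-8) {
  S <- as.matrix(stoichiometric_matrix(model, sparse = FALSE))
  b <- effective_bounds(model, overrides)
  lb <- b$lower_bound
  ub <- b$upper_bound
  j_obj <- match(reaction_id, b$id)
  n <- ncol(S)
  r <- qr(S)$rank
  nfix <- max(n - r, 0)
  combs <- if (nfix == 0) list(integer(0)) else
    utils::combn(n, nfix, simplify = FALSE)
  best <- -Inf
  feasible <- FALSE
  for (fix in combs) {
    free <- setdiff(seq_len(n), fix)
    ng <- length(fix)
    grid <- if (ng) as.matrix(expand.grid(rep(list(c(1, 2)), ng)))
      else matrix(0, 1, 0)
    for (gi in seq_len(nrow(grid))) {
      vfix <- if (ng) ifelse(grid[gi, ] == 1, lb[fix], ub[fix])
        else numeric(0)
      if (any(!is.finite(vfix))) next
      rhs <- if (ng) as.numeric(-S[, fix, drop = FALSE] %*% vfix)
        else numeric(nrow(S))
      Sf <- S[, free, drop = FALSE]
      sol <- tryCatch(qr.solve(Sf, rhs, tol = 1e-12),
                      error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(Sf %*% sol - rhs)) > tol) next
      v <- numeric(n)
      v[fix] <- vfix
      v[free] <- sol
      if (all(v >= lb - tol) && all(v <= ub + tol)) {
        feasible <- TRUE
        if (v[j_obj] > best) best <- v[j_obj]
      }
    }
  }
  if (!feasible) return(list(status = "infeasible", value = NA_real_))
  list(status = "optimal", value = best)
}

# flow_max_flux: for models whose internal reactions all convert exactly one
# metabolite into one metabolite with unit coefficients, the FBA maximum of
# a reaction equals min(its capacity, max-flow from its product back to its
# substrate through the rest of the circulation network). Exchanges attach
# to a shared boundary node. Independent graph-theoretic oracle (igraph).
flow_max_flux <- function(model, reaction_id, overrides = list()) {
  b <- effective_bounds(model, overrides)
  stopifnot(all(vapply(model$stoichiometry,
                       function(s) all(abs(s) == 1) && length(s) <= 2, TRUE)))
  edges <- character(0)
  caps <- numeric(0)
  ids <- b$id
  from <- to <- character(length(ids))
  for (k in seq_along(ids)) {
    s <- model$stoichiometry[[ids[k]]]
    subs <- names(s)[s < 0]
    prods <- names(s)[s > 0]
    from[k] <- if (length(subs)) subs else "BOUNDARY"
    to[k] <- if (length(prods)) prods else "BOUNDARY"
  }
  j <- match(reaction_id, ids)
  keep <- setdiff(seq_along(ids), j)
  g <- igraph::graph_from_data_frame(
    data.frame(from = from[keep], to = to[keep]),
    vertices = unique(c(from, to, "BOUNDARY")))
  fl <- igraph::max_flow(g, source = to[j], target = from[j],
                         capacity = b$upper_bound[keep])
  min(b$upper_bound[j], fl$value)
}
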
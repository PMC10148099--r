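# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Purpose-built for flux balance problems: maximize c'v subject to
# S v = 0 and box bounds lb <= v <= ub (bounds may be infinite).
# Box bounds are reduced to standard form x >= 0 by shifting (finite lb),
# mirroring (lb = -Inf, finite ub) or splitting (both infinite); finite
# residual caps become explicit slack rows. Bland's rule guarantees finite
# termination on degenerate bases at the cost of speed, which is acceptable
# at genome-scale-model screen sizes used here.

#' Solve a bounded steady-state linear program
#'
#' Maximizes (or minimizes) `obj' v` subject to `S v = 0` and
#' `lb <= v <= ub`. This is the workhorse behind [maximize_flux()].
#'
#' @param obj numeric objective coefficients, length = ncol(S).
#' @param S constraint matrix (metabolites x reactions); dense or sparse.
#' @param lb,ub numeric bounds per column; `-Inf`/`Inf` allowed.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot/feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `value` (objective at optimum; `NA` otherwise) and `x` (a feasible
#'   optimal point in the original variables; `NA` otherwise).
#' @export
solve_lp <- function(obj, S, lb, ub, maximize = TRUE, tol = 1e-9) {
  S <- as.matrix(S)
  n <- ncol(S)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub)) stop("lower bound exceeds upper bound")

  # transform v = d*x + t per variable (split variables add a second column)
  cols <- list(); cost <- numeric(0); caps <- numeric(0)
  src <- integer(0)   # original variable of each column
  dsgn <- numeric(0)  # sign d of each column
  shift <- numeric(n) # t per original variable
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) {
      shift[j] <- lb[j]
      cols <- c(cols, list(S[, j]))
      cost <- c(cost, obj[j]); caps <- c(caps, ub[j] - lb[j])
      src <- c(src, j); dsgn <- c(dsgn, 1)
    } else if (is.finite(ub[j])) {
      shift[j] <- ub[j]
      cols <- c(cols, list(-S[, j]))
      cost <- c(cost, -obj[j]); caps <- c(caps, Inf)
      src <- c(src, j); dsgn <- c(dsgn, -1)
    } else {
      shift[j] <- 0
      cols <- c(cols, list(S[, j]), list(-S[, j]))
      cost <- c(cost, obj[j], -obj[j]); caps <- c(caps, Inf, Inf)
      src <- c(src, j, j); dsgn <- c(dsgn, 1, -1)
    }
  }
  A <- do.call(cbind, cols)
  b <- as.numeric(-S %*% shift)
  const <- sum(obj * shift)

  # drop all-zero constraint rows (isolated metabolites); a zero row with
  # nonzero rhs is infeasible outright
  rmax <- apply(abs(A), 1, max)
  if (any(rmax <= tol & abs(b) > tol)) {
    return(list(status = "infeasible", value = NA_real_, x = NA))
  }
  keep <- rmax > tol
  A <- A[keep, , drop = FALSE]; b <- b[keep]

  nx <- ncol(A)
  capped <- which(is.finite(caps))
  m1 <- nrow(A); m2 <- length(capped)
  # rows: m1 equalities S x = b, then m2 cap rows x_j + s_j = cap_j
  ncolsT <- nx + m2
  W <- matrix(0, m1 + m2, ncolsT)
  if (m1) W[seq_len(m1), seq_len(nx)] <- A
  rhs <- c(b, caps[capped])
  for (k in seq_along(capped)) {
    W[m1 + k, capped[k]] <- 1
    W[m1 + k, nx + k] <- 1
  }
  # normalize rhs >= 0 (only equality rows can be negative)
  negr <- which(rhs < 0)
  if (length(negr)) {
    W[negr, ] <- -W[negr, , drop = FALSE]
    rhs[negr] <- -rhs[negr]
  }

  # artificials on equality rows; cap-row slacks start basic
  nart <- m1
  if (nart) {
    Wart <- matrix(0, m1 + m2, nart)
    for (i in seq_len(m1)) Wart[i, i] <- 1
    W <- cbind(W, Wart)
  }
  ntot <- ncol(W)
  art_cols <- if (nart) (ncolsT + 1L):ntot else integer(0)
  basis <- integer(m1 + m2)
  if (m1) basis[seq_len(m1)] <- art_cols
  if (m2) basis[m1 + seq_len(m2)] <- nx + seq_len(m2)

  cost_full <- c(if (maximize) -cost else cost, rep(0, m2), rep(0, nart))

  run_simplex <- function(W, rhs, basis, cvec, allowed, tol) {
    maxit <- 2000L + 200L * length(basis)
    for (it in seq_len(maxit)) {
      cb <- cvec[basis]
      # reduced costs by full pricing
      red <- cvec - as.numeric(cb %*% W)
      red[basis] <- 0
      cand <- which(allowed & red < -tol)
      if (!length(cand)) {
        return(list(W = W, rhs = rhs, basis = basis, status = "optimal"))
      }
      enter <- cand[1L]  # Bland: smallest index
      colv <- W[, enter]
      pos <- which(colv > tol)
      if (!length(pos)) {
        return(list(W = W, rhs = rhs, basis = basis, status = "unbounded"))
      }
      ratios <- rhs[pos] / colv[pos]
      rmin <- min(ratios)
      tie <- pos[ratios <= rmin + tol]
      leave_row <- tie[which.min(basis[tie])]  # Bland tie-break
      piv <- W[leave_row, enter]
      W[leave_row, ] <- W[leave_row, ] / piv
      rhs[leave_row] <- rhs[leave_row] / piv
      for (i in seq_along(rhs)) {
        if (i != leave_row && abs(W[i, enter]) > 0) {
          f <- W[i, enter]
          W[i, ] <- W[i, ] - f * W[leave_row, ]
          rhs[i] <- rhs[i] - f * rhs[leave_row]
        }
      }
      rhs[abs(rhs) < tol] <- pmax(rhs[abs(rhs) < tol], 0)
      basis[leave_row] <- enter
    }
    list(W = W, rhs = rhs, basis = basis, status = "maxiter")
  }

  allowed <- rep(TRUE, ntot)
  if (nart) {
    c1 <- c(rep(0, ncolsT), rep(1, nart))
    r1 <- run_simplex(W, rhs, basis, c1, allowed, tol)
    if (r1$status == "maxiter") stop("LP solver: iteration limit in phase 1")
    W <- r1$W; rhs <- r1$rhs; basis <- r1$basis
    phase1_val <- sum(c1[basis] * rhs)
    if (phase1_val > 1e-7 * max(1, max(abs(b)))) {
      return(list(status = "infeasible", value = NA_real_, x = NA))
    }
    # drive residual zero-valued artificials out of the basis
    for (i in seq_along(basis)) {
      if (basis[i] %in% art_cols) {
        pivcol <- which(abs(W[i, seq_len(ncolsT)]) > tol)
        if (length(pivcol)) {
          enter <- pivcol[1L]
          piv <- W[i, enter]
          W[i, ] <- W[i, ] / piv; rhs[i] <- rhs[i] / piv
          for (k in seq_along(rhs)) {
            if (k != i && abs(W[k, enter]) > 0) {
              f <- W[k, enter]
              W[k, ] <- W[k, ] - f * W[i, ]
              rhs[k] <- rhs[k] - f * rhs[i]
            }
          }
          basis[i] <- enter
        }
        # else: redundant row; harmless to leave the artificial basic at 0
      }
    }
    allowed[art_cols] <- FALSE
  }

  r2 <- run_simplex(W, rhs, basis, cost_full, allowed, tol)
  if (r2$status == "maxiter") stop("LP solver: iteration limit in phase 2")
  if (r2$status == "unbounded") {
    return(list(status = "unbounded", value = NA_real_, x = NA))
  }
  basis <- r2$basis; rhs <- r2$rhs
  xfull <- numeric(ntot)
  xfull[basis] <- rhs
  xcols <- xfull[seq_len(nx)]
  v <- shift
  for (k in seq_len(nx)) v[src[k]] <- v[src[k]] + dsgn[k] * xcols[k]
  value <- sum(obj * v)
  list(status = "optimal", value = value, x = v)
}
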
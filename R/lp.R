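# Dense two-phase primal simplex with Bland's anti-cycling rule, for the
# small flux balance LPs this package solves:
#
#     max c'v   s.t.   S v = 0,   lb <= v <= ub   (all bounds finite)
#
# The problem is shifted to x = v - lb >= 0 and augmented with slack
# variables for the upper bounds, giving equality-only standard form.
# Bland's rule makes the solve deterministic and guarantees termination;
# problem sizes here (tens to a couple hundred variables) keep the dense
# tableau cheap.

# One Gauss-Jordan pivot on tableau M at (prow, pcol); basis updated.
.pivot <- function(M, basis, prow, pcol) {
  M[prow, ] <- M[prow, ] / M[prow, pcol]
  other <- setdiff(seq_len(nrow(M)), prow)
  M[other, ] <- M[other, ] - outer(M[other, pcol], M[prow, ])
  basis[prow] <- pcol
  list(M = M, basis = basis)
}

# Minimize cost'z over { A z = b, z >= 0 } starting from the given feasible
# basis (M = [A | b] already reduced so basic columns are identity).
# allowed: logical over columns eligible to enter. Returns the reduced
# tableau, basis, and status.
.simplex_iterate <- function(M, basis, cost, allowed, tol = 1e-9,
                             max_pivots = 100000L) {
  m <- nrow(M)
  ncols <- ncol(M) - 1L
  for (it in seq_len(max_pivots)) {
    red <- cost - as.vector(crossprod(cost[basis], M[, seq_len(ncols),
                                                     drop = FALSE]))
    entering <- which(allowed & red < -tol)
    if (!length(entering)) {
      return(list(M = M, basis = basis, status = "optimal"))
    }
    j <- min(entering)  # Bland: smallest eligible index
    col <- M[, j]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(M = M, basis = basis, status = "unbounded"))
    }
    ratios <- M[pos, ncols + 1L] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    prow <- cand[which.min(basis[cand])]  # Bland: smallest basic index leaves
    p <- .pivot(M, basis, prow, j)
    M <- p$M
    basis <- p$basis
  }
  list(M = M, basis = basis, status = "maxiter")
}

# Core solver; returns list(status, objective, v).
lp_simplex_bounded <- function(S, obj, lb, ub, tol = 1e-9) {
  n <- length(obj)
  stopifnot(ncol(S) == n, length(lb) == n, length(ub) == n,
            all(is.finite(lb)), all(is.finite(ub)), all(lb <= ub))
  rng <- ub - lb
  beq <- as.vector(-S %*% lb)
  Seq <- unname(S)
  flip <- beq < 0
  Seq[flip, ] <- -Seq[flip, , drop = FALSE]
  beq[flip] <- -beq[flip]
  m1 <- nrow(Seq)
  # columns: x (n) | s (n) | artificials (m1); rows: equalities then bounds
  ncols <- 2L * n + m1
  M <- matrix(0, nrow = m1 + n, ncol = ncols + 1L)
  M[seq_len(m1), seq_len(n)] <- Seq
  M[seq_len(m1), 2L * n + seq_len(m1)] <- diag(m1)
  M[m1 + seq_len(n), seq_len(n)] <- diag(n)
  M[m1 + seq_len(n), n + seq_len(n)] <- diag(n)
  M[, ncols + 1L] <- c(beq, rng)
  basis <- c(2L * n + seq_len(m1), n + seq_len(n))
  # phase 1: drive artificials to zero
  cost1 <- c(rep(0, 2L * n), rep(1, m1))
  allowed <- rep(TRUE, ncols)
  r1 <- .simplex_iterate(M, basis, cost1, allowed, tol)
  if (r1$status == "maxiter") {
    return(list(status = "maxiter", objective = NA_real_, v = NULL))
  }
  M <- r1$M
  basis <- r1$basis
  phase1_obj <- sum(cost1[basis] * M[, ncols + 1L])
  if (phase1_obj > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, v = NULL))
  }
  # pivot any residual (degenerate) artificial out of the basis
  art_cols <- 2L * n + seq_len(m1)
  drop_rows <- integer()
  for (i in seq_along(basis)) {
    if (basis[i] %in% art_cols) {
      piv <- which(abs(M[i, seq_len(2L * n)]) > tol)
      if (length(piv)) {
        p <- .pivot(M, basis, i, min(piv))
        M <- p$M
        basis <- p$basis
      } else {
        drop_rows <- c(drop_rows, i)  # redundant constraint
      }
    }
  }
  if (length(drop_rows)) {
    M <- M[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  allowed[art_cols] <- FALSE
  # phase 2: maximize obj = minimize -obj over x, slacks free of cost
  cost2 <- c(-obj, rep(0, n), rep(0, m1))
  r2 <- .simplex_iterate(M, basis, cost2, allowed, tol)
  if (r2$status != "optimal") {
    return(list(status = r2$status, objective = NA_real_, v = NULL))
  }
  M <- r2$M
  basis <- r2$basis
  z <- numeric(ncols)
  z[basis] <- M[, ncols + 1L]
  v <- z[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * v), v = v)
}
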
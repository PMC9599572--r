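# Independent oracles used across the suite. These deliberately avoid the
# package's own solver paths.

# Brute-force LP oracle: enumerate basic feasible solutions (vertices) of
# { S v = 0, lb <= v <= ub } by fixing n - rank(S) variables at a bound and
# solving the equality system for the rest; return the best objective.
brute_force_fba <- function(S, obj, lb, ub, tol = 1e-7) {
  n <- ncol(S)
  r <- qr(S)$rank
  k <- n - r
  best <- -Inf
  best_v <- NULL
  consider <- function(v) {
    if (max(abs(S %*% v)) > tol) return()
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    val <- sum(obj * v)
    if (val > best + 1e-9) {
      best <<- val
      best_v <<- v
    }
  }
  if (k == 0L) {
    v <- rep(0, n)
    consider(v)
    return(list(objective = best, v = best_v))
  }
  for (fix in utils::combn(n, k, simplify = FALSE)) {
    free <- setdiff(seq_len(n), fix)
    Sf <- S[, free, drop = FALSE]
    if (qr(Sf)$rank < length(free)) next
    bounds <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    for (gi in seq_len(nrow(bounds))) {
      at_ub <- unlist(bounds[gi, ])
      v_fix <- ifelse(at_ub, ub[fix], lb[fix])
      rhs <- -S[, fix, drop = FALSE] %*% v_fix
      v_free <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
      if (is.null(v_free)) next
      v <- numeric(n)
      v[fix] <- v_fix
      v[free] <- v_free
      consider(v)
    }
  }
  list(objective = best, v = best_v)
}

# Oracle wrapper operating on a model + medium like run_fba does.
brute_force_growth <- function(model, medium) {
  S <- stoich_matrix(model)
  bnd <- commniche:::medium_bounds(model, medium)
  obj <- as.numeric(colnames(S) %in% model$biomass_id)
  brute_force_fba(S, obj, unname(bnd$lb), unname(bnd$ub))$objective
}

# Spearman rank correlation from first principles: average ranks for ties,
# then the Pearson product-moment formula on the ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Brute-force minimal gapfill cardinality: try every subset of the
# universal's candidate reactions up to max_k.
brute_force_min_additions <- function(model, medium, universal, max_k = 3,
                                      threshold = 1e-6) {
  cand <- commniche:::gapfill_candidates(model, universal)
  if (predicts_growth(model, medium, threshold)) return(0L)
  for (k in seq_len(min(max_k, length(cand)))) {
    for (s in utils::combn(cand, k, simplify = FALSE)) {
      m2 <- commniche:::add_reactions(model, s, universal)
      if (predicts_growth(m2, medium, threshold)) return(k)
    }
  }
  NA_integer_
}
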
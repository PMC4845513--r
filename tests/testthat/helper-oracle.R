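# Brute-force LP oracle: enumerate the vertices of {S v = 0, lb <= v <= ub}
# by fixing every choice of (n - rank(S)) variables at a bound and solving
# the remaining square system. Independent of the package's solver path;
# only usable for small networks (<= ~10 reactions).
oracle_fba_optimum <- function(model, objective = model$objective_id) {
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  cc <- as.numeric(model$reactions$id == objective)
  n <- ncol(S)
  r <- qr(S)$rank
  k <- n - r
  best <- -Inf
  subsets <- utils::combn(n, k, simplify = FALSE)
  for (cols in subsets) {
    basis <- setdiff(seq_len(n), cols)
    B <- S[, basis, drop = FALSE]
    if (qr(B)$rank < r) next
    for (mask in 0:(2^k - 1)) {
      at_ub <- bitwAnd(mask, 2^(seq_len(k) - 1)) > 0
      vals <- ifelse(at_ub, ub[cols], lb[cols])
      rhs <- -as.vector(S[, cols, drop = FALSE] %*% vals)
      x <- tryCatch(qr.solve(B, rhs, tol = 1e-12), error = function(e) NULL)
      if (is.null(x)) next
      if (max(abs(as.vector(B %*% x) - rhs)) > 1e-8) next
      if (any(x < lb[basis] - 1e-9) || any(x > ub[basis] + 1e-9)) next
      v <- numeric(n); v[cols] <- vals; v[basis] <- x
      obj <- sum(cc * v)
      if (obj > best) best <- obj
    }
  }
  best
}
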
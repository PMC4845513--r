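# Linear-programming backend.
#
# Every constraint-based problem in the package reduces to
#   min / max  c'v   s.t.  A_eq v = b_eq,  A_ub v <= b_ub,  lb <= v <= ub
# with all bounds finite (infinities are clamped to +/-1000 flux units at the
# model layer, so the LP is always bounded). Variables fixed by lb == ub are
# eliminated before solving; the rest are shifted to x = v - lb >= 0 and
# handed to boot::simplex, which wants non-negative variables and
# non-negative right-hand sides.

solve_lp <- function(objective, A_eq = NULL, b_eq = NULL,
                     A_ub = NULL, b_ub = NULL,
                     lb, ub, maximize = TRUE, eps = 1e-10) {
  n <- length(objective)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_, solution = rep(NA_real_, n)))
  }
  # presolve: an equality row with a single non-fixed variable pins that
  # variable; eliminate such rows iteratively (this also removes much of the
  # degeneracy that troubles the simplex phase 1)
  if (!is.null(A_eq) && nrow(A_eq) > 0) {
    repeat {
      fixed <- (ub - lb) < 1e-12
      resid <- b_eq - as.vector(A_eq[, fixed, drop = FALSE] %*% lb[fixed])
      live <- abs(A_eq) > 1e-12
      live[, fixed] <- FALSE
      counts <- rowSums(live)
      singles <- which(counts == 1)
      if (length(singles) == 0) break
      changed <- FALSE
      for (i in singles) {
        j <- which(live[i, ])[1]
        val <- resid[i] / A_eq[i, j]
        if (val < lb[j] - 1e-9 || val > ub[j] + 1e-9) {
          return(list(status = "infeasible", objective = NA_real_,
                      solution = rep(NA_real_, n)))
        }
        val <- min(max(val, lb[j]), ub[j])
        if (ub[j] - lb[j] >= 1e-12) {
          lb[j] <- ub[j] <- val
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  fixed <- (ub - lb) < 1e-12
  vfix <- lb
  free <- which(!fixed)

  obj_const <- sum(objective[fixed] * vfix[fixed])
  if (!is.null(A_eq) && nrow(A_eq) > 0) {
    b_eq <- b_eq - as.vector(A_eq[, fixed, drop = FALSE] %*% vfix[fixed])
  }
  if (!is.null(A_ub) && nrow(A_ub) > 0) {
    b_ub <- b_ub - as.vector(A_ub[, fixed, drop = FALSE] %*% vfix[fixed])
  }

  if (length(free) == 0) {
    feasible <- TRUE
    if (!is.null(A_eq) && nrow(A_eq) > 0) feasible <- all(abs(b_eq) <= 1e-7)
    if (feasible && !is.null(A_ub) && nrow(A_ub) > 0) feasible <- all(b_ub >= -1e-7)
    return(list(
      status = if (feasible) "optimal" else "infeasible",
      objective = if (feasible) obj_const else NA_real_,
      solution = vfix
    ))
  }

  cc <- objective[free]
  lo <- lb[free]
  # shift: x = v_free - lo >= 0
  A3 <- NULL; b3 <- NULL
  if (!is.null(A_eq) && nrow(A_eq) > 0) {
    A3 <- A_eq[, free, drop = FALSE]
    b3 <- b_eq - as.vector(A3 %*% lo)
    # rows with no free variable are satisfied or not by the fixed part alone
    zero_row <- apply(abs(A3), 1, max) < 1e-12
    if (any(zero_row)) {
      if (any(abs(b3[zero_row]) > 1e-7)) {
        return(list(status = "infeasible", objective = NA_real_,
                    solution = rep(NA_real_, n)))
      }
      A3 <- A3[!zero_row, , drop = FALSE]
      b3 <- b3[!zero_row]
    }
    # the simplex phase-1 basis needs full row rank: drop linearly dependent
    # balance rows (e.g. conserved moiety pairs); a dropped row whose
    # right-hand side is inconsistent with the kept ones means infeasibility
    if (nrow(A3) > 1) {
      dec <- qr(t(A3))
      if (dec$rank < nrow(A3)) {
        aug <- qr(t(cbind(A3, b3)))
        if (aug$rank > dec$rank) {
          return(list(status = "infeasible", objective = NA_real_,
                      solution = rep(NA_real_, n)))
        }
        keep <- sort(dec$pivot[seq_len(dec$rank)])
        A3 <- A3[keep, , drop = FALSE]
        b3 <- b3[keep]
      }
    }
    if (nrow(A3) == 0) { A3 <- NULL; b3 <- NULL }
    if (!is.null(A3)) {
      neg <- b3 < 0
      A3[neg, ] <- -A3[neg, , drop = FALSE]
      b3[neg] <- -b3[neg]
    }
  }
  # upper bounds as <= rows
  A1 <- diag(length(free))
  b1 <- ub[free] - lo
  A2 <- NULL; b2 <- NULL
  if (!is.null(A_ub) && nrow(A_ub) > 0) {
    Au <- A_ub[, free, drop = FALSE]
    bu <- b_ub - as.vector(Au %*% lo)
    pos <- bu >= 0
    if (any(pos)) { A1 <- rbind(A1, Au[pos, , drop = FALSE]); b1 <- c(b1, bu[pos]) }
    if (any(!pos)) { A2 <- -Au[!pos, , drop = FALSE]; b2 <- -bu[!pos] }
  }

  n_con <- length(b1) + length(b2) + length(b3)
  fit <- boot::simplex(
    a = cc, A1 = A1, b1 = b1, A2 = A2, b2 = b2, A3 = A3, b3 = b3,
    maxi = maximize, eps = eps,
    n.iter = max(200L, 30L * (length(free) + n_con))
  )
  if (fit$solved == 0) {
    return(list(status = "iteration_limit", objective = NA_real_,
                solution = rep(NA_real_, n)))
  }
  if (fit$solved < 0) {
    return(list(status = "infeasible", objective = NA_real_,
                solution = rep(NA_real_, n)))
  }
  v <- vfix
  v[free] <- fit$soln + lo
  list(status = "optimal",
       objective = sum(objective * v),
       solution = v)
}
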
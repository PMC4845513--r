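# Flux balance analysis, flux variability analysis, and geometric FBA.

# build and solve one FBA-style LP on a model; `lb`/`ub` override the model
# bounds when supplied (used by FVA and geometric FBA to tighten the face)
.fba_lp <- function(model, objective = model$objective_id, maximize = TRUE,
                    lb = NULL, ub = NULL) {
  S <- stoich_matrix(model)
  rxns <- model$reactions$id
  if (is.null(lb)) lb <- model$reactions$lower_bound
  if (is.null(ub)) ub <- model$reactions$upper_bound
  cc <- as.numeric(rxns == objective)
  res <- solve_lp(cc, A_eq = S, b_eq = rep(0, nrow(S)), lb = lb, ub = ub,
                  maximize = maximize)
  res$reactions <- rxns
  res
}

new_fba_result <- function(status, objective_value, fluxes, model,
                           method, iterations = NA_integer_) {
  structure(
    list(
      status = status,
      objective_value = objective_value,
      fluxes = fluxes,
      objective_id = model$objective_id,
      model_id = model$id,
      method = method,
      iterations = iterations
    ),
    class = "fba_result"
  )
}

#' @export
print.fba_result <- function(x, ...) {
  cat(sprintf("<fba_result> method %s, status %s", x$method, x$status))
  if (x$status == "optimal") {
    cat(sprintf(", objective %s = %.6g", x$objective_id, x$objective_value))
  }
  cat("\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the model's objective reaction (typically the biomass
#' pseudo-reaction, whose flux is the growth rate) subject to steady-state
#' mass balance `S v = 0` and the flux bounds. When the optimum is
#' degenerate the individual fluxes of the returned vertex solution are not
#' unique -- only the objective value is; use [geometric_fba()] for a unique
#' central distribution.
#'
#' @param model a [metabolic_model()] with `objective_id` set.
#' @return An `fba_result`: status (`"optimal"`, `"infeasible"` or
#'   `"iteration_limit"`), objective value, and a flux tibble via [tidy()].
#'   Infeasibility is a status, not an error.
#' @export
#' @examples
#' toy <- make_toy(toy_spec())
#' solve_fba(toy$model)$objective_value  # 11.2
solve_fba <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.na(model$objective_id)) abort("model has no objective reaction")
  res <- .fba_lp(model)
  fluxes <- tibble(reaction_id = res$reactions, flux = res$solution)
  new_fba_result(res$status,
                 if (res$status == "optimal") res$objective else NA_real_,
                 fluxes, model, method = "fba")
}

#' Flux variability analysis
#'
#' Minimum and maximum flux attainable by each reaction while the objective
#' is held at (a fraction of) its optimum. With `optimum_fraction = 1` the
#' objective is fixed as an equality (within 1e-9), so the ranges describe
#' the optimal face; smaller fractions impose a one-sided cut.
#'
#' @inheritParams solve_fba
#' @param optimum_fraction fraction of the FBA optimum the objective must
#'   retain, in (0, 1]; 0 is accepted and makes the cut vacuous.
#' @param reactions reaction ids to scan (default: all).
#' @return A tibble (class `fva_ranges`) with `reaction_id`, `min_flux`,
#'   `max_flux`; the FBA optimum is stored in attribute `optimum`.
#' @export
flux_variability <- function(model, optimum_fraction = 1, reactions = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  base <- solve_fba(model)
  if (base$status != "optimal") {
    abort(sprintf("FBA status '%s'; cannot run FVA", base$status))
  }
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  i_obj <- match(model$objective_id, model$reactions$id)
  if (optimum_fraction >= 1) {
    lb[i_obj] <- base$objective_value - 1e-9
    ub[i_obj] <- min(ub[i_obj], base$objective_value + 1e-9)
  } else if (optimum_fraction > 0) {
    lb[i_obj] <- max(lb[i_obj], optimum_fraction * base$objective_value)
  }
  if (is.null(reactions)) reactions <- model$reactions$id
  rng <- purrr::map(reactions, function(rid) {
    lo <- .fba_lp(model, objective = rid, maximize = FALSE, lb = lb, ub = ub)
    hi <- .fba_lp(model, objective = rid, maximize = TRUE, lb = lb, ub = ub)
    if (lo$status != "optimal" || hi$status != "optimal") {
      abort(sprintf("FVA subproblem for '%s' returned status '%s'",
                    rid, if (lo$status != "optimal") lo$status else hi$status))
    }
    tibble(reaction_id = rid, min_flux = lo$objective, max_flux = hi$objective)
  })
  out <- bind_rows(rng)
  attr(out, "optimum") <- base$objective_value
  class(out) <- c("fva_ranges", class(out))
  out
}

#' Geometric flux balance analysis
#'
#' Returns the unique flux distribution central to the set of alternate
#' optima: the objective is fixed at the FBA optimum, then the optimal face
#' is contracted iteratively -- (i) per-reaction flux ranges (FVA) over the
#' current face, (ii) an L1 projection onto the range midpoints, (iii)
#' contraction of every open range to its reach within the set of
#' L1-optimal solutions (a total-deviation budget constraint) -- until every
#' range is narrower than `tol`. The budget step collapses all ranges at
#' once when the midpoint vector is feasible and halves open ranges
#' symmetrically when the projection has ties, so the result is independent
#' of reaction ordering (within `tol`), splits interchangeable pathways
#' equally, and its objective equals the plain FBA optimum.
#'
#' @inheritParams solve_fba
#' @param tol convergence tolerance on range width (flux units).
#' @param max_iter maximum contraction passes.
#' @return An `fba_result` with `method = "geometric_fba"`.
#' @export
#' @examples
#' toy2 <- make_toy(toy_spec(n_pathways = 2))
#' g <- geometric_fba(toy2$model)
#' tidy(g)  # duplicate pathways split equally
geometric_fba <- function(model, tol = 1e-6, max_iter = 50) {
  stopifnot(inherits(model, "metabolic_model"))
  base <- solve_fba(model)
  if (base$status != "optimal") {
    return(new_fba_result(base$status, NA_real_, base$fluxes, model,
                          method = "geometric_fba"))
  }
  S <- stoich_matrix(model)
  rxns <- model$reactions$id
  n <- length(rxns)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  i_obj <- match(model$objective_id, rxns)
  lb[i_obj] <- base$objective_value - 1e-9
  ub[i_obj] <- min(ub[i_obj], base$objective_value + 1e-9)

  # initial FVA over the optimal face
  for (k in seq_len(n)) {
    if (ub[k] - lb[k] < 1e-12) next
    lo <- .fba_lp(model, objective = rxns[k], maximize = FALSE, lb = lb, ub = ub)
    hi <- .fba_lp(model, objective = rxns[k], maximize = TRUE, lb = lb, ub = ub)
    if (lo$status != "optimal" || hi$status != "optimal") {
      abort(sprintf("geometric FBA: FVA subproblem for '%s' failed", rxns[k]))
    }
    lb[k] <- lo$objective
    ub[k] <- min(hi$objective, ub[k])
    if (lb[k] > ub[k]) lb[k] <- ub[k] <- (lb[k] + ub[k]) / 2
  }

  iter <- 0L
  while (any(ub - lb >= tol)) {
    iter <- iter + 1L
    if (iter > max_iter) {
      abort(sprintf(
        "geometric FBA did not converge in %d iterations (%d reactions open, max width %.3g)",
        max_iter, sum(ub - lb >= tol), max(ub - lb)))
    }
    mid <- (lb + ub) / 2

    # L1 projection onto the midpoints: v = mid + p - q with p, q >= 0,
    # p <= ub - mid, q <= mid - lb, minimizing the total deviation D = sum(p+q);
    # the bounds on p and q imply lb <= v <= ub
    cc <- rep(1, 2 * n)
    A_eq <- cbind(S, -S)
    b_eq <- -as.vector(S %*% mid)
    p_ub <- pmax(ub - mid, 0)
    q_ub <- pmax(mid - lb, 0)
    res <- solve_lp(cc, A_eq = A_eq, b_eq = b_eq,
                    lb = rep(0, 2 * n), ub = c(p_ub, q_ub), maximize = FALSE)
    if (res$status != "optimal") {
      abort(sprintf("geometric FBA: centering LP returned status '%s'", res$status))
    }
    d_star <- res$objective

    # contract each range to the reach of the L1-optimal set: min/max v_k
    # subject to the deviation budget sum(p + q) <= D*. When the midpoint is
    # feasible (D* = 0) this collapses every range at once; with degenerate
    # ties it halves the open ranges symmetrically, so the contraction never
    # depends on reaction order.
    budget <- matrix(1, nrow = 1, ncol = 2 * n)
    for (k in which(ub - lb >= tol)) {
      ck <- numeric(2 * n); ck[k] <- 1; ck[n + k] <- -1
      lo <- solve_lp(ck, A_eq = A_eq, b_eq = b_eq,
                     A_ub = budget, b_ub = d_star + 1e-9,
                     lb = rep(0, 2 * n), ub = c(p_ub, q_ub), maximize = FALSE)
      hi <- solve_lp(ck, A_eq = A_eq, b_eq = b_eq,
                     A_ub = budget, b_ub = d_star + 1e-9,
                     lb = rep(0, 2 * n), ub = c(p_ub, q_ub), maximize = TRUE)
      if (lo$status != "optimal" || hi$status != "optimal") {
        abort(sprintf("geometric FBA: budget FVA for '%s' failed", rxns[k]))
      }
      new_l <- mid[k] + lo$objective
      new_u <- mid[k] + hi$objective
      lb[k] <- max(lb[k], new_l)
      ub[k] <- min(ub[k], new_u)
      if (lb[k] > ub[k]) lb[k] <- ub[k] <- (lb[k] + ub[k]) / 2
    }
  }

  v <- (lb + ub) / 2
  fluxes <- tibble(reaction_id = rxns, flux = v)
  new_fba_result("optimal", v[i_obj], fluxes, model,
                 method = "geometric_fba", iterations = iter)
}

#' Flux table of an FBA result
#'
#' @param x an `fba_result`.
#' @param ... unused.
#' @return A tibble with `reaction_id` and `flux`.
#' @export
tidy.fba_result <- function(x, ...) {
  x$fluxes
}

#' One-row FBA result summary
#'
#' @param x an `fba_result`.
#' @param ... unused.
#' @return A tibble with model, method, status, and objective value.
#' @export
glance.fba_result <- function(x, ...) {
  tibble(model_id = x$model_id, method = x$method, status = x$status,
         objective_id = x$objective_id, objective_value = x$objective_value,
         iterations = x$iterations)
}

#' Plot flux variability ranges
#'
#' One horizontal range per reaction; degenerate ranges (unique flux at the
#' optimum) collapse to a point.
#'
#' @param object an `fva_ranges` tibble from [flux_variability()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fva_ranges <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(y = .data$reaction_id)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$min_flux,
                                         xmax = .data$max_flux),
                            linewidth = 1.5, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(x = (.data$min_flux + .data$max_flux) / 2),
                        size = 1) +
    ggplot2::labs(x = "flux (mmol gDW^-1 h^-1)", y = NULL,
                  title = "Flux variability at the optimum") +
    ggplot2::theme_minimal()
}
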
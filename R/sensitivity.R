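# Single-component and maintenance sensitivity of growth-rate predictions.

#' Perturb one biomass coefficient
#'
#' Multiplies a single coefficient by `factor`, leaving every other
#' component and the GAM untouched. The composition is deliberately NOT
#' renormalized afterwards, so one flux unit of biomass no longer weighs
#' exactly 1 g; [bof_mass()] reports the effective mass.
#'
#' @param composition a [biomass_composition()].
#' @param component_id component to perturb.
#' @param factor positive multiplier (0.7 and 1.3 for the standard +/-30%
#'   scan).
#' @return The perturbed `biomass_composition`.
#' @export
perturb_component <- function(composition, component_id, factor) {
  stopifnot(inherits(composition, "biomass_composition"))
  if (factor <= 0) abort("factor must be > 0")
  i <- match(component_id, composition$metabolite_id)
  if (is.na(i)) abort(sprintf("unknown component '%s'", component_id))
  out <- composition
  out$coefficient[i] <- out$coefficient[i] * factor
  new_biomass_composition(as_tibble(out), bof_id(composition), bof_gam(composition))
}

#' Growth-rate sensitivity to single biomass components
#'
#' Varies each biomass coefficient independently by the given factors
#' (default 30% down and up), re-solves the growth optimum, and reports the
#' relative growth-rate change against the unperturbed reference. Per-
#' component infeasibilities are recorded by status and the scan continues.
#'
#' @param model a constrained [metabolic_model()] (nutrients and
#'   maintenance already applied, biomass reaction not yet built).
#' @param composition the reference [biomass_composition()].
#' @param factors multipliers applied to each coefficient in turn.
#' @param gam,gam_species passed to [build_biomass_reaction()]; GAM is held
#'   constant across all perturbations.
#' @param solver `"fba"` (default; the optimum value is unique, and only
#'   the objective is reported) or `"geometric"`.
#' @return A `sensitivity_records` tibble: `component_id`, `factor`,
#'   `direction`, `status`, `growth_rate`, `relative_change` (percent, vs
#'   the reference growth stored in attribute `reference_growth`).
#' @export
component_sensitivity <- function(model, composition, factors = c(0.7, 1.3),
                                  gam = bof_gam(composition), gam_species = NULL,
                                  solver = c("fba", "geometric")) {
  solver <- match.arg(solver)
  run <- function(bof) {
    m <- build_biomass_reaction(model, bof, gam = gam, gam_species = gam_species)
    if (solver == "geometric") geometric_fba(m) else solve_fba(m)
  }
  ref <- run(composition)
  if (ref$status != "optimal") {
    abort(sprintf("reference scenario not solvable (status '%s')", ref$status))
  }
  g0 <- ref$objective_value
  grid <- tidyr::expand_grid(component_id = composition$metabolite_id,
                             factor = factors)
  out <- pmap(grid, function(component_id, factor) {
    res <- run(perturb_component(composition, component_id, factor))
    g <- if (res$status == "optimal") res$objective_value else NA_real_
    tibble(component_id = component_id, factor = factor,
           direction = if (factor < 1) "down" else if (factor > 1) "up" else "unchanged",
           status = res$status, growth_rate = g,
           relative_change = (g - g0) / g0 * 100)
  }) |> bind_rows()
  attr(out, "reference_growth") <- g0
  class(out) <- c("sensitivity_records", class(out))
  out
}

#' Maintenance-cost scan
#'
#' Solves the growth optimum under the four maintenance configurations --
#' (i) none, (ii) GAM only, (iii) NGAM only, (iv) GAM and NGAM -- and
#' reports each growth rate with its percent difference from the full
#' configuration (iv). When no configuration changes the growth rate the
#' model is flagged maintenance-insensitive (attribute
#' `maintenance_insensitive`), the signature of a futile energy-generating
#' cycle.
#'
#' @inheritParams component_sensitivity
#' @param gam_species as in [build_biomass_reaction()].
#' @param ngam_id reaction id of the NGAM drain in `model`.
#' @param gam_ref,ngam_ref the full-maintenance values for configuration
#'   (iv).
#' @param tol relative tolerance (percent) below which a growth difference
#'   counts as zero for the insensitivity flag.
#' @return A `maintenance_scan` tibble: `label` (none/gam_only/ngam_only/
#'   both), `gam`, `ngam`, `status`, `growth_rate`,
#'   `pct_diff_vs_both`.
#' @export
maintenance_scan <- function(model, composition, ngam_id, gam_ref, ngam_ref,
                             gam_species = NULL, tol = 1e-4,
                             solver = c("geometric", "fba")) {
  solver <- match.arg(solver)
  stopifnot(inherits(model, "metabolic_model"))
  if (!is.null(ngam_id) && !ngam_id %in% model$reactions$id) {
    abort(sprintf("unknown NGAM reaction '%s'", ngam_id))
  }
  cases <- tibble(
    label = c("none", "gam_only", "ngam_only", "both"),
    gam = c(0, gam_ref, 0, gam_ref),
    ngam = c(0, 0, ngam_ref, ngam_ref)
  )
  runs <- pmap(cases, function(label, gam, ngam) {
    m <- model
    if (!is.null(ngam_id)) m <- fix_flux(m, ngam_id, ngam)
    res <- tryCatch({
      m <- build_biomass_reaction(m, composition, gam = gam,
                                  gam_species = gam_species)
      if (solver == "geometric") geometric_fba(m) else solve_fba(m)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      return(tibble(label = label, gam = gam, ngam = ngam,
                    status = paste("error:", conditionMessage(res)),
                    growth_rate = NA_real_))
    }
    tibble(label = label, gam = gam, ngam = ngam, status = res$status,
           growth_rate = if (res$status == "optimal") res$objective_value
                         else NA_real_)
  })
  out <- bind_rows(runs)
  g_both <- out$growth_rate[out$label == "both"]
  if (is.na(g_both)) abort("the full-maintenance configuration (iv) is not solvable")
  out$pct_diff_vs_both <- (out$growth_rate - g_both) / g_both * 100
  class(out) <- c("maintenance_scan", class(out))
  attr(out, "maintenance_insensitive") <-
    all(abs(out$pct_diff_vs_both) <= tol, na.rm = TRUE) &&
    !any(is.na(out$growth_rate))
  out
}

#' Correlation between growth-rate change and coefficient size
#'
#' Pearson correlation between the magnitude of the growth-rate changes
#' from a +/-30% component scan (up and down records pooled) and each
#' component's fractional coefficient, either in carbon-atom terms
#' ([carbon_fraction()]) or in weight terms (`c_i MW_i / sum c_j MW_j`).
#' The signed variant is reported alongside. With zero variance on either
#' axis the correlation is undefined and flagged as such rather than
#' returned as 0.
#'
#' @param records a `sensitivity_records` tibble from
#'   [component_sensitivity()].
#' @param composition the reference [biomass_composition()] (source of the
#'   fractional coefficients).
#' @param basis `"carbon"` or `"weight"`.
#' @return A one-row tibble: `basis`, `n`, `r` (on `|relative_change|`),
#'   `r_signed`, `defined`.
#' @export
growth_coefficient_correlation <- function(records, composition,
                                           basis = c("carbon", "weight")) {
  basis <- match.arg(basis)
  stopifnot(inherits(records, "sensitivity_records"))
  frac <- if (basis == "carbon") {
    cf <- carbon_fraction(composition)
    setNames(cf$carbon_fraction, cf$metabolite_id)
  } else {
    if (any(is.na(composition$mw))) abort("molecular weights required for weight basis")
    w <- composition$coefficient * composition$mw
    setNames(w / sum(w), composition$metabolite_id)
  }
  rec <- filter(records, !is.na(.data$relative_change))
  x <- unname(frac[rec$component_id])
  y_abs <- abs(rec$relative_change)
  n <- nrow(rec)
  if (n < 3) abort("need at least 3 records with a solved growth rate")
  if (sd(x) == 0 || sd(y_abs) == 0) {
    return(tibble(basis = basis, n = n, r = NA_real_, r_signed = NA_real_,
                  defined = FALSE))
  }
  tibble(basis = basis, n = n,
         r = cor(x, y_abs),
         r_signed = if (sd(rec$relative_change) > 0) cor(x, rec$relative_change)
                    else NA_real_,
         defined = TRUE)
}

#' Tornado plot of component sensitivities
#'
#' @param object a `sensitivity_records` tibble.
#' @param ... unused.
#' @return A ggplot bar chart of relative growth change per component and
#'   direction.
#' @export
autoplot.sensitivity_records <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$relative_change, y = .data$component_id,
                               fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "growth-rate change vs reference (%)", y = NULL,
                  fill = "coefficient") +
    ggplot2::theme_minimal()
}
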
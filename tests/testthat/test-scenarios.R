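toy_constraints <- function(uptake = 10, ngam = 2) {
  constraint_set("EX_G", uptake, ngam_id = "NGAM", ngam_value = ngam)
}

test_that("apply_constraints sets uptake and maintenance and is idempotent", {
  toy <- make_toy(toy_spec(uptake_bound = 99, ngam = 0.5))
  m <- apply_constraints(toy$model, toy_constraints())
  expect_equal(m$reactions$upper_bound[m$reactions$id == "EX_G"], 10)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "NGAM"], 2)
  expect_equal(solve_fba(m)$objective_value, 11.2, tolerance = 1e-9)
  m2 <- apply_constraints(m, toy_constraints())
  expect_models_equal(m, m2)
  expect_error(apply_constraints(toy$model, constraint_set("no_such_exchange")),
               "missing reactions")
})

test_that("maintenance beyond the energy supply makes the scenario infeasible", {
  toy <- make_toy(toy_spec())
  m <- apply_constraints(toy$model, toy_constraints(uptake = 1, ngam = 50))
  expect_equal(solve_fba(m)$status, "infeasible")
})

test_that("a single model with its own composition reproduces the standalone run", {
  toy <- make_toy(toy_spec())
  res <- run_matrix(list(remove_biomass_reaction(toy$model)),
                    list(toy$composition), toy_constraints())
  expect_equal(nrow(res), 1)
  expect_equal(res$scenario_id, "toy-toyBOF")
  expect_true(res$is_reference)
  expect_equal(res$growth_rate, geometric_fba(toy$model)$objective_value,
               tolerance = 1e-9)
})

test_that("structurally identical models collapse the model axis", {
  tA <- make_toy(toy_spec(), id = "dupA")
  tB <- make_toy(toy_spec(), id = "dupB")
  bofs <- list(tA$composition,
               biomass_composition(
                 tibble::tibble(metabolite_id = c("G", "E"),
                                coefficient = c(1.2, 0.4)), id = "altBOF"))
  res <- run_matrix(list(remove_biomass_reaction(tA$model),
                         remove_biomass_reaction(tB$model)),
                    bofs, toy_constraints())
  expect_equal(nrow(res), 4)
  wide <- tidyr::pivot_wider(res[, c("model_id", "bof_id", "growth_rate")],
                             names_from = "model_id", values_from = "growth_rate")
  expect_equal(wide$dupA, wide$dupB, tolerance = 1e-9)
})

test_that("a heavier composition grows slower in the same model", {
  toy <- make_toy(toy_spec())
  bof_a <- toy$composition
  bof_b <- perturb_component(bof_a, "G", 2)
  attr(bof_b, "bof_id") <- "heavyBOF"
  res <- run_matrix(list(remove_biomass_reaction(toy$model)),
                    list(bof_a, bof_b), toy_constraints(), reference = NULL)
  g <- setNames(res$growth_rate, res$bof_id)
  expect_lt(g[["heavyBOF"]], g[["toyBOF"]])
})

test_that("infeasible scenarios are recorded and the matrix run continues", {
  ok <- make_toy(toy_spec(), id = "okM")
  # this model cannot satisfy the drain once constrained to uptake 10
  starved <- make_toy(toy_spec(), id = "poorM")
  starved_m <- set_bounds(remove_biomass_reaction(starved$model), "EX_G", 0, 0)
  cs <- list(okM = toy_constraints(),
             poorM = constraint_set("EX_G", 0, ngam_id = "NGAM", ngam_value = 2))
  res <- run_matrix(list(remove_biomass_reaction(ok$model), starved_m),
                    list(ok$composition), cs, restrict = FALSE)
  expect_equal(res$status[res$model_id == "okM"], "optimal")
  expect_equal(res$status[res$model_id == "poorM"], "infeasible")
  expect_true(is.na(res$growth_rate[res$model_id == "poorM"]))
})

test_that("central flux extraction maps, lumps, and marks absences", {
  toy2 <- make_toy(toy_spec(n_pathways = 2))
  g <- geometric_fba(toy2$model)
  map <- data.frame(
    label = c("uptake", "catabolism", "growth", "missing_enzyme"),
    reaction_ids = c("EX_G", "CAT;CAT2", "Biomass", "EC_0.0.0.0")
  )
  cf <- extract_central_fluxes(g, map)
  expect_equal(nrow(cf), 4)
  expect_equal(cf$flux[cf$label == "catabolism"], 4.4, tolerance = 1e-6)
  expect_true(is.na(cf$flux[cf$label == "missing_enzyme"]))
  expect_equal(cf$flux[cf$label == "uptake"], 10, tolerance = 1e-6)
})

test_that("dispersion summary computes sample SDs and their medians", {
  # two reactions over three scenarios: fluxes (1,2,3) -> SD 1, (0,0,0) -> 0,
  # (2,4,6) -> 2; medians over reactions follow
  central <- tibble::tibble(
    scenario_id = rep(c("s1", "s2", "s3"), each = 2),
    model_id = rep(c("m1", "m2", "m3"), each = 2),
    bof_id = "b",
    label = rep(c("r1", "r2"), 3),
    flux = c(1, 0, 2, 0, 3, 0)
  )
  d <- dispersion_summary(central, "same_bof_across_models")
  expect_equal(d$per_reaction$sd[d$per_reaction$label == "r1"], 1)
  expect_equal(d$per_reaction$sd[d$per_reaction$label == "r2"], 0)
  expect_equal(d$medians$median_sd, 0.5)
  central2 <- central
  central2$flux <- c(0, 2, 0, 4, 0, 6)
  d2 <- dispersion_summary(central2, "same_bof_across_models")
  expect_equal(d2$medians$median_sd, (0 + 2) / 2)
  # permutation invariance in scenario order
  shuffled <- central2[sample(nrow(central2)), ]
  d3 <- dispersion_summary(shuffled, "same_bof_across_models")
  expect_equal(dplyr::arrange(d3$per_reaction, label),
               dplyr::arrange(d2$per_reaction, label))
  # identical scenarios give zero dispersion
  same <- central
  same$flux <- rep(c(5, 7), 3)
  expect_equal(dispersion_summary(same, "same_bof_across_models")$medians$median_sd, 0)
  # population SD option changes the n-1 denominator
  dp <- dispersion_summary(central, "same_bof_across_models", sd_type = "population")
  expect_equal(dp$per_reaction$sd[dp$per_reaction$label == "r1"],
               sqrt(2 / 3))
  # group of one is an error
  expect_error(dispersion_summary(central[1:2, ], "same_bof_across_models"),
               "at least two")
})

test_that("NA fluxes are excluded pairwise from dispersions", {
  central <- tibble::tibble(
    scenario_id = c("s1", "s2", "s3"),
    model_id = c("m1", "m2", "m3"),
    bof_id = "b",
    label = "r1",
    flux = c(1, NA, 3)
  )
  d <- dispersion_summary(central, "same_bof_across_models")
  expect_equal(d$per_reaction$sd, sd(c(1, 3)))
  expect_equal(d$per_reaction$n, 2L)
})

test_that("FVA overlap classification applies the pairwise-disjoint rule", {
  mk <- function(...) {
    v <- list(...)
    structure(tibble::tibble(
      reaction_id = names(v),
      min_flux = purrr::map_dbl(v, 1),
      max_flux = purrr::map_dbl(v, 2)
    ), class = c("fva_ranges", class(tibble::tibble())))
  }
  two <- list(a = mk(r1 = c(0, 1), r2 = c(0, 2), r3 = c(0, 1)),
              b = mk(r1 = c(2, 3), r2 = c(1, 3), r3 = c(1, 2)))
  cls <- fva_overlap_classification(two)
  expect_equal(cls$classification[cls$reaction_id == "r1"], "non_overlapping")
  expect_equal(cls$classification[cls$reaction_id == "r2"], "overlapping")
  # touching endpoints count as overlapping
  expect_equal(cls$classification[cls$reaction_id == "r3"], "overlapping")
  # three scenarios: one overlapping pair taints the label
  three <- list(a = mk(r1 = c(0, 1)), b = mk(r1 = c(2, 3)), c = mk(r1 = c(2.5, 4)))
  cls3 <- fva_overlap_classification(three)
  expect_equal(cls3$classification, "overlapping")
  detail <- attr(cls3, "pairs")
  expect_equal(nrow(detail), 3)
  expect_equal(sum(detail$disjoint), 2)
  expect_error(fva_overlap_classification(two, reactions = "r9"), "missing")
})

test_that("the reference scenario equals the standalone geometric solution", {
  t1 <- make_toy(toy_spec(), id = "refA")
  t2 <- make_toy(toy_spec(energy_yield = 4), id = "refB")
  res <- run_matrix(list(remove_biomass_reaction(t1$model),
                         remove_biomass_reaction(t2$model)),
                    list(t1$composition, t2$composition), toy_constraints())
  ref <- res[res$is_reference & res$model_id == "refB", ]
  standalone <- geometric_fba(
    apply_constraints(t2$model, toy_constraints()))
  expect_equal(ref$growth_rate, standalone$objective_value, tolerance = 1e-9)
  expect_equal(ref$result[[1]]$fluxes, standalone$fluxes, tolerance = 1e-9)
})
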
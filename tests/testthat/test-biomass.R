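two_component_bof <- function(c1 = 2, c2 = 1, mw1 = 180, mw2 = 120) {
  biomass_composition(
    tibble::tibble(metabolite_id = c("glc", "aa"),
                   coefficient = c(c1, c2),
                   macro_class = c("carbohydrate", "protein"),
                   mw = c(mw1, mw2),
                   carbon_atoms = c(6, 3)),
    id = "twoBOF", gam = 10
  )
}

test_that("normalize_by_weight rescales to exactly 1 g per flux unit", {
  bof <- two_component_bof()
  # mass = 2*0.180 + 1*0.120 = 0.48 g, k = 1/0.48
  expect_equal(bof_mass(bof), 0.48)
  nb <- normalize_by_weight(bof)
  expect_equal(nb$coefficient, c(2, 1) / 0.48, tolerance = 1e-12)
  expect_equal(bof_mass(nb), 1, tolerance = 1e-9)
  # GAM untouched by default, rescaled on request
  expect_equal(bof_gam(nb), 10)
  expect_equal(bof_gam(normalize_by_weight(bof, rescale_gam = TRUE)), 10 / 0.48)
})

test_that("normalization is idempotent and scale-invariant", {
  bof <- two_component_bof()
  n1 <- normalize_by_weight(bof)
  n2 <- normalize_by_weight(n1)
  expect_equal(n2$coefficient, n1$coefficient, tolerance = 1e-12)
  scaled <- two_component_bof(c1 = 2 * 7.3, c2 = 1 * 7.3)
  expect_equal(normalize_by_weight(scaled)$coefficient, n1$coefficient,
               tolerance = 1e-12)
})

test_that("normalization errors on missing or zero molecular weight", {
  bad <- biomass_composition(
    tibble::tibble(metabolite_id = "x", coefficient = 1, mw = 0), id = "z")
  expect_error(normalize_by_weight(bad), "molecular weight")
  na_mw <- biomass_composition(
    tibble::tibble(metabolite_id = "x", coefficient = 1), id = "z")
  expect_error(normalize_by_weight(na_mw), "molecular weight")
})

test_that("class weight percentages are mass fractions summing to 100", {
  bof <- two_component_bof()
  cw <- class_weight_percent(bof)
  expect_equal(sum(cw$weight_percent), 100, tolerance = 1e-9)
  # 0.36/0.48 and 0.12/0.48
  expect_equal(cw$weight_percent[cw$macro_class == "carbohydrate"], 75)
  expect_equal(cw$weight_percent[cw$macro_class == "protein"], 25)
  # equal masses split 50/50; single class is 100
  even <- two_component_bof(c1 = 1, c2 = 1, mw1 = 100, mw2 = 100)
  expect_equal(sort(class_weight_percent(even)$weight_percent), c(50, 50))
  solo <- biomass_composition(
    tibble::tibble(metabolite_id = "x", coefficient = 3, mw = 50,
                   macro_class = "lipid"), id = "s")
  expect_equal(class_weight_percent(solo)$weight_percent, 100)
  # invariant under global coefficient rescaling
  scaled <- two_component_bof(c1 = 2 * 11, c2 = 1 * 11)
  expect_equal(class_weight_percent(scaled), cw)
})

test_that("carbon fractions are normalized carbon demands", {
  bof <- biomass_composition(
    tibble::tibble(metabolite_id = c("a", "b"), coefficient = c(1, 1),
                   carbon_atoms = c(6, 3)), id = "cf")
  cf <- carbon_fraction(bof)
  expect_equal(cf$carbon_fraction, c(2 / 3, 1 / 3))
  expect_equal(sum(cf$carbon_fraction), 1)
  # scale invariance
  bof2 <- biomass_composition(
    tibble::tibble(metabolite_id = c("a", "b"), coefficient = c(4, 4),
                   carbon_atoms = c(6, 3)), id = "cf2")
  expect_equal(carbon_fraction(bof2)$carbon_fraction, cf$carbon_fraction)
  # single carbon-containing component takes fraction 1
  one <- biomass_composition(
    tibble::tibble(metabolite_id = c("a", "b"), coefficient = c(1, 1),
                   carbon_atoms = c(5, 0)), id = "cf3")
  expect_equal(carbon_fraction(one)$carbon_fraction, c(1, 0))
  zero <- biomass_composition(
    tibble::tibble(metabolite_id = c("a", "b"), coefficient = c(1, 1),
                   carbon_atoms = c(0, 0)), id = "cf4")
  expect_error(carbon_fraction(zero), "no carbon")
})

test_that("producibility follows nutrient availability", {
  toy <- make_toy(toy_spec())
  expect_true(producible(toy$model, "E"))
  expect_true(producible(toy$model, "G"))
  # nothing enters the system -> nothing is producible
  closed <- set_bounds(toy$model, "EX_G", 0, 0)
  closed <- fix_flux(closed, "NGAM", 0)
  expect_false(producible(closed, "E"))
  # metabolite in no producing reaction
  m <- add_metabolite(toy$model, "inert")
  expect_false(producible(m, "inert"))
  # absent metabolite is simply not producible
  expect_false(producible(toy$model, "unobtainium"))
})

test_that("intersect_components keeps only components every model can make", {
  t1 <- make_toy(toy_spec(), id = "mA")
  t2 <- make_toy(toy_spec(energy_yield = 4), id = "mB")
  # model C lacks the E-producing pathway entirely
  mc <- metabolic_model("mC") |>
    add_metabolite("G") |>
    add_metabolite("E") |>
    add_exchange("G", "import", reaction_id = "EX_G")
  bof <- t1$composition
  res <- intersect_components(list(bof), list(t1$model, t2$model, mc))
  expect_equal(res$common, "G")
  expect_equal(res$excluded$model_id, "mC")
  expect_equal(res$excluded$metabolite_id, "E")
  # all models produce everything -> full set, in any list order
  res2 <- intersect_components(list(bof), list(t1$model, t2$model))
  expect_setequal(res2$common, c("E", "G"))
  res3 <- intersect_components(list(bof), list(t2$model, t1$model))
  expect_equal(sort(res2$common), sort(res3$common))
})

test_that("build_biomass_reaction writes the expected biomass column", {
  toy <- make_toy(toy_spec())
  S <- stoich_matrix(toy$model)
  expect_equal(S[c("G", "E", "biomass"), "Biomass"],
               c(G = -0.5, E = -1, biomass = 1))
  expect_equal(toy$model$objective_id, "Biomass")
  # gam = 0: no energy terms beyond the composition itself
  expect_equal(length(toy$model$reactions$stoichiometry[[
    match("Biomass", toy$model$reactions$id)]]), 3)
  # missing component metabolite errors by name
  bad <- biomass_composition(
    tibble::tibble(metabolite_id = "ghost", coefficient = 1), id = "bad")
  expect_error(build_biomass_reaction(remove_biomass_reaction(toy$model), bad),
               "ghost")
  # gam > 0 without an ATP species errors
  expect_error(
    build_biomass_reaction(remove_biomass_reaction(toy$model),
                           toy$composition, gam = 5),
    "atp")
})

test_that("GAM adds hydrolysis terms to the biomass column", {
  toy <- make_toy(toy_spec())
  base <- remove_biomass_reaction(toy$model)
  m <- build_biomass_reaction(base, toy$composition, gam = 53.26,
                              gam_species = c(atp = "E"))
  st <- m$reactions$stoichiometry[[match("Biomass", m$reactions$id)]]
  expect_equal(st[["E"]], -1 - 53.26)  # composition demand plus GAM
})

test_that("removing the biomass machinery restores the original model", {
  toy <- make_toy(toy_spec())
  base <- remove_biomass_reaction(toy$model)
  rebuilt <- remove_biomass_reaction(build_biomass_reaction(base, toy$composition))
  expect_models_equal(base, rebuilt)
})

test_that("swapping the composition changes only the biomass column of S", {
  toy <- make_toy(toy_spec())
  other <- biomass_composition(
    tibble::tibble(metabolite_id = c("G", "E"), coefficient = c(1.0, 0.3)),
    id = "otherBOF")
  m2 <- build_biomass_reaction(toy$model, other)
  S1 <- stoich_matrix(toy$model)
  S2 <- stoich_matrix(m2)
  # all columns identical except the biomass reaction's
  keep <- setdiff(colnames(S1), "Biomass")
  expect_equal(S2[, keep], S1[, keep])
  expect_false(isTRUE(all.equal(S2[, "Biomass"], S1[, "Biomass"])))
})

test_that("composition tables round-trip through delimited text", {
  bof <- two_component_bof()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_biomass_composition(bof, path)
  back <- read_biomass_composition(path, id = bof_id(bof), gam = bof_gam(bof))
  expect_equal(as.data.frame(back), as.data.frame(bof))
  expect_equal(bof_gam(back), 10)
  expect_error(read_biomass_composition(path, sep = ","), "needs columns")
})
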
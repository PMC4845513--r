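# Synthetic toy metabolic networks with known analytic optima.
#
# The generated networks mirror, at test scale, the structure the analysis
# targets: a bounded carbon uptake, one or more parallel catabolic routes
# converting substrate to an ATP-like energy currency (parallel copies make
# the FBA optimum degenerate), a fixed maintenance drain, and a
# multi-component biomass reaction.

#' Specification of a toy metabolic network
#'
#' @param n_pathways number of parallel catabolic routes (>= 1); more than
#'   one makes the FBA optimum degenerate.
#' @param energy_yield units of energy currency per unit substrate.
#' @param uptake_bound maximum substrate uptake (flux units).
#' @param ngam non-growth-associated maintenance: fixed energy drain.
#' @param c_substrate,c_energy biomass coefficients of the substrate and the
#'   energy currency (mmol per unit biomass flux).
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(n_pathways = 1, energy_yield = 3, uptake_bound = 10,
                     ngam = 2, c_substrate = 0.5, c_energy = 1) {
  stopifnot(n_pathways >= 1, energy_yield > 0, uptake_bound > 0,
            ngam >= 0, c_substrate > 0, c_energy > 0)
  structure(list(n_pathways = as.integer(n_pathways),
                 energy_yield = energy_yield, uptake_bound = uptake_bound,
                 ngam = ngam, c_substrate = c_substrate, c_energy = c_energy),
            class = "toy_spec")
}

#' Analytic growth optimum of a toy network
#'
#' With uptake u, yield y, maintenance m and biomass coefficients
#' (c_G, c_E), eliminating the steady-state balances gives
#' `v* = (y u - m) / (y c_G + c_E)`.
#'
#' @param spec a [toy_spec()].
#' @return The optimal biomass flux (may be negative for
#'   infeasible-by-design parameter sets).
#' @export
toy_optimum <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  (spec$energy_yield * spec$uptake_bound - spec$ngam) /
    (spec$energy_yield * spec$c_substrate + spec$c_energy)
}

#' Build a toy metabolic network
#'
#' Network: an uptake exchange for substrate `G` (bounded at
#' `uptake_bound`), `n_pathways` parallel copies of the catabolic reaction
#' `G -> energy_yield * E`, a maintenance drain on `E` fixed at `ngam`, and
#' a biomass reaction consuming `c_substrate` G + `c_energy` E.
#'
#' @param spec a [toy_spec()].
#' @param id model identifier (several toys can then enter one scenario
#'   matrix).
#' @param bof_id identifier for the generated composition.
#' @return A list with `model` (objective set to the biomass reaction),
#'   `composition` (the toy BOF), `optimum` (the analytic optimum from
#'   [toy_optimum()]) and `feasible` (`FALSE` when the parameters make the
#'   maintenance drain unsatisfiable).
#' @export
#' @examples
#' toy <- make_toy(toy_spec())
#' toy$optimum                     # 11.2
#' solve_fba(toy$model)$objective_value
make_toy <- function(spec, id = "toy", bof_id = paste0(id, "BOF")) {
  stopifnot(inherits(spec, "toy_spec"))
  # metabolites carry no formulas: the lumped catabolic reaction is not
  # element-balanced by design, and the element audit is opt-in
  m <- metabolic_model(id) |>
    add_metabolite("G", name = "substrate") |>
    add_metabolite("E", name = "energy currency") |>
    add_exchange("G", "import", reaction_id = "EX_G")
  m <- set_bounds(m, "EX_G", 0, spec$uptake_bound)
  for (i in seq_len(spec$n_pathways)) {
    rid <- if (i == 1) "CAT" else paste0("CAT", i)
    m <- add_reaction(m, rid, c(G = -1, E = spec$energy_yield), 0,
                      FLUX_BOUND_DEFAULT, name = paste("catabolic route", i))
  }
  m <- add_reaction(m, "NGAM", c(E = -1), spec$ngam, spec$ngam,
                    name = "maintenance drain", is_exchange = FALSE)
  bof <- biomass_composition(
    tibble(metabolite_id = c("G", "E"),
           coefficient = c(spec$c_substrate, spec$c_energy),
           macro_class = c("carbohydrate", "soluble"),
           mw = c(180.16, 507.18),
           carbon_atoms = c(6, 10)),
    id = bof_id, gam = 0
  )
  m <- build_biomass_reaction(m, bof)
  v <- toy_optimum(spec)
  list(model = m, composition = bof, optimum = v, feasible = v >= 0)
}

#' Draw a random toy specification
#'
#' Parameters are drawn from ranges that keep the network feasible and the
#' optimum away from degenerate scales; used for property sweeps against the
#' analytic optimum and the LP oracle.
#'
#' @param seed integer seed; each seed gives one reproducible spec.
#' @return A [toy_spec()].
#' @export
random_toy_spec <- function(seed) {
  with_local_seed(seed, {
    toy_spec(
      n_pathways = sample(1:3, 1),
      energy_yield = runif(1, 1, 5),
      uptake_bound = runif(1, 1, 20),
      ngam = runif(1, 0, 0.5) * runif(1, 1, 5),  # kept below supply a.s.
      c_substrate = runif(1, 0.1, 2),
      c_energy = runif(1, 0.1, 2)
    )
  })
}

#' Generate a random biomass composition
#'
#' Coefficients are drawn log-uniformly, molecular weights uniformly in
#' 60-800 g/mol and carbon counts in 2-40, then the whole composition is
#' weight-normalized to 1 g per flux unit. Macromolecule classes are
#' assigned by sampling from `class_mix`, emulating real compositions in
#' which a few classes dominate the mass.
#'
#' @param n_components number of components (>= 1).
#' @param class_mix named numeric vector of class proportions summing to 1.
#' @param seed integer seed.
#' @return A normalized [biomass_composition()].
#' @export
make_random_composition <- function(n_components,
                                    class_mix = c(`cell wall` = 0.5,
                                                  protein = 0.3, lipid = 0.2),
                                    seed = 1) {
  stopifnot(n_components >= 1)
  if (abs(sum(class_mix) - 1) > 1e-9) abort("class_mix must sum to 1")
  comp <- with_local_seed(seed, {
    tibble(
      metabolite_id = sprintf("cmp_%03d", seq_len(n_components)),
      coefficient = 10^runif(n_components, -2, 0.5),
      macro_class = sample(names(class_mix), n_components, replace = TRUE,
                           prob = class_mix),
      mw = runif(n_components, 60, 800),
      carbon_atoms = sample(2:40, n_components, replace = TRUE)
    )
  })
  normalize_by_weight(
    biomass_composition(comp, id = sprintf("randomBOF_seed%d", seed), gam = 0)
  )
}

#' Add an energy-generating futile cycle to a toy network
#'
#' Grafts a three-reaction loop (`A -> B + E`, `B -> A`, `B + E -> A`) onto
#' a toy model. The loop regenerates the energy currency at zero cost, so
#' the maintenance constraints stop binding -- the situation flagged by
#' [maintenance_scan()] as maintenance-insensitive. The loop can also spin
#' without net production, so its reactions show wide FVA ranges up to the
#' bound cap.
#'
#' @param toy a list from [make_toy()] (or a bare [metabolic_model()]).
#' @return The model with the cycle added; the ids of the added metabolites
#'   and reactions are in attribute `futile_ids`.
#' @export
make_futile_cycle_model <- function(toy) {
  m <- if (inherits(toy, "metabolic_model")) toy else toy$model
  m <- m |>
    add_metabolite("A", name = "cycle carrier A") |>
    add_metabolite("B", name = "cycle carrier B") |>
    add_reaction("CYC_gen", c(A = -1, B = 1, E = 1), 0, FLUX_BOUND_DEFAULT,
                 name = "cycle: energy-generating leg") |>
    add_reaction("CYC_ret", c(B = -1, A = 1), 0, FLUX_BOUND_DEFAULT,
                 name = "cycle: return leg") |>
    add_reaction("CYC_dis", c(B = -1, E = -1, A = 1), 0, FLUX_BOUND_DEFAULT,
                 name = "cycle: dissipating leg")
  attr(m, "futile_ids") <- list(
    metabolites = c("A", "B"),
    reactions = c("CYC_gen", "CYC_ret", "CYC_dis")
  )
  m
}

#' Remove a futile cycle added by [make_futile_cycle_model()]
#'
#' @param model a model carrying the `futile_ids` attribute.
#' @return The model with the cycle reactions and carrier metabolites
#'   removed.
#' @export
remove_futile_cycle <- function(model) {
  ids <- attr(model, "futile_ids")
  if (is.null(ids)) abort("model has no futile cycle annotation")
  for (rid in ids$reactions) model <- remove_reaction(model, rid)
  model$metabolites <- filter(model$metabolites, !.data$id %in% ids$metabolites)
  attr(model, "futile_ids") <- NULL
  model
}

# evaluate code under a temporary RNG state; never leaves global state behind
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
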
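# Model x biomass-composition scenario matrix.

#' Define a simulation constraint set
#'
#' The constraint set fixes the nutrient environment: one bounded carbon
#' uptake (the sole carbon and energy source), freely open nutrient
#' exchanges (N, S, P sources), a fixed non-growth-associated maintenance
#' (NGAM) drain, and optionally closed exchanges.
#'
#' @param carbon_uptake_id exchange reaction id of the carbon source.
#' @param carbon_uptake_value maximum uptake, flux units (default 10).
#' @param ngam_id reaction id of the maintenance drain (`NULL` to skip).
#' @param ngam_value fixed maintenance flux (default 2.02).
#' @param open_exchanges exchange ids opened to `[-1000, 1000]`.
#' @param closed_exchanges exchange ids fixed to zero.
#' @return A `constraint_set` list.
#' @export
constraint_set <- function(carbon_uptake_id, carbon_uptake_value = 10,
                           ngam_id = NULL, ngam_value = 2.02,
                           open_exchanges = character(),
                           closed_exchanges = character()) {
  stopifnot(length(carbon_uptake_id) == 1, carbon_uptake_value >= 0,
            is.null(ngam_id) || ngam_value >= 0)
  structure(list(carbon_uptake_id = carbon_uptake_id,
                 carbon_uptake_value = carbon_uptake_value,
                 ngam_id = ngam_id, ngam_value = ngam_value,
                 open_exchanges = open_exchanges,
                 closed_exchanges = closed_exchanges),
            class = "constraint_set")
}

#' Apply a constraint set to a model
#'
#' Bounds the carbon uptake at its value (in the uptake direction, with the
#' opposite direction closed), opens the listed nutrient exchanges, fixes
#' the NGAM drain, and closes the listed exchanges. Idempotent: applying
#' the same constraints twice gives the same model.
#'
#' @param model a [metabolic_model()].
#' @param constraints a [constraint_set()].
#' @return The constrained model.
#' @export
apply_constraints <- function(model, constraints) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(constraints, "constraint_set"))
  cs <- constraints
  need <- c(cs$carbon_uptake_id, cs$ngam_id, cs$open_exchanges, cs$closed_exchanges)
  missing <- setdiff(need, model$reactions$id)
  if (length(missing) > 0) {
    abort(sprintf("constraint set references missing reactions: %s",
                  paste(missing, collapse = ", ")))
  }
  # uptake direction follows the exchange's stoichiometric convention:
  # positive flux imports when the internal metabolite is produced
  i <- match(cs$carbon_uptake_id, model$reactions$id)
  st <- model$reactions$stoichiometry[[i]]
  internal <- model$metabolites$id[!model$metabolites$boundary]
  coef <- st[names(st) %in% internal][1]
  if (coef > 0) {
    model <- set_bounds(model, cs$carbon_uptake_id, 0, cs$carbon_uptake_value)
  } else {
    model <- set_bounds(model, cs$carbon_uptake_id, -cs$carbon_uptake_value, 0)
  }
  for (ex in cs$open_exchanges) {
    model <- set_bounds(model, ex, -FLUX_BOUND_DEFAULT, FLUX_BOUND_DEFAULT)
  }
  for (ex in cs$closed_exchanges) model <- set_bounds(model, ex, 0, 0)
  if (!is.null(cs$ngam_id)) model <- fix_flux(model, cs$ngam_id, cs$ngam_value)
  model
}

#' Run the model x biomass-composition scenario matrix
#'
#' Every model is combined with every biomass composition; each pair is
#' constrained, given the composition's biomass reaction (with a common GAM
#' held constant across scenarios) and solved by [geometric_fba()].
#' Scenarios are named `<model>-<BOF>`, and a model's own composition is
#' flagged as its reference scenario. Infeasible pairs are recorded by
#' status and the run continues.
#'
#' @param models list of [metabolic_model()] objects (distinct ids).
#' @param bofs list of [biomass_composition()] objects (distinct ids).
#' @param constraints a [constraint_set()], or a list of them named by model
#'   id when exchange ids differ between models.
#' @param gam common growth-associated maintenance applied in every
#'   scenario (default 0).
#' @param gam_species as in [build_biomass_reaction()]; a single vector, or
#'   a list named by model id.
#' @param reference named character vector `model_id -> bof_id` marking
#'   reference pairs; defaults to pairing by position when the lists have
#'   equal length.
#' @param restrict restrict every composition to the components producible
#'   in all models (via [intersect_components()]) before building biomass
#'   reactions.
#' @param fva also run [flux_variability()] for each feasible scenario.
#' @param solver `"geometric"` (default) or `"fba"`.
#' @return A `scenario_results` tibble: `scenario_id`, `model_id`, `bof_id`,
#'   `is_reference`, `status`, `growth_rate`, and list-columns `result`
#'   (the `fba_result`) and `fva`.
#' @export
run_matrix <- function(models, bofs, constraints, gam = 0, gam_species = NULL,
                       reference = NULL, restrict = TRUE, fva = FALSE,
                       solver = c("geometric", "fba")) {
  solver <- match.arg(solver)
  model_ids <- map_chr(models, function(m) m$id)
  bof_ids <- map_chr(bofs, bof_id)
  stopifnot(!anyDuplicated(model_ids), !anyDuplicated(bof_ids))
  get_cs <- function(mid) {
    if (inherits(constraints, "constraint_set")) constraints else constraints[[mid]]
  }
  get_gs <- function(mid) {
    if (is.null(gam_species) || is.character(gam_species)) gam_species
    else gam_species[[mid]]
  }
  if (is.null(reference) && length(models) == length(bofs)) {
    reference <- setNames(bof_ids, model_ids)
  }

  constrained <- map(models, function(m) apply_constraints(m, get_cs(m$id)))
  names(constrained) <- model_ids
  if (restrict) {
    inter <- intersect_components(bofs, constrained)
    bofs <- map(bofs, restrict_components, keep = inter$common)
  }

  grid <- tidyr::expand_grid(model_id = model_ids, bid = bof_ids)
  rows <- pmap(grid, function(model_id, bid) {
    bof <- bofs[[match(bid, bof_ids)]]
    res <- tryCatch({
      m <- build_biomass_reaction(constrained[[model_id]], bof, gam = gam,
                                  gam_species = get_gs(model_id))
      if (solver == "geometric") geometric_fba(m) else solve_fba(m)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      return(tibble(scenario_id = paste0(model_id, "-", bid),
                    model_id = model_id, bof_id = bid,
                    status = paste("error:", conditionMessage(res)),
                    growth_rate = NA_real_, result = list(NULL), fva = list(NULL)))
    }
    fva_tbl <- NULL
    if (fva && res$status == "optimal") {
      m <- build_biomass_reaction(constrained[[model_id]], bof, gam = gam,
                                  gam_species = get_gs(model_id))
      fva_tbl <- flux_variability(m)
    }
    tibble(scenario_id = paste0(model_id, "-", bid),
           model_id = model_id, bof_id = bid, status = res$status,
           growth_rate = if (res$status == "optimal") res$objective_value else NA_real_,
           result = list(res), fva = list(fva_tbl))
  })
  out <- bind_rows(rows)
  is_ref <- if (is.null(reference)) {
    rep(FALSE, nrow(out))
  } else {
    !is.na(reference[out$model_id]) & reference[out$model_id] == out$bof_id
  }
  out <- mutate(out, is_reference = unname(is_ref), .after = "bof_id")
  class(out) <- c("scenario_results", class(out))
  out
}

#' Central-pathway fluxes of one solved scenario
#'
#' Maps a curated set of labeled central-metabolism reactions onto the
#' model's reaction ids and reads their (signed) fluxes from a solution.
#' Several parallel reactions may share one label, in which case their
#' fluxes are summed (lumping, e.g. alternative electron-transport routes).
#' Labels whose reactions are absent from the model yield `NA`, not 0.
#'
#' @param result an `fba_result`.
#' @param reaction_map a data frame with columns `label` and `reaction_ids`
#'   (one id, or several separated by `;`), or a named list
#'   `label -> character vector of ids`.
#' @return A tibble with `label` and `flux` (`NA` for absent reactions).
#' @export
extract_central_fluxes <- function(result, reaction_map) {
  stopifnot(inherits(result, "fba_result"))
  if (is.data.frame(reaction_map)) {
    ids <- strsplit(reaction_map$reaction_ids, ";", fixed = TRUE)
    reaction_map <- setNames(map(ids, trimws), reaction_map$label)
  }
  fluxes <- setNames(result$fluxes$flux, result$fluxes$reaction_id)
  tibble(
    label = names(reaction_map),
    flux = unname(map_dbl(reaction_map, function(rids) {
      if (!all(rids %in% names(fluxes))) return(NA_real_)
      sum(fluxes[rids])
    }))
  )
}

#' Central fluxes across a scenario matrix
#'
#' @param results a `scenario_results` tibble from [run_matrix()].
#' @param reaction_map as in [extract_central_fluxes()]; a single map used
#'   for all models, or a list of maps named by model id.
#' @return A long tibble: `scenario_id`, `model_id`, `bof_id`, `label`,
#'   `flux`.
#' @export
scenario_central_fluxes <- function(results, reaction_map) {
  stopifnot(inherits(results, "scenario_results"))
  ok <- filter(results, .data$status == "optimal")
  per_model <- !is.data.frame(reaction_map) &&
    all(unique(ok$model_id) %in% names(reaction_map))
  pmap(list(ok$scenario_id, ok$model_id, ok$bof_id, ok$result),
       function(sid, mid, bid, res) {
         rmap <- if (per_model) reaction_map[[mid]] else reaction_map
         mutate(extract_central_fluxes(res, rmap),
                scenario_id = sid, model_id = mid, bof_id = bid,
                .before = 1)
       }) |> bind_rows()
}

#' Flux dispersion across scenarios
#'
#' For each labeled reaction, the standard deviation of its flux across the
#' scenarios of a group -- either the scenarios sharing a biomass
#' composition across models (the model-structure axis) or those sharing a
#' model across compositions (the biomass axis) -- followed by the median
#' of those per-reaction SDs per group. `NA` fluxes (reactions absent from
#' a model) are dropped pairwise.
#'
#' @param central a long flux tibble from [scenario_central_fluxes()] (or
#'   any tibble with `model_id`, `bof_id`, `label`, `flux`).
#' @param grouping `"same_bof_across_models"` or
#'   `"same_model_across_bofs"`.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A list with `per_reaction` (tibble `group`, `label`, `sd`, `n`)
#'   and `medians` (tibble `group`, `median_sd`).
#' @export
dispersion_summary <- function(central,
                               grouping = c("same_bof_across_models",
                                            "same_model_across_bofs"),
                               sd_type = c("sample", "population")) {
  grouping <- match.arg(grouping)
  sd_type <- match.arg(sd_type)
  key <- if (grouping == "same_bof_across_models") "bof_id" else "model_id"
  sizes <- central |>
    distinct(.data[[key]], .data$scenario_id) |>
    dplyr::count(.data[[key]])
  if (any(sizes$n < 2)) {
    abort("each group needs at least two scenarios to compute a dispersion")
  }
  sd_fun <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    if (sd_type == "sample") sd(x) else sqrt(mean((x - mean(x))^2))
  }
  per_reaction <- central |>
    group_by(group = .data[[key]], .data$label) |>
    summarise(n = sum(!is.na(.data$flux)), sd = sd_fun(.data$flux),
              .groups = "drop")
  medians <- per_reaction |>
    group_by(.data$group) |>
    summarise(median_sd = median(.data$sd, na.rm = TRUE), .groups = "drop")
  list(per_reaction = per_reaction, medians = medians)
}

#' Classify FVA ranges across scenarios as overlapping or not
#'
#' A reaction's flux prediction counts as non-overlapping (i.e. genuinely
#' different between scenarios) only when its `[min, max]` flux-variability
#' intervals are pairwise disjoint across all compared scenarios; touching
#' endpoints count as overlapping. The per-pair detail is returned in
#' attribute `pairs`.
#'
#' @param fva_by_scenario named list of `fva_ranges` tibbles, one per
#'   scenario, covering a common reaction set.
#' @param reactions reaction ids to classify (default: those present in
#'   every scenario's table).
#' @return A tibble `reaction_id`, `classification`
#'   (`"non_overlapping"`/`"overlapping"`), with per-pair detail in
#'   `attr(, "pairs")`.
#' @export
fva_overlap_classification <- function(fva_by_scenario, reactions = NULL) {
  stopifnot(is.list(fva_by_scenario), length(fva_by_scenario) >= 2)
  if (is.null(names(fva_by_scenario))) {
    names(fva_by_scenario) <- paste0("scenario", seq_along(fva_by_scenario))
  }
  common <- Reduce(intersect, map(fva_by_scenario, function(f) f$reaction_id))
  if (is.null(reactions)) reactions <- common
  missing <- setdiff(reactions, common)
  if (length(missing) > 0) {
    abort(sprintf("FVA missing for: %s", paste(missing, collapse = ", ")))
  }
  scn <- names(fva_by_scenario)
  pair_idx <- utils::combn(seq_along(scn), 2)
  pairs <- purrr::map(reactions, function(rid) {
    iv <- map(fva_by_scenario, function(f) {
      r <- f[f$reaction_id == rid, ]
      c(r$min_flux, r$max_flux)
    })
    purrr::map(seq_len(ncol(pair_idx)), function(k) {
      a <- iv[[pair_idx[1, k]]]; b <- iv[[pair_idx[2, k]]]
      tibble(reaction_id = rid,
             scenario_a = scn[pair_idx[1, k]], scenario_b = scn[pair_idx[2, k]],
             disjoint = a[2] < b[1] || b[2] < a[1])
    }) |> bind_rows()
  }) |> bind_rows()
  out <- pairs |>
    group_by(.data$reaction_id) |>
    summarise(classification = if (all(.data$disjoint)) "non_overlapping"
              else "overlapping", .groups = "drop")
  out <- out[match(reactions, out$reaction_id), ]
  attr(out, "pairs") <- pairs
  out
}

#' Growth-rate heatmap of a scenario matrix
#'
#' @param object a `scenario_results` tibble.
#' @param ... unused.
#' @return A ggplot tile plot, models x compositions, filled by growth rate.
#' @export
autoplot.scenario_results <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bof_id, y = .data$model_id,
                                       fill = .data$growth_rate)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$growth_rate), "inf.",
                     sprintf("%.3g", .data$growth_rate))), size = 3) +
    ggplot2::labs(x = "biomass composition", y = "model",
                  fill = "growth rate\n(flux units)") +
    ggplot2::theme_minimal()
}
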
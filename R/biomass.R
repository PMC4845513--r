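#' Create a biomass composition
#'
#' A biomass composition (biomass objective function, BOF) lists the
#' precursor metabolites consumed per unit of biomass: coefficients `c_i` in
#' mmol per g dry weight, a macromolecule class per component, and optional
#' molecular weights (g/mol) and carbon counts used for weight
#' normalization and carbon-fraction summaries. Growth-associated
#' maintenance (GAM, ATP-equivalents hydrolyzed per unit biomass flux) is a
#' separate scalar attribute, not a component, so swapping compositions
#' between models never alters the maintenance cost.
#'
#' @param components a data frame with columns `metabolite_id`,
#'   `coefficient` (> 0, mmol/gDW) and optionally `macro_class`,
#'   `mw` (g/mol) and `carbon_atoms`.
#' @param id composition identifier (e.g. `"leafBOF"`).
#' @param gam growth-associated maintenance, ATP per unit biomass flux.
#' @return A `biomass_composition` tibble with attributes `bof_id` and `gam`.
#' @export
#' @examples
#' bof <- biomass_composition(
#'   data.frame(metabolite_id = c("G", "E"), coefficient = c(0.5, 1)),
#'   id = "toyBOF"
#' )
biomass_composition <- function(components, id = "BOF", gam = 0) {
  comp <- as_tibble(components)
  if (!all(c("metabolite_id", "coefficient") %in% names(comp))) {
    abort("components needs columns metabolite_id and coefficient")
  }
  if (!"macro_class" %in% names(comp)) comp$macro_class <- "other"
  if (!"mw" %in% names(comp)) comp$mw <- NA_real_
  if (!"carbon_atoms" %in% names(comp)) comp$carbon_atoms <- NA_real_
  comp <- select(comp, "metabolite_id", "coefficient", "macro_class",
                 "mw", "carbon_atoms")
  if (anyDuplicated(comp$metabolite_id)) abort("duplicate component metabolite_id")
  if (any(comp$coefficient <= 0)) abort("coefficients must be > 0")
  if (gam < 0) abort("gam must be >= 0")
  new_biomass_composition(comp, id, gam)
}

new_biomass_composition <- function(comp, id, gam) {
  structure(comp, bof_id = id, gam = gam,
            class = c("biomass_composition", class(tibble())))
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat(sprintf("<biomass_composition '%s'> %d components, GAM = %g\n",
              attr(x, "bof_id"), nrow(x), attr(x, "gam")))
  NextMethod()
}

#' Growth-associated maintenance of a composition
#' @param composition a [biomass_composition()].
#' @return The GAM scalar (ATP per unit biomass flux).
#' @export
bof_gam <- function(composition) attr(composition, "gam")

#' Identifier of a composition
#' @inheritParams bof_gam
#' @return The composition id string.
#' @export
bof_id <- function(composition) attr(composition, "bof_id")

#' Total mass of one flux unit of biomass
#'
#' `sum(c_i * MW_i / 1000)` in grams. Equals 1 after
#' [normalize_by_weight()]; for perturbed compositions (which are
#' deliberately not renormalized) it is the effective g of biomass per flux
#' unit.
#'
#' @inheritParams bof_gam
#' @return Mass in g per unit biomass flux.
#' @export
bof_mass <- function(composition) {
  if (any(is.na(composition$mw))) abort("composition has components without molecular weight")
  sum(composition$coefficient * composition$mw / 1000)
}

#' Normalize a biomass composition by weight
#'
#' Rescales all coefficients by one common factor so that one unit of flux
#' through the biomass reaction consumes exactly 1 g of precursors
#' (`sum(c_i * MW_i / 1000) = 1`). This puts compositions stated in
#' different source conventions on a common per-gram basis.
#'
#' @inheritParams bof_gam
#' @param rescale_gam also multiply GAM by the same factor (off by default:
#'   maintenance is normally held fixed in flux units).
#' @return The normalized `biomass_composition`.
#' @export
normalize_by_weight <- function(composition, rescale_gam = FALSE) {
  stopifnot(inherits(composition, "biomass_composition"))
  if (any(is.na(composition$mw)) || any(composition$mw <= 0)) {
    abort("every component needs a positive molecular weight")
  }
  mass <- bof_mass(composition)
  if (mass <= 0) abort("zero total mass")
  k <- 1 / mass
  out <- composition
  out$coefficient <- out$coefficient * k
  gam <- attr(composition, "gam")
  new_biomass_composition(as_tibble(out), bof_id(composition),
                          if (rescale_gam) gam * k else gam)
}

#' Weight percentage per macromolecule class
#'
#' @inheritParams bof_gam
#' @return A tibble with `macro_class` and `weight_percent` summing to 100.
#' @export
class_weight_percent <- function(composition) {
  stopifnot(inherits(composition, "biomass_composition"))
  if (nrow(composition) == 0) abort("empty composition")
  if (any(is.na(composition$mw))) abort("molecular weights required")
  tbl <- as_tibble(composition)
  total <- sum(tbl$coefficient * tbl$mw)
  tbl |>
    group_by(.data$macro_class) |>
    summarise(weight_percent = sum(.data$coefficient * .data$mw) / total * 100,
              .groups = "drop")
}

#' Fractional carbon-atom contribution per component
#'
#' `f_i = c_i * nC_i / sum_j(c_j * nC_j)`; the share of the biomass carbon
#' demand each component accounts for. Invariant under global rescaling of
#' the coefficients.
#'
#' @inheritParams bof_gam
#' @return A tibble with `metabolite_id` and `carbon_fraction` summing to 1.
#' @export
carbon_fraction <- function(composition) {
  stopifnot(inherits(composition, "biomass_composition"))
  if (any(is.na(composition$carbon_atoms))) abort("carbon_atoms required for all components")
  total <- sum(composition$coefficient * composition$carbon_atoms)
  if (total <= 0) abort("composition contains no carbon")
  tibble(
    metabolite_id = composition$metabolite_id,
    carbon_fraction = composition$coefficient * composition$carbon_atoms / total
  )
}

#' Can a model produce a metabolite?
#'
#' A metabolite is producible when maximizing its export carries positive
#' flux under the model's current (nutrient) constraints. A metabolite the
#' model does not contain is not producible.
#'
#' @param model a [metabolic_model()] with its nutrient exchanges configured.
#' @param metabolite_id metabolite to test.
#' @param tol positive-flux threshold.
#' @return `TRUE` or `FALSE`.
#' @export
producible <- function(model, metabolite_id, tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!metabolite_id %in% model$metabolites$id) return(FALSE)
  tmp_id <- ".tmp_export_probe"
  m <- add_reaction(model, tmp_id, setNames(-1, metabolite_id), 0, FLUX_BOUND_DEFAULT)
  res <- .fba_lp(m, objective = tmp_id, maximize = TRUE)
  res$status == "optimal" && res$objective > tol
}

#' Intersect biomass components across models by producibility
#'
#' Components are kept only when every model can produce them under its
#' constraints, so that the same component list can be imposed on all models
#' for a fair comparison. Also reports, per model, which components were
#' excluded because that model cannot make them.
#'
#' @param compositions a list of [biomass_composition()] objects.
#' @param models a list of constrained [metabolic_model()] objects.
#' @param tol producibility threshold passed to [producible()].
#' @return A list with `common` (character vector of component ids, sorted)
#'   and `excluded` (tibble `model_id`, `metabolite_id`).
#' @export
intersect_components <- function(compositions, models, tol = 1e-6) {
  stopifnot(length(compositions) >= 1, length(models) >= 1)
  all_ids <- sort(unique(unlist(map(compositions, function(b) b$metabolite_id))))
  excluded <- purrr::map(models, function(m) {
    bad <- all_ids[!map_lgl(all_ids, function(id) producible(m, id, tol))]
    tibble(model_id = m$id, metabolite_id = bad)
  }) |> bind_rows()
  list(common = setdiff(all_ids, unique(excluded$metabolite_id)),
       excluded = excluded)
}

#' Restrict a composition to a set of components
#'
#' @inheritParams bof_gam
#' @param keep component ids to retain (e.g. the `common` set from
#'   [intersect_components()]).
#' @return The restricted `biomass_composition` (not renormalized).
#' @export
restrict_components <- function(composition, keep) {
  stopifnot(inherits(composition, "biomass_composition"))
  out <- as_tibble(composition) |> filter(.data$metabolite_id %in% keep)
  if (nrow(out) == 0) abort("no components left after restriction")
  new_biomass_composition(out, bof_id(composition), bof_gam(composition))
}

#' Assemble the biomass reaction in a model
#'
#' Adds (or replaces) a pseudo-reaction `Biomass` consuming `c_i` of each
#' precursor plus the GAM ATP hydrolysis (ATP + H2O -> ADP + Pi), producing
#' one `biomass` pseudo-metabolite that leaves through a sink exchange. The
#' model objective is set to the biomass reaction.
#'
#' @inheritParams producible
#' @param composition a [biomass_composition()].
#' @param gam GAM override in ATP-equivalents per unit biomass flux;
#'   defaults to the composition's own GAM attribute.
#' @param gam_species named character vector locating the energy species,
#'   e.g. `c(atp = "ATP_c", adp = "ADP_c", pi = "Pi_c", h2o = "H2O_c")`;
#'   `atp` is required when `gam > 0`, the hydrolysis products are included
#'   only when named (a lumped energy currency may track none).
#' @param reaction_id id of the biomass reaction.
#' @return The model with the biomass reaction installed and the objective
#'   set to it.
#' @export
build_biomass_reaction <- function(model, composition, gam = bof_gam(composition),
                                   gam_species = NULL, reaction_id = "Biomass") {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(composition, "biomass_composition"))
  missing <- setdiff(composition$metabolite_id, model$metabolites$id)
  if (length(missing) > 0) {
    abort(sprintf("biomass components missing from model: %s",
                  paste(missing, collapse = ", ")))
  }
  st <- setNames(-composition$coefficient, composition$metabolite_id)
  if (gam > 0) {
    if (is.null(gam_species) || !"atp" %in% names(gam_species)) {
      abort("gam > 0 requires gam_species naming at least the atp species")
    }
    bad <- setdiff(gam_species, model$metabolites$id)
    if (length(bad) > 0) {
      abort(sprintf("GAM species missing from model: %s", paste(bad, collapse = ", ")))
    }
    add_term <- function(st, species, coef) {
      st[species] <- (if (species %in% names(st)) st[[species]] else 0) + coef
      st
    }
    # ATP (+ H2O) -> ADP + Pi (+ H); hydrolysis products are added only when
    # the model tracks them (a lumped energy currency has none)
    st <- add_term(st, gam_species[["atp"]], -gam)
    for (sp in c("h2o")) {
      if (sp %in% names(gam_species)) st <- add_term(st, gam_species[[sp]], -gam)
    }
    for (sp in c("adp", "pi", "h")) {
      if (sp %in% names(gam_species)) st <- add_term(st, gam_species[[sp]], gam)
    }
  }

  if (reaction_id %in% model$reactions$id) model <- remove_reaction(model, reaction_id)
  biomass_met <- "biomass"
  if (!biomass_met %in% model$metabolites$id) {
    model <- add_metabolite(model, biomass_met, name = "biomass pseudo-metabolite",
                            compartment = "c")
  }
  st[biomass_met] <- 1
  model <- add_reaction(model, reaction_id, st, 0, FLUX_BOUND_DEFAULT,
                        name = paste0("biomass assembly (", bof_id(composition), ")"))
  sink_id <- paste0("EX_", biomass_met)
  if (!sink_id %in% model$reactions$id) {
    model <- add_exchange(model, biomass_met, "export", reaction_id = sink_id)
  }
  set_objective(model, reaction_id)
}

#' Remove the biomass machinery from a model
#'
#' Drops the biomass reaction, its sink and the pseudo-metabolite, undoing
#' [build_biomass_reaction()] exactly.
#'
#' @inheritParams producible
#' @param reaction_id id of the biomass reaction.
#' @return The model without the biomass reaction.
#' @export
remove_biomass_reaction <- function(model, reaction_id = "Biomass") {
  if (reaction_id %in% model$reactions$id) model <- remove_reaction(model, reaction_id)
  sink_id <- "EX_biomass"
  if (sink_id %in% model$reactions$id) model <- remove_reaction(model, sink_id)
  if ("biomass" %in% model$metabolites$id) {
    model$metabolites <- filter(model$metabolites, .data$id != "biomass")
  }
  model
}

#' Read a biomass composition table
#'
#' Expects delimited text with header `metabolite_id`,
#' `coefficient_mmol_per_gDW`, `macro_class`, `mw_g_per_mol`, `carbon_atoms`
#' (the last three optional).
#'
#' @param path file path.
#' @param id composition identifier.
#' @param gam growth-associated maintenance scalar.
#' @param sep field separator (default tab).
#' @return A [biomass_composition()].
#' @export
read_biomass_composition <- function(path, id = basename(path), gam = 0, sep = "\t") {
  tbl <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  req <- c("metabolite_id", "coefficient_mmol_per_gDW")
  if (!all(req %in% names(tbl))) {
    abort(sprintf("composition table needs columns: %s", paste(req, collapse = ", ")))
  }
  comp <- tibble(
    metabolite_id = tbl$metabolite_id,
    coefficient = tbl$coefficient_mmol_per_gDW,
    macro_class = if ("macro_class" %in% names(tbl)) tbl$macro_class else "other",
    mw = if ("mw_g_per_mol" %in% names(tbl)) tbl$mw_g_per_mol else NA_real_,
    carbon_atoms = if ("carbon_atoms" %in% names(tbl)) tbl$carbon_atoms else NA_real_
  )
  biomass_composition(comp, id = id, gam = gam)
}

#' Write a biomass composition table
#'
#' @inheritParams bof_gam
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_biomass_composition <- function(composition, path, sep = "\t") {
  stopifnot(inherits(composition, "biomass_composition"))
  out <- data.frame(
    metabolite_id = composition$metabolite_id,
    coefficient_mmol_per_gDW = composition$coefficient,
    macro_class = composition$macro_class,
    mw_g_per_mol = composition$mw,
    carbon_atoms = composition$carbon_atoms
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Class-weight bar chart of one or more compositions
#'
#' @param object a [biomass_composition()] or list of them.
#' @param ... unused.
#' @return A ggplot object showing weight percent per macromolecule class.
#' @export
autoplot.biomass_composition <- function(object, ...) {
  plot_class_weights(list(object))
}

#' @rdname autoplot.biomass_composition
#' @param compositions list of [biomass_composition()] objects.
#' @export
plot_class_weights <- function(compositions, ...) {
  tbl <- purrr::map(compositions, function(b) {
    mutate(class_weight_percent(b), bof = bof_id(b))
  }) |> bind_rows()
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$bof, y = .data$weight_percent,
                                    fill = .data$macro_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "weight percent of biomass",
                  fill = "class") +
    ggplot2::theme_minimal()
}
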
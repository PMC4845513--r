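# SBML reader/writer for flux-balance models.
#
# Reading accepts SBML Level 2 (flux bounds in kinetic-law parameters named
# LOWER_BOUND/UPPER_BOUND, the legacy COBRA convention) and Level 3 with the
# fbc extension (bounds as parameters referenced from
# fbc:lowerFluxBound/upperFluxBound). Writing emits Level 3 + fbc version 2.
# Only the constraint-based skeleton is handled: species, compartments,
# stoichiometry, bounds, objective; no kinetics, units, or annotations.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.parse_formula <- function(s) {
  if (is.na(s) || s == "") return(NULL)
  parts <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
  counts <- integer(0)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    k <- sub("^[A-Za-z]+", "", p)
    add <- if (k == "") 1L else as.integer(k)
    counts[el] <- if (el %in% names(counts)) counts[[el]] + add else add
  }
  counts
}

.format_formula <- function(f) {
  if (is.null(f)) return(NA_character_)
  paste0(names(f), ifelse(f == 1, "", f), collapse = "")
}

#' Read an SBML flux-balance model
#'
#' Parses SBML Level 2 or Level 3 into a [metabolic_model()]. Flux bounds
#' are taken from the fbc attributes when present, else from kinetic-law
#' LOWER_BOUND/UPPER_BOUND parameters; reactions without encoded bounds
#' default to `[-1000, 1000]` when reversible and `[0, 1000]` otherwise.
#' Species with `boundaryCondition="true"` -- or whose id matches
#' `boundary_suffix`, for source models using an id convention instead --
#' are excluded from the mass-balance rows. The active fbc objective, if
#' any, becomes the model objective.
#'
#' @param path path to an SBML file.
#' @param boundary_suffix optional regular expression; species ids matching
#'   it are treated as boundary species (e.g. `"_b$"`).
#' @param quiet suppress the note about which bound encoding was used.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path, boundary_suffix = NULL, quiet = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  doc <- xml2::read_xml(path)  # malformed XML errors here, naming the line
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model_node, "xml_missing")) abort("no <model> element found")
  model_id <- xml2::xml_attr(model_node, "id") %|na|% "model"

  m <- metabolic_model(model_id)

  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_ids <- xml2::xml_attr(species, "id")
  if (anyDuplicated(sp_ids)) {
    abort(sprintf("duplicate species ids: %s",
                  paste(unique(sp_ids[duplicated(sp_ids)]), collapse = ", ")))
  }
  for (sp in species) {
    id <- xml2::xml_attr(sp, "id")
    boundary <- identical(xml2::xml_attr(sp, "boundaryCondition"), "true")
    if (!is.null(boundary_suffix) && grepl(boundary_suffix, id)) boundary <- TRUE
    m <- add_metabolite(
      m, id,
      name = xml2::xml_attr(sp, "name") %|na|% id,
      compartment = xml2::xml_attr(sp, "compartment") %|na|% "c",
      boundary = boundary,
      formula = .parse_formula(xml2::xml_attr(sp, "chemicalFormula"))
    )
  }

  params <- xml2::xml_find_all(doc, ".//model/listOfParameters/parameter")
  par_vals <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                       xml2::xml_attr(params, "id"))

  reactions <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rx_ids <- xml2::xml_attr(reactions, "id")
  if (anyDuplicated(rx_ids)) {
    abort(sprintf("duplicate reaction ids: %s",
                  paste(unique(rx_ids[duplicated(rx_ids)]), collapse = ", ")))
  }
  used_fbc <- FALSE; used_kinetic <- FALSE
  for (rx in reactions) {
    id <- xml2::xml_attr(rx, "id")
    reversible <- !identical(xml2::xml_attr(rx, "reversible"), "false")

    st <- numeric(0)
    for (sr in xml2::xml_find_all(rx, "./listOfReactants/speciesReference")) {
      sid <- xml2::xml_attr(sr, "species")
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %|na|% "1")
      st[sid] <- (st[sid] %|na0|% 0) - coef
    }
    for (sr in xml2::xml_find_all(rx, "./listOfProducts/speciesReference")) {
      sid <- xml2::xml_attr(sr, "species")
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %|na|% "1")
      st[sid] <- (st[sid] %|na0|% 0) + coef
    }
    st <- st[st != 0]
    bad <- setdiff(names(st), sp_ids)
    if (length(bad) > 0) {
      abort(sprintf("reaction '%s' references unknown species: %s",
                    id, paste(bad, collapse = ", ")))
    }

    lb <- NA_real_; ub <- NA_real_
    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    if (!is.na(lb_ref) || !is.na(ub_ref)) {
      used_fbc <- TRUE
      if (!is.na(lb_ref)) lb <- par_vals[lb_ref] %|na0|% suppressWarnings(as.numeric(lb_ref))
      if (!is.na(ub_ref)) ub <- par_vals[ub_ref] %|na0|% suppressWarnings(as.numeric(ub_ref))
    } else {
      kl <- xml2::xml_find_all(
        rx, "./kineticLaw//parameter | ./kineticLaw//localParameter")
      if (length(kl) > 0) {
        kp <- setNames(as.numeric(xml2::xml_attr(kl, "value")),
                       xml2::xml_attr(kl, "id"))
        if ("LOWER_BOUND" %in% names(kp)) { lb <- kp[["LOWER_BOUND"]]; used_kinetic <- TRUE }
        if ("UPPER_BOUND" %in% names(kp)) { ub <- kp[["UPPER_BOUND"]]; used_kinetic <- TRUE }
      }
    }
    if (is.na(lb)) lb <- if (reversible) -FLUX_BOUND_DEFAULT else 0
    if (is.na(ub)) ub <- FLUX_BOUND_DEFAULT

    m <- add_reaction(m, id, st, lb, ub, name = xml2::xml_attr(rx, "name") %|na|% id)
  }

  # the fbc objective elements keep their prefix even after namespace
  # stripping, so match on local names; the first flux objective of the
  # active (or only) objective becomes the model objective
  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing")) {
    rid <- xml2::xml_attr(fo, "reaction")
    if (!is.na(rid) && rid %in% m$reactions$id) m <- set_objective(m, rid)
  }

  if (!quiet) {
    message(sprintf("read '%s': bounds from %s", basename(path),
                    if (used_fbc) "fbc attributes"
                    else if (used_kinetic) "kinetic-law parameters"
                    else "reversibility defaults"))
  }
  m
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
`%|na0|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Write a model as SBML Level 3 with fbc bounds
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mn <- xml2::xml_add_child(doc, "model", id = model$id, "fbc:strict" = "true")

  comps <- unique(model$metabolites$compartment)
  lc <- xml2::xml_add_child(mn, "listOfCompartments")
  for (cmp in comps) {
    xml2::xml_add_child(lc, "compartment", id = cmp, constant = "true")
  }

  ls <- xml2::xml_add_child(mn, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    row <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(
      ls, "species", id = row$id, name = row$name, compartment = row$compartment,
      boundaryCondition = tolower(as.character(row$boundary)),
      hasOnlySubstanceUnits = "false", constant = "false"
    )
    ff <- .format_formula(row$formula[[1]])
    if (!is.na(ff)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", ff)
  }

  lp <- xml2::xml_add_child(mn, "listOfParameters")
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    xml2::xml_add_child(lp, "parameter", id = paste0("lb_", rid),
                        value = format(model$reactions$lower_bound[i], digits = 15),
                        constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0("ub_", rid),
                        value = format(model$reactions$upper_bound[i], digits = 15),
                        constant = "true")
  }

  lr <- xml2::xml_add_child(mn, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    row <- model$reactions[i, ]
    rx <- xml2::xml_add_child(
      lr, "reaction", id = row$id, name = row$name,
      reversible = tolower(as.character(row$lower_bound < 0)), fast = "false"
    )
    xml2::xml_set_attr(rx, "fbc:lowerFluxBound", paste0("lb_", row$id))
    xml2::xml_set_attr(rx, "fbc:upperFluxBound", paste0("ub_", row$id))
    st <- row$stoichiometry[[1]]
    reactants <- st[st < 0]; products <- st[st > 0]
    if (length(reactants) > 0) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (sid in names(reactants)) {
        xml2::xml_add_child(lre, "speciesReference", species = sid,
                            stoichiometry = format(-reactants[[sid]], digits = 15),
                            constant = "true")
      }
    }
    if (length(products) > 0) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (sid in names(products)) {
        xml2::xml_add_child(lpr, "speciesReference", species = sid,
                            stoichiometry = format(products[[sid]], digits = 15),
                            constant = "true")
      }
    }
  }

  if (!is.na(model$objective_id)) {
    lo <- xml2::xml_add_child(mn, "fbc:listOfObjectives")
    xml2::xml_set_attr(lo, "fbc:activeObjective", "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective")
    xml2::xml_set_attr(ob, "fbc:id", "obj")
    xml2::xml_set_attr(ob, "fbc:type", "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    fo <- xml2::xml_add_child(lfo, "fbc:fluxObjective")
    xml2::xml_set_attr(fo, "fbc:reaction", model$objective_id)
    xml2::xml_set_attr(fo, "fbc:coefficient", "1")
  }

  xml2::write_xml(doc, path)
  invisible(path)
}
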
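#' Create an empty stoichiometric model
#'
#' A `metabolic_model` holds the metabolites and reactions of a
#' constraint-based (flux-balance) model. Metabolites and reactions live in
#' tibbles; reaction stoichiometries are named numeric vectors (negative =
#' consumed, positive = produced) kept in a list-column, and the
#' stoichiometric matrix S is assembled on demand with [stoich_matrix()].
#'
#' @param id model identifier.
#' @return A `metabolic_model` with no metabolites or reactions.
#' @seealso [add_metabolite()], [add_reaction()], [read_sbml()]
#' @export
#' @examples
#' m <- metabolic_model("toy") |>
#'   add_metabolite("G") |>
#'   add_metabolite("E") |>
#'   add_reaction("upt", c(G = 1), 0, 10) |>
#'   add_reaction("cat", c(G = -1, E = 3), 0, 1000)
#' m
metabolic_model <- function(id = "model") {
  structure(
    list(
      id = id,
      metabolites = tibble(
        id = character(), name = character(), compartment = character(),
        boundary = logical(), formula = list()
      ),
      reactions = tibble(
        id = character(), name = character(),
        lower_bound = double(), upper_bound = double(),
        stoichiometry = list(), is_exchange = logical()
      ),
      objective_id = NA_character_
    ),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "<metabolic_model '%s'> %d metabolites (%d boundary), %d reactions (%d exchange)\n",
    x$id, nrow(x$metabolites), sum(x$metabolites$boundary),
    nrow(x$reactions), sum(x$reactions$is_exchange)
  ))
  if (!is.na(x$objective_id)) cat("objective:", x$objective_id, "\n")
  invisible(x)
}

#' Add a metabolite to a model
#'
#' @param model a [metabolic_model()].
#' @param id metabolite identifier, unique within the model.
#' @param name display name.
#' @param compartment compartment label.
#' @param boundary if `TRUE` the species sits outside the system boundary and
#'   is excluded from the mass-balance rows of S.
#' @param formula optional named integer vector of element counts,
#'   e.g. `c(C = 6, H = 12, O = 6)`.
#' @return The model with one more metabolite.
#' @export
add_metabolite <- function(model, id, name = id, compartment = "c",
                           boundary = FALSE, formula = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  if (id %in% model$metabolites$id) {
    abort(sprintf("duplicate metabolite id '%s'", id))
  }
  if (!is.null(formula)) {
    if (is.null(names(formula)) || any(formula < 0) ||
        any(formula != round(formula))) {
      abort("formula must be a named vector of non-negative integer counts")
    }
  }
  model$metabolites <- bind_rows(
    model$metabolites,
    tibble(id = id, name = name, compartment = compartment,
           boundary = boundary, formula = list(formula))
  )
  model
}

# an exchange touches exactly one non-boundary metabolite; anything else it
# references must be a boundary species
.is_exchange <- function(stoich, metabolites) {
  internal <- metabolites$id[!metabolites$boundary]
  sum(names(stoich) %in% internal) == 1 &&
    all(names(stoich) %in% metabolites$id) &&
    sum(!(names(stoich) %in% internal)) == length(stoich) - 1
}

#' Add a reaction to a model
#'
#' @inheritParams add_metabolite
#' @param stoichiometry named numeric vector over metabolite ids; negative
#'   entries are consumed, positive produced.
#' @param lower_bound,upper_bound flux bounds (mmol gDW^-1 h^-1 scale).
#'   Non-finite values are clamped to +/-1000 flux units so every linear
#'   program stays bounded.
#' @param is_exchange override the structural exchange detection; e.g. a
#'   lumped maintenance drain touches a single metabolite like an exchange
#'   but is conceptually an internal energy sink.
#' @return The model with one more reaction (column of S).
#' @export
add_reaction <- function(model, id, stoichiometry, lower_bound = -1000,
                         upper_bound = 1000, name = id, is_exchange = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  if (id %in% model$reactions$id) abort(sprintf("duplicate reaction id '%s'", id))
  if (length(stoichiometry) == 0) abort("stoichiometry must be non-empty")
  missing <- setdiff(names(stoichiometry), model$metabolites$id)
  if (length(missing) > 0) {
    abort(sprintf("unknown metabolite(s) in reaction '%s': %s",
                  id, paste(missing, collapse = ", ")))
  }
  lower_bound <- max(lower_bound, -FLUX_BOUND_DEFAULT)
  upper_bound <- min(upper_bound, FLUX_BOUND_DEFAULT)
  if (lower_bound > upper_bound) abort("lower_bound > upper_bound")
  exch <- if (is.null(is_exchange)) {
    .is_exchange(stoichiometry, model$metabolites)
  } else {
    isTRUE(is_exchange)
  }
  model$reactions <- bind_rows(
    model$reactions,
    tibble(id = id, name = name,
           lower_bound = lower_bound, upper_bound = upper_bound,
           stoichiometry = list(stoichiometry),
           is_exchange = exch)
  )
  model
}

#' Remove a reaction from a model
#'
#' @inheritParams add_metabolite
#' @param reaction_id reaction to drop.
#' @return The model without that reaction; the objective is cleared if it
#'   pointed at it.
#' @export
remove_reaction <- function(model, reaction_id) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!reaction_id %in% model$reactions$id) {
    abort(sprintf("unknown reaction '%s'", reaction_id))
  }
  model$reactions <- filter(model$reactions, .data$id != reaction_id)
  if (identical(model$objective_id, reaction_id)) {
    model$objective_id <- NA_character_
  }
  model
}

#' Assemble the stoichiometric matrix S
#'
#' Rows are the non-boundary metabolites, columns the reactions; boundary
#' species do not get a mass-balance row.
#'
#' @inheritParams add_metabolite
#' @return A dense numeric matrix with dimnames.
#' @export
stoich_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites$id[!model$metabolites$boundary]
  S <- matrix(0, nrow = length(mets), ncol = nrow(model$reactions),
              dimnames = list(mets, model$reactions$id))
  for (j in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[j]]
    st <- st[names(st) %in% mets]
    if (length(st)) S[names(st), j] <- S[names(st), j] + unname(st)
  }
  S
}

#' Set the objective reaction
#'
#' @inheritParams remove_reaction
#' @return The model with `objective_id` set.
#' @export
set_objective <- function(model, reaction_id) {
  if (!reaction_id %in% model$reactions$id) {
    abort(sprintf("unknown reaction '%s'", reaction_id))
  }
  model$objective_id <- reaction_id
  model
}

#' Set flux bounds on a reaction
#'
#' @inheritParams remove_reaction
#' @param lb,ub new lower and upper bound.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction_id, lb, ub) {
  stopifnot(inherits(model, "metabolic_model"))
  if (lb > ub) abort("lb > ub")
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) abort(sprintf("unknown reaction '%s'", reaction_id))
  model$reactions$lower_bound[i] <- lb
  model$reactions$upper_bound[i] <- ub
  model
}

#' Fix a reaction flux to a single value
#'
#' Sets both bounds to `value`, so every feasible flux distribution carries
#' exactly that flux. Used for non-growth-associated maintenance drains.
#'
#' @inheritParams set_bounds
#' @param value the fixed flux.
#' @return The modified model.
#' @export
fix_flux <- function(model, reaction_id, value) {
  set_bounds(model, reaction_id, value, value)
}

#' Add an exchange reaction for a metabolite
#'
#' Creates a boundary reaction importing and/or exporting one metabolite.
#' Import produces the metabolite from nothing (bounds `[0, 1000]`), export
#' consumes it (bounds `[0, 1000]`), `"both"` is reversible
#' (`[-1000, 1000]`, positive flux = import).
#'
#' @inheritParams add_metabolite
#' @param metabolite_id internal metabolite to exchange.
#' @param direction one of `"import"`, `"export"`, `"both"`.
#' @param reaction_id exchange id; defaults to `EX_<metabolite_id>`. Supply
#'   e.g. `"H2S_tx"` to follow a source model's transporter naming.
#' @param replace overwrite an existing exchange for this metabolite instead
#'   of erroring.
#' @return The model with the exchange added.
#' @export
add_exchange <- function(model, metabolite_id, direction = c("both", "import", "export"),
                         reaction_id = paste0("EX_", metabolite_id),
                         replace = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  direction <- match.arg(direction)
  if (!metabolite_id %in% model$metabolites$id) {
    abort(sprintf("unknown metabolite '%s'", metabolite_id))
  }
  existing <- model$reactions$id[
    model$reactions$is_exchange &
      map_lgl(model$reactions$stoichiometry, function(s) {
        ids <- names(s)
        internal <- model$metabolites$id[!model$metabolites$boundary]
        identical(intersect(ids, internal), metabolite_id)
      })
  ]
  if (length(existing) > 0) {
    if (!replace) {
      abort(sprintf("metabolite '%s' already has exchange '%s' (use replace = TRUE)",
                    metabolite_id, existing[1]))
    }
    for (rid in existing) model <- remove_reaction(model, rid)
  }
  # import produces the metabolite, export consumes it
  st <- switch(direction,
    import = setNames(1, metabolite_id),
    export = setNames(-1, metabolite_id),
    both = setNames(1, metabolite_id)
  )
  lb <- if (direction == "both") -FLUX_BOUND_DEFAULT else 0
  add_reaction(model, reaction_id, st, lb, FLUX_BOUND_DEFAULT)
}

#' Apply a declarative patch to a model
#'
#' Model edits (bound changes, direction flips, added exchanges) are taken
#' from a YAML/JSON-style list rather than hard-coded, so curation fixes to
#' published models stay declarative and auditable. Each entry is one of
#' \describe{
#'   \item{bounds}{`{reaction_id, new_lb, new_ub}`}
#'   \item{flip}{`{reaction_id, flip_direction: true}` negates the
#'     stoichiometry and swaps/negates bounds (a direction correction)}
#'   \item{exchange}{`{add_exchange: {metabolite_id, direction, reaction_id}}`}
#' }
#'
#' @inheritParams add_metabolite
#' @param patch a list of edits, or a path to a YAML file containing one.
#' @param quiet suppress the per-edit log messages.
#' @return The patched model.
#' @export
apply_model_patch <- function(model, patch, quiet = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.character(patch) && length(patch) == 1) {
    patch <- yaml::read_yaml(patch)
  }
  for (entry in patch) {
    if (!is.null(entry$add_exchange)) {
      ex <- entry$add_exchange
      args <- list(model = model, metabolite_id = ex$metabolite_id,
                   direction = ex$direction %||% "both")
      if (!is.null(ex$reaction_id)) args$reaction_id <- ex$reaction_id
      model <- do.call(add_exchange, args)
      if (!quiet) message(sprintf("patch: added exchange for '%s'", ex$metabolite_id))
    } else if (isTRUE(entry$flip_direction)) {
      i <- match(entry$reaction_id, model$reactions$id)
      if (is.na(i)) abort(sprintf("patch: unknown reaction '%s'", entry$reaction_id))
      old <- c(model$reactions$lower_bound[i], model$reactions$upper_bound[i])
      model$reactions$stoichiometry[[i]] <- -model$reactions$stoichiometry[[i]]
      model$reactions$lower_bound[i] <- -old[2]
      model$reactions$upper_bound[i] <- -old[1]
      if (!quiet) message(sprintf("patch: flipped '%s' (bounds [%g, %g] -> [%g, %g])",
                                  entry$reaction_id, old[1], old[2], -old[2], -old[1]))
    } else {
      i <- match(entry$reaction_id, model$reactions$id)
      if (is.na(i)) abort(sprintf("patch: unknown reaction '%s'", entry$reaction_id))
      old <- c(model$reactions$lower_bound[i], model$reactions$upper_bound[i])
      model <- set_bounds(model, entry$reaction_id,
                          entry$new_lb %||% old[1], entry$new_ub %||% old[2])
      if (!quiet) message(sprintf("patch: '%s' bounds [%g, %g] -> [%g, %g]",
                                  entry$reaction_id, old[1], old[2],
                                  model$reactions$lower_bound[i],
                                  model$reactions$upper_bound[i]))
    }
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Report structural issues in a model
#'
#' Checks for orphan metabolites (in no reaction), blocked reactions (flux
#' variability range `{0}` with all exchange bounds opened), and internal
#' reactions that are elementally unbalanced for metabolites carrying
#' formulas. Reactions touching any metabolite without a formula are skipped
#' by the element audit. Never mutates the model.
#'
#' @inheritParams add_metabolite
#' @param check_blocked run the (2n-LP) blocked-reaction scan; on by default.
#' @return A list with tibbles `orphan_metabolites`, `blocked_reactions`,
#'   `unbalanced_reactions`, and a logical `ok`.
#' @export
validate_model <- function(model, check_blocked = TRUE) {
  stopifnot(inherits(model, "metabolic_model"))
  used <- unique(unlist(map(model$reactions$stoichiometry, names)))
  orphans <- setdiff(model$metabolites$id, used)

  unbalanced <- character()
  formulas <- setNames(model$metabolites$formula, model$metabolites$id)
  for (j in seq_len(nrow(model$reactions))) {
    if (model$reactions$is_exchange[j]) next
    st <- model$reactions$stoichiometry[[j]]
    fs <- formulas[names(st)]
    if (any(map_lgl(fs, is.null))) next  # audit is opt-in via formulas
    elements <- unique(unlist(map(fs, names)))
    net <- map_dbl(elements, function(el) {
      sum(map_dbl(seq_along(st), function(k) {
        st[k] * (fs[[k]][el] %||% 0)
      }), na.rm = TRUE)
    })
    if (any(abs(net) > 1e-9)) unbalanced <- c(unbalanced, model$reactions$id[j])
  }

  blocked <- character()
  if (check_blocked && nrow(model$reactions) > 0) {
    open <- model$reactions$is_exchange
    m <- model
    m$reactions$lower_bound[open] <- -FLUX_BOUND_DEFAULT
    m$reactions$upper_bound[open] <- FLUX_BOUND_DEFAULT
    for (rid in m$reactions$id) {
      lo <- .fba_lp(m, objective = rid, maximize = FALSE)
      hi <- .fba_lp(m, objective = rid, maximize = TRUE)
      if (lo$status == "optimal" && hi$status == "optimal" &&
          abs(lo$objective) < 1e-6 && abs(hi$objective) < 1e-6) {
        blocked <- c(blocked, rid)
      }
    }
  }

  res <- list(
    orphan_metabolites = tibble(metabolite_id = orphans),
    blocked_reactions = tibble(reaction_id = blocked),
    unbalanced_reactions = tibble(reaction_id = unbalanced),
    ok = length(orphans) == 0 && length(blocked) == 0 && length(unbalanced) == 0
  )
  class(res) <- "model_validation"
  res
}

#' @export
print.model_validation <- function(x, ...) {
  cat(sprintf("model validation: %s\n", if (x$ok) "no issues" else "issues found"))
  if (nrow(x$orphan_metabolites)) {
    cat(" orphan metabolites:", paste(x$orphan_metabolites$metabolite_id, collapse = ", "), "\n")
  }
  if (nrow(x$blocked_reactions)) {
    cat(" blocked reactions:", paste(x$blocked_reactions$reaction_id, collapse = ", "), "\n")
  }
  if (nrow(x$unbalanced_reactions)) {
    cat(" elementally unbalanced:", paste(x$unbalanced_reactions$reaction_id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reaction table of a model
#'
#' @param x a [metabolic_model()].
#' @param ... unused.
#' @return A tibble with one row per reaction: id, name, bounds, exchange
#'   flag, and a compact reaction string.
#' @export
tidy.metabolic_model <- function(x, ...) {
  eq <- map_chr(x$reactions$stoichiometry, function(st) {
    lhs <- st[st < 0]; rhs <- st[st > 0]
    fmt <- function(v) {
      if (length(v) == 0) return("")
      paste(ifelse(abs(v) == 1, names(v), paste0(abs(v), " ", names(v))), collapse = " + ")
    }
    paste(fmt(lhs), "->", fmt(rhs))
  })
  mutate(select(x$reactions, -"stoichiometry"), equation = eq)
}

#' One-row model summary
#'
#' @param x a [metabolic_model()].
#' @param ... unused.
#' @return A tibble with metabolite/reaction counts and the objective id.
#' @export
glance.metabolic_model <- function(x, ...) {
  tibble(
    model_id = x$id,
    n_metabolites = nrow(x$metabolites),
    n_boundary = sum(x$metabolites$boundary),
    n_reactions = nrow(x$reactions),
    n_exchanges = sum(x$reactions$is_exchange),
    objective_id = x$objective_id
  )
}
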
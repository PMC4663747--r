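## Metabolic model containers.
##
## A model is a plain list with class "metabolic_model": an organism id, an
## optional taxonomy (rank -> label), a metabolite table, a named list of
## reactions, and the id of the single biomass reaction. Two compartments
## only (cytosol, extracellular) -- enough for medium manipulation, which is
## all the downstream analyses need. Exchange reactions follow the community
## convention "1 M_ext -> (nothing)": positive flux secretes, negative flux
## takes up, so a maximal uptake of 10 mmol/gDW/h is a lower bound of -10.

COMPARTMENTS <- c("cytosol", "extracellular")
DEFAULT_UB <- 1000
DEFAULT_LB_REVERSIBLE <- -1000

#' Construct a metabolite
#'
#' @param id unique whitespace-free token.
#' @param name free-text description.
#' @param compartment `"cytosol"` or `"extracellular"`.
#' @export
metabolite <- function(id, name = id, compartment = "cytosol") {
  list(id = id, name = name, compartment = compartment)
}

#' Construct a reaction
#'
#' Stoichiometric coefficients are signed: negative consumes, positive
#' produces. Bounds are in mmol/gDW/h; when omitted the conventional
#' "effectively unbounded" caps are used (`[0, 1000]` if `reversible` is
#' `FALSE`, `[-1000, 1000]` otherwise).
#'
#' @param id unique whitespace-free token.
#' @param stoichiometry named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound flux bounds (mmol/gDW/h).
#' @param is_exchange boundary pseudo-reaction moving one extracellular
#'   metabolite in or out of the system.
#' @param is_biomass the growth objective; its flux is read as growth rate.
#' @param reversible used only to pick default bounds when bounds are absent.
#' @export
reaction <- function(id, stoichiometry, lower_bound = NULL, upper_bound = NULL,
                     is_exchange = FALSE, is_biomass = FALSE,
                     reversible = FALSE) {
  if (is.null(lower_bound))
    lower_bound <- if (reversible) DEFAULT_LB_REVERSIBLE else 0
  if (is.null(upper_bound)) upper_bound <- DEFAULT_UB
  list(id = id,
       stoichiometry = stoichiometry,
       lower_bound = as.numeric(lower_bound),
       upper_bound = as.numeric(upper_bound),
       is_exchange = isTRUE(is_exchange),
       is_biomass = isTRUE(is_biomass))
}

#' Construct a metabolic model
#'
#' @param organism_id organism identifier.
#' @param metabolites list of [metabolite()] entries.
#' @param reactions list of [reaction()] entries.
#' @param biomass_reaction_id id of the unique biomass reaction.
#' @param taxonomy named list of rank -> label (e.g. class, genus, phenotype).
#' @return object of class `metabolic_model`. Use [validate_model()] to
#'   check invariants; constructors do not validate so that violating
#'   fixtures can be built in tests.
#' @export
metabolic_model <- function(organism_id, metabolites, reactions,
                            biomass_reaction_id, taxonomy = list()) {
  names(reactions) <- vapply(reactions, function(r) r$id %||% "", character(1))
  structure(list(organism_id = organism_id,
                 taxonomy = taxonomy,
                 metabolites = metabolites,
                 reactions = reactions,
                 biomass_reaction_id = biomass_reaction_id),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions (%d exchange), biomass = %s\n",
              x$organism_id, length(x$metabolites), length(x$reactions),
              length(exchange_ids(x)), x$biomass_reaction_id))
  invisible(x)
}

metabolite_ids <- function(model)
  vapply(model$metabolites, `[[`, character(1), "id")

reaction_ids <- function(model)
  vapply(model$reactions, `[[`, character(1), "id")

#' Ids of exchange reactions of a model
#' @export
exchange_ids <- function(model) {
  ids <- reaction_ids(model)
  unname(ids[vapply(model$reactions, function(r) isTRUE(r$is_exchange), logical(1))])
}

## the single metabolite moved by an exchange reaction
exchanged_metabolite <- function(model, rxn_id) {
  names(model$reactions[[rxn_id]]$stoichiometry)[1]
}

## metabolite id -> exchange reaction id (NA when not exchanged)
exchange_for_metabolite <- function(model, metabolite_id) {
  for (rid in exchange_ids(model)) {
    if (exchanged_metabolite(model, rid) == metabolite_id) return(rid)
  }
  NA_character_
}

#' Validate a metabolic model
#'
#' Checks every structural invariant and returns all violations as
#' human-readable strings (an empty character vector means the model is
#' valid). Violations are data, not errors.
#'
#' @param model a `metabolic_model`.
#' @return character vector of violation descriptions.
#' @export
validate_model <- function(model) {
  v <- character()
  add <- function(msg, ...) v <<- c(v, sprintf(msg, ...))

  if (!is_string(model$organism_id) || !nzchar(model$organism_id))
    add("model: organism_id must be a nonempty string")

  mids <- metabolite_ids(model)
  if (anyDuplicated(mids))
    add("metabolite %s: duplicated id", unique(mids[duplicated(mids)]))
  if (any(grepl("[[:space:]]", mids)))
    add("metabolite %s: id contains whitespace", mids[grepl("[[:space:]]", mids)])
  comp <- vapply(model$metabolites, function(m) m$compartment %||% "", character(1))
  bad <- !comp %in% COMPARTMENTS
  if (any(bad))
    add("metabolite %s: compartment '%s' not in {cytosol, extracellular}",
        mids[bad], comp[bad])
  compof <- stats::setNames(comp, mids)

  rids <- reaction_ids(model)
  if (anyDuplicated(rids))
    add("reaction %s: duplicated id", unique(rids[duplicated(rids)]))
  if (any(grepl("[[:space:]]", rids)))
    add("reaction %s: id contains whitespace", rids[grepl("[[:space:]]", rids)])

  n_biomass <- 0L
  n_exchange <- 0L
  for (r in model$reactions) {
    rid <- r$id
    st <- r$stoichiometry
    if (length(st) == 0L)
      add("reaction %s: empty stoichiometry", rid)
    if (!all(names(st) %in% mids))
      add("reaction %s: references unknown metabolite(s) %s", rid,
          paste(setdiff(names(st), mids), collapse = ", "))
    if (any(!is.finite(unlist(st))))
      add("reaction %s: non-finite stoichiometric coefficient", rid)
    if (!is_number(r$lower_bound) || !is_number(r$upper_bound)) {
      add("reaction %s: bounds must be finite numbers", rid)
    } else if (r$lower_bound > r$upper_bound) {
      add("reaction %s: lower_bound (%g) exceeds upper_bound (%g)",
          rid, r$lower_bound, r$upper_bound)
    }
    if (isTRUE(r$is_exchange)) {
      n_exchange <- n_exchange + 1L
      if (length(st) != 1L) {
        add("reaction %s: exchange reaction must reference exactly one metabolite", rid)
      } else if (!identical(unname(compof[names(st)]), "extracellular")) {
        add("reaction %s: exchanged metabolite %s is not extracellular",
            rid, names(st))
      }
    }
    if (isTRUE(r$is_biomass)) {
      n_biomass <- n_biomass + 1L
      if (isTRUE(r$is_exchange))
        add("reaction %s: biomass reaction cannot be an exchange reaction", rid)
    }
  }
  if (n_biomass != 1L)
    add("model: expected exactly one biomass reaction, found %d", n_biomass)
  if (n_biomass >= 1L) {
    bio <- unname(rids[vapply(model$reactions, function(r) isTRUE(r$is_biomass), logical(1))])
    if (!identical(model$biomass_reaction_id, bio[1]) && n_biomass == 1L)
      add("model: biomass_reaction_id '%s' does not match the biomass reaction '%s'",
          model$biomass_reaction_id %||% "<missing>", bio[1])
  }
  if (n_exchange == 0L)
    add("model: at least one exchange reaction is required")
  v
}

assert_valid_model <- function(model) {
  v <- validate_model(model)
  if (length(v) > 0L)
    stop_validation("invalid metabolic model '%s':\n- %s",
                    model$organism_id %||% "<unnamed>",
                    paste(v, collapse = "\n- "))
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model a valid `metabolic_model`.
#' @return dense matrix, metabolites in rows, reactions in columns.
#' @export
s_matrix <- function(model) {
  mids <- metabolite_ids(model)
  rids <- reaction_ids(model)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (r in model$reactions) {
    S[names(r$stoichiometry), r$id] <- as.numeric(unlist(r$stoichiometry))
  }
  S
}

#' Bundle models into a collection
#'
#' Models are stored in canonical sorted order by organism id; duplicate ids
#' are rejected.
#' @param models list of `metabolic_model` objects.
#' @export
model_collection <- function(models) {
  ids <- vapply(models, `[[`, character(1), "organism_id")
  if (anyDuplicated(ids))
    stop_validation("duplicate organism ids in collection: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  models <- models[order(ids)]
  names(models) <- sort(ids)
  structure(list(models = models), class = "model_collection")
}

#' @export
print.model_collection <- function(x, ...) {
  cat(sprintf("<model_collection> %d models: %s%s\n", length(x$models),
              paste(utils::head(names(x$models), 5), collapse = ", "),
              if (length(x$models) > 5) ", ..." else ""))
  invisible(x)
}

#' Canonical organism ids of a container
#'
#' @param x a `model_collection`, `binary_profile` or `org_dist`.
#' @export
organism_ids <- function(x) UseMethod("organism_ids")

#' @export
organism_ids.model_collection <- function(x) names(x$models)

#' Organism-by-reaction presence matrix over a model collection
#'
#' Columns are the sorted union of reaction ids across all models; entry
#' (o, r) is 1 when model o contains reaction r. Presence of reactions,
#' nutrients and annotations is always assessed against the union of the
#' whole collection so that profiles from different organisms are directly
#' comparable.
#'
#' @param collection a [model_collection()] with at least two models.
#' @return a [binary_profile()] with `feature_kind = "reaction"`.
#' @export
build_presence_matrix <- function(collection) {
  stopifnot(inherits(collection, "model_collection"))
  if (length(collection$models) < 2L)
    stop_validation("build_presence_matrix needs at least 2 models")
  per_model <- lapply(collection$models, reaction_ids)
  feats <- sort(unique(unlist(per_model)))
  orgs <- organism_ids(collection)
  M <- matrix(0L, length(orgs), length(feats), dimnames = list(orgs, feats))
  for (o in orgs) M[o, per_model[[o]]] <- 1L
  binary_profile(M, feature_kind = "reaction")
}
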
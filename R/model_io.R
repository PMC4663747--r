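## Model serialization.
##
## The on-disk format is a small package-defined JSON schema:
##
##   {
##     "organism_id":        "org_0001",
##     "taxonomy":           {"class": "...", "genus": "...", ...},   # optional
##     "metabolites":        [{"id", "name", "compartment"}, ...],    # sorted by id
##     "reactions":          [{"id", "stoichiometry": {met: coef, ...},
##                             "lower_bound", "upper_bound",
##                             "is_exchange", "is_biomass"}, ...],    # sorted by id
##     "biomass_reaction_id": "biomass"
##   }
##
## Writing is canonical (sorted keys, sorted reactions, full-precision
## numbers) so semantically equal models produce byte-identical files and
## write -> read round-trips exactly.

#' Write a metabolic model to canonical JSON
#'
#' Refuses invalid models (including non-finite bounds). Output ordering is
#' canonical so files are diff-stable.
#'
#' @param model a valid `metabolic_model`.
#' @param path output file path.
#' @export
write_model <- function(model, path) {
  assert_valid_model(model)
  mets <- model$metabolites[order(vapply(model$metabolites, `[[`, character(1), "id"))]
  rxns <- model$reactions[order(reaction_ids(model))]
  doc <- list(
    organism_id = model$organism_id,
    taxonomy = if (length(model$taxonomy))
      model$taxonomy[order(names(model$taxonomy))] else NULL,
    metabolites = lapply(mets, function(m)
      list(id = m$id, name = m$name, compartment = m$compartment)),
    reactions = lapply(unname(rxns), function(r) {
      st <- as.list(r$stoichiometry[order(names(r$stoichiometry))])
      list(id = r$id, stoichiometry = st,
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           is_exchange = r$is_exchange, is_biomass = r$is_biomass)
    }),
    biomass_reaction_id = model$biomass_reaction_id
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = 2)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(json, con)
  invisible(path)
}

#' Read a metabolic model
#'
#' @param path model file.
#' @param format `"json"` (package schema) or `"sbml_subset"` (a minimal
#'   SBML Level 3 reader covering species, reactions, flux bounds, and the
#'   active objective; everything else is ignored with a warning).
#' @return a validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("json", "sbml_subset")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_validation("model file does not exist: %s", path)
  model <- switch(format,
                  json = read_model_json(path),
                  sbml_subset = read_sbml_subset(path))
  assert_valid_model(model)
  model
}

read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop_validation("malformed JSON in %s: %s",
                                        path, conditionMessage(e)))
  for (field in c("organism_id", "metabolites", "reactions", "biomass_reaction_id")) {
    if (is.null(doc[[field]]))
      stop_validation("malformed model file %s: missing element '%s'", path, field)
  }
  mets <- lapply(doc$metabolites, function(m) {
    if (is.null(m$id))
      stop_validation("malformed model file %s: metabolite without id", path)
    metabolite(m$id, m$name %||% m$id, m$compartment %||% "cytosol")
  })
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id))
      stop_validation("malformed model file %s: reaction without id", path)
    st <- unlist(r$stoichiometry)
    if (is.null(st))
      stop_validation("malformed model file %s: reaction '%s' without stoichiometry",
                      path, r$id)
    reaction(r$id, st,
             lower_bound = r$lower_bound,
             upper_bound = r$upper_bound,
             is_exchange = isTRUE(r$is_exchange),
             is_biomass = isTRUE(r$is_biomass),
             reversible = !isFALSE(r$reversible))
  })
  metabolic_model(doc$organism_id, mets, rxns, doc$biomass_reaction_id,
                  taxonomy = lapply(doc$taxonomy %||% list(), as.character))
}

#' Read models from a directory
#'
#' @param dir directory containing `*.json` model files.
#' @return a [model_collection()].
#' @export
read_model_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0L)
    stop_validation("no model JSON files found in %s", dir)
  model_collection(lapply(files, read_model))
}

#' Write all models of a collection into a directory
#' @export
write_model_dir <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in collection$models)
    write_model(m, file.path(dir, paste0(m$organism_id, ".json")))
  invisible(dir)
}
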
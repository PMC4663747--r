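## Minimal SBML Level 3 reader (read-only, optional input path).
##
## Covers exactly what the analyses need: species with compartments,
## reactions with stoichiometry and reversibility, flux bounds through the
## fbc package (parameter references or local values), and the active fbc
## objective to locate the biomass reaction. Anything beyond that subset
## (rules, events, annotations, extra compartments' contents) is ignored
## with a single warning. Compartment ids are mapped onto the two-compartment
## scheme: ids in {e, ext, extracellular, C_e} become "extracellular",
## everything else "cytosol".

read_sbml_subset <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_validation(
                    "malformed SBML in %s: %s", path, conditionMessage(e)))
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (is.na(xml2::xml_name(model_node)))
    stop_validation("malformed SBML in %s: no <model> element", path)

  extra <- c("listOfRules", "listOfEvents", "listOfConstraints",
             "listOfInitialAssignments", "listOfFunctionDefinitions")
  seen <- extra[vapply(extra, function(tag) {
    !is.na(xml2::xml_name(xml2::xml_find_first(
      model_node, sprintf("./*[local-name()='%s']", tag))))
  }, logical(1))]
  if (length(seen))
    warning(sprintf("SBML reader: ignoring unsupported element(s) %s in %s",
                    paste(seen, collapse = ", "), path))

  attr_or <- function(node, a, default = NA_character_) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) default else v
  }
  ext_compartment <- function(cid)
    if (tolower(cid) %in% c("e", "ext", "extracellular", "c_e")) "extracellular" else "cytosol"

  species <- xml2::xml_find_all(model_node, ".//*[local-name()='species']")
  mets <- lapply(species, function(s) {
    sid <- xml2::xml_attr(s, "id")
    metabolite(sid, attr_or(s, "name", sid),
               ext_compartment(attr_or(s, "compartment", "c")))
  })

  ## fbc flux-bound parameters
  params <- xml2::xml_find_all(model_node, ".//*[local-name()='parameter']")
  pval <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))

  ## active objective -> biomass reaction id
  fluxobj <- xml2::xml_find_first(model_node, ".//*[local-name()='fluxObjective']")
  biomass_id <- if (!is.na(xml2::xml_name(fluxobj)))
    xml2::xml_attr(fluxobj, "reaction") else NA_character_

  comp_of <- stats::setNames(vapply(mets, `[[`, character(1), "compartment"),
                             vapply(mets, `[[`, character(1), "id"))

  rx_nodes <- xml2::xml_find_all(model_node, ".//*[local-name()='reaction']")
  rxns <- lapply(rx_nodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    reversible <- !identical(xml2::xml_attr(rn, "reversible"), "false")
    stoich <- numeric()
    add_refs <- function(list_tag, sign) {
      for (ref in xml2::xml_find_all(rn, sprintf(
          "./*[local-name()='%s']/*[local-name()='speciesReference']", list_tag))) {
        sp <- xml2::xml_attr(ref, "species")
        k <- suppressWarnings(as.numeric(attr_or(ref, "stoichiometry", "1")))
        if (is.na(k)) k <- 1
        cur <- if (sp %in% names(stoich)) stoich[[sp]] else 0
        stoich[sp] <<- cur + sign * k
      }
    }
    add_refs("listOfReactants", -1)
    add_refs("listOfProducts", +1)
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]] else NULL
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]] else NULL
    ## boundary pseudo-reactions: one extracellular species, not the objective
    is_ex <- length(stoich) == 1L && !identical(rid, biomass_id) &&
      identical(unname(comp_of[names(stoich)]), "extracellular")
    reaction(rid, stoich, lower_bound = lb, upper_bound = ub,
             is_exchange = is_ex,
             is_biomass = identical(rid, biomass_id),
             reversible = reversible)
  })

  if (is.na(biomass_id))
    stop_validation("SBML file %s declares no flux objective (biomass reaction)", path)

  metabolic_model(
    organism_id = attr_or(model_node, "id", basename(path)),
    metabolites = mets, reactions = rxns,
    biomass_reaction_id = biomass_id)
}
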
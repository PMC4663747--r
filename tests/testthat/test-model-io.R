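test_that("toy model round-trips through canonical JSON", {
  m <- toy_chain_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$organism_id, m$organism_id)
  expect_setequal(names(m2$reactions), names(m$reactions))
  expect_equal(sum(vapply(m2$reactions, `[[`, logical(1), "is_biomass")), 1)
  expect_equal(length(exchange_ids(m2)), 1)
  expect_equal(m2$reactions$biomass$stoichiometry, c(B_c = -1))
  ## canonical output: writing the re-read model reproduces identical bytes
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model(m2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("canonicalization makes semantically equal models byte-identical", {
  m1 <- toy_chain_model()
  m2 <- metabolic_model(m1$organism_id,
                        rev(m1$metabolites),
                        rev(m1$reactions),
                        m1$biomass_reaction_id)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_model(m1, p1); write_model(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("write-then-read round-trips 20 generated models byte-identically", {
  cfg <- sim_config(n_organisms = 20, n_features = 30, n_nutrients = 3,
                    n_class = 2, n_genus = 4, seed = 11)
  com <- simulate_community(cfg)
  for (m in com$models$models) {
    p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
    write_model(m, p1)
    write_model(read_model(p1), p2)
    expect_identical(readLines(p1), readLines(p2))
  }
})

test_that("validation reports each violated invariant by entity and rule", {
  m <- toy_chain_model()
  expect_length(validate_model(m), 0)

  ## two biomass reactions
  m2 <- m
  m2$reactions$CORE$is_biomass <- TRUE
  expect_match(paste(validate_model(m2), collapse = " "), "exactly one biomass")

  ## exchange with two metabolites
  m3 <- m
  m3$reactions$EX_A$stoichiometry <- c(A_e = -1, B_c = 1)
  expect_match(paste(validate_model(m3), collapse = " "),
               "exactly one metabolite")

  ## inverted bounds name the reaction
  m4 <- m
  m4$reactions$CORE$lower_bound <- 5
  m4$reactions$CORE$upper_bound <- 1
  v <- validate_model(m4)
  expect_length(v, 1)
  expect_match(v, "CORE")

  ## non-extracellular exchanged metabolite
  m5 <- m
  m5$metabolites[[1]]$compartment <- "cytosol"
  expect_match(paste(validate_model(m5), collapse = " "), "not extracellular")
})

test_that("invalid models are refused on write and read", {
  m <- toy_chain_model()
  m$reactions$CORE$upper_bound <- NaN
  expect_error(write_model(m, withr::local_tempfile()), "bounds")

  good <- toy_chain_model()
  p <- withr::local_tempfile()
  write_model(good, p)
  txt <- readLines(p)
  txt <- sub("\"is_biomass\": false", "\"is_biomass\": true", txt)[
    seq_along(txt)]
  writeLines(txt, p)
  expect_error(read_model(p), "biomass")
})

test_that("malformed files raise parse errors naming the problem", {
  p <- withr::local_tempfile()
  writeLines("{not json", p)
  expect_error(read_model(p), "malformed")
  writeLines('{"organism_id": "x"}', p)
  expect_error(read_model(p), "missing element")
  expect_error(read_model("/nonexistent/file.json"), "does not exist")
})

test_that("presence matrix equals the set-union oracle and is order-invariant", {
  ## forced tiny examples
  m1 <- toy_chain_model(organism_id = "org_a")
  m2 <- toy_chain_model(organism_id = "org_b")
  pm <- build_presence_matrix(model_collection(list(m1, m2)))
  expect_true(all(pm$values == 1))
  expect_equal(dim(pm$values), c(2, 4))

  ## disjoint reaction sets {a, b} vs {c}: block structure
  mk <- function(id, rxn_ids) {
    rxns <- c(lapply(rxn_ids, function(r)
      reaction(r, c(M_c = -1, N_c = 1))),
      list(reaction("EX_Z", c(Z_e = -1), lower_bound = -10, upper_bound = 10,
                    is_exchange = TRUE),
           reaction("bio", c(M_c = -1), is_biomass = TRUE)))
    metabolic_model(id, list(metabolite("M_c"), metabolite("N_c"),
                             metabolite("Z_e", compartment = "extracellular")),
                    rxns, "bio")
  }
  pm2 <- build_presence_matrix(model_collection(list(mk("o1", c("a", "b")),
                                                     mk("o2", "c"))))
  shared <- c("EX_Z", "bio")
  own <- setdiff(colnames(pm2$values), shared)
  expect_equal(pm2$values[, sort(own)],
               matrix(c(1L, 0L, 1L, 0L, 0L, 1L), 2,
                      dimnames = list(c("o1", "o2"), c("a", "b", "c"))))

  ## generated models: column count equals the brute-force union size
  cfg <- sim_config(n_organisms = 20, n_features = 25, n_nutrients = 3,
                    n_class = 2, n_genus = 3, seed = 3)
  com <- simulate_community(cfg)
  pm3 <- build_presence_matrix(com$models)
  union_size <- length(Reduce(union, lapply(com$models$models,
                                            function(m) names(m$reactions))))
  expect_equal(ncol(pm3$values), union_size)
  expect_true(all(colSums(pm3$values) >= 1))

  ## permuting model order only permutes rows
  shuffled <- model_collection(rev(com$models$models))
  pm4 <- build_presence_matrix(shuffled)
  expect_identical(pm4$values, pm3$values)  # canonical sort restores order
})

test_that("duplicate organism ids are rejected", {
  expect_error(model_collection(list(toy_chain_model(), toy_chain_model())),
               "duplicate organism ids")
})

test_that("the SBML subset reader recovers species, bounds, and objective", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2">
 <model id="mini" fbc:strict="true">
  <listOfCompartments>
   <compartment id="c" constant="true"/><compartment id="e" constant="true"/>
  </listOfCompartments>
  <listOfSpecies>
   <species id="A_e" compartment="e" constant="false"/>
   <species id="A_c" compartment="c" constant="false"/>
  </listOfSpecies>
  <listOfParameters>
   <parameter id="lbm10" value="-10" constant="true"/>
   <parameter id="ub1000" value="1000" constant="true"/>
   <parameter id="zero" value="0" constant="true"/>
  </listOfParameters>
  <listOfReactions>
   <reaction id="EX_A" reversible="true" fbc:lowerFluxBound="lbm10" fbc:upperFluxBound="ub1000">
    <listOfReactants><speciesReference species="A_e" stoichiometry="1" constant="true"/></listOfReactants>
   </reaction>
   <reaction id="TR_A" reversible="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub1000">
    <listOfReactants><speciesReference species="A_e" stoichiometry="1" constant="true"/></listOfReactants>
    <listOfProducts><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfProducts>
   </reaction>
   <reaction id="GROW" reversible="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub1000">
    <listOfReactants><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfReactants>
   </reaction>
  </listOfReactions>
  <fbc:listOfObjectives fbc:activeObjective="obj">
   <fbc:objective fbc:id="obj" fbc:type="maximize">
    <fbc:listOfFluxObjectives>
     <fbc:fluxObjective fbc:reaction="GROW" fbc:coefficient="1"/>
    </fbc:listOfFluxObjectives>
   </fbc:objective>
  </fbc:listOfObjectives>
 </model>
</sbml>'
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, p)
  m <- read_model(p, format = "sbml_subset")
  expect_identical(m$biomass_reaction_id, "GROW")
  expect_identical(sort(exchange_ids(m)), "EX_A")
  expect_equal(m$reactions$EX_A$lower_bound, -10)
  expect_equal(m$reactions$TR_A$stoichiometry[["A_c"]], 1)
  comp <- vapply(m$metabolites, `[[`, character(1), "compartment")
  expect_setequal(comp, c("extracellular", "cytosol"))
})
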
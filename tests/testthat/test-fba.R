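test_that("growth optimum is pinned by the uptake bound and stoichiometry", {
  m <- toy_chain_model()
  res <- solve_fba(m)
  expect_identical(res$status, "optimal")
  expect_equal(res$growth_rate, 10)
  expect_equal(unname(res$fluxes["biomass"]), res$growth_rate)
  ## mass balance of the reported flux vector
  expect_lt(max(abs(s_matrix(m) %*% res$fluxes)), 1e-7)

  ## two units of precursor per biomass unit halve the optimum
  res2 <- solve_fba(toy_chain_model(b_per_unit = 2))
  expect_equal(res2$growth_rate, 5)
})

test_that("rich medium opens every exchange at the configured uptake limit", {
  m <- two_substrate_model()
  med <- rich_medium(m)
  expect_setequal(names(med$max_uptake), c("EX_A", "EX_B"))
  expect_true(all(med$max_uptake == 10))
  med2 <- rich_medium(m, screen_config(uptake_limit = 7.5))
  expect_true(all(med2$max_uptake == 7.5))
  ## both substrates feed growth: optimum is the sum of both uptakes
  expect_equal(solve_fba(m, med2)$growth_rate, 15)
})

test_that("metabolite removal closes the exchange and is idempotent", {
  m <- toy_chain_model()
  rich <- rich_medium(m)
  closed <- remove_metabolite(rich, m, "A_e")
  expect_identical(closed$closed, "EX_A")
  expect_false("EX_A" %in% names(closed$max_uptake))
  expect_identical(remove_metabolite(closed, m, "A_e")$closed, "EX_A")
  expect_equal(solve_fba(m, closed)$growth_rate, 0)
  ## the original medium is untouched
  expect_true("EX_A" %in% names(rich$max_uptake))
  expect_error(remove_metabolite(rich, m, "B_c"), "no exchange reaction")
})

test_that("essentiality screen classifies by the growth cutoff", {
  ## single-route chain: the sole carbon source is essential
  scr <- essential_nutrients(toy_chain_model())
  expect_identical(scr$essential, "A_e")
  expect_equal(unname(scr$growth["A_e"]), 0)

  ## interchangeable substrates: neither essential
  scr2 <- essential_nutrients(two_substrate_model())
  expect_length(scr2$essential, 0)
  expect_equal(unname(scr2$growth), c(10, 10))
})

test_that("the 0.05 1/h cutoff splits residual growth 0.049 from 0.051", {
  ## chain model plus a weak bypass producing the precursor at a capped rate
  weak_bypass_model <- function(cap) {
    metabolic_model(
      "toy_weak",
      metabolites = list(metabolite("A_e", compartment = "extracellular"),
                         metabolite("C_e", compartment = "extracellular"),
                         metabolite("B_c")),
      reactions = list(
        reaction("EX_A", c(A_e = -1), lower_bound = -1000, upper_bound = 1000,
                 is_exchange = TRUE),
        reaction("EX_C", c(C_e = -1), lower_bound = -1000, upper_bound = 1000,
                 is_exchange = TRUE),
        reaction("MAIN", c(A_e = -1, B_c = 1)),
        reaction("WEAK", c(C_e = -1, B_c = 1), upper_bound = cap),
        reaction("biomass", c(B_c = -1), is_biomass = TRUE)),
      biomass_reaction_id = "biomass")
  }
  scr_lo <- essential_nutrients(weak_bypass_model(0.049))
  expect_true("A_e" %in% scr_lo$essential)
  expect_equal(unname(scr_lo$growth["A_e"]), 0.049)
  scr_hi <- essential_nutrients(weak_bypass_model(0.051))
  expect_false("A_e" %in% scr_hi$essential)
})

test_that("a model that cannot grow on rich medium aborts the screen", {
  m <- toy_chain_model()
  m$reactions$CORE$upper_bound <- 0.001   # growth far below cutoff
  expect_error(essential_nutrients(m), "baseline infeasible")
})

test_that("anaerobic capability reflects oxygen dependence", {
  expect_true(check_anaerobic_growth(toy_chain_model())$capable)
  aero <- check_anaerobic_growth(oxygen_dependent_model())
  expect_false(aero$capable)
  expect_equal(aero$growth_rate, 0)
  ## with oxygen available the same model grows
  expect_equal(solve_fba(oxygen_dependent_model())$growth_rate, 10)
})

test_that("growth responds monotonically to medium changes", {
  for (seed in 1:10) {
    m <- random_lp_model(seed)
    g5 <- solve_fba(m, rich_medium(m, screen_config(uptake_limit = 5)))$growth_rate
    g10 <- solve_fba(m, rich_medium(m, screen_config(uptake_limit = 10)))$growth_rate
    expect_gte(g10, g5 - 1e-9)
    ## closing any exchange never increases growth
    rich <- rich_medium(m)
    for (ex in exchange_ids(m)) {
      met <- names(m$reactions[[ex]]$stoichiometry)
      g_closed <- solve_fba(m, remove_metabolite(rich, m, met))$growth_rate
      expect_lte(g_closed, g10 + 1e-9)
    }
  }
})

test_that("purely linear networks scale growth with the uptake limit", {
  m <- toy_chain_model()
  g1 <- solve_fba(m, rich_medium(m, screen_config(uptake_limit = 4)))$growth_rate
  g2 <- solve_fba(m, rich_medium(m, screen_config(uptake_limit = 8)))$growth_rate
  expect_equal(g2, 2 * g1)
})

test_that("media validate against the target model", {
  m <- toy_chain_model()
  expect_error(solve_fba(m, medium(c(NOPE = 10))), "non-exchange")
  expect_error(medium(c(EX_A = 10), closed = "EX_A"), "both open and closed")
  ## medium TSV round trip
  med <- medium(c(EX_A = 2.5), closed = "EX_B")
  p <- withr::local_tempfile()
  write_medium_tsv(med, p)
  med2 <- read_medium_tsv(p)
  expect_equal(med2$max_uptake, med$max_uptake)
  expect_identical(med2$closed, med$closed)
})

test_that("uptake-only closure keeps the secretion direction open", {
  ## secretion-capable chain: removal under "both" blocks secretion too
  m <- toy_chain_model()
  rich <- rich_medium(m, screen_config(removal = "uptake_only"))
  closed <- remove_metabolite(rich, m, "A_e")
  bounds <- microrep:::apply_medium(m, closed)
  expect_equal(unname(bounds$lb["EX_A"]), 0)
  expect_gt(unname(bounds$ub["EX_A"]), 0)
})

test_that("LP solutions agree with exhaustive vertex enumeration", {
  ## small-instance spot check (the acceptance suite runs 200 instances)
  for (seed in 1:25) {
    m <- random_lp_model(seed)
    med <- rich_medium(m)
    got <- solve_fba(m, med)$growth_rate
    want <- fba_vertex_optimum(m, med)
    expect_equal(got, want, tolerance = 1e-6)
  }
})
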
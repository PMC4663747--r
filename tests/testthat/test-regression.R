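test_that("pair tables enumerate unordered pairs in canonical order", {
  for (n in c(2, 10, 25)) {
    pf <- random_binary_profile(n, n_org = n, n_feat = 12)
    pt <- pair_table(jaccard_distance(pf))
    expect_equal(nrow(pt), n * (n - 1) / 2)
    expect_true(all(pt$org_i < pt$org_j))
    expect_false(any(duplicated(paste(pt$org_i, pt$org_j))))
  }
  d <- jaccard_distance(random_binary_profile(1, n_org = 5))
  bad <- org_dist(d$values[rev(rownames(d$values)), rev(rownames(d$values))],
                  "phylogenetic")
  expect_error(pair_table(d, bad), "not aligned")
})

test_that("noiseless exponential data is recovered exactly", {
  x <- seq(0.01, 1, length.out = 50)
  pt <- make_pairs(x, y = 10^(-1 + 2 * x))
  fit <- fit_exponential(pt)
  expect_equal(fit$alpha, -1, tolerance = 1e-12)
  expect_equal(fit$beta, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$correlation, 1)
  expect_identical(fit$correlation_kind, "spearman")
  expect_lt(fit$rmse, 1e-12)
})

test_that("degenerate exponential inputs behave as documented", {
  ## constant positive y: slope 0 and (by convention) zero rank correlation
  pt <- make_pairs(seq(0, 1, length.out = 20), y = rep(0.5, 20))
  fit <- fit_exponential(pt)
  expect_equal(fit$beta, 0, tolerance = 1e-12)
  expect_equal(fit$correlation, 0)

  ## y = 0 pairs are excluded from the log fit but kept in n_pairs
  x <- seq(0.01, 1, length.out = 30)
  y <- 10^(-1 + 2 * x); y[1:5] <- 0
  fit2 <- fit_exponential(make_pairs(x, y = y))
  expect_equal(fit2$n_used, 25)
  expect_equal(fit2$n_pairs, 30)
  expect_equal(fit2$beta, 2, tolerance = 1e-12)

  expect_error(fit_exponential(make_pairs(x, y = rep(0, 30))), "y > 0")
  expect_error(fit_exponential(make_pairs(rep(0.3, 30), y = 10^rnorm(30))),
               "zero variance")
})

test_that("noisy exponential data recovers the generating parameters", {
  set.seed(1234)
  x <- runif(2000)
  y <- 10^(-1 + 2 * x + rnorm(2000, sd = 0.1))
  fit <- fit_exponential(make_pairs(x, y = y))
  se <- summary(stats::lm(log10(y) ~ x))$coefficients[, "Std. Error"]
  expect_lt(abs(fit$alpha - (-1)), 3 * se[1])
  expect_lt(abs(fit$beta - 2), 3 * se[2])
  expect_gt(fit$correlation, 0.9)
})

test_that("linear fits match analytic expectations", {
  x <- seq(0, 1, length.out = 40)
  fit <- fit_linear(make_pairs(x, z = 0.1 + 0.5 * x))
  expect_equal(fit$alpha, 0.1, tolerance = 1e-12)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$correlation, 1, tolerance = 1e-12)
  expect_identical(fit$correlation_kind, "pearson")

  fit2 <- fit_linear(make_pairs(x, z = 1 - x))
  expect_equal(fit2$correlation, -1, tolerance = 1e-12)

  ## independent response: small correlation, R^2 near zero
  set.seed(99)
  fit3 <- fit_linear(make_pairs(runif(500), z = runif(500)))
  expect_lt(abs(fit3$correlation), 0.15)
  expect_lt(fit3$r_squared, 0.02)
})

test_that("R^2 of the simple linear fit equals the squared Pearson correlation", {
  set.seed(7)
  for (rep in 1:5) {
    x <- runif(60); z <- 0.3 * x + rnorm(60, sd = 0.2)
    fit <- fit_linear(make_pairs(x, z = z))
    expect_equal(fit$r_squared, fit$correlation^2, tolerance = 1e-12)
  }
})

test_that("taxon subsets restrict pairs and enforce the size minimum", {
  tax <- data.frame(organism = sprintf("o%02d", 1:8),
                    class = rep(c("X", "Y"), c(5, 3)),
                    genus = rep(c("g1", "g2", "g3"), c(3, 2, 3)))
  pf <- random_binary_profile(8, n_org = 8)
  rownames(pf$values) <- tax$organism
  pf <- binary_profile(pf$values, "reaction")
  pt <- pair_table(jaccard_distance(pf))
  sub <- taxon_subset(tax, pt, "class", "X")
  expect_equal(nrow(sub), 10)   # 5 choose 2
  expect_identical(attr(sub, "subset_label"), "class:X")
  expect_true(all(sub$org_i %in% tax$organism[tax$class == "X"]))
  expect_error(taxon_subset(tax, pt, "class", "NOPE"), "at least 3")
  expect_error(taxon_subset(tax, pt, "genus", "g2"), "at least 3")
  expect_error(taxon_subset(tax, pt, "kingdom", "X"), "unknown rank")

  ## union of within-class pair sets is a strict subset of all pairs
  sub2 <- taxon_subset(tax, pt, "class", "Y")
  expect_lt(nrow(sub) + nrow(sub2), nrow(pt))
})

test_that("subset fits are invariant to organism order", {
  com <- simulate_community(sim_config(n_organisms = 16, n_features = 60,
                                       n_nutrients = 4, n_class = 2,
                                       n_genus = 4, seed = 21))
  pm <- build_presence_matrix(com$models)
  d_met <- jaccard_distance(pm)
  d_phy <- cophenetic_distance(com$tree)
  al <- align_organisms(d_met, d_phy)
  pt <- pair_table(al[[1]], al[[2]])
  f1 <- fit_exponential(taxon_subset(com$taxonomy, pt, "class", "cls01"))
  shuffled <- com$taxonomy[rev(seq_len(nrow(com$taxonomy))), ]
  f2 <- fit_exponential(taxon_subset(shuffled, pt, "class", "cls01"))
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-12)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
})

test_that("the fit summary table mirrors the per-taxon layout", {
  com <- simulate_community(sim_config(n_organisms = 20, n_features = 60,
                                       n_nutrients = 4, n_class = 3,
                                       n_genus = 5, seed = 31))
  pm <- build_presence_matrix(com$models)
  ess <- truth_essential_profile(com)
  al <- align_organisms(jaccard_distance(pm), cophenetic_distance(com$tree),
                        jaccard_distance(ess))
  pt <- pair_table(al[[1]], al[[2]], al[[3]])
  classes <- unique(com$taxonomy$class)
  tb <- fit_summary_table(com$taxonomy, pt,
                          as.list(paste0("class:", classes)))
  expect_equal(nrow(tb), 1 + length(classes))
  expect_identical(tb$subset[1], "All taxa")
  ok <- tb$note == ""
  expect_true(ok[1])
  expect_true(all(tb$spearman[ok] >= -1 & tb$spearman[ok] <= 1))

  ## degenerate subset produces an error marker, not a crash
  tb2 <- fit_summary_table(com$taxonomy, pt, list("class:ABSENT"))
  expect_equal(nrow(tb2), 2)
  expect_match(tb2$note[2], "at least 3")
})

test_that("moving averages equal brute-force windowed means", {
  set.seed(17)
  x <- runif(200); y <- runif(200)
  pt <- make_pairs(x, y = y)
  ma <- moving_average(pt, "y", window_fraction = 0.05)
  w <- ceiling(0.05 * 200)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  want <- vapply(seq_len(200 - w + 1),
                 function(i) mean(ys[i:(i + w - 1)]), numeric(1))
  expect_equal(ma$mean_response, want, tolerance = 1e-12)
  expect_true(all(diff(ma$x_center) >= -1e-12))

  ## constant response -> constant curve
  mc <- moving_average(make_pairs(x, y = rep(2, 200)), "y")
  expect_true(all(abs(mc$mean_response - 2) < 1e-12))

  ## response strictly increasing in x -> nondecreasing curve
  mi <- moving_average(make_pairs(x, y = x^2), "y")
  expect_true(all(diff(mi$mean_response) >= -1e-12))

  expect_error(moving_average(make_pairs(numeric(0), y = numeric(0)), "y"),
               "empty")
})
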
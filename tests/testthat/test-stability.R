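test_that("CS-coefficient implements the probability-threshold definition", {
  grid <- seq(0.05, 0.75, by = 0.05)
  all_one <- setNames(lapply(grid, function(q) rep(1, 100)),
                      format(grid, trim = TRUE))
  expect_equal(cs_coefficient(all_one), 0.75)

  all_zero <- setNames(lapply(grid, function(q) rep(0, 100)),
                       format(grid, trim = TRUE))
  expect_equal(cs_coefficient(all_zero), 0)

  # 96% above 0.7 at q = 0.2 qualifies, 94% at q = 0.3 does not
  constructed <- list(
    "0.2" = c(rep(0.9, 96), rep(0.1, 4)),
    "0.3" = c(rep(0.9, 94), rep(0.1, 6)))
  expect_equal(cs_coefficient(constructed), 0.2)

  # pointwise enlarging correlations never decreases the CS value
  bumped <- lapply(constructed, function(v) pmin(v + 0.65, 1))
  expect_gte(cs_coefficient(bumped), cs_coefficient(constructed))

  expect_error(cs_coefficient(list()), "empty")
})

test_that("case-dropping bootstrap is reproducible and tracks signal", {
  pnl <- small_default_panel(n_total = 900, seed = 91)
  cd <- case_drop_bootstrap(pnl, estimator = "clpn", index = "out_strength",
                            drop_grid = c(0.1, 0.25), n_boot = 12, seed = 92,
                            group = "no_diabetes",
                            fit_args = list(selection = "ebic", seed = 93))
  expect_s3_class(cd, "case_drop")
  expect_named(cd$correlations, c("0.1", "0.25"))
  expect_length(cd$correlations[["0.1"]], 12)

  cd2 <- case_drop_bootstrap(pnl, estimator = "clpn", index = "out_strength",
                             drop_grid = c(0.1, 0.25), n_boot = 12, seed = 92,
                             group = "no_diabetes",
                             fit_args = list(selection = "ebic", seed = 93))
  expect_identical(cd$correlations, cd2$correlations)

  # a strong chain graph gives a node-strength ranking that subsamples
  # reproduce at a 25% case drop
  p <- 6
  th <- matrix(0, p, p)
  for (i in 1:(p - 1)) th[i, i + 1] <- th[i + 1, i] <- 1.2
  cbc <- codebook(paste0("I", 1:p),
                  item_group = c(rep("depression", p - 1), "behaviour"))
  w1 <- sample_ising_gibbs(ising_parameters(th, rep(-0.5, p)), 2500,
                           seed = 89, burn_in = 150, thin = 3)
  vals <- array(NA_real_, c(2500, p, 2))
  vals[, , 1] <- w1; vals[, , 2] <- w1
  chain_pnl <- binary_panel(vals, group = rep("diabetes", 2500),
                            codebook = cbc)
  cds <- case_drop_bootstrap(chain_pnl, estimator = "ising",
                             index = "strength", drop_grid = 0.25,
                             n_boot = 12, seed = 90)
  expect_gt(median(cds$correlations[["0.25"]], na.rm = TRUE), 0.6)

  # an estimator returning constant centralities is flagged degenerate
  tiny <- panel_subset(pnl, 1:60)
  expect_warning(
    cd0 <- case_drop_bootstrap(
      tiny, estimator = "ising", index = "strength",
      drop_grid = 0.1, n_boot = 3, seed = 94,
      fit_args = list(gamma = 5)),   # huge penalty: empty graphs throughout
    "constant")
  expect_true(all(is.na(cd0$correlations[["0.1"]])))
})

test_that("edge bootstrap CIs cover planted structure sensibly", {
  p <- 5
  th <- matrix(0, p, p)
  th[1, 2] <- th[2, 1] <- 1.5
  cb <- codebook(paste0("I", 1:p),
                 item_group = c(rep("depression", p - 1), "behaviour"))
  w1 <- sample_ising_gibbs(ising_parameters(th, rep(-0.5, p)), 1200,
                           seed = 95, burn_in = 150, thin = 3)
  vals <- array(NA_real_, c(1200, p, 2))
  vals[, , 1] <- w1
  vals[, , 2] <- simulate_wave5(
    w1, clpn_parameters(rep(0, p), matrix(0, p, p)), seed = 96)
  pnl <- binary_panel(vals, group = rep("diabetes", 1200), codebook = cb)

  ci <- edge_ci_bootstrap(pnl, estimator = "ising", n_boot = 60, seed = 97)
  expect_s3_class(ci, "edge_ci")
  expect_equal(nrow(ci$edges), p * (p - 1) / 2)
  planted <- ci$edges[ci$edges$from == "I1" & ci$edges$to == "I2", ]
  expect_gt(planted$lower, 0)             # strong edge: CI excludes zero
  others <- ci$edges[!(ci$edges$from == "I1" & ci$edges$to == "I2"), ]
  expect_gte(mean(others$lower <= 0 & others$upper >= 0), 0.9)
  expect_true(all(ci$edges$lower <= ci$edges$estimate + 1e-12))
  expect_true(all(ci$edges$upper >= ci$edges$estimate - 1e-12))

  ci2 <- edge_ci_bootstrap(pnl, estimator = "ising", n_boot = 60, seed = 97)
  expect_identical(ci$edges, ci2$edges)
})
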
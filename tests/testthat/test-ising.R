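test_that("nodewise lasso path starts null and satisfies KKT optimality", {
  set.seed(51)
  p <- 5; n <- 1500
  th <- matrix(0, p, p)
  th[1, 2] <- th[2, 1] <- 1.0
  th[2, 3] <- th[3, 2] <- 0.8
  x <- sample_ising_gibbs(ising_parameters(th, rep(-0.3, p)), n,
                          seed = 52, burn_in = 200, thin = 5)
  path <- nodewise_logistic_path(x, node = 2)

  # at the top of the path all slopes are zero and the intercept is the
  # marginal log-odds
  expect_equal(path$df[1], 0)
  expect_equal(unname(path$intercepts[1]), qlogis(mean(x[, 2])),
               tolerance = 1e-6)

  # KKT conditions of the penalized objective, checked independently:
  # (1/n) X_j'(y - mu) equals lambda * sign(beta_j) on the active set and
  # is bounded by lambda elsewhere
  k <- max(which(path$df > 0 & path$df < p - 1))
  lam <- path$lambda[k]
  beta <- path$coefficients[, k]
  X <- x[, -2]; y <- x[, 2]
  mu <- plogis(path$intercepts[k] + as.numeric(X %*% beta))
  grad <- as.numeric(crossprod(X, y - mu)) / n
  active <- beta != 0
  expect_true(all(abs(grad[active] - lam * sign(beta[active])) < 1e-3))
  expect_true(all(abs(grad[!active]) <= lam + 1e-3))
  expect_lt(abs(mean(y - mu)), 1e-6)

  xconst <- x; xconst[, 4] <- 1
  expect_error(nodewise_logistic_path(xconst, node = 4), "constant")
})

test_that("EBIC selection reduces to BIC at gamma 0 and prefers sparsity", {
  fake <- list(lambda = c(0.5, 0.1),
               coefficients = cbind(c(0.4, 0), c(0.4, 0.2)),
               intercepts = c(0, 0), loglik = c(-100, -100), df = c(1L, 2L),
               node = 1L)
  # equal log-likelihoods: the k = 1 candidate must win at any gamma
  sel <- ebic_select(fake, n = 500, p_cand = 4, gamma = 0.25)
  expect_equal(sel$index, 1L)
  expect_equal(unname(sel$coefficients), c(0.4, 0))

  # gamma = 0 equals plain BIC by construction of the criterion
  fake2 <- list(lambda = c(0.5, 0.1),
                coefficients = cbind(c(0.4, 0), c(0.5, 0.2)),
                intercepts = c(0, 0), loglik = c(-110, -100), df = c(1L, 2L),
                node = 1L)
  sel0 <- ebic_select(fake2, n = 500, p_cand = 4, gamma = 0)
  bic <- -2 * fake2$loglik + fake2$df * log(500)
  expect_equal(sel0$index, which.min(bic))
  expect_equal(sel0$ebic, min(bic))
})

test_that("AND/OR assembly follows the rule definitions", {
  cm <- matrix(0, 3, 3)
  cm[1, 2] <- 0.8           # coefficient of node 2 in regression of node 1
  w_and <- assemble_ising(cm, "AND")
  w_or <- assemble_ising(cm, "OR")
  expect_equal(w_and[1, 2], 0)
  expect_equal(w_or[1, 2], 0.4)

  cm[2, 1] <- 0.6
  expect_equal(assemble_ising(cm, "AND")[1, 2], 0.7)
  expect_equal(assemble_ising(cm, "OR")[2, 1], 0.7)

  expect_equal(assemble_ising(matrix(0, 4, 4), "AND"), matrix(0, 4, 4))
})

test_that("fitted Ising networks are symmetric, sparse-consistent and signed", {
  p <- 6
  th <- matrix(0, p, p)
  for (i in 1:(p - 1)) th[i, i + 1] <- th[i + 1, i] <- 1.2
  x <- sample_ising_gibbs(ising_parameters(th, rep(-0.5, p)), 8000,
                          seed = 53, burn_in = 300, thin = 5)
  fit <- ising_fit(x, gamma = 0.25, rule = "AND")
  W <- coef(fit)
  expect_identical(W, t(W))
  expect_true(all(diag(W) == 0))
  # chain support recovered without spurious edges at this n
  expect_identical(unname(W != 0), unname(th != 0))
  expect_true(all(W[th != 0] > 0))
  expect_equal(ising_density(fit), proportion_pct(p - 1, p * (p - 1) / 2))

  # increasing gamma never adds edges
  n_edges <- sapply(c(0, 0.25, 0.5, 1), function(g)
    sum(coef(ising_fit(x, gamma = g)) != 0))
  expect_true(all(diff(n_edges) <= 0))

  # independence yields (near-)empty graphs
  set.seed(54)
  ind <- matrix(rbinom(3000 * p, 1, 0.4), ncol = p)
  expect_lte(sum(coef(ising_fit(ind)) != 0), 2)
})

test_that("ising_fit works on panels and simulate() round-trips the model", {
  pnl <- small_default_panel(n_total = 600, seed = 55)
  fit <- ising_fit(pnl, group = "no_diabetes", items = c("Dep1", "Dep2",
                                                         "Dep3", "P"))
  expect_s3_class(fit, "ising_net")
  expect_equal(fit$items, c("Dep1", "Dep2", "Dep3", "P"))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.ising_net")
  expect_equal(nrow(sm$centrality), 4)

  y <- simulate(fit, nsim = 200, seed = 56, burn_in = 50, thin = 2)
  expect_equal(dim(y), c(200L, 4L))
  expect_true(all(y %in% c(0, 1)))
})
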
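test_that("pgls with lambda 0 reduces exactly to OLS on ultrametric trees", {
  rt <- random_tree_trait(25, 41)
  set.seed(42)
  X <- cbind(x = rnorm(25))
  rownames(X) <- rt$tree$tip.label
  y <- 1 + 0.5 * X[, 1] + rnorm(25, 0, 0.1)
  names(y) <- rt$tree$tip.label
  f0 <- pgls_fit(rt$tree, y, X, lambda = 0)
  fo <- fit_ols(y[rt$tree$tip.label], X[rt$tree$tip.label, , drop = FALSE])
  expect_equal(coef(f0), coef(fo), tolerance = 1e-10)
})

test_that("pgls matches the nlme::gls oracle under Brownian correlation", {
  skip_if_not_installed("nlme")
  rt <- random_tree_trait(40, 43)
  set.seed(44)
  xr <- stats::setNames(rnorm(40), rt$tree$tip.label)
  y <- 2 + 0.3 * xr + rt$x
  X <- cbind(x = xr[rt$tree$tip.label])
  rownames(X) <- rt$tree$tip.label
  f <- pgls_fit(rt$tree, y, X, lambda = 1)
  d <- data.frame(y = y[rt$tree$tip.label], x = xr[rt$tree$tip.label],
                  sp = rt$tree$tip.label)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corBrownian(1, rt$tree, form = ~sp))
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-8)
})

test_that("pgls recovers a generative slope on average", {
  tr <- simulate_yule_tree(150, 0.1, seed = 50)
  slopes <- vapply(1:100, function(i) {
    set.seed(5000 + i)
    xr <- stats::setNames(rnorm(150), tr$tip.label)
    u <- simulate_bm_traits(tr, 0.001, seed = 6000 + i)$tips
    y <- 0.1 * xr + u
    X <- cbind(x = xr)
    rownames(X) <- tr$tip.label
    unname(coef(pgls_fit(tr, y, X))["x"])
  }, numeric(1))
  expect_equal(mean(slopes), 0.1, tolerance = 0.005)
})

test_that("pgls rejects constant predictors", {
  rt <- random_tree_trait(20, 51)
  X <- cbind(x = rep(1, 20))
  rownames(X) <- rt$tree$tip.label
  expect_error(pgls_fit(rt$tree, rt$x, X), "singular")
})

test_that("bpmm posterior agrees with pgls and is seed-reproducible", {
  tr <- simulate_yule_tree(60, 0.1, seed = 60)
  set.seed(61)
  xr <- stats::setNames(rnorm(60), tr$tip.label)
  u <- simulate_bm_traits(tr, 0.002, seed = 62)$tips
  y <- 1 + 0.1 * xr + u
  X <- cbind(x = xr)
  rownames(X) <- tr$tip.label
  b1 <- suppressWarnings(bpmm_sample(tr, y, X, iterations = 6000,
                                     burnin = 1000, thin = 5, seed = 63))
  expect_equal(nrow(b1$Sol), (6000 - 1000) / 5)
  f <- pgls_fit(tr, y, X)
  post_sd <- apply(b1$Sol, 2, sd)
  expect_lt(abs(coef(b1)["x"] - coef(f)["x"]), 3 * post_sd["x"])
  # identical seeds reproduce bit-identically
  b2 <- suppressWarnings(bpmm_sample(tr, y, X, iterations = 6000,
                                     burnin = 1000, thin = 5, seed = 63))
  expect_identical(b1$Sol, b2$Sol)
  # independent seeds agree within Monte-Carlo error
  b3 <- suppressWarnings(bpmm_sample(tr, y, X, iterations = 6000,
                                     burnin = 1000, thin = 5, seed = 64))
  mcse <- post_sd / sqrt(nrow(b1$Sol) / 10)  # generous autocorrelation margin
  expect_lt(abs(coef(b1)["x"] - coef(b3)["x"]), 3 * mcse["x"])
})

test_that("phylogenetic variance collapses when the signal is absent", {
  tr <- simulate_yule_tree(60, 0.1, seed = 70)
  set.seed(71)
  y <- stats::setNames(rnorm(60), tr$tip.label)
  X <- cbind(x = rnorm(60))
  rownames(X) <- tr$tip.label
  b <- suppressWarnings(bpmm_sample(tr, y, X, iterations = 6000,
                                    burnin = 1000, thin = 5, seed = 72))
  expect_lt(median(b$VCV[, "phylo"]), 0.5 * median(b$VCV[, "resid"]))
})

test_that("DIC improves when the true predictor enters the model", {
  tr <- simulate_yule_tree(50, 0.1, seed = 80)
  wins <- vapply(1:10, function(i) {
    set.seed(800 + i)
    xr <- stats::setNames(rnorm(50), tr$tip.label)
    u <- simulate_bm_traits(tr, 0.001, seed = 900 + i)$tips
    y <- 0.5 * xr + u + rnorm(50, 0, 0.05)
    X1 <- cbind(x = xr); rownames(X1) <- tr$tip.label
    X0 <- matrix(numeric(0), 50, 0); rownames(X0) <- tr$tip.label
    b1 <- suppressWarnings(bpmm_sample(tr, y, X1, iterations = 4000,
                                       burnin = 1000, thin = 5,
                                       seed = 1000 + i))
    b0 <- suppressWarnings(bpmm_sample(tr, y, X0, iterations = 4000,
                                       burnin = 1000, thin = 5,
                                       seed = 1100 + i))
    delta_dic(b0$DIC, b1$DIC)$delta > 0
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("pmcmc implements the clamped two-tailed rule", {
  expect_equal(pmcmc(rep(1, 10)), 0.2)
  expect_equal(pmcmc(c(rep(1, 500), rep(-1, 500))), 1.0)
  expect_equal(pmcmc(c(rep(1, 990), rep(-1, 10))), 0.02)
  expect_error(pmcmc(numeric(0)), "draws")
  expect_error(pmcmc(1), "at least 2")
  # distributional behaviour
  set.seed(90)
  expect_gt(pmcmc(rnorm(2000)), 0.8)
  expect_equal(pmcmc(rnorm(2000, mean = 5)), 2 / 2000)
})

test_that("delta_dic applies the >= 2 significance threshold", {
  expect_equal(delta_dic(100, 97), list(delta = 3, significant = TRUE))
  expect_equal(delta_dic(100, 99), list(delta = 1, significant = FALSE))
  r <- delta_dic(-60, -65.98)
  expect_equal(r$delta, 5.98)
  expect_true(r$significant)
  expect_true(delta_dic(97, 100)$significant)   # |delta| rule is two-sided
  expect_error(delta_dic(NA, 1), "finite")
})
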
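test_that("birth and death acceptance ratios are exact inverses", {
  alpha <- function(type, dL, k, m) {
    cochlevol:::rj_log_alpha(type, dL, k, m, pois_mean = 1)
  }
  for (k in 0:5) {
    for (dL in c(-3.3, 0, 1.7)) {
      fwd <- alpha("birth", dL, k, 20)
      rev <- alpha("death", -dL, k + 1, 20)
      expect_equal(fwd + rev, 0, tolerance = 1e-10)
    }
  }
  expect_equal(alpha("relocate", 1.2, 3, 20), 1.2)
  expect_identical(alpha("birth", 0, 20, 20), -Inf)
  expect_identical(alpha("death", 0, 0, 20), -Inf)
})

test_that("with jumps disabled the sampler matches the single-rate estimate", {
  tr <- simulate_yule_tree(48, 0.1, seed = 101)
  x <- simulate_bm_traits(tr, 0.02, seed = 102)$tips
  rs <- rjmcmc_rates(tr, x, generations = 50000, sample_interval = 100,
                     seed = 103,
                     move_weights = c(rate = 1, birth = 0, death = 0,
                                      relocate = 0))
  expect_true(all(rs$samples$k == 0))
  s2 <- attr(pic_contrasts(tr, x), "sigma2_hat")
  expect_equal(mean(rs$samples$r0), s2, tolerance = 0.1)
})

test_that("the sampler is deterministic given a seed", {
  tr <- simulate_yule_tree(24, 0.1, seed = 110)
  x <- simulate_bm_traits(tr, 0.05, seed = 111)$tips
  a <- rjmcmc_rates(tr, x, generations = 20000, sample_interval = 100,
                    seed = 7)
  b <- rjmcmc_rates(tr, x, generations = 20000, sample_interval = 100,
                    seed = 7)
  expect_identical(a$shift_prob, b$shift_prob)
  expect_identical(a$samples, b$samples)
  expect_equal(nrow(a$samples),
               200 - floor(0.25 * 200))  # post burn-in sample count
})

test_that("detection power rises with the simulated rate multiplier", {
  tr <- simulate_yule_tree(48, 0.1, seed = 120)
  n <- 48
  sizes <- vapply((n + 2):(n + tr$Nnode), function(nd) {
    sum(cochlevol:::.clade_nodes(tr, nd) <= n)
  }, numeric(1))
  nd <- ((n + 2):(n + tr$Nnode))[which.min(abs(sizes - 12))]
  probs <- vapply(c(1, 2, 5, 10), function(mult) {
    x <- simulate_bm_traits(tr, 0.02,
                            rate_multipliers = stats::setNames(mult, nd),
                            seed = 121)$tips
    rs <- rjmcmc_rates(tr, x, generations = 100000, sample_interval = 200,
                       seed = 122)
    unname(rs$shift_prob[as.character(nd)])
  }, numeric(1))
  expect_true(all(diff(probs) > -0.05))   # monotone up to MC noise
  expect_gt(probs[4], probs[1])
})

test_that("shift_summary thresholds probabilities and assigns direction", {
  tr <- simulate_yule_tree(32, 0.1, seed = 130)
  n <- 32
  sizes <- vapply((n + 2):(n + tr$Nnode), function(nd) {
    sum(cochlevol:::.clade_nodes(tr, nd) <= n)
  }, numeric(1))
  nd <- ((n + 2):(n + tr$Nnode))[which.min(abs(sizes - 10))]
  # strong rate decrease inside the clade
  x <- simulate_bm_traits(tr, 0.05,
                          rate_multipliers = stats::setNames(0.02, nd),
                          seed = 131)$tips
  rs <- rjmcmc_rates(tr, x, generations = 150000, sample_interval = 200,
                     seed = 132)
  s <- shift_summary(rs, threshold = 0.9)
  if (nrow(s) > 0 && nd %in% s$node) {
    expect_equal(s$direction[s$node == nd], "decrease")
  }
  # a threshold of 1 can never be exceeded
  expect_equal(nrow(shift_summary(rs, threshold = 1)), 0)
})

test_that("input contracts are enforced", {
  tr <- simulate_yule_tree(6, 0.1, seed = 140)
  x <- simulate_bm_traits(tr, 1, seed = 141)$tips
  expect_error(rjmcmc_rates(tr, x, seed = 1), "at least 8 tips")
  tr2 <- simulate_yule_tree(10, 0.1, seed = 142)
  const <- stats::setNames(rep(1, 10), tr2$tip.label)
  expect_error(rjmcmc_rates(tr2, const, seed = 1), "zero variance")
  x2 <- simulate_bm_traits(tr2, 1, seed = 143)$tips
  expect_error(rjmcmc_rates(tr2, x2, seed = 1,
                            move_weights = c(0.5, 0.3, 0.1, 0.1)),
               "equal")
})
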
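test_that("bm_covariance encodes shared path lengths and lambda scaling", {
  expect_equal(unname(bm_covariance(cherry())), diag(2))
  C <- bm_covariance(three_tip())
  expect_equal(C[c("A", "B", "C"), c("A", "B", "C")],
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  C0 <- bm_covariance(three_tip(), lambda = 0)
  expect_equal(unname(C0), diag(c(2, 2, 2)))
  Ch <- bm_covariance(three_tip(), lambda = 0.5)
  expect_equal(Ch["A", "B"], 0.5)
  expect_equal(Ch["A", "A"], 2)
})

test_that("bm_covariance agrees with the ape::vcv oracle on random trees", {
  for (seed in 1:8) {
    tr <- simulate_yule_tree(25, 0.2, seed = seed)
    C <- bm_covariance(tr)
    V <- ape::vcv(tr)[rownames(C), colnames(C)]
    expect_equal(C, V, tolerance = 1e-12)
  }
})

test_that("pic contrasts follow the pruning recursion", {
  p <- pic_contrasts(read_newick("(A:1,B:1);", quiet = TRUE),
                     c(A = 0, B = 2))
  expect_equal(abs(p$contrast), 2 / sqrt(2), tolerance = 1e-9)
  expect_equal(p$node_estimate, 1)

  p4 <- pic_contrasts(four_tip(), c(A = 1, B = 3, C = 5, D = 7))
  expect_equal(sort(p4$node_estimate), c(2, 4, 6))
  expect_equal(attr(p4, "root_estimate"), 4)

  pc <- pic_contrasts(four_tip(), c(A = 2, B = 2, C = 2, D = 2))
  expect_equal(pc$contrast, rep(0, 3))
  expect_equal(pc$node_estimate, rep(2, 3))

  expect_error(pic_contrasts(four_tip(), c(A = 1, B = 2)), "missing")
})

test_that("pic matches ape::pic and estimates sigma2 without bias", {
  for (seed in 1:8) {
    rt <- random_tree_trait(30, seed)
    p <- pic_contrasts(rt$tree, rt$x)
    oracle <- ape::pic(rt$x, rt$tree)
    expect_equal(sort(abs(p$contrast)), sort(abs(unname(oracle))),
                 tolerance = 1e-9)
  }
  # mean of sum(c^2)/(n-1) over replicates approaches the true rate
  tr <- simulate_yule_tree(32, 0.2, seed = 99)
  s2 <- vapply(1:400, function(i) {
    x <- simulate_bm_traits(tr, sigma2 = 0.5, seed = i)$tips
    attr(pic_contrasts(tr, x), "sigma2_hat")
  }, numeric(1))
  expect_equal(mean(s2), 0.5, tolerance = 0.05)
})

test_that("GLS ancestral states satisfy closed forms and PIC equivalence", {
  a <- ancestral_ml_bm(read_newick("(A:1,B:3);", quiet = TRUE),
                       c(A = 0, B = 4))
  expect_equal(attr(a, "root_state"), 1, tolerance = 1e-10)

  a4 <- ancestral_ml_bm(four_tip(), c(A = 1, B = 3, C = 5, D = 7))
  expect_equal(attr(a4, "root_state"), 4, tolerance = 1e-10)

  const <- ancestral_ml_bm(four_tip(), c(A = 2, B = 2, C = 2, D = 2))
  expect_equal(const$estimate, rep(2, 3))
  expect_equal(const$se, rep(0, 3))

  pic_route <- ancestral_states(four_tip(), c(A = 1, B = 3, C = 5, D = 7),
                                method = "PIC")
  expect_equal(attr(pic_route, "method"), "PIC")
  expect_equal(attr(pic_route, "root_state"), attr(a4, "root_state"))
})

test_that("dense and contrast likelihood evaluations coincide", {
  for (seed in 1:6) {
    rt <- random_tree_trait(20, seed)
    for (lam in c(1, 0.6)) {
      l1 <- bm_loglik(rt$tree, rt$x, lambda = lam, method = "dense")
      l2 <- bm_loglik(rt$tree, rt$x, lambda = lam, method = "contrasts")
      expect_equal(as.numeric(l1), as.numeric(l2), tolerance = 1e-8)
      expect_equal(attr(l1, "sigma2"), attr(l2, "sigma2"), tolerance = 1e-8)
    }
  }
})

test_that("lambda transform leaves tip depths and BM likelihood consistent", {
  tr <- simulate_yule_tree(15, 0.2, seed = 3)
  lt <- lambda_transform(tr, 0.4)
  expect_equal(node_depths(lt)[1:15], node_depths(tr)[1:15], tolerance = 1e-12)
  expect_equal(write_newick(lambda_transform(tr, 1)), write_newick(tr))
  # lambda = 1 likelihood identical to untransformed BM likelihood
  x <- simulate_bm_traits(tr, 0.1, seed = 8)$tips
  expect_equal(as.numeric(bm_loglik(tr, x, lambda = 1)),
               as.numeric(bm_loglik(tr, x)))
})

test_that("fit_lambda matches the phytools oracle and flags signal", {
  skip_if_not_installed("phytools")
  # lambda-diluted signal gives an interior optimum both searches can find
  tr <- simulate_yule_tree(60, 0.1, seed = 31)
  x <- simulate_bm_traits(tr, 0.01, lambda = 0.6, seed = 32)$tips
  lf <- fit_lambda(tr, x)
  ps <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(lf$lambda, ps$lambda, tolerance = 1e-3)
  expect_equal(lf$logL, ps$logL, tolerance = 1e-4)
  expect_true(lf$logL >= max(lf$logL0, lf$logL1) - 1e-8)
  expect_true(all(c(lf$p0, lf$p1) >= 0 & c(lf$p0, lf$p1) <= 1))
  # iid data on the same tree: no signal
  set.seed(77)
  y <- stats::setNames(rnorm(60), tr$tip.label)
  lf0 <- fit_lambda(tr, y)
  expect_lt(lf0$lambda, 0.3)
})

test_that("polytomies are resolved with a warning and zero-length branches", {
  poly <- read_newick("(A:1,B:1,C:1);", quiet = TRUE)
  expect_warning(p <- pic_contrasts(poly, c(A = 1, B = 2, C = 3)),
                 "polytomies")
  expect_equal(nrow(p), 2)
})
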
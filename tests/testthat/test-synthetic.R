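test_that("yule simulation produces valid ultrametric trees", {
  tr2 <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(ape::Ntip(tr2), 2)
  expect_true(is_ultrametric(tr2))

  tr <- simulate_yule_tree(100, 0.5, seed = 2)
  expect_equal(tr$Nnode, 99)
  expect_true(is_ultrametric(tr))
  expect_true(ape::is.binary.phylo(tr))
  expect_error(simulate_yule_tree(1, 1), "n_tips")
  expect_error(simulate_yule_tree(10, -1), "positive")
})

test_that("yule root heights match the closed-form expectation", {
  n <- 10; br <- 0.5
  heights <- vapply(1:500, function(i) {
    max(node_depths(simulate_yule_tree(n, br, seed = i))[1:n])
  }, numeric(1))
  expected <- sum(1 / (br * 2:n))
  expect_equal(mean(heights), expected, tolerance = 0.1)
})

test_that("BM simulation has the right moments and multiplier behaviour", {
  tr <- simulate_yule_tree(8, 0.5, seed = 11)
  # zero rate: all tips at the root state
  z <- simulate_bm_traits(tr, sigma2 = 0, root_state = 3, seed = 12)
  expect_equal(unname(z$tips), rep(3, 8))
  # tip variance ~ sigma2 * depth
  depth <- max(node_depths(tr)[1:8])
  tips <- vapply(1:2000, function(i) {
    simulate_bm_traits(tr, sigma2 = 0.5, seed = i)$tips[1]
  }, numeric(1))
  expect_equal(var(tips), 0.5 * depth, tolerance = 0.1 * 0.5 * depth)
  # clade multiplier inflates within-clade divergence
  tr2 <- simulate_yule_tree(32, 0.2, seed = 13)
  n <- 32
  sizes <- vapply((n + 2):(n + tr2$Nnode), function(nd) {
    sum(cochlevol:::.clade_nodes(tr2, nd) <= n)
  }, numeric(1))
  nd <- ((n + 2):(n + tr2$Nnode))[which.min(abs(sizes - 10))]
  cl_tips <- intersect(cochlevol:::.clade_nodes(tr2, nd), 1:n)
  vin <- vout <- numeric(100)
  for (i in 1:100) {
    x <- simulate_bm_traits(tr2, 0.1,
                            rate_multipliers = stats::setNames(10, nd),
                            seed = 5000 + i)$tips
    p <- pic_contrasts(tr2, x)
    inside <- p$node %in% cochlevol:::.clade_nodes(tr2, nd)
    vin[i] <- mean(p$contrast[inside]^2)
    vout[i] <- mean(p$contrast[!inside]^2)
  }
  expect_gt(mean(vin), 3 * mean(vout))
  expect_error(
    simulate_bm_traits(tr, 1, rate_multipliers = stats::setNames(2, 999)),
    "unknown clade")
})

test_that("spiral generator and morphometry measurers agree", {
  g <- generate_spiral_path(2.5, n_points = 86)
  expect_equal(count_turns(g)$quarter_rounded, 2.5)
  expect_equal(polyline_length(g), attr(g, "true_length"), tolerance = 0.005)
  g43 <- generate_spiral_path(2.5, n_points = 43)
  expect_lt(polyline_length(g43), polyline_length(g))
  shortfall <- 1 - polyline_length(g43) / attr(g43, "true_length")
  expect_gt(shortfall, 0.0005)   # a fraction-of-a-percent to a few percent
  expect_lt(shortfall, 0.08)
  expect_error(generate_spiral_path(0), "positive")
  expect_error(generate_spiral_path(2, n_points = 1), "at least 2")
})

test_that("generators are bit-reproducible and validator-clean", {
  cfg <- study_config(n_species = 40, seed = 500)
  d1 <- generate_study_dataset(cfg)
  d2 <- generate_study_dataset(cfg)
  expect_identical(d1$traits, d2$traits)
  expect_identical(write_newick(d1$tree), write_newick(d2$tree))
  expect_identical(d1$calibration, d2$calibration)
  expect_silent(validate_phylogeny(d1$tree))
  expect_silent(validate_trait_table(d1$traits))
  expect_error(study_config(n_species = 40), "seed")
})

test_that("zero-noise datasets sit on the allometry; offsets push above", {
  quiet_cfg <- study_config(n_species = 60, seed = 501, echo_offset = 0,
                            bm_sigma2 = 0, noise_sd = 0)
  ds <- generate_study_dataset(quiet_cfg)
  d <- data.frame(log_membrane = log10(ds$traits$membrane_length),
                  log_mass_cuberoot = log10(ds$traits$mass) / 3)
  f <- fit_allometry(log_membrane ~ log_mass_cuberoot, d)
  cls <- suppressWarnings(
    classify_by_interval(f, d$log_mass_cuberoot, d$log_membrane))
  expect_true(all(cls$class == "within"))

  # echolocator offset of 4 noise sds: most echolocators flagged above
  loud_cfg <- study_config(n_species = 120, seed = 502, echo_offset = 0.2,
                           bm_sigma2 = 0, noise_sd = 0.05)
  ds2 <- generate_study_dataset(loud_cfg)
  echo <- ds2$traits$echolocation_type != "none"
  d2 <- data.frame(log_membrane = log10(ds2$traits$membrane_length),
                   log_mass_cuberoot = log10(ds2$traits$mass) / 3)
  f2 <- fit_allometry(log_membrane ~ log_mass_cuberoot, d2, exclude = echo)
  cls2 <- classify_by_interval(f2, d2$log_mass_cuberoot[echo],
                               d2$log_membrane[echo])
  expect_gt(mean(cls2$class == "above"), 0.5)
})
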
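test_that("built-in coefficient sets load and evaluate", {
  phylo <- builtin_call_freq_model("davies2013_phylo")
  ols <- builtin_call_freq_model("davies2013_ols")
  expect_s3_class(phylo, "call_freq_model")
  expect_false(isTRUE(all.equal(phylo$intercept, ols$intercept)))
  # degenerate model: constant prediction regardless of morphology
  flat <- call_freq_model(data.frame(parameter = c("min", "peak", "max"),
                                     intercept = 2, log_membrane = 0,
                                     log_turns = 0))
  expect_equal(unname(predict_call_frequencies(5, 2, flat)), rep(100, 3))
  expect_equal(unname(predict_call_frequencies(20, 3.5, flat)), rep(100, 3))
})

test_that("ancestral morphology reproduces the published call predictions", {
  f <- predict_call_frequencies(11.75, 2.45)
  expect_equal(unname(f["min"]), 38.3, tolerance = 0.01)
  expect_equal(unname(f["peak"]), 52.1, tolerance = 0.01)
  expect_equal(unname(f["max"]), 65.4, tolerance = 0.01)
  expect_error(predict_call_frequencies(-1, 2), "positive")
  expect_error(predict_call_frequencies(10, 0), "positive")
})

test_that("noise-free calibration recovers generating coefficients exactly", {
  set.seed(201)
  n <- 20
  traits <- data.frame(species = paste0("s", 1:n),
                       membrane_length = runif(n, 5, 15),
                       turns = runif(n, 1.5, 3.5),
                       mass = runif(n, 5, 500))
  rel <- relative_membrane_length(traits$membrane_length, traits$mass)
  aud <- data.frame(species = traits$species,
                    hf30 = 10^(3.0 - 1.8 * log10(rel)),
                    hf60 = 10^(3.2 - 1.8 * log10(rel)),
                    lf30 = 10^(2.0 - 0.7 * log10(traits$membrane_length) *
                                 traits$turns),
                    lf60 = 10^(2.1 - 0.7 * log10(traits$membrane_length) *
                                 traits$turns))
  cal <- fit_hearing_calibration(aud, traits)
  expect_equal(unname(coef(cal$fits$hf30)), c(3.0, -1.8), tolerance = 1e-10)
  expect_equal(unname(coef(cal$fits$lf60)), c(2.1, -0.7), tolerance = 1e-10)
  # round trip: predictions equal the generating curves
  pred <- predict_hearing_limits(10, 2.5, 50, cal)
  rel0 <- relative_membrane_length(10, 50)
  expect_equal(unname(pred["hf30"]), 10^(3.0 - 1.8 * log10(rel0)),
               tolerance = 1e-8)
  expect_equal(unname(pred["lf30"]), 10^(2.0 - 0.7 * log10(10) * 2.5),
               tolerance = 1e-8)
  expect_error(fit_hearing_calibration(aud[1:3, ], traits), "insufficient")
})

test_that("noisy calibration recovers coefficients within their CIs", {
  hits <- vapply(1:30, function(i) {
    set.seed(300 + i)
    n <- 38   # 14 bats + 24 non-bats in the emulated design
    traits <- data.frame(species = paste0("s", 1:n),
                         membrane_length = runif(n, 4, 40),
                         turns = runif(n, 1.5, 4),
                         mass = 10^runif(n, 0.5, 5))
    rel <- relative_membrane_length(traits$membrane_length, traits$mass)
    aud <- data.frame(species = traits$species,
                      hf30 = 10^(3.0 - 1.8 * log10(rel) + rnorm(n, 0, 0.05)),
                      hf60 = 10^(3.2 - 1.8 * log10(rel) + rnorm(n, 0, 0.05)),
                      lf30 = 10^(2.0 - 0.7 * log10(traits$membrane_length) *
                                   traits$turns + rnorm(n, 0, 0.05)),
                      lf60 = 10^(2.1 - 0.7 * log10(traits$membrane_length) *
                                   traits$turns + rnorm(n, 0, 0.05)))
    f <- fit_hearing_calibration(aud, traits)$fits$hf30
    ci <- coef(f)[2] + c(-1, 1) * qt(0.975, f$df_residual) * f$se[2]
    ci[1] <= -1.8 && -1.8 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("predictions respond to morphology with the fitted signs", {
  set.seed(210)
  n <- 12
  traits <- data.frame(species = paste0("s", 1:n),
                       membrane_length = seq(5, 16, length.out = n),
                       turns = seq(1.5, 3.5, length.out = n),
                       mass = rep(20, n))
  rel <- relative_membrane_length(traits$membrane_length, traits$mass)
  aud <- data.frame(species = traits$species,
                    hf30 = 10^(3.0 - 2 * log10(rel)),
                    hf60 = 10^(3.2 - 2 * log10(rel)),
                    lf30 = 10^(2.0 - 0.8 * log10(traits$membrane_length) *
                                 traits$turns),
                    lf60 = 10^(2.0 - 0.8 * log10(traits$membrane_length) *
                                 traits$turns))
  cal <- fit_hearing_calibration(aud, traits)
  # longer relative membranes predict lower high-frequency limits
  h <- vapply(c(8, 10, 12, 14), function(m) {
    predict_hearing_limits(m, 2.5, 20, cal)["hf60"]
  }, numeric(1))
  expect_true(all(diff(h) < 0))
  # mass x 8 halves relative length, scaling the prediction by 2^(-slope):
  # with slope -2 on log10 relative length the limit quadruples
  p1 <- predict_hearing_limits(10, 2.5, 20, cal)["hf60"]
  p8 <- predict_hearing_limits(10, 2.5, 160, cal)["hf60"]
  expect_equal(unname(p8 / p1), 4, tolerance = 1e-8)
  # intervals bracket the point prediction (zero-width here: exact fit)
  pi_ <- suppressWarnings(predict_hearing_limits(10, 2.5, 20, cal,
                                                 interval = TRUE))
  expect_true(all(pi_[, "lwr"] <= pi_[, "fit"] & pi_[, "fit"] <= pi_[, "upr"]))
})
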
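#' Echolocation call-frequency model
#'
#' A set of log10-scale regressions, one per call parameter (minimum, peak
#' and maximum frequency), each of the form
#' `log10(kHz) = intercept + c_m * log10(membrane mm) + c_t * log10(turns)`.
#' Membrane length here is absolute (mm), not mass-scaled.
#'
#' @param coefs data.frame with columns `parameter` (containing `min`,
#'   `peak`, `max`), `intercept`, `log_membrane`, `log_turns`.
#' @param provenance character tag recording where the coefficients come
#'   from.
#' @return an object of class `call_freq_model`.
#' @export
call_freq_model <- function(coefs, provenance = "user") {
  coefs <- as.data.frame(coefs)
  need <- c("parameter", "intercept", "log_membrane", "log_turns")
  if (!all(need %in% names(coefs))) {
    stop("coefficient table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("min", "peak", "max") %in% coefs$parameter)) {
    stop("need coefficient rows for min, peak and max frequency", call. = FALSE)
  }
  rownames(coefs) <- coefs$parameter
  structure(coefs[c("min", "peak", "max"), need],
            provenance = provenance, class = c("call_freq_model", "data.frame"))
}

#' Built-in call-frequency coefficient sets
#'
#' `"davies2013_phylo"`: coefficients from Bayesian phylogenetic mixed
#' models of call frequency on cochlear morphology across laryngeal
#' echolocators. `"davies2013_ols"`: the corresponding non-phylogenetic
#' stepwise-regression set. Both ship as data files under `extdata`.
#'
#' @param name which set to load.
#' @return a `call_freq_model`.
#' @export
builtin_call_freq_model <- function(name = c("davies2013_phylo",
                                             "davies2013_ols")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("call_freq_", name, ".csv"),
                      package = "cochlevol", mustWork = TRUE)
  call_freq_model(read.csv(path), provenance = name)
}

#' @export
print.call_freq_model <- function(x, ...) {
  cat("Call-frequency model (", attr(x, "provenance"), "):\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Predict echolocation call frequencies from cochlear morphology
#'
#' Evaluates each regression of a [call_freq_model()] at the given
#' morphology and anti-logs, giving frequencies in kHz. A predicted
#' minimum above the predicted maximum triggers a warning (the model
#' parameters are fitted independently, so ordering is not guaranteed).
#'
#' @param membrane_length basilar membrane length in mm (> 0).
#' @param turns number of cochlear turns (> 0).
#' @param model a `call_freq_model`; default the phylogenetically
#'   corrected built-in set.
#' @return named numeric vector (or matrix, when vectorised) with entries
#'   `min`, `peak`, `max` in kHz.
#' @export
predict_call_frequencies <- function(membrane_length, turns,
                                     model = builtin_call_freq_model()) {
  if (any(!is.finite(membrane_length)) || any(membrane_length <= 0) ||
      any(!is.finite(turns)) || any(turns <= 0)) {
    stop("membrane length and turns must be finite and positive",
         call. = FALSE)
  }
  stopifnot(inherits(model, "call_freq_model"))
  lm_ <- log10(membrane_length)
  lt_ <- log10(turns)
  out <- sapply(c("min", "peak", "max"), function(p) {
    10^(model[p, "intercept"] + model[p, "log_membrane"] * lm_ +
          model[p, "log_turns"] * lt_)
  })
  if (is.matrix(out)) {
    bad <- out[, "min"] > out[, "max"]
  } else {
    bad <- out["min"] > out["max"]
  }
  if (any(bad)) {
    warning("predicted minimum frequency exceeds predicted maximum",
            call. = FALSE)
  }
  out
}

#' Fit hearing-limit calibration regressions
#'
#' Four OLS regressions on log10 kHz hearing limits from published-style
#' audiograms: the high-frequency limits (at 30 and 60 dB) on log10
#' relative basilar membrane length, and the low-frequency limits (30 and
#' 60 dB) on the product of log10 membrane length (mm) and the number of
#' cochlear turns.
#'
#' @param audiograms data.frame with columns `species`, `hf30`, `hf60`,
#'   `lf30`, `lf60` (limits in kHz).
#' @param traits trait table with columns `species`, `membrane_length`,
#'   `turns`, `mass`.
#' @param exponent mass-scaling exponent for relative length (default 1/3).
#' @return an object of class `hearing_calibration`: a list of four
#'   `allo_fit`s (`hf30`, `hf60`, `lf30`, `lf60`).
#' @export
fit_hearing_calibration <- function(audiograms, traits, exponent = 1/3) {
  need_a <- c("species", "hf30", "hf60", "lf30", "lf60")
  need_t <- c("species", "membrane_length", "turns", "mass")
  if (!all(need_a %in% names(audiograms))) {
    stop("audiogram table needs columns: ", paste(need_a, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_t %in% names(traits))) {
    stop("trait table needs columns: ", paste(need_t, collapse = ", "),
         call. = FALSE)
  }
  d <- merge(audiograms, traits[need_t], by = "species")
  d <- d[complete.cases(d[c("hf30", "hf60", "lf30", "lf60",
                            "membrane_length", "turns", "mass")]), ]
  if (nrow(d) < 4) {
    stop("insufficient species: need >= 4 with both traits and audiogram ",
         "limits, got ", nrow(d), call. = FALSE)
  }
  rel <- relative_membrane_length(d$membrane_length, d$mass, exponent)
  x_high <- cbind(log_rel_membrane = log10(rel))
  x_low <- cbind(log_membrane_x_turns = log10(d$membrane_length) * d$turns)
  fits <- list(
    hf30 = fit_ols(log10(d$hf30), x_high, labels = d$species),
    hf60 = fit_ols(log10(d$hf60), x_high, labels = d$species),
    lf30 = fit_ols(log10(d$lf30), x_low, labels = d$species),
    lf60 = fit_ols(log10(d$lf60), x_low, labels = d$species))
  structure(list(fits = fits, exponent = exponent, n = nrow(d)),
            class = "hearing_calibration")
}

#' @export
print.hearing_calibration <- function(x, ...) {
  cat("Hearing-limit calibration on", x$n, "species\n")
  for (nm in names(x$fits)) {
    cat(sprintf("  %s: log10(kHz) = %.3f %+.3f * %s (RSE %.3f)\n", nm,
                x$fits[[nm]]$coefficients[1], x$fits[[nm]]$coefficients[2],
                names(x$fits[[nm]]$coefficients)[2], x$fits[[nm]]$sigma))
  }
  invisible(x)
}

#' Predict hearing limits from cochlear morphology
#'
#' High-frequency limits use log10 relative membrane length (mass-scaled);
#' low-frequency limits use the log10(membrane) x turns product. Values
#' are anti-logged to kHz; optional prediction intervals propagate the
#' calibration uncertainty.
#'
#' @inheritParams predict_call_frequencies
#' @param mass body mass in g (> 0).
#' @param calibration a fitted `hearing_calibration`.
#' @param interval if `TRUE`, return prediction intervals.
#' @param level interval coverage (default 0.95).
#' @return named vector of limits in kHz (`hf30`, `hf60`, `lf30`, `lf60`),
#'   or a matrix with `fit`, `lwr`, `upr` when `interval = TRUE`.
#' @export
predict_hearing_limits <- function(membrane_length, turns, mass, calibration,
                                   interval = FALSE, level = 0.95) {
  stopifnot(inherits(calibration, "hearing_calibration"))
  if (any(c(membrane_length, turns, mass) <= 0) ||
      any(!is.finite(c(membrane_length, turns, mass)))) {
    stop("morphology inputs must be finite and positive", call. = FALSE)
  }
  rel <- relative_membrane_length(membrane_length, mass, calibration$exponent)
  x_high <- log10(rel)
  x_low <- log10(membrane_length) * turns
  xs <- list(hf30 = x_high, hf60 = x_high, lf30 = x_low, lf60 = x_low)
  if (!interval) {
    return(vapply(names(xs), function(nm) {
      10^predict(calibration$fits[[nm]], xs[[nm]])
    }, numeric(1)))
  }
  out <- t(vapply(names(xs), function(nm) {
    10^prediction_interval(calibration$fits[[nm]], xs[[nm]], level = level)[1, ]
  }, numeric(3)))
  colnames(out) <- c("fit", "lwr", "upr")
  out
}
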
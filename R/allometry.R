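#' Ordinary least-squares fit storing everything needed for intervals
#'
#' Fits `y = b0 + X b + e` by OLS (an intercept is always included). The
#' returned object stores the coefficients, residual standard error,
#' residual degrees of freedom, R^2, the overall F test, the predictor
#' means and the unscaled inverse cross-product matrix, which together
#' suffice to reproduce predictions and prediction intervals without the
#' original data.
#'
#' @param y numeric response vector.
#' @param X numeric predictor vector or matrix (one column per predictor,
#'   no intercept column).
#' @param labels optional observation labels (stored, used by classifiers).
#' @return an object of class `allo_fit`.
#' @export
fit_ols <- function(y, X, labels = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X) + 1L
  if (n <= p - 1L) stop("need more observations than parameters", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in y or X", call. = FALSE)
  }
  Xa <- cbind("(Intercept)" = 1, X)
  qx <- qr(Xa)
  if (qx$rank < ncol(Xa)) {
    stop("singular design: predictors are collinear or constant", call. = FALSE)
  }
  if (n == p) stop("no residual degrees of freedom", call. = FALSE)
  fit <- lm.fit(Xa, y)
  res <- fit$residuals
  df_res <- n - p
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  if (rss <= 1e-20 * max(tss, .Machine$double.eps)) rss <- 0  # exact fit

  sigma <- sqrt(rss / df_res)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  f <- if (rss > 0) ((tss - rss) / (p - 1)) / (rss / df_res) else Inf
  pval <- if (is.finite(f)) pf(f, p - 1, df_res, lower.tail = FALSE) else 0
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(Xa), colnames(Xa))
  se <- sigma * sqrt(diag(xtx_inv))
  structure(list(
    coefficients = setNames(fit$coefficients, colnames(Xa)),
    se = se,
    sigma = sigma,
    df_residual = df_res,
    r_squared = r2,
    fstatistic = c(value = f, numdf = p - 1, dendf = df_res),
    p_value = pval,
    n = n,
    x_means = colMeans(X),
    xtx_inv = xtx_inv,
    labels = labels
  ), class = "allo_fit")
}

#' Allometric regression from a formula and trait table
#'
#' Convenience wrapper for [fit_ols()] fitting a reference allometry on a
#' subset of species. The reference set is chosen by a caller-supplied
#' logical mask (e.g. excluding bats and whales), never by built-in taxon
#' lists.
#'
#' @param formula model formula, e.g. `log_membrane ~ log_mass_cuberoot`.
#' @param data data.frame containing the model variables (and optionally a
#'   `species` column used for labels).
#' @param exclude logical vector marking rows to leave out of the fit.
#' @return an `allo_fit`.
#' @export
fit_allometry <- function(formula, data, exclude = NULL) {
  if (!is.null(exclude)) {
    stopifnot(length(exclude) == nrow(data))
    data <- data[!exclude, , drop = FALSE]
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  labels <- if ("species" %in% names(data)) data$species else rownames(data)
  fit_ols(y, X, labels = labels)
}

#' @export
print.allo_fit <- function(x, ...) {
  cat("Ordinary least-squares allometric fit\n")
  cat("  n =", x$n, ", residual df =", x$df_residual, "\n  coefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  RSE = %.4g, R^2 = %.3f, F(%d, %d) = %.3f, p = %.3g\n",
              x$sigma, x$r_squared, x$fstatistic["numdf"],
              x$fstatistic["dendf"], x$fstatistic["value"], x$p_value))
  invisible(x)
}

#' @export
summary.allo_fit <- function(object, ...) {
  tval <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = tval,
               `Pr(>|t|)` = 2 * pt(abs(tval), object$df_residual,
                                   lower.tail = FALSE))
  out <- list(coefficients = tab, sigma = object$sigma,
              df_residual = object$df_residual, r_squared = object$r_squared,
              fstatistic = object$fstatistic, p_value = object$p_value)
  class(out) <- "summary.allo_fit"
  out
}

#' @export
print.summary.allo_fit <- function(x, ...) {
  stats::printCoefmat(x$coefficients)
  cat(sprintf("RSE %.4g on %d df; R^2 %.3f; F(%d, %d) = %.3f, p = %.3g\n",
              x$sigma, x$df_residual, x$r_squared, x$fstatistic["numdf"],
              x$fstatistic["dendf"], x$fstatistic["value"], x$p_value))
  invisible(x)
}

#' @export
coef.allo_fit <- function(object, ...) object$coefficients

#' @export
predict.allo_fit <- function(object, newdata, ...) {
  X0 <- .as_predictor_matrix(object, newdata)
  drop(cbind(1, X0) %*% object$coefficients)
}

.as_predictor_matrix <- function(fit, x0) {
  k <- length(fit$coefficients) - 1L
  X0 <- as.matrix(x0)
  if (ncol(X0) == 1L && k > 1L) X0 <- matrix(X0, ncol = k, byrow = TRUE)
  if (k == 1L && ncol(X0) != 1L) X0 <- matrix(as.numeric(X0), ncol = 1L)
  if (ncol(X0) != k) {
    stop("newdata has ", ncol(X0), " columns, fit has ", k, " predictors",
         call. = FALSE)
  }
  X0
}

#' Prediction interval for a fitted allometry
#'
#' Interval for a new observation at predictor values `x0`:
#' `yhat +/- t(1 - alpha/2, df) * RSE * sqrt(1 + leverage(x0))`. The width
#' is minimal at the predictor mean and grows with leverage. A degenerate
#' fit (RSE = 0) returns a zero-width interval with a warning.
#'
#' @param fit an `allo_fit`.
#' @param x0 predictor values: vector (recycled as rows for a single
#'   predictor) or matrix with one row per prediction point.
#' @param level coverage level, default 0.95.
#' @return matrix with columns `fit`, `lwr`, `upr`.
#' @export
prediction_interval <- function(fit, x0, level = 0.95) {
  stopifnot(inherits(fit, "allo_fit"), level > 0, level < 1)
  if (fit$df_residual < 1L) stop("need residual df >= 1", call. = FALSE)
  X0 <- .as_predictor_matrix(fit, x0)
  Xa <- cbind(1, X0)
  yhat <- drop(Xa %*% fit$coefficients)
  lev <- rowSums((Xa %*% fit$xtx_inv) * Xa)
  if (fit$sigma == 0) {
    warning("degenerate fit (zero residual error): zero-width interval",
            call. = FALSE)
  }
  tq <- qt(1 - (1 - level) / 2, fit$df_residual)
  half <- tq * fit$sigma * sqrt(1 + lev)
  cbind(fit = yhat, lwr = yhat - half, upr = yhat + half)
}

#' Classify points against the prediction interval of a reference fit
#'
#' Each point is labelled `above`, `within` or `below` the level-`level`
#' prediction interval of `fit` at its own predictor value, the criterion
#' used to flag species lying off a reference allometry.
#'
#' @param fit an `allo_fit` (the reference regression).
#' @param x predictor values of the points to classify.
#' @param y observed responses.
#' @param labels optional point labels.
#' @inheritParams prediction_interval
#' @return data.frame with columns `label`, `x` (first predictor), `y`,
#'   `fit`, `lwr`, `upr`, `class`.
#' @export
classify_by_interval <- function(fit, x, y, labels = NULL, level = 0.95) {
  pi_ <- prediction_interval(fit, x, level = level)
  if (nrow(pi_) != length(y)) stop("x and y lengths differ", call. = FALSE)
  # a point on the boundary (to machine precision) counts as within
  tol <- sqrt(.Machine$double.eps) * pmax(1, abs(pi_[, "fit"]))
  cls <- ifelse(y > pi_[, "upr"] + tol, "above",
                ifelse(y < pi_[, "lwr"] - tol, "below", "within"))
  X0 <- .as_predictor_matrix(fit, x)
  data.frame(
    label = if (is.null(labels)) as.character(seq_along(y)) else labels,
    x = X0[, 1], y = y, fit = pi_[, "fit"], lwr = pi_[, "lwr"],
    upr = pi_[, "upr"],
    class = factor(cls, levels = c("above", "within", "below")),
    stringsAsFactors = FALSE)
}
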
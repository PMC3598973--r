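#' Phylogenetic generalized least squares
#'
#' GLS regression whose error covariance is the (lambda-scaled) BM matrix
#' of the tree. With `lambda = 0` on an ultrametric tree the error
#' covariance is proportional to the identity and the fit reduces exactly
#' to [fit_ols()]. `lambda = "ml"` profiles lambda by maximum likelihood.
#'
#' @param tree an [ape::phylo] object.
#' @param y named numeric response (names = tip labels) or in tip order.
#' @param X predictor vector or matrix (no intercept column), rows in the
#'   same order as `y`.
#' @param lambda a value in \[0, 1\], or `"ml"`.
#' @return an object of class `c("pgls_fit", "allo_fit")` with the fields
#'   of an `allo_fit` plus `lambda` and `logLik`.
#' @export
pgls_fit <- function(tree, y, X, lambda = 1) {
  y <- .match_trait(tree, setNames(as.numeric(y),
                                   if (is.null(names(y))) NULL else names(y)))
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (nrow(X) != length(y)) stop("X rows must match y", call. = FALSE)
  if (!is.null(rownames(X))) X <- X[tree$tip.label, , drop = FALSE]
  if (identical(lambda, "ml")) {
    prof <- function(l) .pgls_core(tree, y, X, l)$logLik
    grid <- seq(0, 1, by = 0.1)
    vals <- vapply(grid, prof, numeric(1))
    i <- which.max(vals)
    opt <- optimize(prof, c(grid[max(i - 1, 1)], grid[min(i + 1, length(grid))]),
                    maximum = TRUE, tol = 1e-6)
    lambda <- if (opt$objective >= max(vals[1], vals[length(vals)]))
      opt$maximum else grid[i]
  }
  out <- .pgls_core(tree, y, X, lambda)
  out
}

.pgls_core <- function(tree, y, X, lambda) {
  n <- length(y)
  p <- ncol(X) + 1L
  V <- bm_covariance(tree, lambda)
  R <- chol(V)
  Xa <- cbind("(Intercept)" = 1, X)
  yw <- forwardsolve(t(R), y)
  Xw <- forwardsolve(t(R), Xa)
  qx <- qr(Xw)
  if (qx$rank < p) stop("singular design: predictors are collinear or constant",
                        call. = FALSE)
  fit <- lm.fit(Xw, yw)
  res <- fit$residuals
  rss <- sum(res^2)
  df_res <- n - p
  sigma <- sqrt(rss / df_res)
  # null model: GLS intercept only
  w0 <- forwardsolve(t(R), rep(1, n))
  mu0 <- sum(w0 * yw) / sum(w0^2)
  tss <- sum((yw - mu0 * w0)^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  f <- if (rss > 0) ((tss - rss) / (p - 1)) / (rss / df_res) else Inf
  pval <- if (is.finite(f)) pf(f, p - 1, df_res, lower.tail = FALSE) else 0
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(Xa), colnames(Xa))
  sigma2_ml <- rss / n
  logLik <- -0.5 * (n * log(2 * pi * sigma2_ml) + 2 * sum(log(diag(R))) + n)
  structure(list(
    coefficients = setNames(fit$coefficients, colnames(Xa)),
    se = sigma * sqrt(diag(xtx_inv)),
    sigma = sigma, df_residual = df_res, r_squared = r2,
    fstatistic = c(value = f, numdf = p - 1, dendf = df_res),
    p_value = pval, n = n, x_means = colMeans(X), xtx_inv = xtx_inv,
    labels = tree$tip.label, lambda = lambda, logLik = logLik
  ), class = c("pgls_fit", "allo_fit"))
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic GLS (lambda = %.3f, logLik = %.3f)\n",
              x$lambda, x$logLik))
  print(round(x$coefficients, 4))
  cat(sprintf("  RSE = %.4g, R^2 = %.3f, n = %d\n", x$sigma, x$r_squared, x$n))
  invisible(x)
}

#' Bayesian phylogenetic mixed model by Gibbs sampling
#'
#' Linear mixed model `y = X b + u + e` with a phylogenetic random effect
#' `u ~ N(0, sigma2_p C)` (C the BM covariance of the tree) and residual
#' `e ~ N(0, sigma2_e I)`. Priors: improper flat on fixed effects,
#' inverse-gamma(`prior_shape`, `prior_scale`) on both variance components.
#' All conditionals are conjugate, so the chain is a pure Gibbs sampler;
#' the phylogenetic effect is sampled in the eigenbasis of C, where its
#' conditional is diagonal. DIC is computed as
#' `2 * mean(deviance) - deviance(posterior means)` with the conditional
#' Gaussian deviance, the convention of the standard BPMM tooling.
#'
#' @inheritParams pgls_fit
#' @param iterations total MCMC iterations (default 13000).
#' @param thin record every `thin`-th post-burn-in iteration (default 10).
#' @param burnin iterations discarded before recording (default 3000).
#' @param seed RNG seed (required for reproducibility).
#' @param prior_shape,prior_scale inverse-gamma hyperparameters (0.001,
#'   0.001 by default).
#' @return an object of class `bpmm`: fixed-effect draws (`Sol`), variance
#'   draws (`VCV`), per-draw deviance, `DIC`, `pMCMC`, split-chain
#'   diagnostics and chain metadata.
#' @export
bpmm_sample <- function(tree, y, X, iterations = 13000, thin = 10,
                        burnin = 3000, seed = NULL,
                        prior_shape = 0.001, prior_scale = 0.001) {
  stopifnot(iterations > burnin, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  y <- .match_trait(tree, setNames(as.numeric(y),
                                   if (is.null(names(y))) NULL else names(y)))
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (!is.null(rownames(X))) X <- X[tree$tip.label, , drop = FALSE]
  n <- length(y)
  Xa <- cbind("(Intercept)" = 1, X)
  p <- ncol(Xa)
  if (qr(Xa)$rank < p) stop("singular design", call. = FALSE)
  C <- bm_covariance(tree)
  C <- C / mean(diag(C))        # unit-diagonal-scale so sigma2_p is per-trait-variance
  eig <- eigen(C, symmetric = TRUE)
  Q <- eig$vectors
  ev <- pmax(eig$values, 1e-12)
  XtX <- crossprod(Xa)
  XtX_chol <- chol(XtX)
  XtX_inv <- chol2inv(XtX_chol)
  ols <- drop(XtX_inv %*% crossprod(Xa, y))
  beta <- ols
  s2e <- max(var(y - drop(Xa %*% beta)), 1e-6)
  s2p <- s2e
  u <- numeric(n)
  n_draws <- floor((iterations - burnin) / thin)
  Sol <- matrix(NA_real_, n_draws, p, dimnames = list(NULL, colnames(Xa)))
  VCV <- matrix(NA_real_, n_draws, 2,
                dimnames = list(NULL, c("phylo", "resid")))
  dev <- numeric(n_draws)
  u_sum <- numeric(n)
  d <- 0L
  for (it in seq_len(iterations)) {
    # phylogenetic effect in the eigenbasis of C (diagonal conditional)
    z <- drop(crossprod(Q, y - drop(Xa %*% beta)))
    prec <- 1 / (s2p * ev) + 1 / s2e
    mu_u <- (z / s2e) / prec
    ut <- rnorm(n, mu_u, sqrt(1 / prec))
    u <- drop(Q %*% ut)
    # fixed effects
    ystar <- y - u
    bhat <- drop(XtX_inv %*% crossprod(Xa, ystar))
    beta <- bhat + drop(backsolve(XtX_chol, rnorm(p)) * sqrt(s2e))
    # variance components
    qp <- sum(ut^2 / ev)
    s2p <- 1 / rgamma(1, prior_shape + n / 2, rate = prior_scale + qp / 2)
    e <- ystar - drop(Xa %*% beta)
    s2e <- 1 / rgamma(1, prior_shape + n / 2, rate = prior_scale + sum(e^2) / 2)
    if (it > burnin && (it - burnin) %% thin == 0) {
      d <- d + 1L
      Sol[d, ] <- beta
      VCV[d, ] <- c(s2p, s2e)
      dev[d] <- -2 * sum(dnorm(y, drop(Xa %*% beta) + u, sqrt(s2e), log = TRUE))
      u_sum <- u_sum + u
    }
  }
  u_bar <- u_sum / n_draws
  beta_bar <- colMeans(Sol)
  s2e_bar <- mean(VCV[, "resid"])
  d_hat <- -2 * sum(dnorm(y, drop(Xa %*% beta_bar) + u_bar, sqrt(s2e_bar),
                          log = TRUE))
  dic <- 2 * mean(dev) - d_hat
  pmc <- apply(Sol, 2, pmcmc)
  rhat <- apply(Sol, 2, .split_rhat)
  if (any(rhat > 1.1)) {
    warning("split-chain Rhat > 1.1 for: ",
            paste(names(rhat)[rhat > 1.1], collapse = ", "),
            " (max ", round(max(rhat), 3), "); consider a longer chain",
            call. = FALSE)
  }
  structure(list(Sol = Sol, VCV = VCV, deviance = dev, DIC = dic,
                 pMCMC = pmc, rhat = rhat, u_mean = setNames(u_bar, tree$tip.label),
                 meta = list(iterations = iterations, thin = thin,
                             burnin = burnin, seed = seed, n_draws = n_draws)),
            class = "bpmm")
}

.split_rhat <- function(draws) {
  m <- length(draws) %/% 2L
  a <- draws[seq_len(m)]; b <- draws[m + seq_len(m)]
  W <- (var(a) + var(b)) / 2
  B <- m * var(c(mean(a), mean(b)))
  if (W == 0) return(1)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' @export
print.bpmm <- function(x, ...) {
  cat("Bayesian phylogenetic mixed model (", x$meta$n_draws, " draws)\n",
      sep = "")
  tab <- cbind(post.mean = colMeans(x$Sol),
               `l-95%` = apply(x$Sol, 2, quantile, 0.025),
               `u-95%` = apply(x$Sol, 2, quantile, 0.975),
               pMCMC = x$pMCMC)
  print(round(tab, 4))
  cat("Variance components (posterior means): phylo =",
      format(mean(x$VCV[, "phylo"]), digits = 4), ", resid =",
      format(mean(x$VCV[, "resid"]), digits = 4), "\n")
  cat("DIC:", format(x$DIC, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.bpmm <- function(object, ...) print(object)

#' @export
coef.bpmm <- function(object, ...) colMeans(object$Sol)

#' pMCMC: a Bayesian two-tailed significance measure
#'
#' Twice the posterior probability that the parameter is greater or less
#' than zero, whichever is smaller, clamped below at `2 / length(draws)`
#' (a tail probability is never estimated as exactly zero from finitely
#' many draws).
#'
#' @param draws numeric vector of posterior draws (at least 2).
#' @return a probability in (0, 1\].
#' @export
pmcmc <- function(draws) {
  if (length(draws) == 0L) stop("no posterior draws", call. = FALSE)
  if (length(draws) < 2L) stop("need at least 2 draws", call. = FALSE)
  p <- 2 * min(mean(draws > 0), mean(draws < 0))
  max(p, 2 / length(draws))
}

#' DIC model comparison with the >= 2 significance rule
#'
#' `delta = dic_a - dic_b`. A positive delta means model `b` has the lower
#' DIC (fits better); a negative delta means model `b` is worse. The
#' difference is flagged significant when `|delta| >= 2`.
#'
#' @param dic_a,dic_b DIC values of two models fitted to the same data.
#' @return list with `delta` and logical `significant`.
#' @export
delta_dic <- function(dic_a, dic_b) {
  stopifnot(is.finite(dic_a), is.finite(dic_b))
  delta <- dic_a - dic_b
  list(delta = delta, significant = abs(delta) >= 2)
}
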
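#' Brownian-motion covariance matrix of a tree
#'
#' Under Brownian motion the covariance between two tips is the root-to-MRCA
#' shared path length and the variance of a tip is its depth. Pagel's
#' lambda multiplies the off-diagonal entries only, leaving tip variances
#' untouched: `lambda = 1` is pure BM, `lambda = 0` a star phylogeny.
#'
#' @param tree an [ape::phylo] object with branch lengths (My).
#' @param lambda signal multiplier in \[0, 1\].
#' @return tips x tips covariance matrix (My units), positive definite.
#' @export
bm_covariance <- function(tree, lambda = 1) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0, lambda <= 1)
  n <- ape::Ntip(tree)
  depth <- node_depths(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  children <- split(po$edge[, 2], po$edge[, 1])
  tipsets <- c(as.list(seq_len(n)), vector("list", tree$Nnode))
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  diag(C) <- depth[seq_len(n)]
  for (nd in unique(po$edge[, 1])) {          # postorder over internal nodes
    kids <- children[[as.character(nd)]]
    sets <- tipsets[kids]
    if (length(sets) > 1) {
      for (a in seq_len(length(sets) - 1)) {
        for (b in (a + 1):length(sets)) {
          C[sets[[a]], sets[[b]]] <- depth[nd]
          C[sets[[b]], sets[[a]]] <- depth[nd]
        }
      }
    }
    tipsets[[nd]] <- unlist(sets, use.names = FALSE)
  }
  if (lambda != 1) {
    d <- diag(C)
    C <- C * lambda
    diag(C) <- d
  }
  ok <- tryCatch({chol(C); TRUE}, error = function(e) FALSE)
  if (!ok) {
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    stop("BM covariance is not positive definite (min eigenvalue ",
         format(min(ev)), "); check for duplicated tips or zero depths",
         call. = FALSE)
  }
  C
}

# match a named trait vector to tree tips, erroring on mismatches
.match_trait <- function(tree, trait) {
  if (is.null(names(trait))) {
    if (length(trait) != ape::Ntip(tree)) {
      stop("unnamed trait vector must have one value per tip", call. = FALSE)
    }
    names(trait) <- tree$tip.label
    return(trait)
  }
  missing_ <- setdiff(tree$tip.label, names(trait))
  if (length(missing_)) {
    stop("trait values missing for tips: ",
         paste(head(missing_, 10), collapse = ", "), call. = FALSE)
  }
  trait[tree$tip.label]
}

# force a rooted binary tree, resolving polytomies (including a basal
# multifurcation) with zero-length branches
.force_binary <- function(tree) {
  if (!ape::is.binary.phylo(tree) || !ape::is.rooted(tree)) {
    warning("polytomies resolved arbitrarily with zero-length branches",
            call. = FALSE)
    tree <- ape::multi2di(tree, random = FALSE)
  }
  tree
}

#' Phylogenetic independent contrasts
#'
#' Felsenstein's pruning recursion: at each internal node of a binary tree
#' the standardized contrast is `(x_i - x_j) / sqrt(b_i + b_j)`, the node
#' value is the branch-weighted average of its children and the node's own
#' branch is extended by `b_i * b_j / (b_i + b_j)`. The sum of squared
#' contrasts divided by (n - 1) estimates the BM rate sigma^2.
#'
#' @param tree an [ape::phylo] object; polytomies are resolved arbitrarily
#'   with zero-length branches (with a warning).
#' @param trait named numeric vector of tip values.
#' @return an object of class `pic_set`: data.frame with one row per
#'   internal node (`node`, `contrast`, `node_estimate`,
#'   `adj_branch_length`), with attributes `sigma2_hat` and `root_estimate`.
#' @export
pic_contrasts <- function(tree, trait) {
  tree <- .force_binary(tree)
  x <- .match_trait(tree, trait)
  n <- ape::Ntip(tree)
  n_node <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  elen <- numeric(n_node)                 # parent-edge length per node
  elen[po$edge[, 2]] <- po$edge.length
  xval <- numeric(n_node)
  vadj <- numeric(n_node)
  xval[seq_len(n)] <- x
  vadj[seq_len(n)] <- elen[seq_len(n)]
  inodes <- unique(po$edge[, 1])
  out <- data.frame(node = inodes, contrast = NA_real_,
                    node_estimate = NA_real_, adj_branch_length = NA_real_)
  children <- split(po$edge[, 2], po$edge[, 1])
  for (k in seq_along(inodes)) {
    nd <- inodes[k]
    kids <- children[[as.character(nd)]]
    stopifnot(length(kids) == 2L)
    v1 <- vadj[kids[1]]; v2 <- vadj[kids[2]]
    if (v1 + v2 <= 0) {
      stop("zero combined branch length at node ", nd,
           ": contrast undefined", call. = FALSE)
    }
    out$contrast[k] <- (xval[kids[1]] - xval[kids[2]]) / sqrt(v1 + v2)
    xval[nd] <- (v2 * xval[kids[1]] + v1 * xval[kids[2]]) / (v1 + v2)
    vadj[nd] <- elen[nd] + v1 * v2 / (v1 + v2)
    out$node_estimate[k] <- xval[nd]
    out$adj_branch_length[k] <- vadj[nd]
  }
  root <- n + 1L
  structure(out,
            sigma2_hat = sum(out$contrast^2) / (n - 1),
            root_estimate = xval[root],
            class = c("pic_set", "data.frame"))
}

#' Ancestral state reconstruction under Brownian motion
#'
#' Maximum-likelihood (GLS) states for every internal node: the root state
#' is `(1' C^-1 x) / (1' C^-1 1)` and each node estimate is the BM
#' conditional expectation given the tips, with standard errors that
#' account for root-state estimation. The root estimate coincides with the
#' independent-contrasts root on the same binary tree and data.
#'
#' @inheritParams pic_contrasts
#' @param method `"ML"` (GLS under BM; the default) or `"PIC"` (node
#'   values from the contrasts recursion; no standard errors).
#' @return an object of class `bm_ancestral`: data.frame (`node`,
#'   `estimate`, `se`) with attributes `method`, `sigma2`, `root_state`.
#' @export
ancestral_states <- function(tree, trait, method = c("ML", "PIC")) {
  method <- match.arg(method)
  if (method == "ML") return(ancestral_ml_bm(tree, trait))
  pic <- pic_contrasts(tree, trait)
  structure(data.frame(node = pic$node, estimate = pic$node_estimate,
                       se = NA_real_),
            method = "PIC", sigma2 = attr(pic, "sigma2_hat"),
            root_state = attr(pic, "root_estimate"),
            class = c("bm_ancestral", "data.frame"))
}

#' @rdname ancestral_states
#' @export
ancestral_ml_bm <- function(tree, trait) {
  x <- .match_trait(tree, trait)
  n <- ape::Ntip(tree)
  C <- bm_covariance(tree)
  R <- chol(C)
  Ci_x <- backsolve(R, forwardsolve(t(R), x))
  Ci_1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
  denom <- sum(Ci_1)
  root <- sum(Ci_x) / denom
  resid <- x - root
  Ci_r <- backsolve(R, forwardsolve(t(R), resid))
  sigma2 <- sum(resid * Ci_r) / n
  depth <- node_depths(tree)
  mrca_all <- ape::mrca(tree, full = TRUE)
  inodes <- (n + 1L):(n + tree$Nnode)
  est <- se <- numeric(length(inodes))
  for (k in seq_along(inodes)) {
    nd <- inodes[k]
    w <- depth[mrca_all[nd, seq_len(n)]]
    Ci_w <- backsolve(R, forwardsolve(t(R), w))
    est[k] <- root + sum(w * Ci_r)          # w' C^-1 (x - root)
    vark <- sigma2 * (depth[nd] - sum(w * Ci_w) +
                        (1 - sum(Ci_w))^2 / denom)
    se[k] <- sqrt(max(vark, 0))
  }
  structure(data.frame(node = inodes, estimate = est, se = se),
            method = "ML", sigma2 = sigma2, root_state = root,
            class = c("bm_ancestral", "data.frame"))
}

#' @export
print.bm_ancestral <- function(x, ...) {
  cat("Ancestral states under Brownian motion (", attr(x, "method"),
      "), sigma2 = ", format(attr(x, "sigma2"), digits = 4),
      ", root = ", format(attr(x, "root_state"), digits = 4), "\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more nodes)\n", sep = "")
  invisible(x)
}

#' Traitgram of a reconstructed trait
#'
#' Plots the phylogeny in (trait, time) space: tips at their observed
#' values, internal nodes at their reconstructed states, connected along
#' the tree edges.
#'
#' @param x a `bm_ancestral` object.
#' @param tree the tree used for the reconstruction.
#' @param trait the tip values used.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the node coordinate table.
#' @export
traitgram <- function(x, tree, trait, ...) {
  trait <- .match_trait(tree, trait)
  depth <- node_depths(tree)
  vals <- c(trait, setNames(x$estimate, x$node))
  ids <- c(seq_len(ape::Ntip(tree)), x$node)
  ord <- order(ids)
  vals <- vals[ord]; ids <- ids[ord]
  graphics::plot(vals, depth[ids], type = "n",
                 xlab = "trait value", ylab = "time (My)", ...)
  for (i in seq_len(nrow(tree$edge))) {
    e <- tree$edge[i, ]
    graphics::segments(vals[e[1]], depth[e[1]], vals[e[2]], depth[e[2]],
                       col = "grey40")
  }
  graphics::points(vals, depth[ids], pch = 19, cex = 0.6)
  invisible(data.frame(node = ids, trait = vals, depth = depth[ids]))
}

#' Pagel's lambda branch-length transformation
#'
#' Multiplies internal branches by `lambda` and stretches terminal branches
#' so every tip keeps its original depth; equivalent to scaling the
#' off-diagonal entries of the BM covariance by `lambda`.
#'
#' @inheritParams bm_covariance
#' @return the transformed tree.
#' @export
lambda_transform <- function(tree, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (lambda == 1) return(tree)
  depth <- node_depths(tree)
  n <- ape::Ntip(tree)
  out <- tree
  is_tip <- tree$edge[, 2] <= n
  out$edge.length[!is_tip] <- lambda * tree$edge.length[!is_tip]
  tip_child <- tree$edge[is_tip, 2]
  tip_parent <- tree$edge[is_tip, 1]
  out$edge.length[is_tip] <- depth[tip_child] - lambda * depth[tip_parent]
  out
}

#' Brownian-motion log-likelihood of tip data
#'
#' Two independent evaluations of the same quantity: a dense multivariate
#' normal with the lambda-scaled BM covariance, and the pruning (contrast)
#' factorisation on the lambda-transformed tree. When `sigma2` or `root`
#' are omitted they are profiled at their ML values.
#'
#' @inheritParams pic_contrasts
#' @param sigma2,root BM rate and root state; `NULL` profiles them.
#' @param lambda Pagel's lambda in \[0, 1\].
#' @param method `"dense"` or `"contrasts"`.
#' @return log-likelihood (scalar) with attributes `sigma2` and `root`.
#' @export
bm_loglik <- function(tree, trait, sigma2 = NULL, root = NULL, lambda = 1,
                      method = c("dense", "contrasts")) {
  method <- match.arg(method)
  x <- .match_trait(tree, trait)
  n <- length(x)
  if (method == "dense") {
    C <- bm_covariance(tree, lambda)
    R <- chol(C)
    logdet <- 2 * sum(log(diag(R)))
    Ci_1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
    if (is.null(root)) root <- sum(backsolve(R, forwardsolve(t(R), x))) / sum(Ci_1)
    resid <- x - root
    q <- sum(resid * backsolve(R, forwardsolve(t(R), resid)))
    if (is.null(sigma2)) sigma2 <- q / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + q / sigma2)
  } else {
    tr <- lambda_transform(tree, lambda)
    tr <- .force_binary(tr)
    prune <- .prune_likelihood_parts(tr, x)
    if (is.null(root)) root <- prune$root_value
    if (is.null(sigma2)) {
      q <- sum(prune$contrast2_over_v) + (prune$root_value - root)^2 / prune$root_var
      sigma2 <- q / n
    }
    q <- sum(prune$contrast2_over_v) + (prune$root_value - root)^2 / prune$root_var
    ll <- -0.5 * (n * log(2 * pi * sigma2) +
                    sum(log(prune$contrast_v)) + log(prune$root_var) +
                    q / sigma2)
  }
  structure(ll, sigma2 = sigma2, root = root)
}

# pruning pass returning the pieces of the factorised BM likelihood
.prune_likelihood_parts <- function(tree, x) {
  n <- ape::Ntip(tree)
  n_node <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  elen <- numeric(n_node)
  elen[po$edge[, 2]] <- po$edge.length
  xval <- numeric(n_node); vadj <- numeric(n_node)
  xval[seq_len(n)] <- x
  vadj[seq_len(n)] <- elen[seq_len(n)]
  children <- split(po$edge[, 2], po$edge[, 1])
  inodes <- unique(po$edge[, 1])
  cv <- c2v <- numeric(length(inodes))
  for (k in seq_along(inodes)) {
    nd <- inodes[k]
    kids <- children[[as.character(nd)]]
    v1 <- vadj[kids[1]]; v2 <- vadj[kids[2]]
    if (v1 + v2 <= 0) stop("zero combined branch length in pruning", call. = FALSE)
    cv[k] <- v1 + v2
    c2v[k] <- (xval[kids[1]] - xval[kids[2]])^2 / (v1 + v2)
    xval[nd] <- (v2 * xval[kids[1]] + v1 * xval[kids[2]]) / (v1 + v2)
    vadj[nd] <- elen[nd] + v1 * v2 / (v1 + v2)
  }
  root <- n + 1L
  list(contrast_v = cv, contrast2_over_v = c2v,
       root_value = xval[root], root_var = vadj[root])
}

#' Estimate Pagel's lambda by profile maximum likelihood
#'
#' Profiles the BM likelihood over `lambda` in \[0, 1\] (sigma^2 and the
#' root state maximised analytically at each `lambda`), using a coarse grid
#' followed by bounded scalar search (tolerance 1e-6). Likelihood-ratio
#' tests against `lambda = 0` (no signal) and `lambda = 1` (pure BM) use a
#' chi-square with 1 df; at the `lambda = 1` boundary this mirrors the
#' behaviour of the standard tooling but is conservative.
#'
#' @inheritParams pic_contrasts
#' @return an object of class `lambda_fit` with elements `lambda`, `logL`,
#'   `logL0`, `logL1`, `lr0`, `p0`, `lr1`, `p1`, `sigma2`, `root_state`, `n`.
#' @export
fit_lambda <- function(tree, trait) {
  x <- .match_trait(tree, trait)
  n <- length(x)
  if (n < 10) warning("fewer than 10 tips: lambda is weakly identified",
                      call. = FALSE)
  C0 <- bm_covariance(tree, 1)
  d0 <- diag(C0)
  prof <- function(lam) {
    C <- C0 * lam
    diag(C) <- d0
    R <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    logdet <- 2 * sum(log(diag(R)))
    Ci_x <- backsolve(R, forwardsolve(t(R), x))
    Ci_1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
    root <- sum(Ci_x) / sum(Ci_1)
    resid <- x - root
    q <- sum(resid * backsolve(R, forwardsolve(t(R), resid)))
    if (q <= 0) return(-Inf)
    sigma2 <- q / n
    -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  }
  grid <- seq(0, 1, by = 0.05)
  vals <- vapply(grid, prof, numeric(1))
  if (all(!is.finite(vals))) stop("lambda profile likelihood is degenerate",
                                  call. = FALSE)
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-6)
  cand <- rbind(c(opt$maximum, opt$objective), c(0, vals[1]),
                c(1, vals[length(vals)]))
  best <- cand[which.max(cand[, 2]), ]
  lam <- best[1]; ll <- best[2]
  ll0 <- vals[1]; ll1 <- vals[length(vals)]
  lr0 <- max(2 * (ll - ll0), 0); lr1 <- max(2 * (ll - ll1), 0)
  # recompute sigma2/root at the optimum
  fit_at <- bm_loglik(tree, x, lambda = lam, method = "dense")
  structure(list(lambda = lam, logL = ll, logL0 = ll0, logL1 = ll1,
                 lr0 = lr0, p0 = pchisq(lr0, 1, lower.tail = FALSE),
                 lr1 = lr1, p1 = pchisq(lr1, 1, lower.tail = FALSE),
                 sigma2 = attr(fit_at, "sigma2"),
                 root_state = attr(fit_at, "root"), n = n),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("Pagel's lambda: %.4f (logL %.3f, sigma2 %.4g, root %.4g, n = %d)\n",
              x$lambda, x$logL, x$sigma2, x$root_state, x$n))
  cat(sprintf("  vs lambda = 0: LR = %.3f, p = %.3g\n", x$lr0, x$p0))
  cat(sprintf("  vs lambda = 1: LR = %.3f, p = %.3g\n", x$lr1, x$p1))
  invisible(x)
}

#' @export
coef.lambda_fit <- function(object, ...) {
  c(lambda = object$lambda, sigma2 = object$sigma2,
    root_state = object$root_state)
}
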
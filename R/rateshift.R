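#' Reversible-jump MCMC detection of Brownian rate shifts
#'
#' Samples over partitions of the branches of a time-calibrated tree into
#' Brownian-motion rate classes. A shift is placed at a node and inherited
#' by the whole descendant clade (including the node's own branch) until
#' overridden by a nested shift; the variance accrued on a branch is
#' rate x branch length. Moves are a log-scale random walk on rates, shift
#' birth and death (with a truncated Poisson prior on the number of
#' shifts; births propose the new rate from its prior so the Hastings
#' ratio is exact), and shift relocation. The background and shift rates
#' carry a log-normal prior centred on the independent-contrasts rate
#' estimate. The likelihood is the REML (contrast) BM likelihood, so no
#' root state is sampled.
#'
#' @inheritParams pic_contrasts
#' @param generations number of MCMC generations (default 200000;
#'   full-scale analyses typically use 4000000 sampled every 4000).
#' @param sample_interval record every so many generations (default 200).
#' @param burnin_fraction fraction of recorded samples discarded (default
#'   0.25).
#' @param seed RNG seed (required: the chain is deterministic given it).
#' @param pois_mean mean of the Poisson prior on the shift count
#'   (default 1).
#' @param rate_sdlog sd of the log-normal rate prior (default 1.5).
#' @param step_sd sd of the log-rate random-walk proposal (default 0.7).
#' @param move_weights relative probabilities of the rate / birth / death /
#'   relocate moves; birth and death must be equal.
#' @return an object of class `rate_shift_posterior`: per-node shift
#'   posterior probabilities, model-averaged relative branch rates, chain
#'   traces, per-move acceptance rates and metadata.
#' @export
rjmcmc_rates <- function(tree, trait, generations = 200000,
                         sample_interval = 200, burnin_fraction = 0.25,
                         seed = NULL, pois_mean = 1, rate_sdlog = 1.5,
                         step_sd = 0.7,
                         move_weights = c(rate = 0.5, birth = 0.2,
                                          death = 0.2, relocate = 0.1)) {
  if (ape::Ntip(tree) < 8) stop("need at least 8 tips", call. = FALSE)
  stopifnot(generations >= sample_interval, sample_interval >= 1,
            burnin_fraction >= 0, burnin_fraction < 1,
            length(move_weights) == 4, all(move_weights >= 0))
  if (move_weights[2] != move_weights[3]) {
    stop("birth and death move weights must be equal for reversibility",
         call. = FALSE)
  }
  tree <- .force_binary(tree)
  x <- .match_trait(tree, trait)
  if (var(x) == 0) stop("trait has zero variance", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  n_node <- n + tree$Nnode
  root <- n + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  elen <- numeric(n_node)
  elen[po$edge[, 2]] <- po$edge.length
  parent <- integer(n_node)
  parent[po$edge[, 2]] <- po$edge[, 1]
  child <- split(po$edge[, 2], po$edge[, 1])
  po_nodes <- unique(po$edge[, 1])
  child_left <- child_right <- integer(n_node)
  for (nd in po_nodes) {
    kids <- child[[as.character(nd)]]
    child_left[nd] <- kids[1]
    child_right[nd] <- kids[2]
  }
  pre_nodes <- po$edge[rev(seq_len(nrow(po$edge))), 2]
  sigma2_hat <- attr(pic_contrasts(tree, x), "sigma2_hat")
  res <- rjmcmc_rates_cpp(
    po_nodes = po_nodes,
    child_left = c(0L, child_left), child_right = c(0L, child_right),
    pre_nodes = pre_nodes, parent = c(0L, parent),
    elen = c(0, elen), x = unname(x), ntip = n,
    generations = as.integer(generations),
    sample_interval = as.integer(sample_interval),
    pois_mean = pois_mean, rate_meanlog = log(sigma2_hat),
    rate_sdlog = rate_sdlog, step_sd = step_sd,
    move_weights = as.numeric(move_weights))
  n_samples <- nrow(res$rates)
  keep <- seq_len(n_samples) > floor(burnin_fraction * n_samples)
  rates <- res$rates[keep, , drop = FALSE]
  shifts <- res$shifts[keep, , drop = FALSE]
  # relative rates: each sample scaled by its median non-root edge rate
  non_root <- setdiff(seq_len(n_node), root)
  med <- apply(rates[, non_root, drop = FALSE], 1, median)
  rel <- sweep(rates, 1, med, "/")
  shift_prob <- colMeans(shifts)
  shift_prob[root] <- 0
  acc <- data.frame(move = c("rate", "birth", "death", "relocate"),
                    attempts = res$attempts, accepts = res$accepts,
                    rate = ifelse(res$attempts > 0,
                                  res$accepts / res$attempts, NA))
  branch <- data.frame(node = non_root, parent = parent[non_root],
                       rel_rate = colMeans(rel)[non_root],
                       abs_rate = colMeans(rates)[non_root])
  structure(list(
    shift_prob = setNames(shift_prob, seq_len(n_node)),
    branch_rates = branch,
    samples = data.frame(k = res$k[keep], r0 = res$r0[keep],
                         logL = res$logL[keep]),
    acceptance = acc,
    sigma2_prior_center = sigma2_hat,
    tree = tree,
    meta = list(generations = generations, sample_interval = sample_interval,
                burnin_fraction = burnin_fraction, seed = seed,
                n_samples_total = n_samples, n_samples_used = sum(keep),
                pois_mean = pois_mean, rate_sdlog = rate_sdlog)
  ), class = "rate_shift_posterior")
}

#' @export
print.rate_shift_posterior <- function(x, ...) {
  cat("rjMCMC rate-shift posterior:", x$meta$generations, "generations,",
      x$meta$n_samples_used, "post-burn-in samples\n")
  cat("mean shift count:", round(mean(x$samples$k), 2),
      "; background rate (posterior mean):",
      format(mean(x$samples$r0), digits = 4), "\n")
  top <- sort(x$shift_prob, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(5, sum(top > 0)))]
  if (length(top)) {
    cat("highest shift probabilities:\n")
    print(round(top, 3))
  }
  invisible(x)
}

#' Significant rate shifts and their direction
#'
#' Nodes whose posterior shift probability exceeds `threshold` (0.95 is
#' the conventional cut-off), with the direction of the shift judged by
#' comparing the model-averaged relative rate of the node's clade (its own
#' branch plus all descendant branches) to the tree-wide median relative
#' branch rate.
#'
#' @param posterior a `rate_shift_posterior`.
#' @param threshold posterior probability cut-off (default 0.95).
#' @return data.frame with columns `node`, `prob`, `direction`
#'   (`"increase"` or `"decrease"`), `clade_rate`, `background_rate`;
#'   zero rows when nothing exceeds the threshold.
#' @export
shift_summary <- function(posterior, threshold = 0.95) {
  stopifnot(inherits(posterior, "rate_shift_posterior"))
  pr <- posterior$shift_prob
  hits <- as.integer(names(pr)[pr > threshold])
  bg <- median(posterior$branch_rates$rel_rate)
  if (length(hits) == 0) {
    return(data.frame(node = integer(), prob = numeric(),
                      direction = character(), clade_rate = numeric(),
                      background_rate = numeric()))
  }
  tree <- posterior$tree
  out <- do.call(rbind, lapply(hits, function(nd) {
    desc <- .clade_nodes(tree, nd)
    br <- posterior$branch_rates
    clade_rate <- mean(br$rel_rate[br$node %in% desc])
    data.frame(node = nd, prob = unname(pr[as.character(nd)]),
               direction = if (clade_rate >= bg) "increase" else "decrease",
               clade_rate = clade_rate, background_rate = bg)
  }))
  rownames(out) <- NULL
  out
}

# node plus all its descendants
.clade_nodes <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  c(node, unlist(lapply(kids, .clade_nodes, tree = tree)))
}
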
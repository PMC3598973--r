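#' Simulate an ultrametric tree under a Yule (pure-birth) process
#'
#' Forward simulation: starting from the root split (two lineages), while
#' `k` lineages are alive the next split waits an exponential time with
#' rate `birth_rate * k`; after the n-th lineage appears one final
#' exponential waiting time with rate `birth_rate * n` elapses before the
#' present. The expected root height is therefore
#' `sum(1 / (birth_rate * k))` for `k = 2..n`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per lineage per My (> 0).
#' @param seed RNG seed.
#' @return an ultrametric binary [ape::phylo] with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (!is.numeric(n_tips) || n_tips < 2) stop("need n_tips >= 2", call. = FALSE)
  if (!is.numeric(birth_rate) || birth_rate <= 0) {
    stop("birth_rate must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)
  root <- n + 1L
  # active lineages: parent node and the time their branch started
  act_parent <- c(root, root)
  act_start <- c(0, 0)
  next_int <- root + 1L
  t <- 0
  edges <- matrix(0L, 2L * n - 2L, 2L)
  elen <- numeric(2L * n - 2L)
  ne <- 0L
  k <- 2L
  while (k < n) {
    t <- t + rexp(1, birth_rate * k)
    j <- sample.int(k, 1)
    ne <- ne + 1L
    edges[ne, ] <- c(act_parent[j], next_int)
    elen[ne] <- t - act_start[j]
    act_parent[j] <- next_int
    act_start[j] <- t
    act_parent <- c(act_parent, next_int)
    act_start <- c(act_start, t)
    next_int <- next_int + 1L
    k <- k + 1L
  }
  t <- t + rexp(1, birth_rate * n)
  for (j in seq_len(n)) {
    ne <- ne + 1L
    edges[ne, ] <- c(act_parent[j], j)
    elen[ne] <- t - act_start[j]
  }
  tree <- list(edge = edges, edge.length = elen,
               tip.label = paste0("t", seq_len(n)), Nnode = n - 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  validate_phylogeny(tree)
  tree
}

#' Simulate a continuous trait under Brownian motion on a tree
#'
#' Each branch contributes an independent Gaussian increment with variance
#' `sigma2 * multiplier * branch length`. Pagel's lambda is applied as a
#' branch-length transformation before simulation. Clade-specific rate
#' multipliers are keyed by node id and apply to the node's own branch and
#' every descendant branch (nested multipliers override outer ones). True
#' internal-node states are returned for recovery tests.
#'
#' @param tree an [ape::phylo] object.
#' @param sigma2 BM rate (trait variance per My, >= 0).
#' @param root_state trait value at the root.
#' @param lambda Pagel's lambda in \[0, 1\].
#' @param rate_multipliers named numeric vector, `node id -> factor`.
#' @param seed RNG seed.
#' @return list with `tips` (named vector), `node_states` (named by node
#'   id) and `edge_rates` (multiplier per edge, in `tree$edge` order).
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, root_state = 0, lambda = 1,
                               rate_multipliers = NULL, seed = NULL) {
  stopifnot(sigma2 >= 0, lambda >= 0, lambda <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  n_node <- n + tree$Nnode
  tr <- lambda_transform(tree, lambda)
  mult <- rep(1, n_node)
  if (!is.null(rate_multipliers)) {
    if (is.null(names(rate_multipliers))) {
      stop("rate_multipliers must be named by node id", call. = FALSE)
    }
    ids <- as.integer(names(rate_multipliers))
    if (any(is.na(ids)) || any(ids < 1) || any(ids > n_node)) {
      stop("unknown clade node id in rate_multipliers: ",
           paste(names(rate_multipliers)[is.na(ids) | ids < 1 | ids > n_node],
                 collapse = ", "), call. = FALSE)
    }
    if (any(rate_multipliers <= 0)) {
      stop("rate multipliers must be positive", call. = FALSE)
    }
  }
  state <- numeric(n_node)
  state[n + 1L] <- root_state
  po <- ape::reorder.phylo(tr, "postorder")
  edge_mult <- rep(1, nrow(po$edge))
  # preorder: assign multipliers by inheritance, then simulate increments
  ord <- rev(seq_len(nrow(po$edge)))
  node_mult <- rep(1, n_node)
  for (i in ord) {
    p_ <- po$edge[i, 1]; c_ <- po$edge[i, 2]
    m <- if (!is.null(rate_multipliers) &&
             as.character(c_) %in% names(rate_multipliers)) {
      unname(rate_multipliers[as.character(c_)])
    } else if (p_ == n + 1L) 1 else node_mult[p_]
    node_mult[c_] <- m
    edge_mult[i] <- m
    state[c_] <- state[p_] + rnorm(1, 0, sqrt(sigma2 * m * po$edge.length[i]))
  }
  list(tips = setNames(state[seq_len(n)], tree$tip.label),
       node_states = setNames(state[(n + 1L):n_node], (n + 1L):n_node),
       edge_rates = edge_mult)
}

#' Generate a cochlea-like spiral landmark path with known ground truth
#'
#' A tapered helix (logarithmic spiral in plan view, linear rise along the
#' axis) sampled at approximately equal arc-length increments, emulating a
#' landmark series placed along the basilar membrane. The true arc length
#' is computed by dense numerical quadrature (1e5 chords) and returned as
#' an oracle together with the true number of turns.
#'
#' @param turns number of revolutions (> 0).
#' @param base_radius plan-view radius at the base, mm.
#' @param taper exponential decay of radius per radian (>= 0).
#' @param pitch axial rise per full turn, mm.
#' @param n_points number of landmarks (>= 2; 86 emulates a standard
#'   digitisation protocol).
#' @param noise_sd isotropic Gaussian jitter added to each landmark, mm.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return a `landmark_path` with attributes `true_length` (mm) and
#'   `true_turns`.
#' @export
generate_spiral_path <- function(turns, base_radius = 1, taper = 0.15,
                                 pitch = 0.5, n_points = 86, noise_sd = 0,
                                 seed = NULL) {
  if (turns <= 0) stop("turns must be positive", call. = FALSE)
  if (n_points < 2) stop("need at least 2 points", call. = FALSE)
  if (base_radius <= 0 || taper < 0 || pitch < 0) {
    stop("invalid spiral geometry", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  theta_max <- 2 * pi * turns
  th <- seq(0, theta_max, length.out = 1e5 + 1)
  r <- base_radius * exp(-taper * th)
  dense <- cbind(x = r * cos(th), y = r * sin(th), z = pitch * th / (2 * pi))
  seg <- sqrt(rowSums(diff(dense)^2))
  cum <- c(0, cumsum(seg))
  true_length <- cum[length(cum)]
  s_target <- seq(0, true_length, length.out = n_points)
  th_pts <- stats::approx(cum, th, xout = s_target, ties = "ordered")$y
  r_pts <- base_radius * exp(-taper * th_pts)
  pts <- cbind(r_pts * cos(th_pts), r_pts * sin(th_pts),
               pitch * th_pts / (2 * pi))
  if (noise_sd > 0) pts <- pts + rnorm(length(pts), 0, noise_sd)
  out <- landmark_path(pts, specimen = "synthetic")
  attr(out, "true_length") <- true_length
  attr(out, "true_turns") <- turns
  out
}

#' Configuration for a synthetic comparative study
#'
#' Defaults emulate the statistical structure of a bat-and-mammal cochlear
#' dataset: a Yule chronogram; log10 body mass evolving by BM from a
#' 19.22 g root; log10 membrane length following the mammalian allometry
#' (slope 0.498, intercept 0.717 on log10 cube-root mass) plus an
#' echolocator clade offset, a lambda-diluted BM deviation and iid
#' measurement noise; log10 turns following the published relation to
#' relative membrane length (slope 0.123, intercept 0.342, residual sd
#' 0.122); call frequencies from the phylogenetic call-frequency model;
#' and an audiogram calibration table of 38 species.
#'
#' @param n_species number of species (default 100).
#' @param birth_rate Yule rate per My (default 0.065, giving bat-order
#'   root heights of roughly 60-70 My at the default size).
#' @param seed RNG seed (mandatory).
#' @param mass_root_g root body mass in g.
#' @param mass_sigma2 BM rate of log10 mass per My.
#' @param allometric_slope,allometric_intercept reference allometry of
#'   log10 membrane (mm) on log10 mass^(1/3).
#' @param echo_offset log10 offset of the echolocator clade.
#' @param bm_sigma2 BM rate of the membrane deviation from the allometry.
#' @param lambda phylogenetic signal of the membrane deviation.
#' @param noise_sd iid log10 measurement noise on membrane length.
#' @param turns_slope,turns_intercept,turns_noise_sd log10 turns on log10
#'   relative membrane length.
#' @param call_model a [call_freq_model()] generating call frequencies.
#' @param call_noise_sd iid log10 noise on call frequencies.
#' @param rate_multipliers optional clade rate multipliers (node -> factor)
#'   applied to the membrane BM deviation.
#' @param n_calibration audiogram species count (default 38: 14 bats +
#'   24 non-bats in the emulated design).
#' @param hearing_coefs generative hearing-limit coefficients: named list
#'   of `c(intercept, slope)` for `hf30`, `hf60` (on log10 relative
#'   length) and `lf30`, `lf60` (on log10 membrane x turns).
#' @param hearing_noise_sd iid log10 noise on audiogram limits.
#' @return a `study_config` list.
#' @export
study_config <- function(n_species = 100, birth_rate = 0.065, seed,
                         mass_root_g = 19.22, mass_sigma2 = 0.01,
                         allometric_slope = 0.498,
                         allometric_intercept = 0.717,
                         echo_offset = 0.2, bm_sigma2 = 4e-5, lambda = 0.9,
                         noise_sd = 0.05, turns_slope = 0.123,
                         turns_intercept = 0.342, turns_noise_sd = 0.122,
                         call_model = builtin_call_freq_model(),
                         call_noise_sd = 0.05, rate_multipliers = NULL,
                         n_calibration = 38,
                         hearing_coefs = list(hf30 = c(3.058, -2.0),
                                              hf60 = c(3.28, -2.0),
                                              lf30 = c(2.1, -0.8),
                                              lf60 = c(2.1, -0.8)),
                         hearing_noise_sd = 0.1) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_species >= 4, birth_rate > 0, mass_root_g > 0,
              mass_sigma2 >= 0, bm_sigma2 >= 0, lambda >= 0, lambda <= 1,
              noise_sd >= 0, turns_noise_sd >= 0, call_noise_sd >= 0,
              hearing_noise_sd >= 0, n_calibration >= 4)
  })
  structure(cfg, class = "study_config")
}

#' Generate a joint synthetic study dataset
#'
#' Builds a tree, trait table and audiogram calibration table with the
#' generative structure described in [study_config()], returning every
#' generative parameter and latent state alongside for recovery tests.
#' The echolocator group is the clade whose size is closest to half the
#' species, mirroring how a discrete ecological trait is phylogenetically
#' clustered.
#'
#' @param config a [study_config()].
#' @return list with `tree`, `traits` (species, membrane_length, turns,
#'   mass, echolocation_type, call_min/peak/max), `calibration`
#'   (species, hf30, hf60, lf30, lf60 in kHz) and `truth` (the config plus
#'   latent node states and the echolocator clade node).
#' @export
generate_study_dataset <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  set.seed(cfg$seed)
  tree <- simulate_yule_tree(cfg$n_species, cfg$birth_rate)
  n <- ape::Ntip(tree)
  # echolocator clade: internal node with clade size closest to n/2
  inodes <- (n + 1L):(n + tree$Nnode)
  sizes <- vapply(inodes, function(nd) sum(.clade_nodes(tree, nd) <= n),
                  numeric(1))
  echo_node <- inodes[inodes != n + 1L][which.min(abs(sizes[inodes != n + 1L] -
                                                        n / 2))]
  cl <- .clade_nodes(tree, echo_node)
  echo_tips <- tree$tip.label[cl[cl <= n]]
  is_echo <- tree$tip.label %in% echo_tips
  mass_sim <- simulate_bm_traits(tree, cfg$mass_sigma2,
                                 root_state = log10(cfg$mass_root_g))
  dev_sim <- simulate_bm_traits(tree, cfg$bm_sigma2, root_state = 0,
                                lambda = cfg$lambda,
                                rate_multipliers = cfg$rate_multipliers)
  mass <- 10^mass_sim$tips
  log_mass_cuberoot <- log10(mass) / 3
  log_membrane <- cfg$allometric_intercept +
    cfg$allometric_slope * log_mass_cuberoot +
    cfg$echo_offset * is_echo + dev_sim$tips +
    rnorm(n, 0, cfg$noise_sd)
  membrane <- 10^log_membrane
  rel <- relative_membrane_length(membrane, mass)
  log_turns <- cfg$turns_intercept + cfg$turns_slope * log10(rel) +
    rnorm(n, 0, cfg$turns_noise_sd)
  turns <- 10^log_turns
  calls <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("min", "peak", "max")))
  if (any(is_echo)) {
    # min > max can occur at extreme turn counts because the per-parameter
    # regressions are independent; harmless for a generated dataset
    base <- suppressWarnings(
      predict_call_frequencies(membrane[is_echo], turns[is_echo],
                               model = cfg$call_model))
    base <- if (is.matrix(base)) base else matrix(base, 1,
                                                  dimnames = list(NULL, names(base)))
    calls[is_echo, ] <- 10^(log10(base) +
                              rnorm(length(base), 0, cfg$call_noise_sd))
  }
  traits <- data.frame(
    species = tree$tip.label,
    membrane_length = membrane, turns = turns, mass = mass,
    echolocation_type = ifelse(is_echo, "FM", "none"),
    call_min = calls[, "min"], call_peak = calls[, "peak"],
    call_max = calls[, "max"], stringsAsFactors = FALSE)
  # audiogram calibration subset
  n_cal <- min(cfg$n_calibration, n)
  cal_idx <- sort(sample.int(n, n_cal))
  x_high <- log10(rel[cal_idx])
  x_low <- log10(membrane[cal_idx]) * turns[cal_idx]
  hc <- cfg$hearing_coefs
  gen_limit <- function(cc, x) 10^(cc[1] + cc[2] * x +
                                     rnorm(length(x), 0, cfg$hearing_noise_sd))
  calibration <- data.frame(
    species = tree$tip.label[cal_idx],
    hf30 = gen_limit(hc$hf30, x_high), hf60 = gen_limit(hc$hf60, x_high),
    lf30 = gen_limit(hc$lf30, x_low), lf60 = gen_limit(hc$lf60, x_low),
    stringsAsFactors = FALSE)
  truth <- c(unclass(cfg),
             list(echo_node = echo_node, echo_tips = echo_tips,
                  mass_node_states = mass_sim$node_states,
                  deviation_node_states = dev_sim$node_states,
                  deviation_tips = dev_sim$tips))
  list(tree = tree, traits = traits, calibration = calibration, truth = truth)
}
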
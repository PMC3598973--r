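# small fixed trees used across tests
cherry <- function() read_newick("(A:1,B:1):0;", quiet = TRUE)
three_tip <- function() read_newick("((A:1,B:1):1,C:2):0;", quiet = TRUE)
four_tip <- function() read_newick("((A:1,B:1):1,(C:1,D:1):1);", quiet = TRUE)

# planar Archimedean spiral r = theta as a landmark path (tiny z drift so
# consecutive points stay distinct)
archimedean_path <- function(theta_max, n = 400) {
  th <- seq(0, theta_max, length.out = n)
  landmark_path(cbind(th * cos(th), th * sin(th),
                      seq(0, 1e-9, length.out = n)))
}

# random ultrametric tree + BM trait, for property loops
random_tree_trait <- function(n_tips, seed, sigma2 = 0.01) {
  tree <- simulate_yule_tree(n_tips, birth_rate = 0.1, seed = seed)
  x <- simulate_bm_traits(tree, sigma2 = sigma2, root_state = 0,
                          seed = seed + 1000L)$tips
  list(tree = tree, x = x)
}

# random rigid motion of a point matrix
rigid_motion <- function(pts, seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- rnorm(3, 0, 5)
  sweep(pts %*% R, 2, shift, "+")
}
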
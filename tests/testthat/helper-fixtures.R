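# shared helpers: random mode sets, rigid-body transforms, random graphs,
# and brute-force oracles used across test files

random_modeset <- function(n, M, seed) {
  set.seed(seed)
  shapes <- array(stats::rnorm(M * n * 3), c(M, n, 3))
  dyn_modes(sort(stats::runif(M, 0.3, 5)), shapes)
}

random_structure <- function(n, seed, spread = 8) {
  set.seed(seed)
  repeat {
    coords <- matrix(stats::rnorm(n * 3, sd = spread), n, 3)
    if (min(stats::dist(coords)) > 1) break
  }
  dyn_structure(coords, strrep("A", n))
}

random_rigid_transform <- function(seed) {
  set.seed(seed)
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 20))
}

apply_rigid <- function(structure, tf) {
  s2 <- structure
  s2$coords <- structure$coords %*% t(tf$R) +
    matrix(tf$t, nrow(structure$coords), 3, byrow = TRUE)
  s2
}

# Erdos-Renyi edge set over n nodes (0-based), guaranteed >= 1 edge
random_edge_set <- function(n, p, seed, edge_type = "graph") {
  set.seed(seed)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(ut)) < p
  if (!any(keep)) keep[sample(length(keep), 1)] <- TRUE
  dynamelt:::new_edge_set(cbind(ut[keep, 1] - 1L, ut[keep, 2] - 1L),
                          edge_type, n)
}

# eigendecomposition route to the Laplacian energy (independent oracle)
laplacian_energy_eigen <- function(edge_set, n = NULL) {
  if (inherits(edge_set, "dyn_edge_set")) {
    n <- edge_set$n
    edges <- edge_set$edges
  } else {
    edges <- edge_set
  }
  A <- matrix(0, n, n)
  if (nrow(edges)) {
    A[edges + 1L] <- 1
    A[edges[, c(2, 1), drop = FALSE] + 1L] <- 1
  }
  L <- diag(rowSums(A)) - A
  sum(eigen(L, symmetric = TRUE, only.values = TRUE)$values^2)
}

# brute-force centrality by explicit node deletion + eigendecomposition
laplacian_centrality_bruteforce <- function(edge_set) {
  n <- edge_set$n
  U <- laplacian_energy_eigen(edge_set)
  vapply(seq_len(n) - 1L, function(v) {
    keep <- edge_set$edges[, 1] != v & edge_set$edges[, 2] != v
    sub <- edge_set$edges[keep, , drop = FALSE]
    (U - laplacian_energy_eigen(sub, n = n)) / U
  }, numeric(1))
}

# tiny labeled dataset cache so several test files can share one build
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_labeled_dataset(
        fixture_config(n_proteins = 24L, length_range = c(15L, 30L), seed = 42L))
    }
    cache
  }
})
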
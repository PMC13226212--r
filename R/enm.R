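#' Anisotropic elastic-network Hessian from alpha-carbon coordinates
#'
#' Builds the 3n x 3n Hessian of a Cartesian anisotropic network model (ANM):
#' every residue pair within `cutoff` is joined by a Hookean spring of
#' stiffness `spring_constant` along the equilibrium separation vector. The
#' 3x3 super-element for a connected pair (i, j) is
#' \eqn{H_{ij} = -k \, d d^T / |d|^2} with d the separation vector, and each
#' diagonal block is minus the sum of its row's off-diagonal blocks, so block
#' rows sum to zero (translational invariance).
#'
#' @param structure A [dyn_structure()].
#' @param cutoff Interaction cutoff distance in Angstrom (default 15).
#' @param spring_constant Uniform spring force constant (default 1).
#'
#' @return Object of class `dyn_hessian`: list with `matrix` (3n x 3n),
#'   `cutoff`, `spring_constant`, `n_residues`.
#' @seealso [compute_modes()]
#' @export
build_hessian <- function(structure, cutoff = 15, spring_constant = 1) {
  stopifnot_structure(structure)
  if (!is.numeric(cutoff) || cutoff <= 0) stop("'cutoff' must be positive")
  n <- n_residues(structure)
  xyz <- structure$coords
  dmat <- as.matrix(stats::dist(xyz))
  if (any(dmat[upper.tri(dmat)] < 1e-9)) {
    stop("degenerate geometry: two residues at (near) zero distance")
  }
  H <- matrix(0, 3L * n, 3L * n)
  pairs <- which(upper.tri(dmat) & dmat <= cutoff, arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    d <- xyz[j, ] - xyz[i, ]
    blk <- -spring_constant * tcrossprod(d) / sum(d * d)
    ri <- (3L * i - 2L):(3L * i); rj <- (3L * j - 2L):(3L * j)
    H[ri, rj] <- blk
    H[rj, ri] <- blk
    H[ri, ri] <- H[ri, ri] - blk
    H[rj, rj] <- H[rj, rj] - blk
  }
  structure(
    list(matrix = H, cutoff = cutoff, spring_constant = spring_constant,
         n_residues = n),
    class = "dyn_hessian"
  )
}

#' Normal-mode spectrum of an elastic-network Hessian
#'
#' Diagonalizes the Hessian, discards the six zero-frequency rigid-body
#' modes, and returns the remaining eigenpairs in ascending order of the
#' squared frequency \eqn{\omega_\alpha^2}. Eigenvectors are reshaped so each
#' mode gives every residue a 3-vector displacement. Eigenvalues below
#' `rigid_tol` times the largest eigenvalue count as rigid; finding more than
#' six means the contact network is disconnected at the chosen cutoff.
#'
#' @param hessian A `dyn_hessian` from [build_hessian()].
#' @param n_modes Number of non-rigid modes to keep, or `"all"` (default).
#' @param rigid_tol Relative tolerance for classifying rigid modes
#'   (default 1e-8).
#'
#' @return Object of class `dyn_modes`: list with `omega_sq` (length-M
#'   ascending positive eigenvalues), `shapes` (M x n x 3 array of mode
#'   displacement vectors), `n_residues`.
#' @export
compute_modes <- function(hessian, n_modes = "all", rigid_tol = 1e-8) {
  if (!inherits(hessian, "dyn_hessian")) stop("expected a 'dyn_hessian'")
  n <- hessian$n_residues
  eig <- eigen(hessian$matrix, symmetric = TRUE)
  vals <- rev(eig$values)             # ascending
  vecs <- eig$vectors[, rev(seq_along(eig$values)), drop = FALSE]
  lmax <- max(vals)
  if (lmax <= 0) {
    stop("disconnected contact network: Hessian has no positive eigenvalues")
  }
  rigid <- vals < rigid_tol * lmax
  n_rigid <- sum(rigid)
  if (n_rigid > 6L) {
    stop(sprintf(paste0(
      "disconnected contact network: %d near-zero modes found ",
      "(tolerance %g x largest eigenvalue), expected 6"), n_rigid, rigid_tol))
  }
  # a generic connected 3-D structure has exactly 6 rigid modes; degenerate
  # (collinear) toys can have 5, which the tolerance test handles correctly
  keep <- which(!rigid)
  M <- length(keep)
  if (!identical(n_modes, "all")) {
    n_modes <- as.integer(n_modes)
    if (n_modes < 1L || n_modes > M) stop("'n_modes' out of range [1, ", M, "]")
    keep <- keep[seq_len(n_modes)]
    M <- n_modes
  }
  shapes <- array(0, dim = c(M, n, 3L))
  for (m in seq_len(M)) {
    shapes[m, , ] <- matrix(vecs[, keep[m]], n, 3L, byrow = TRUE)
  }
  structure(
    list(omega_sq = vals[keep], shapes = shapes, n_residues = n),
    class = "dyn_modes"
  )
}

#' @export
print.dyn_modes <- function(x, ...) {
  cat(sprintf("<dyn_modes> %d modes over %d residues; omega^2 in [%.4g, %.4g]\n",
              length(x$omega_sq), x$n_residues,
              min(x$omega_sq), max(x$omega_sq)))
  invisible(x)
}

#' Construct a ModeSet directly from frequencies and shapes
#'
#' Mostly useful in tests and for hand-built toy systems; validates the
#' container invariants without running an eigendecomposition.
#'
#' @param omega_sq Positive numeric vector of squared mode frequencies.
#' @param shapes M x n x 3 array of per-residue mode displacement vectors.
#' @return A `dyn_modes` object.
#' @export
dyn_modes <- function(omega_sq, shapes) {
  shapes <- as.array(shapes)
  if (length(dim(shapes)) != 3L || dim(shapes)[3L] != 3L) {
    stop("'shapes' must be an M x n x 3 array")
  }
  if (length(omega_sq) != dim(shapes)[1L]) {
    stop("length(omega_sq) must equal the number of modes in 'shapes'")
  }
  if (any(omega_sq <= 0)) stop("all omega_sq must be positive")
  structure(
    list(omega_sq = as.numeric(omega_sq), shapes = shapes,
         n_residues = dim(shapes)[2L]),
    class = "dyn_modes"
  )
}
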
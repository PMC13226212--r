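#' Dynamical residue-pair coupling matrices
#'
#' Three symmetric n x n couplings summarize how residue pairs move in the
#' normal-mode ensemble, each mode weighted by \eqn{1/\omega_\alpha^2}
#' (equipartition: every mode carries the same thermal energy, so soft modes
#' dominate).
#'
#' \describe{
#'   \item{co-directionality}{the 1/\eqn{\omega^2}-weighted average cosine
#'     between the two residues' mode displacement vectors; 1 when the pair
#'     always moves in the same direction, -1 when always opposed.}
#'   \item{coordination}{one minus half the 1/\eqn{\omega^2}-weighted squared
#'     projection of the pair's relative displacement onto the equilibrium
#'     pair axis; near 1 when the inter-residue distance is invariant across
#'     modes ("moving in unison").}
#'   \item{deformation}{the largest eigenvalue of \eqn{F^T F} for the 3x3
#'     linear-response operator F mapping a unit force on residue j to the
#'     displacement of residue i; always non-negative.}
#' }
#'
#' @param modes A `dyn_modes` object from [compute_modes()].
#' @param structure A [dyn_structure()] (coordination only: supplies the
#'   equilibrium pair axes).
#' @param tol Displacement-norm tolerance below which a residue's direction
#'   is undefined in a mode (co-directionality only, default 1e-12). Modes in
#'   which either residue of a pair is static are dropped from that pair's
#'   weighted average; a pair with no valid modes gets `NaN` with a warning.
#'
#' @return A `dyn_coupling` object: list with `values` (n x n symmetric
#'   matrix) and `kind` (one of `"codirectionality"`, `"coordination"`,
#'   `"deformation"`).
#' @name couplings
NULL

new_coupling <- function(values, kind) {
  structure(list(values = values, kind = kind), class = "dyn_coupling")
}

#' @export
print.dyn_coupling <- function(x, ...) {
  cat(sprintf("<dyn_coupling> kind=%s, %d x %d\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname couplings
#' @export
codirectionality <- function(modes, tol = 1e-12) {
  if (!inherits(modes, "dyn_modes")) stop("expected a 'dyn_modes'")
  n <- modes$n_residues
  w <- 1 / modes$omega_sq
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (a in seq_along(w)) {
    X <- modes$shapes[a, , , drop = TRUE]
    if (n == 1L) X <- matrix(X, 1L, 3L)
    nrm <- sqrt(rowSums(X * X))
    valid <- nrm > tol
    Xh <- X / ifelse(valid, nrm, 1)
    Xh[!valid, ] <- 0
    cosmat <- tcrossprod(Xh)              # zero rows/cols where invalid
    pairmask <- tcrossprod(as.numeric(valid))
    num <- num + w[a] * cosmat
    den <- den + w[a] * pairmask
  }
  vals <- num / den
  if (any(den == 0)) {
    warning("co-directionality undefined (all modes static) for some pairs; NaN returned")
    vals[den == 0] <- NaN
  }
  diag(vals) <- 1
  new_coupling(vals, "codirectionality")
}

#' @rdname couplings
#' @export
coordination <- function(modes, structure) {
  if (!inherits(modes, "dyn_modes")) stop("expected a 'dyn_modes'")
  stopifnot_structure(structure)
  n <- modes$n_residues
  if (n_residues(structure) != n) stop("structure / modes residue-count mismatch")
  xyz <- structure$coords
  # unit equilibrium separation vectors, componentwise n x n
  ux <- outer(xyz[, 1L], xyz[, 1L], "-")
  uy <- outer(xyz[, 2L], xyz[, 2L], "-")
  uz <- outer(xyz[, 3L], xyz[, 3L], "-")
  dd <- sqrt(ux^2 + uy^2 + uz^2)
  off <- row(dd) != col(dd)
  if (any(dd[off] < 1e-9)) {
    stop("degenerate geometry: coincident residue positions")
  }
  diag(dd) <- 1
  ux <- ux / dd; uy <- uy / dd; uz <- uz / dd
  w <- 1 / modes$omega_sq
  acc <- matrix(0, n, n)
  for (a in seq_along(w)) {
    X <- modes$shapes[a, , , drop = TRUE]
    if (n == 1L) X <- matrix(X, 1L, 3L)
    proj <- ux * outer(X[, 1L], X[, 1L], "-") +
            uy * outer(X[, 2L], X[, 2L], "-") +
            uz * outer(X[, 3L], X[, 3L], "-")
    acc <- acc + w[a] * proj^2
  }
  vals <- 1 - 0.5 * acc
  diag(vals) <- 1                          # zero relative motion by convention
  new_coupling(vals, "coordination")
}

#' @rdname couplings
#' @export
deformation <- function(modes) {
  if (!inherits(modes, "dyn_modes")) stop("expected a 'dyn_modes'")
  n <- modes$n_residues
  w <- 1 / modes$omega_sq
  M <- length(w)
  # component matrices X_m: M x n, rows scaled by w when used once
  Xc <- lapply(1:3, function(m) matrix(modes$shapes[, , m], M, n))
  # F^(ij)_mn = sum_a x_ima * x_jna * w_a  -> F_mn over all pairs is the
  # n x n matrix t(Xm) %*% diag(w) %*% Xn
  Fmn <- vector("list", 9L)
  k <- 0L
  for (m in 1:3) {
    Xm_w <- Xc[[m]] * w
    for (nn in 1:3) {
      k <- k + 1L
      Fmn[[k]] <- crossprod(Xm_w, Xc[[nn]])   # index [i, j]
    }
  }
  # G = F^T F per pair (3x3 symmetric PSD); largest eigenvalue via the
  # closed-form trigonometric solution, vectorized over all n^2 pairs
  Fm <- function(m, nn) Fmn[[(m - 1L) * 3L + nn]]
  G <- vector("list", 6L)       # G11, G22, G33, G12, G13, G23
  G[[1L]] <- Fm(1,1)^2 + Fm(2,1)^2 + Fm(3,1)^2
  G[[2L]] <- Fm(1,2)^2 + Fm(2,2)^2 + Fm(3,2)^2
  G[[3L]] <- Fm(1,3)^2 + Fm(2,3)^2 + Fm(3,3)^2
  G[[4L]] <- Fm(1,1)*Fm(1,2) + Fm(2,1)*Fm(2,2) + Fm(3,1)*Fm(3,2)
  G[[5L]] <- Fm(1,1)*Fm(1,3) + Fm(2,1)*Fm(2,3) + Fm(3,1)*Fm(3,3)
  G[[6L]] <- Fm(1,2)*Fm(1,3) + Fm(2,2)*Fm(2,3) + Fm(3,2)*Fm(3,3)
  vals <- sym3_eigmax(G[[1L]], G[[2L]], G[[3L]], G[[4L]], G[[5L]], G[[6L]])
  vals <- 0.5 * (vals + t(vals))           # absorb floating-point asymmetry
  new_coupling(vals, "deformation")
}

# Largest eigenvalue of symmetric 3x3 matrices [[a11,a12,a13],[.,a22,a23],
# [.,.,a33]], elementwise over equal-shaped numeric arrays. Trigonometric
# closed form; exact for multiples of the identity via the p ~ 0 branch.
sym3_eigmax <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) -
          a12 * (a12 * b33 - a23 * a13) +
          a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  out <- q + 2 * p * cos(phi)
  out[p2 <= 0] <- q[p2 <= 0]
  out
}
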
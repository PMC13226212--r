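#' Laplacian energy of a graph
#'
#' The Laplacian energy of a simple undirected graph is the sum of squared
#' eigenvalues of its combinatorial Laplacian L = D - A. For an unweighted
#' graph this equals \eqn{trace(L^2) = \sum_i d_i^2 + 2m} with m the edge
#' count, which is what this function computes; the eigendecomposition route
#' is kept as an independent oracle in the test-suite.
#'
#' @param edge_set A `dyn_edge_set`, or a 2-column 0-based edge matrix.
#' @param n Number of nodes (taken from the edge set when omitted).
#' @return Non-negative scalar energy.
#' @export
laplacian_energy <- function(edge_set, n = NULL) {
  eg <- as_edge_matrix(edge_set, n)
  d <- tabulate(c(eg$edges[, 1L], eg$edges[, 2L]) + 1L, nbins = eg$n)
  sum(d^2) + 2 * nrow(eg$edges)
}

#' Laplacian node-centrality profile
#'
#' The Laplacian centrality of node v is the relative drop in Laplacian
#' energy when v and its incident edges are deleted:
#' \eqn{C_L(G, v) = (U_L(G) - U_L(G - v)) / U_L(G)}. Isolated nodes score 0;
#' articulation-like hubs score near 1. Used on coordination graphs it
#' highlights residues whose motion is coordinated with many others, which
#' the interpretation analysis relates to functionally annotated sites.
#'
#' @param edge_set A `dyn_edge_set`, or 2-column 0-based edge matrix.
#' @param n Number of nodes (taken from the edge set when omitted).
#' @param protein_id Identifier carried into the profile.
#' @return A `dyn_centrality` object: list with `values` (length-n in
#'   `[0, 1]`), `edge_type`, `protein_id`.
#' @export
laplacian_centrality_profile <- function(edge_set, n = NULL, protein_id = "protein") {
  eg <- as_edge_matrix(edge_set, n)
  U <- laplacian_energy(edge_set, n)
  if (U == 0) stop("Laplacian centrality undefined on an edgeless graph")
  d <- tabulate(c(eg$edges[, 1L], eg$edges[, 2L]) + 1L, nbins = eg$n)
  # removing node v: each neighbour u loses one degree unit, so
  # U(G-v) = sum_{u != v} (d_u - A_uv)^2 + 2 (m - d_v)
  #        = (sum d^2 - d_v^2) - 2 * sum_{u in N(v)} d_u + d_v + 2 (m - d_v)
  nbr_deg_sum <- numeric(eg$n)
  if (nrow(eg$edges)) {
    i <- eg$edges[, 1L] + 1L; j <- eg$edges[, 2L] + 1L
    agg <- rowsum(c(d[j], d[i]), c(i, j))
    nbr_deg_sum[as.integer(rownames(agg))] <- agg[, 1L]
  }
  sumd2 <- sum(d^2); m <- nrow(eg$edges)
  U_minus <- (sumd2 - d^2) - 2 * nbr_deg_sum + d + 2 * (m - d)
  vals <- (U - U_minus) / U
  et <- if (inherits(edge_set, "dyn_edge_set")) edge_set$edge_type else "graph"
  structure(list(values = vals, edge_type = et, protein_id = protein_id),
            class = "dyn_centrality")
}

#' @export
print.dyn_centrality <- function(x, ...) {
  cat(sprintf("<dyn_centrality> %s / %s: %d nodes, max %.3f\n",
              x$protein_id, x$edge_type, length(x$values), max(x$values)))
  invisible(x)
}

#' Flag local centrality peaks (heuristic)
#'
#' Labels residues that are strict local maxima of the profile and above the
#' given quantile of all values. A convenience for eyeballing candidate
#' critical residues; it is a heuristic, not a site predictor.
#'
#' @param profile A `dyn_centrality`.
#' @param quantile Minimum profile quantile for a peak (default 0.9).
#' @return Integer vector of 0-based residue indices.
#' @export
centrality_peaks <- function(profile, quantile = 0.9) {
  v <- profile$values
  n <- length(v)
  if (n < 3L) return(integer(0L))
  thr <- stats::quantile(v, quantile, names = FALSE)
  idx <- which(v >= thr)
  is_peak <- vapply(idx, function(i) {
    left <- if (i > 1L) v[i] > v[i - 1L] else TRUE
    right <- if (i < n) v[i] > v[i + 1L] else TRUE
    left && right
  }, logical(1L))
  idx[is_peak] - 1L
}

as_edge_matrix <- function(edge_set, n = NULL) {
  if (inherits(edge_set, "dyn_edge_set")) {
    list(edges = edge_set$edges, n = if (is.null(n)) edge_set$n else as.integer(n))
  } else {
    if (is.null(n)) stop("'n' is required with a plain edge matrix")
    list(edges = matrix(as.integer(edge_set), ncol = 2L), n = as.integer(n))
  }
}
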
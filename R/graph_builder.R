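#' Edge sets and multigraph assembly
#'
#' An edge set is an unweighted simple undirected graph over the residues of
#' one protein: a two-column integer matrix of 0-based residue index pairs
#' (i < j) plus an `edge_type` tag. Multigraph samples bundle several edge
#' sets ("dimensions") over one shared node set.
#'
#' @name edge_sets
NULL

new_edge_set <- function(pairs, edge_type, n, coupling_values = NULL) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  colnames(pairs) <- c("i", "j")
  if (nrow(pairs)) {
    swap <- pairs[, 1L] > pairs[, 2L]
    pairs[swap, ] <- pairs[swap, c(2L, 1L)]
    if (any(pairs[, 1L] == pairs[, 2L])) stop("self-loops are not allowed")
    if (any(pairs < 0L) || any(pairs >= n)) stop("edge index out of range")
    o <- order(pairs[, 1L], pairs[, 2L])
    pairs <- pairs[o, , drop = FALSE]
    if (!is.null(coupling_values)) coupling_values <- coupling_values[o]
    if (anyDuplicated(paste(pairs[, 1L], pairs[, 2L]))) {
      stop("duplicate edges are not allowed")
    }
  }
  structure(
    list(edges = pairs, edge_type = edge_type, n = as.integer(n),
         coupling_values = coupling_values),
    class = "dyn_edge_set"
  )
}

#' @export
print.dyn_edge_set <- function(x, ...) {
  cat(sprintf("<dyn_edge_set> type=%s, %d nodes, %d edges\n",
              x$edge_type, x$n, nrow(x$edges)))
  invisible(x)
}

n_edges <- function(edge_set) nrow(edge_set$edges)

#' Contact edges from alpha-carbon distances
#'
#' All residue pairs whose alpha-carbon distance is at most `cutoff`.
#'
#' @param structure A [dyn_structure()].
#' @param cutoff Contact distance cutoff in Angstrom (default 12).
#' @return A `dyn_edge_set` with `edge_type = "contact"`.
#' @export
contact_edges <- function(structure, cutoff = 12) {
  stopifnot_structure(structure)
  if (cutoff <= 0) stop("'cutoff' must be positive")
  dmat <- as.matrix(stats::dist(structure$coords))
  sel <- which(upper.tri(dmat) & dmat <= cutoff, arr.ind = TRUE)
  new_edge_set(cbind(sel[, 1L] - 1L, sel[, 2L] - 1L), "contact",
               n_residues(structure))
}

#' Backbone (chain-adjacency) edges
#'
#' Edges between sequence-consecutive residues, giving the path graph
#' 0-1-2-...-(n-1).
#'
#' @param n Number of residues (>= 2).
#' @return A `dyn_edge_set` with `edge_type = "backbone"`.
#' @export
backbone_edges <- function(n) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be at least 2")
  new_edge_set(cbind(0:(n - 2L), 1:(n - 1L)), "backbone", n)
}

#' Threshold specification for coupling graphs
#'
#' The seven tested schemes for turning a dense coupling matrix into an edge
#' set. Per-protein schemes: `N` keeps pairs with coupling at or above the
#' value (100-N)% up the protein's min-max coupling range; `SIGMA` keeps
#' pairs strictly above mu + SIGMA x sigma of the protein's couplings;
#' `CONT` keeps the top `round(CONT x N_cont)` pairs where N_cont is the
#' protein's contact-edge count at `contact_cutoff`; `PAIR` keeps the top
#' `round(PAIR/100 x n(n-1)/2)` pairs. Dataset-wide schemes `DN`, `DSIGMA`,
#' `DCONT` replace the per-protein range, moments, and contact count with
#' training-set statistics from [dataset_stats()].
#'
#' @param scheme One of `"N"`, `"SIGMA"`, `"CONT"`, `"PAIR"`, `"DN"`,
#'   `"DSIGMA"`, `"DCONT"`.
#' @param parameter Positive scheme parameter (e.g. 20 for 20N, 1 for 1CONT).
#' @param contact_cutoff Contact cutoff in Angstrom used by `CONT`
#'   (default 12).
#' @return A `dyn_threshold_spec`.
#' @export
threshold_spec <- function(scheme, parameter, contact_cutoff = 12) {
  scheme <- match.arg(scheme, c("N", "SIGMA", "CONT", "PAIR", "DN", "DSIGMA", "DCONT"))
  if (!is.numeric(parameter) || length(parameter) != 1L || parameter <= 0) {
    stop("'parameter' must be a positive number")
  }
  structure(list(scheme = scheme, parameter = parameter,
                 contact_cutoff = contact_cutoff),
            class = "dyn_threshold_spec")
}

#' Training-set coupling statistics for dataset-wide thresholds
#'
#' Pools the upper-triangle (off-diagonal) coupling values of the training
#' proteins and records the range, mean, and population standard deviation,
#' plus the average number of 12-Angstrom contact edges per training protein
#' (N_cont-bar, used by `DCONT`).
#'
#' @param couplings List of `dyn_coupling` objects (training proteins only),
#'   all of one kind.
#' @param structures List of matching [dyn_structure()] objects.
#' @param contact_cutoff Contact cutoff for the mean contact-edge count
#'   (default 12).
#' @return A `dyn_dataset_stats` with fields `coupling_min`, `coupling_max`,
#'   `mu`, `sigma`, `mean_contact_edges`, `kind`.
#' @export
dataset_stats <- function(couplings, structures, contact_cutoff = 12) {
  if (!length(couplings)) stop("need at least one training protein")
  kinds <- unique(vapply(couplings, function(cc) cc$kind, character(1L)))
  if (length(kinds) != 1L) stop("all couplings must share one kind")
  vals <- unlist(lapply(couplings, function(cc) {
    v <- cc$values
    v[upper.tri(v)]
  }))
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))       # population sd
  mce <- mean(vapply(structures, function(s) {
    n_edges(contact_edges(s, contact_cutoff))
  }, numeric(1L)))
  structure(
    list(coupling_min = min(vals), coupling_max = max(vals),
         mu = mu, sigma = sigma, mean_contact_edges = mce, kind = kinds),
    class = "dyn_dataset_stats"
  )
}

#' Threshold a coupling matrix into an edge set
#'
#' Applies a [threshold_spec()] scheme to the upper triangle of a coupling
#' matrix (diagonals are never eligible). Count-based schemes rank pairs by
#' descending coupling, breaking ties by lower i then lower j; fractional
#' edge targets are rounded half-to-even. Requesting more edges than pairs
#' keeps all pairs with a warning.
#'
#' @param coupling A `dyn_coupling`.
#' @param spec A `dyn_threshold_spec`.
#' @param structure The protein's [dyn_structure()] (needed by `CONT` for
#'   the per-protein contact count).
#' @param stats A `dyn_dataset_stats` (required by `DN`/`DSIGMA`/`DCONT`).
#' @return A `dyn_edge_set` whose `edge_type` is the coupling kind.
#' @export
apply_threshold <- function(coupling, spec, structure = NULL, stats = NULL) {
  if (!inherits(coupling, "dyn_coupling")) stop("expected a 'dyn_coupling'")
  if (!inherits(spec, "dyn_threshold_spec")) stop("expected a 'dyn_threshold_spec'")
  vals <- coupling$values
  n <- nrow(vals)
  ut <- which(upper.tri(vals), arr.ind = TRUE)
  cv <- vals[upper.tri(vals)]
  scheme <- spec$scheme
  p <- spec$parameter

  if (scheme %in% c("DN", "DSIGMA", "DCONT")) {
    if (is.null(stats)) {
      stop("scheme ", scheme, " requires dataset statistics ('stats')")
    }
    if (!inherits(stats, "dyn_dataset_stats")) stop("invalid 'stats'")
  }

  keep <- switch(scheme,
    N = {
      thr <- min(cv) + (100 - p) / 100 * (max(cv) - min(cv))
      cv >= thr
    },
    DN = {
      thr <- stats$coupling_min +
        (100 - p) / 100 * (stats$coupling_max - stats$coupling_min)
      cv >= thr
    },
    SIGMA = {
      mu <- mean(cv)
      sigma <- sqrt(mean((cv - mu)^2))
      cv > mu + p * sigma
    },
    DSIGMA = cv > stats$mu + p * stats$sigma,
    CONT = {
      if (is.null(structure)) stop("scheme CONT requires 'structure'")
      ncont <- n_edges(contact_edges(structure, spec$contact_cutoff))
      top_k_mask(cv, ut, round(p * ncont))
    },
    DCONT = top_k_mask(cv, ut, round(p * stats$mean_contact_edges)),
    PAIR = top_k_mask(cv, ut, round(p / 100 * length(cv)))
  )
  new_edge_set(cbind(ut[keep, 1L] - 1L, ut[keep, 2L] - 1L),
               coupling$kind, n, coupling_values = cv[keep])
}

# logical mask keeping the top-k couplings, ties broken by (lower i, lower j)
top_k_mask <- function(cv, ut, k) {
  k <- as.integer(k)
  m <- length(cv)
  if (k >= m) {
    if (k > m) warning("requested ", k, " edges but only ", m, " pairs exist; keeping all")
    return(rep(TRUE, m))
  }
  mask <- rep(FALSE, m)
  if (k > 0L) {
    o <- order(-cv, ut[, 1L], ut[, 2L])
    mask[o[seq_len(k)]] <- TRUE
  }
  mask
}

#' Connectivity screen over a protein set
#'
#' Graph representations averaging fewer than 10 edges per protein are too
#' sparse to train on and are excluded.
#'
#' @param edge_sets List of `dyn_edge_set`, one per protein.
#' @param min_mean_edges Exclusion boundary (default 10; the mean must reach
#'   it to pass).
#' @return List with `pass` (logical) and `mean_edges`.
#' @export
screen_connectivity <- function(edge_sets, min_mean_edges = 10) {
  if (!length(edge_sets)) stop("empty protein set")
  m <- mean(vapply(edge_sets, n_edges, numeric(1L)))
  list(pass = m >= min_mean_edges, mean_edges = m)
}

#' Assemble a multigraph sample
#'
#' Bundles a shared node-feature matrix with one edge set per requested
#' dimension, the organism optimal growth temperature, and (optionally) the
#' melting-temperature label. The study's best configuration uses the four
#' dimensions contact + co-directionality + coordination + deformation, each
#' dynamical one thresholded with scheme CONT at parameter 1 (same edge
#' count as the 12-Angstrom contact graph).
#'
#' @param structure A [dyn_structure()].
#' @param node_features n x F numeric matrix (default: [one_hot_features()]).
#' @param edge_sets Named or unnamed list of `dyn_edge_set` objects sharing
#'   this structure's n; names default to each set's `edge_type`.
#' @param ogt Organism optimal growth temperature in Celsius.
#' @param label_tm Melting temperature label in Celsius, or `NULL`.
#' @param protein_id Identifier string.
#' @return A `dyn_multigraph` sample.
#' @export
assemble_multigraph <- function(structure, edge_sets, ogt,
                                node_features = NULL, label_tm = NULL,
                                protein_id = "protein") {
  stopifnot_structure(structure)
  n <- n_residues(structure)
  if (is.null(node_features)) node_features <- one_hot_features(structure)
  node_features <- as.matrix(node_features)
  if (nrow(node_features) != n) {
    stop("node_features has ", nrow(node_features), " rows but structure has ",
         n, " residues")
  }
  if (!length(edge_sets)) stop("at least one edge set is required")
  for (es in edge_sets) {
    if (!inherits(es, "dyn_edge_set")) stop("edge_sets must contain 'dyn_edge_set' objects")
    if (es$n != n) stop("edge set over ", es$n, " nodes does not match n = ", n)
  }
  if (is.null(names(edge_sets)) || any(!nzchar(names(edge_sets)))) {
    names(edge_sets) <- vapply(edge_sets, function(e) e$edge_type, character(1L))
  }
  structure(
    list(node_features = node_features, edge_sets = edge_sets,
         ogt = as.numeric(ogt), label_tm = if (is.null(label_tm)) NULL else as.numeric(label_tm),
         protein_id = as.character(protein_id)),
    class = "dyn_multigraph"
  )
}

#' @export
print.dyn_multigraph <- function(x, ...) {
  cat(sprintf("<dyn_multigraph> %s: %d residues, dims {%s}, OGT %.1f C%s\n",
              x$protein_id, nrow(x$node_features),
              paste(names(x$edge_sets), collapse = ", "), x$ogt,
              if (is.null(x$label_tm)) "" else sprintf(", Tm %.1f C", x$label_tm)))
  invisible(x)
}

# dense adjacency matrix of an edge set
adjacency_matrix <- function(edge_set) {
  A <- matrix(0, edge_set$n, edge_set$n)
  if (n_edges(edge_set)) {
    ij <- edge_set$edges + 1L
    A[ij] <- 1
    A[ij[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
}
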
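#' Ideal helical alpha-carbon trace
#'
#' Places residue i at (r cos(i theta), r sin(i theta), i * rise): the
#' standard alpha-helix geometry with ~3.8 Angstrom consecutive alpha-carbon
#' spacing at the defaults. Deterministic; sequence is poly-alanine.
#'
#' @param n Number of residues (>= 2).
#' @param radius Helix radius in Angstrom (default 2.3).
#' @param rise Rise per residue in Angstrom (default 1.5).
#' @param twist_deg Twist per residue in degrees (default 100).
#' @return A [dyn_structure()].
#' @export
make_helix <- function(n, radius = 2.3, rise = 1.5, twist_deg = 100) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be at least 2")
  i <- seq_len(n) - 1L
  theta <- i * twist_deg * pi / 180
  coords <- cbind(radius * cos(theta), radius * sin(theta), i * rise)
  dyn_structure(coords, strrep("A", n))
}

#' Self-avoiding random-coil alpha-carbon trace
#'
#' Seeded self-avoiding random walk with a fixed 3.8 Angstrom bond length
#' and a minimum 4 Angstrom separation between non-consecutive residues,
#' confined to a sphere sized like a globular protein of the same length
#' (radius ~ 3.8 n^0.38 Angstrom, the empirical radius-of-gyration scaling
#' with headroom). Confinement keeps the decoys compact, as real
#' single-domain proteins are; an unconfined walk would be an unrealistically
#' extended polymer. The sequence is drawn uniformly from the 20 standard
#' amino acids under the same seed.
#'
#' @param n Number of residues (>= 2).
#' @param seed Integer RNG seed.
#' @param confinement_radius Sphere radius in Angstrom (default
#'   `max(3.8 * n^0.38, 10)`).
#' @param max_retries Bounded placement retries per residue; a fully stuck
#'   walk restarts (up to 20 times, still seed-deterministic) before
#'   erroring.
#' @return A [dyn_structure()].
#' @export
make_coil <- function(n, seed = 1L, confinement_radius = NULL,
                      max_retries = 500L) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be at least 2")
  if (is.null(confinement_radius)) {
    confinement_radius <- max(3.8 * n^0.38, 10)
  }
  set.seed(seed)
  bond <- 3.8
  min_sep <- 4
  for (attempt in seq_len(20L)) {
    coords <- matrix(NA_real_, n, 3L)
    coords[1L, ] <- c(0, 0, 0)
    stuck <- FALSE
    for (i in 2:n) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        # uniform direction on the sphere
        v <- stats::rnorm(3L)
        cand <- coords[i - 1L, ] + bond * v / sqrt(sum(v^2))
        if (sqrt(sum(cand^2)) > confinement_radius) next
        if (i > 2L) {
          prev <- coords[seq_len(i - 2L), , drop = FALSE]
          d2 <- rowSums((prev - matrix(cand, i - 2L, 3L, byrow = TRUE))^2)
          if (min(d2) < min_sep^2) next
        }
        coords[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { stuck <- TRUE; break }
    }
    if (!stuck) {
      aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
      return(dyn_structure(coords, sample(aa, n, replace = TRUE)))
    }
  }
  stop("coil placement failed after ", max_retries,
       " retries in each of 20 restarts")
}

#' Fixture-dataset configuration
#'
#' Defines the synthetic study conditions: how many proteins, their length
#' range and geometry, coordinate noise, and the generative label model
#' `Tm = intercept + ogt_slope * OGT + graph_slope * mean-coordination-coupling
#' + N(0, label_noise_sd^2)` with OGT drawn uniformly in 20-80 Celsius.
#'
#' @param n_proteins Number of proteins (default 400).
#' @param length_range Length-2 integer residue-count range (default 30-80).
#' @param geometry `"mixed"` (default; alternating helix/coil), `"helix"`,
#'   or `"coil"`.
#' @param noise_sd Gaussian coordinate jitter in Angstrom (default 0.3;
#'   helices only, coils are already random).
#' @param label_coefficients Numeric `(intercept, ogt_slope, graph_slope)`
#'   (default 20, 0.5, 30).
#' @param label_noise_sd Label noise in Celsius (default 2).
#' @param seed Integer seed; the generator is a pure function of this
#'   config.
#' @return A `dyn_fixture_config`.
#' @export
fixture_config <- function(n_proteins = 400L, length_range = c(30L, 80L),
                           geometry = c("mixed", "helix", "coil"),
                           noise_sd = 0.3,
                           label_coefficients = c(20, 0.5, 30),
                           label_noise_sd = 2, seed = 1L) {
  geometry <- match.arg(geometry)
  if (any(length_range < 5L)) stop("lengths must be at least 5")
  if (noise_sd < 0 || label_noise_sd < 0) stop("noise must be non-negative")
  structure(
    list(n_proteins = as.integer(n_proteins),
         length_range = as.integer(length_range), geometry = geometry,
         noise_sd = noise_sd, label_coefficients = label_coefficients,
         label_noise_sd = label_noise_sd, seed = as.integer(seed)),
    class = "dyn_fixture_config"
  )
}

#' Generate a labeled synthetic multigraph dataset
#'
#' Produces structures per the configured geometry, runs the real pipeline
#' (elastic-network modes at `enm_cutoff`, the three couplings, contact
#' edges at `contact_cutoff`, and CONT-thresholded dynamical edges), draws
#' OGT uniformly in 20-80 Celsius, and labels each protein with the
#' generative model in [fixture_config()]. The generative ingredients (OGT,
#' mean coordination coupling, noise draw) are recorded in each sample's
#' `meta` field.
#'
#' @param config A [fixture_config()].
#' @param threshold A [threshold_spec()] for the dynamical edge sets
#'   (default scheme CONT with parameter 1, the study's best configuration).
#' @param enm_cutoff Elastic-network cutoff in Angstrom (default 15).
#' @param contact_cutoff Contact cutoff in Angstrom (default 12).
#' @return List of labeled `dyn_multigraph` samples, each with edge sets
#'   contact, codirectionality, coordination, deformation.
#' @export
make_labeled_dataset <- function(config,
                                 threshold = threshold_spec("CONT", 1),
                                 enm_cutoff = 15, contact_cutoff = 12) {
  if (!inherits(config, "dyn_fixture_config")) stop("expected a 'dyn_fixture_config'")
  set.seed(config$seed)
  nP <- config$n_proteins
  lens <- sample(config$length_range[1L]:config$length_range[2L], nP,
                 replace = TRUE)
  ogts <- stats::runif(nP, 20, 80)
  noise <- stats::rnorm(nP, 0, config$label_noise_sd)
  kinds <- switch(config$geometry,
                  helix = rep("helix", nP),
                  coil = rep("coil", nP),
                  mixed = rep_len(c("helix", "coil"), nP))
  sub_seeds <- sample.int(.Machine$integer.max, nP)
  cf <- config$label_coefficients
  samples <- vector("list", nP)
  for (pidx in seq_len(nP)) {
    s <- fixture_structure(kinds[pidx], lens[pidx], sub_seeds[pidx],
                           config$noise_sd)
    modes <- compute_modes(build_hessian(s, cutoff = enm_cutoff))
    co <- codirectionality(modes)
    cr <- coordination(modes, s)
    de <- deformation(modes)
    es <- list(
      contact = contact_edges(s, contact_cutoff),
      codirectionality = apply_threshold(co, threshold, s),
      coordination = apply_threshold(cr, threshold, s),
      deformation = apply_threshold(de, threshold, s)
    )
    mean_coord <- mean(cr$values[upper.tri(cr$values)])
    tm <- cf[1L] + cf[2L] * ogts[pidx] + cf[3L] * mean_coord + noise[pidx]
    sm <- assemble_multigraph(s, es, ogt = ogts[pidx], label_tm = tm,
                              protein_id = sprintf("synth%04d", pidx))
    sm$meta <- list(geometry = kinds[pidx], length = lens[pidx],
                    mean_coordination = mean_coord, noise = noise[pidx],
                    coefficients = cf, seed = sub_seeds[pidx],
                    structure = s)
    samples[[pidx]] <- sm
  }
  samples
}

fixture_structure <- function(kind, len, seed, noise_sd) {
  if (kind == "coil") {
    make_coil(len, seed = seed)
  } else {
    s <- make_helix(len)
    if (noise_sd > 0) {
      set.seed(seed)
      s$coords <- s$coords + matrix(stats::rnorm(3L * len, 0, noise_sd),
                                    len, 3L)
    }
    s
  }
}
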
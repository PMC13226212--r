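#' Construct a coarse-grained protein structure
#'
#' A `dyn_structure` holds one alpha-carbon per residue for a single protein
#' chain: the equilibrium coordinates every elastic-network quantity is built
#' from, the one-letter sequence, and the author residue numbering used in
#' reports.
#'
#' @param coords n x 3 numeric matrix of alpha-carbon coordinates (Angstrom).
#' @param sequence Length-n one-letter amino-acid string, or a character
#'   vector of n single letters.
#' @param residue_ids Integer vector of author residue numbers (default
#'   `seq_len(n)`).
#' @param chain_id Single chain identifier string (default `"A"`).
#'
#' @return An object of class `dyn_structure` with fields `coords`,
#'   `sequence`, `residue_ids`, `chain_id`.
#' @examples
#' s <- dyn_structure(matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE), "AA")
#' s$coords
#' @export
dyn_structure <- function(coords, sequence, residue_ids = NULL, chain_id = "A") {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L) {
    stop("'coords' must be an n x 3 numeric matrix")
  }
  n <- nrow(coords)
  if (n < 2L) stop("a structure needs at least 2 residues")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1L]]
  }
  sequence <- as.character(sequence)
  if (length(sequence) != n) {
    stop("sequence length (", length(sequence), ") != number of residues (", n, ")")
  }
  if (is.null(residue_ids)) residue_ids <- seq_len(n)
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) != n) stop("residue_ids length mismatch")
  dimnames(coords) <- NULL
  structure(
    list(coords = coords, sequence = sequence, residue_ids = residue_ids,
         chain_id = as.character(chain_id)[1L]),
    class = "dyn_structure"
  )
}

#' @export
print.dyn_structure <- function(x, ...) {
  cat(sprintf("<dyn_structure> chain %s, %d residues\n", x$chain_id, nrow(x$coords)))
  cat("  sequence: ", paste(utils::head(x$sequence, 40L), collapse = ""),
      if (length(x$sequence) > 40L) "..." else "", "\n", sep = "")
  invisible(x)
}

n_residues <- function(structure) nrow(structure$coords)

stopifnot_structure <- function(structure) {
  if (!inherits(structure, "dyn_structure")) {
    stop("expected a 'dyn_structure' object")
  }
  invisible(structure)
}

#' One-hot amino-acid node features
#'
#' Default node-feature matrix when no precomputed embedding is supplied:
#' each residue is encoded as a 20-dimensional indicator over the standard
#' amino-acid alphabet. Unknown letters (e.g. X) get an all-zero row.
#'
#' @param structure A [dyn_structure()].
#' @return n x 20 numeric matrix with column names the amino-acid letters.
#' @export
one_hot_features <- function(structure) {
  stopifnot_structure(structure)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  idx <- match(structure$sequence, aa)
  out <- matrix(0, n_residues(structure), 20L, dimnames = list(NULL, aa))
  keep <- !is.na(idx)
  out[cbind(which(keep), idx[keep])] <- 1
  out
}
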
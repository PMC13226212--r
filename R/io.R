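#' Read a single-chain alpha-carbon structure from PDB or mmCIF
#'
#' Parses the file with bio3d, keeps one alpha-carbon per residue of the
#' selected chain in file order, resolves alternate locations to the
#' highest occupancy (ties to altloc "A"), and skips residues missing their
#' alpha-carbon with a warning.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param chain Chain identifier, or `"first"` (default) for the first chain
#'   in the file.
#' @return A [dyn_structure()].
#' @export
read_structure <- function(path, chain = "first") {
  if (!file.exists(path)) stop("no such file: ", path)
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path)
  atoms <- pdb$atom
  ca <- atoms[atoms$elety == "CA" & atoms$type %in% c("ATOM", ""), , drop = FALSE]
  if (!nrow(ca)) stop("empty structure: no alpha-carbon atoms in ", path)
  if (identical(chain, "first")) chain <- ca$chain[1L]
  ca <- ca[ca$chain %in% chain, , drop = FALSE]
  if (!nrow(ca)) stop("no alpha-carbons in chain ", chain)
  # altloc policy: highest occupancy, ties broken toward 'A'/blank
  key <- paste(ca$resno, ca$insert)
  keep <- unlist(lapply(split(seq_len(nrow(ca)), factor(key, levels = unique(key))),
                        function(rows) {
    if (length(rows) == 1L) return(rows)
    occ <- ca$o[rows]
    occ[is.na(occ)] <- 1
    alt <- ca$alt[rows]
    alt[is.na(alt)] <- ""
    rows[order(-occ, alt != "" & alt != "A")][1L]
  }), use.names = FALSE)
  ca <- ca[sort(keep), , drop = FALSE]
  seq1 <- suppressWarnings(bio3d::aa321(ca$resid))
  seq1[is.na(seq1)] <- "X"
  dyn_structure(cbind(ca$x, ca$y, ca$z), seq1,
                residue_ids = ca$resno, chain_id = chain)
}

#' Write an alpha-carbon-only PDB file for a structure
#'
#' Emits one ATOM record per residue (element CA), suitable for feeding the
#' pipeline's own reader or external viewers. Fixture structures written
#' this way are synthetic, not experimental models.
#'
#' @param structure A [dyn_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  stopifnot_structure(structure)
  aa3 <- bio3d::aa123(structure$sequence)
  aa3[is.na(aa3) | aa3 == "X"] <- "UNK"
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(structure$coords)),
                   type = "ATOM",
                   resno = structure$residue_ids,
                   resid = aa3,
                   elety = rep("CA", n_residues(structure)),
                   chain = rep(structure$chain_id, n_residues(structure)))
  invisible(path)
}

#' Serialize and restore coupling matrices
#'
#' Matrices are written as dense whitespace-delimited text with a JSON
#' sidecar (`<path>.json`) recording the coupling kind and size; the
#' round-trip is exact to full double precision.
#'
#' @param coupling A `dyn_coupling`.
#' @param path Output path for the matrix text file.
#' @param meta Optional named list merged into the sidecar.
#' @return `path`, invisibly (writer); a `dyn_coupling` (reader).
#' @export
write_coupling <- function(coupling, path, meta = list()) {
  if (!inherits(coupling, "dyn_coupling")) stop("expected a 'dyn_coupling'")
  utils::write.table(format(coupling$values, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  side <- c(list(kind = coupling$kind, n = nrow(coupling$values)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_coupling
#' @export
read_coupling <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(vals) <- NULL
  if (nrow(vals) != side$n) stop("matrix size does not match sidecar metadata")
  new_coupling(vals, side$kind)
}

#' Serialize and restore edge lists
#'
#' Tab-separated columns: protein_id, edge_type, i, j, coupling_value
#' (0-based indices, i < j; coupling_value is NA for contact/backbone
#' edges).
#'
#' @param edge_set A `dyn_edge_set`.
#' @param path Output TSV path.
#' @param protein_id Identifier written in the first column.
#' @param append Append to an existing file without a header (default
#'   FALSE).
#' @return `path`, invisibly (writer); a named list of `dyn_edge_set` per
#'   protein/edge type (reader) with attribute `n` taken from the `n`
#'   argument.
#' @export
write_edges <- function(edge_set, path, protein_id = "protein", append = FALSE) {
  if (!inherits(edge_set, "dyn_edge_set")) stop("expected a 'dyn_edge_set'")
  cv <- edge_set$coupling_values
  if (is.null(cv)) cv <- rep(NA_real_, n_edges(edge_set))
  df <- data.frame(protein_id = protein_id, edge_type = edge_set$edge_type,
                   i = edge_set$edges[, 1L], j = edge_set$edges[, 2L],
                   coupling_value = format(cv, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !append, append = append)
  invisible(path)
}

#' @rdname write_edges
#' @param n Node count for the restored edge sets.
#' @export
read_edges <- function(path, n) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- lapply(split(df, list(df$protein_id, df$edge_type), drop = TRUE),
                function(g) {
    es <- new_edge_set(cbind(g$i, g$j), g$edge_type[1L], n,
                       coupling_values = suppressWarnings(as.numeric(g$coupling_value)))
    es
  })
  out
}

#' Serialize a centrality profile
#'
#' Tab-separated columns: residue_index (0-based), residue_id (author
#' numbering), amino_acid, centrality. An optional annotation track
#' (TSV with columns residue_id, annotation_label) is merged for
#' side-by-side reporting.
#'
#' @param profile A `dyn_centrality`.
#' @param structure The matching [dyn_structure()].
#' @param path Output TSV path.
#' @param annotations Optional data frame or TSV path with columns
#'   `residue_id`, `annotation_label`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, structure, path, annotations = NULL) {
  stopifnot_structure(structure)
  n <- n_residues(structure)
  if (length(profile$values) != n) stop("profile / structure length mismatch")
  df <- data.frame(residue_index = seq_len(n) - 1L,
                   residue_id = structure$residue_ids,
                   amino_acid = structure$sequence,
                   centrality = format(profile$values, digits = 17, trim = TRUE))
  if (!is.null(annotations)) {
    if (is.character(annotations)) {
      annotations <- utils::read.table(annotations, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)
    }
    df$annotation <- annotations$annotation_label[
      match(df$residue_id, annotations$residue_id)]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load per-residue node features from a numeric text matrix
#'
#' Accepts a whitespace- or tab-delimited numeric matrix with one row per
#' residue. Precomputed language-model embeddings commonly arrive with two
#' flanking rows for start/end tokens; a matrix with n + 2 rows is accepted
#' and the first and last rows are discarded.
#'
#' @param path Path to the matrix file.
#' @param n Expected number of residues.
#' @return n x F numeric matrix.
#' @export
read_node_features <- function(path, n) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) == n + 2L) {
    m <- m[2:(n + 1L), , drop = FALSE]
  } else if (nrow(m) != n) {
    stop("node-feature matrix has ", nrow(m), " rows; expected ", n,
         " or ", n + 2L)
  }
  storage.mode(m) <- "double"
  m
}

#' Save / load a trained model checkpoint as JSON
#'
#' A single text file embedding the configuration, the released weights,
#' batch-normalization statistics, and the label scaler.
#'
#' @param cv_or_model A `dyn_model_cv` (its released model is saved) or a
#'   released-model list.
#' @param config The `dyn_model_config` (taken from a `dyn_model_cv`
#'   automatically).
#' @param path Checkpoint path.
#' @return `path` invisibly (writer); list with `model` and `config`
#'   (reader).
#' @export
save_checkpoint <- function(cv_or_model, path, config = NULL) {
  if (inherits(cv_or_model, "dyn_model_cv")) {
    model <- cv_or_model$released
    config <- cv_or_model$config
  } else {
    model <- cv_or_model
    if (is.null(config)) stop("'config' required when saving a bare model")
  }
  ser <- list(config = unclass(config),
              scaler = unclass(model$scaler),
              bn_run = model$bn_run,
              params = serialize_params(model$params))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  # no vector simplification: the parameter tree mixes scalars, vectors and
  # matrices, and jsonlite's columnar simplification would mangle it
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg_fields <- lapply(ser$config[c(
    "extractor", "dimensions", "graph_feature_width", "ogt_widths",
    "activation_slope", "lr", "weight_decay", "betas", "epochs",
    "batch_size", "folds", "seed")], unlist)
  config <- do.call(model_config, cfg_fields)
  model <- list(params = deserialize_params(ser$params),
                bn_run = lapply(ser$bn_run, function(r)
                  list(mean = as.numeric(unlist(r$mean)),
                       var = as.numeric(unlist(r$var)))),
                scaler = structure(lapply(ser$scaler, unlist),
                                   class = "dyn_label_scaler"))
  list(model = model, config = config)
}

serialize_params <- function(p) {
  if (is.list(p)) {
    lapply(p, serialize_params)
  } else if (is.matrix(p)) {
    list(.dim = dim(p), .data = as.numeric(p))
  } else {
    list(.dim = integer(0), .data = as.numeric(p))
  }
}

deserialize_params <- function(p) {
  if (is.list(p) && ".data" %in% names(p)) {
    d <- as.numeric(unlist(p$.data))
    dm <- as.integer(unlist(p$.dim))
    if (length(dm) == 2L) matrix(d, dm[1L], dm[2L]) else d
  } else {
    lapply(p, deserialize_params)
  }
}

#' Write a dataset manifest
#'
#' Tab-separated columns protein_id, ogt, tm for a list of multigraph
#' samples.
#'
#' @param samples List of `dyn_multigraph`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(samples, path) {
  df <- data.frame(
    protein_id = vapply(samples, function(s) s$protein_id, character(1L)),
    ogt = vapply(samples, function(s) s$ogt, numeric(1L)),
    tm = vapply(samples, function(s)
      if (is.null(s$label_tm)) NA_real_ else s$label_tm, numeric(1L)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
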
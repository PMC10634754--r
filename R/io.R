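## Delimited-text I/O for connectivity matrices, radius tables and
## embeddings, plus JSON (de)serialization of graphs and models.

#' Read a connectivity matrix from CSV
#'
#' Expects a square numeric CSV whose header row carries ROI names.
#' Symmetry and the `[0, 1]` value range are validated; the diagonal is
#' zeroed by convention.
#'
#' @param path CSV file.
#' @return Symmetric numeric matrix with ROI dimnames.
#' @export
readConnectivityMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M)) stop("connectivity matrix must be square, got ",
                               nrow(M), "x", ncol(M))
  rownames(M) <- colnames(M)
  if (max(abs(M - t(M))) > 1e-8) stop("connectivity matrix is not symmetric")
  diag(M) <- 0
  if (any(M < 0 | M > 1)) stop("PLV values must lie in [0, 1]")
  M
}

#' Write a connectivity matrix to CSV
#'
#' @param M Symmetric matrix (ROI names taken from `colnames`).
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
writeConnectivityMatrix <- function(M, path) {
  if (is.null(colnames(M))) colnames(M) <- paste0("roi", seq_len(ncol(M)))
  utils::write.csv(as.data.frame(M), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a BrainGraph to a JSON file
#'
#' Stores the PLV matrix, adjacency, edge probabilities, node metadata and
#' annotations in one self-contained JSON document.
#'
#' @param g A [BrainGraph-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeBrainGraph <- function(g, path) {
  obj <- list(subjectId = subjectId(g), session = session(g),
              group = groupLabel(g), nodeMeta = nodeMeta(g),
              plv = plvMatrix(g), adjacency = adjacency(g),
              edgeProb = edgeProb(g))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null", dataframe = "columns")
  invisible(path)
}

#' Read a BrainGraph from JSON
#'
#' @param path File written by [writeBrainGraph()].
#' @return A [BrainGraph-class].
#' @export
readBrainGraph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- as.data.frame(obj$nodeMeta)
  for (col in c("roi", "hemisphere", "subnetwork"))
    if (is.null(nm[[col]])) nm[[col]] <- NA_character_
  nm[] <- lapply(nm, as.character)
  methods::new("BrainGraph", adjacency = as.matrix(obj$adjacency),
               edgeProb = as.matrix(obj$edgeProb), plv = as.matrix(obj$plv),
               nodeMeta = nm,
               subjectId = obj$subjectId, session = obj$session,
               group = if (is.null(obj$group) || is.na(obj$group))
                 NA_character_ else obj$group)
}

#' Save / load a trained model
#'
#' Model parameters are stored as a JSON document (weights, biases, raw
#' curvature parameters, dimensions, mode, seed) so checkpoints remain
#' plain text.
#'
#' @param model A [GraphEmbeddingModel-class].
#' @param path Output file.
#' @return `path` (write) or the model (read).
#' @export
writeModel <- function(model, path) {
  obj <- list(type = model@type, W1 = model@W1, b1 = model@b1,
              W2 = model@W2, b2 = model@b2, c1raw = model@c1raw,
              c2raw = model@c2raw, curvatureMode = model@curvatureMode,
              D = model@D, lossTrace = model@lossTrace, seed = model@seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("GraphEmbeddingModel", type = o$type, W1 = as.matrix(o$W1),
               b1 = as.numeric(o$b1), W2 = as.matrix(o$W2),
               b2 = as.numeric(o$b2), c1raw = o$c1raw, c2raw = o$c2raw,
               curvatureMode = o$curvatureMode, D = as.integer(o$D),
               lossTrace = as.numeric(o$lossTrace), seed = as.integer(o$seed))
}
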
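## PLV connectivity and graph construction.
##
## Source phases are represented as a list with one element per ROI, each a
## 3-d array [source, epoch, time] of instantaneous phases in radians. The
## per-epoch PLV between two ROIs averages |mean_t exp(-i(phiA - phiB))| over
## all source pairs; epochs are combined by averaging the per-epoch PLVs
## (optionally by pooling all epochs into one window).

#' Bundle per-region instantaneous phase arrays
#'
#' @param phases List with one element per region; each element a numeric
#'   array of dimension `c(nSources, nEpochs, T)` of phases in radians.
#'   A matrix is interpreted as a single source (`nEpochs x T`); a vector as
#'   a single source and single epoch.
#' @return Validated list of 3-d arrays (class `"SourcePhases"`).
#' @export
sourcePhases <- function(phases) {
  stopifnot(is.list(phases), length(phases) >= 1L)
  out <- lapply(phases, function(p) {
    if (is.vector(p)) p <- array(p, dim = c(1L, 1L, length(p)))
    else if (is.matrix(p)) p <- array(p, dim = c(1L, nrow(p), ncol(p)))
    if (length(dim(p)) != 3L) stop("each region needs a [source, epoch, time] array")
    if (!all(is.finite(p))) stop("phases must be finite")
    if (dim(p)[3] < 2L) stop("need at least T = 2 samples per epoch")
    p
  })
  Ts <- vapply(out, function(p) dim(p)[3], integer(1))
  Es <- vapply(out, function(p) dim(p)[2], integer(1))
  if (length(unique(Ts)) != 1L) stop("mismatched T across regions: ",
                                     paste(unique(Ts), collapse = ", "))
  if (length(unique(Es)) != 1L) stop("mismatched epoch counts across regions")
  structure(out, class = "SourcePhases")
}

#' Phase locking value between two regions
#'
#' Averages the source-pairwise phase locking value over all source pairs of
#' the two regions: for sources \eqn{p, q}, \eqn{|T^{-1}\sum_t
#' e^{-j(\phi_{A_p}(t) - \phi_{B_q}(t))}|}, then the mean over the
#' \eqn{N_A N_B} pairs. Each epoch is evaluated separately and the per-epoch
#' values averaged (`pooled = TRUE` instead concatenates all epochs into one
#' window).
#'
#' @param phases A `SourcePhases` object (see [sourcePhases()]).
#' @param regionA,regionB Region indices.
#' @param pooled Combine epochs by pooling samples rather than averaging
#'   per-epoch PLVs (default `FALSE`).
#' @return PLV in `[0, 1]`.
#' @export
computePLV <- function(phases, regionA, regionB, pooled = FALSE) {
  if (!inherits(phases, "SourcePhases")) phases <- sourcePhases(phases)
  A <- phases[[regionA]]; B <- phases[[regionB]]
  nE <- dim(A)[2]; Tlen <- dim(A)[3]
  pairPLV <- function(MA, MB) {
    ## MA: nA x T phases, MB: nB x T; returns mean over pairs of |mean_t ...|
    ZA <- exp(-1i * MA); ZB <- exp(1i * MB)
    cross <- (ZA %*% t(ZB)) / ncol(MA)
    mean(Mod(cross))
  }
  if (pooled) {
    MA <- matrix(aperm(A, c(1, 3, 2)), nrow = dim(A)[1])
    MB <- matrix(aperm(B, c(1, 3, 2)), nrow = dim(B)[1])
    return(min(pairPLV(MA, MB), 1))
  }
  v <- vapply(seq_len(nE), function(e)
    pairPLV(matrix(A[, e, ], nrow = dim(A)[1], ncol = Tlen),
            matrix(B[, e, ], nrow = dim(B)[1], ncol = Tlen)), numeric(1))
  min(mean(v), 1)
}

#' ROI-by-ROI PLV connectivity matrix
#'
#' Applies [computePLV()] to every region pair; the diagonal is set to zero
#' by convention.
#'
#' @inheritParams computePLV
#' @return Symmetric `R x R` matrix of PLVs with zero diagonal.
#' @export
roiPLVMatrix <- function(phases, pooled = FALSE) {
  if (!inherits(phases, "SourcePhases")) phases <- sourcePhases(phases)
  R <- length(phases)
  if (R < 2L) stop("need at least two regions")
  M <- matrix(0, R, R)
  for (a in seq_len(R - 1L)) for (b in seq.int(a + 1L, R)) {
    M[a, b] <- M[b, a] <- computePLV(phases, a, b, pooled = pooled)
  }
  dimnames(M) <- list(names(phases), names(phases))
  M
}

#' Binarize a connectivity matrix
#'
#' Keeps edges whose connectivity strictly exceeds a threshold. Either an
#' absolute `threshold` (the study default for alpha-band PLV being 0.329,
#' which retains roughly 20% of edges) or a `targetDensity`, in which case
#' the threshold is the `(1 - density)` quantile of the off-diagonal
#' upper-triangle values.
#'
#' @param plv Symmetric connectivity matrix.
#' @param threshold Absolute threshold (exclusive with `targetDensity`).
#' @param targetDensity Desired edge density in `(0, 1)`.
#' @return Binary symmetric adjacency matrix with zero diagonal.
#' @export
binarize <- function(plv, threshold = NULL, targetDensity = NULL) {
  if (is.null(threshold) == is.null(targetDensity))
    stop("give exactly one of threshold or targetDensity")
  ut <- plv[upper.tri(plv)]
  if (!is.null(targetDensity)) {
    if (targetDensity <= 0 || targetDensity >= 1)
      stop("targetDensity must lie in (0, 1), got ", targetDensity)
    threshold <- stats::quantile(ut, 1 - targetDensity, names = FALSE, type = 7)
  }
  A <- (plv > threshold) * 1
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  attr(A, "threshold") <- threshold
  A
}

#' Min-max scale connectivity values to link probabilities
#'
#' Rescales off-diagonal connectivity values to `[0, 1]` by
#' `(x - min)/(max - min)`, producing the continuous link-probability targets
#' of the weighted decoder loss. The diagonal stays zero.
#'
#' @param plv Symmetric connectivity matrix.
#' @param scope `"per_graph"` (scale within this matrix, the default) or a
#'   numeric `c(min, max)` pair to apply a global scaling computed elsewhere.
#' @return Symmetric matrix spanning `[0, 1]` off-diagonally.
#' @export
scaleProbabilities <- function(plv, scope = "per_graph") {
  ut <- plv[upper.tri(plv)]
  if (is.numeric(scope) && length(scope) == 2L) {
    lo <- scope[1]; hi <- scope[2]
  } else {
    lo <- min(ut); hi <- max(ut)
  }
  if (hi - lo <= 0)
    stop("connectivity matrix is constant off-diagonal; cannot min-max scale")
  P <- (plv - lo) / (hi - lo)
  P <- pmin(pmax(P, 0), 1)
  diag(P) <- 0
  P
}

#' Load and validate an ROI-to-subnetwork assignment table
#'
#' Reads a CSV with columns `roi`, `hemisphere`, `subnetwork` and validates
#' it: every expected ROI exactly once, labels restricted to the eight
#' functional subnetworks (pDMN, aDMN, DAN, FPN, VN, VAN, SN, SMN).
#'
#' The table shipped with the package
#' (`system.file("extdata", "aal90_subnetworks_default.csv", package =
#' "hyperMEG")`) is an approximate, literature-based default assignment of
#' the 90 AAL atlas regions and is intended to be replaced by a
#' study-specific table when one is available.
#'
#' @param path CSV file path (default: the shipped table).
#' @param rois Optional character vector of expected ROI names; defaults to
#'   the ROI names in the table itself (uniqueness is still checked).
#' @return `data.frame` with columns `roi`, `hemisphere`, `subnetwork`.
#' @export
loadSubnetworkMap <- function(path = NULL, rois = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aal90_subnetworks_default.csv",
                        package = "hyperMEG")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi", "hemisphere", "subnetwork")
  if (!all(need %in% names(tab)))
    stop("subnetwork map must have columns ", paste(need, collapse = ", "))
  dup <- tab$roi[duplicated(tab$roi)]
  if (length(dup)) stop("duplicate ROI(s) in subnetwork map: ",
                        paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(tab$subnetwork), .SUBNETWORKS)
  if (length(bad)) stop("unknown subnetwork label(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(rois)) {
    missing <- setdiff(rois, tab$roi)
    extra <- setdiff(tab$roi, rois)
    if (length(missing)) stop("subnetwork map missing ROI(s): ",
                              paste(missing, collapse = ", "))
    if (length(extra)) stop("subnetwork map has unexpected ROI(s): ",
                            paste(extra, collapse = ", "))
    tab <- tab[match(rois, tab$roi), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab[need]
}

#' Construct a BrainGraph from a connectivity matrix
#'
#' Thresholds the PLV matrix into a binary adjacency (absolute threshold
#' 0.329 by default, or a target density), min-max scales the PLVs into
#' edge-probability targets, and attaches node metadata.
#'
#' @param plv Symmetric connectivity matrix in `[0, 1]`.
#' @param threshold,targetDensity Passed to [binarize()] (exactly one).
#' @param nodeMeta Optional `data.frame` with `roi`, `hemisphere`,
#'   `subnetwork`; defaults to unlabeled nodes.
#' @param subjectId,session,group Annotations (session `"pre"`/`"post"`).
#' @param scaleScope Passed to [scaleProbabilities()].
#' @return A [BrainGraph-class] object.
#' @export
brainGraph <- function(plv, threshold = 0.329, targetDensity = NULL,
                       nodeMeta = NULL, subjectId = "s1", session = "pre",
                       group = NA_character_, scaleScope = "per_graph") {
  if (!is.null(targetDensity)) threshold <- NULL
  plv <- as.matrix(plv)
  diag(plv) <- 0
  R <- nrow(plv)
  A <- binarize(plv, threshold = threshold, targetDensity = targetDensity)
  attr(A, "threshold") <- NULL
  P <- scaleProbabilities(plv, scope = scaleScope)
  if (is.null(nodeMeta))
    nodeMeta <- data.frame(roi = paste0("roi", seq_len(R)),
                           hemisphere = NA_character_,
                           subnetwork = NA_character_,
                           stringsAsFactors = FALSE)
  methods::new("BrainGraph", adjacency = unname(A), edgeProb = unname(P),
               plv = unname(plv), nodeMeta = nodeMeta, subjectId = subjectId,
               session = session, group = group)
}

## BrainGraph straight from a binary adjacency (edgeProb = plv = adjacency),
## used for synthetic trees and unit fixtures.
.graphFromAdjacency <- function(A, nodeMeta = NULL, subjectId = "s1",
                                session = "pre", group = NA_character_) {
  A <- unname(as.matrix(A)); diag(A) <- 0
  R <- nrow(A)
  if (is.null(nodeMeta))
    nodeMeta <- data.frame(roi = paste0("n", seq_len(R)),
                           hemisphere = NA_character_,
                           subnetwork = NA_character_, stringsAsFactors = FALSE)
  methods::new("BrainGraph", adjacency = A, edgeProb = A, plv = A,
               nodeMeta = nodeMeta, subjectId = subjectId, session = session,
               group = group)
}
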
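#' @import methods
NULL

.SUBNETWORKS <- c("pDMN", "aDMN", "DAN", "FPN", "VN", "VAN", "SN", "SMN")

#' BrainGraph: a thresholded functional connectivity network
#'
#' One participant/session network: the symmetric PLV connectivity matrix,
#' its binarized adjacency, the min-max scaled edge-probability matrix used
#' as the regression target of the link decoder, and per-node metadata
#' (region name, hemisphere, functional subnetwork).
#'
#' @slot adjacency Binary symmetric matrix, zero diagonal.
#' @slot edgeProb Symmetric matrix in `[0, 1]`, zero diagonal; min-max scaled
#'   connectivity used as continuous link-probability targets.
#' @slot plv Symmetric matrix in `[0, 1]`; raw phase-locking values (zero
#'   diagonal by convention).
#' @slot nodeMeta `data.frame` with columns `roi`, `hemisphere`,
#'   `subnetwork` (one of pDMN, aDMN, DAN, FPN, VN, VAN, SN, SMN, or `NA`).
#' @slot subjectId,session,group Character scalars; `session` is `"pre"` or
#'   `"post"`, `group` typically `"HC"`/`"SCD"` (or `NA`).
#' @export
setClass("BrainGraph",
  representation(adjacency = "matrix", edgeProb = "matrix", plv = "matrix",
                 nodeMeta = "data.frame", subjectId = "character",
                 session = "character", group = "character"))

setValidity("BrainGraph", function(object) {
  A <- object@adjacency; P <- object@edgeProb; V <- object@plv
  msgs <- character(0)
  R <- nrow(A)
  for (nm in c("adjacency", "edgeProb", "plv")) {
    M <- slot(object, nm)
    if (nrow(M) != R || ncol(M) != R)
      msgs <- c(msgs, paste0(nm, " must be ", R, "x", R))
    else {
      if (max(abs(M - t(M))) > 1e-10) msgs <- c(msgs, paste0(nm, " not symmetric"))
      if (any(diag(M) != 0)) msgs <- c(msgs, paste0(nm, " has nonzero diagonal"))
    }
  }
  if (!all(A %in% c(0, 1))) msgs <- c(msgs, "adjacency must be binary")
  if (any(P < 0 | P > 1)) msgs <- c(msgs, "edgeProb must lie in [0, 1]")
  if (any(V < 0 | V > 1)) msgs <- c(msgs, "plv must lie in [0, 1]")
  if (nrow(object@nodeMeta) != R)
    msgs <- c(msgs, "nodeMeta must have one row per node")
  if (!all(c("roi", "hemisphere", "subnetwork") %in% names(object@nodeMeta)))
    msgs <- c(msgs, "nodeMeta needs columns roi, hemisphere, subnetwork")
  else {
    sn <- object@nodeMeta$subnetwork
    if (!all(is.na(sn) | sn %in% .SUBNETWORKS))
      msgs <- c(msgs, "unknown subnetwork label in nodeMeta")
  }
  if (length(msgs)) msgs else TRUE
})

#' GraphEmbeddingModel: trained graph-convolution parameters
#'
#' Parameters of the two-layer hyperbolic (or Euclidean) graph convolutional
#' network: feature-transform weights and biases per layer, raw curvature
#' parameters (curvature is `-softplus(raw)` so it stays negative), the
#' model family and curvature mode, and the training loss trace.
#'
#' @slot type `"hgcn"` or `"gcn"`.
#' @slot W1,b1,W2,b2 Layer weights (input x output orientation) and biases.
#' @slot c1raw,c2raw Raw curvature parameters; `K = -softplus(raw)`.
#' @slot curvatureMode `"fixed"` (all K = -1) or `"learned"`.
#' @slot D Output embedding dimension.
#' @slot lossTrace Per-epoch mean training loss.
#' @slot seed Integer seed the parameters were initialized/trained with.
#' @export
setClass("GraphEmbeddingModel",
  representation(type = "character", W1 = "matrix", b1 = "numeric",
                 W2 = "matrix", b2 = "numeric", c1raw = "numeric",
                 c2raw = "numeric", curvatureMode = "character",
                 D = "integer", lossTrace = "numeric", seed = "integer"))

setValidity("GraphEmbeddingModel", function(object) {
  msgs <- character(0)
  if (!object@type %in% c("hgcn", "gcn")) msgs <- c(msgs, "type must be hgcn or gcn")
  if (!object@curvatureMode %in% c("fixed", "learned"))
    msgs <- c(msgs, "curvatureMode must be fixed or learned")
  if (ncol(object@W1) != length(object@b1)) msgs <- c(msgs, "W1/b1 dims differ")
  if (ncol(object@W2) != length(object@b2)) msgs <- c(msgs, "W2/b2 dims differ")
  if (nrow(object@W2) != ncol(object@W1)) msgs <- c(msgs, "W1/W2 dims differ")
  if (length(msgs)) msgs else TRUE
})

#' EmbeddingResult: node embeddings of one network
#'
#' Output coordinates of every node on the Poincare ball (or in Euclidean
#' space for the GCN baseline), the final curvature, and the per-node
#' hyperbolic radius (geodesic distance from the ball center), which proxies
#' the node's position in the network hierarchy (smaller radius = higher
#' hierarchy).
#'
#' @slot coords Numeric matrix, one node per row.
#' @slot K Final curvature (negative; `NA` for Euclidean embeddings).
#' @slot radii Per-node radius (geodesic distance from the origin).
#' @slot subjectId,session,model Character annotations.
#' @export
setClass("EmbeddingResult",
  representation(coords = "matrix", K = "numeric", radii = "numeric",
                 subjectId = "character", session = "character",
                 model = "character"))

setValidity("EmbeddingResult", function(object) {
  msgs <- character(0)
  if (length(object@radii) != nrow(object@coords))
    msgs <- c(msgs, "radii length must match number of nodes")
  if (!is.na(object@K) && object@K >= 0) msgs <- c(msgs, "K must be negative or NA")
  if (!is.na(object@K)) {
    lim <- 1 / sqrt(-object@K)
    if (any(sqrt(rowSums(object@coords^2)) >= lim))
      msgs <- c(msgs, "coordinates must lie strictly inside the ball")
  }
  if (length(msgs)) msgs else TRUE
})

## ---- generics & accessors ----

#' @describeIn BrainGraph-accessors Binary adjacency matrix.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @describeIn BrainGraph-accessors Edge-probability (scaled PLV) matrix.
#' @export
setGeneric("edgeProb", function(x) standardGeneric("edgeProb"))
#' @describeIn BrainGraph-accessors Raw PLV connectivity matrix.
#' @export
setGeneric("plvMatrix", function(x) standardGeneric("plvMatrix"))
#' @describeIn BrainGraph-accessors Per-node metadata table.
#' @export
setGeneric("nodeMeta", function(x) standardGeneric("nodeMeta"))
#' @describeIn BrainGraph-accessors Subject identifier.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @describeIn BrainGraph-accessors Session label (`"pre"`/`"post"`).
#' @export
setGeneric("session", function(x) standardGeneric("session"))
#' @describeIn BrainGraph-accessors Group label (e.g. `"HC"`/`"SCD"`).
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @describeIn EmbeddingResult-accessors Embedding coordinates.
#' @export
setGeneric("embCoords", function(x) standardGeneric("embCoords"))
#' @describeIn EmbeddingResult-accessors Per-node hyperbolic radius.
#' @export
setGeneric("nodeRadius", function(x) standardGeneric("nodeRadius"))
#' @describeIn GraphEmbeddingModel-accessors Layer curvatures `c(K1, K2)`.
#' @export
setGeneric("curvatures", function(x) standardGeneric("curvatures"))

#' Accessors for BrainGraph objects
#'
#' @param x A [BrainGraph-class] object.
#' @return The corresponding slot content.
#' @name BrainGraph-accessors
NULL

#' @rdname BrainGraph-accessors
#' @export
setMethod("adjacency", "BrainGraph", function(x) x@adjacency)
#' @rdname BrainGraph-accessors
#' @export
setMethod("edgeProb", "BrainGraph", function(x) x@edgeProb)
#' @rdname BrainGraph-accessors
#' @export
setMethod("plvMatrix", "BrainGraph", function(x) x@plv)
#' @rdname BrainGraph-accessors
#' @export
setMethod("nodeMeta", "BrainGraph", function(x) x@nodeMeta)
#' @rdname BrainGraph-accessors
#' @export
setMethod("subjectId", "BrainGraph", function(x) x@subjectId)
#' @rdname BrainGraph-accessors
#' @export
setMethod("session", "BrainGraph", function(x) x@session)
#' @rdname BrainGraph-accessors
#' @export
setMethod("groupLabel", "BrainGraph", function(x) x@group)

#' Accessors for EmbeddingResult objects
#'
#' @param x An [EmbeddingResult-class] object.
#' @return Coordinates matrix or radius vector.
#' @name EmbeddingResult-accessors
NULL

#' @rdname EmbeddingResult-accessors
#' @export
setMethod("embCoords", "EmbeddingResult", function(x) x@coords)

#' @rdname EmbeddingResult-accessors
#' @export
setMethod("subjectId", "EmbeddingResult", function(x) x@subjectId)
#' @rdname EmbeddingResult-accessors
#' @export
setMethod("session", "EmbeddingResult", function(x) x@session)

#' Accessors for GraphEmbeddingModel objects
#'
#' @param x A [GraphEmbeddingModel-class] object.
#' @return For `curvatures`, the vector `c(K1, K2)` (hidden and output layer
#'   curvature, both negative; `NA` for the Euclidean GCN).
#' @name GraphEmbeddingModel-accessors
NULL

#' @rdname GraphEmbeddingModel-accessors
#' @export
setMethod("curvatures", "GraphEmbeddingModel", function(x) {
  if (x@type == "gcn") return(c(K1 = NA_real_, K2 = NA_real_))
  c(K1 = -.softplus(x@c1raw), K2 = -.softplus(x@c2raw))
})

setMethod("show", "BrainGraph", function(object) {
  cat("BrainGraph:", nrow(object@adjacency), "nodes,",
      sum(object@adjacency) / 2, "edges\n")
  cat("  subject:", object@subjectId, " session:", object@session,
      " group:", object@group, "\n")
  sn <- object@nodeMeta$subnetwork
  if (any(!is.na(sn)))
    cat("  subnetworks:", paste(names(table(sn)), collapse = ", "), "\n")
})

setMethod("show", "GraphEmbeddingModel", function(object) {
  cat(sprintf("GraphEmbeddingModel <%s> %dx%d -> %d (curvature %s)\n",
              object@type, nrow(object@W1), ncol(object@W1), object@D,
              object@curvatureMode))
  if (length(object@lossTrace))
    cat(sprintf("  trained %d epochs; final loss %.5f\n",
                length(object@lossTrace), utils::tail(object@lossTrace, 1)))
  if (object@type == "hgcn") {
    k <- curvatures(object)
    cat(sprintf("  K1 = %.3f, K2 = %.3f\n", k[1], k[2]))
  }
})

setMethod("show", "EmbeddingResult", function(object) {
  cat(sprintf("EmbeddingResult <%s>: %d nodes in %dD, K = %s\n",
              object@model, nrow(object@coords), ncol(object@coords),
              format(object@K, digits = 3)))
  cat(sprintf("  radius range [%.3f, %.3f]\n",
              min(object@radii), max(object@radii)))
})

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
.softplusInv <- function(y) log(expm1(y))
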
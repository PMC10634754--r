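## Embedding models: two-layer HGCN with Frechet aggregation, the flat
## (Euclidean) GCN baseline with identical architecture, and the shallow
## Poincare embedding baseline.

#' Fermi-Dirac link decoder
#'
#' Converts a squared embedding distance into a link probability,
#' \eqn{p = 1/(e^{(d^2 - r)/t} + 1)}: a sigmoid in squared distance with
#' inflection point `r` and steepness `t`. Defaults `r = 2`, `t = 1`.
#'
#' @param dSq Squared distance(s), non-negative.
#' @param r Inflection offset (default 2).
#' @param t Temperature, strictly positive (default 1).
#' @return Probabilities in `(0, 1)`, strictly decreasing in `dSq`.
#' @examples
#' fermiDirac(2)   # 0.5 at the inflection point
#' @export
fermiDirac <- function(dSq, r = 2, t = 1) {
  if (t <= 0) stop("Fermi-Dirac temperature t must be > 0, got ", t)
  if (any(!is.finite(dSq))) stop("dSq must be finite")
  1 / (exp((dSq - r) / t) + 1)
}

#' One hyperbolic graph convolution layer
#'
#' Reference (non-differentiable-path) implementation composing the public
#' geometry operations: feature transform
#' \eqn{h_i = (W \otimes_{K_{prev}} x_i) \oplus_{K_{prev}} b_{pt}} with the
#' bias lifted by [expMap0()], Frechet-mean aggregation over the closed
#' neighborhood \eqn{\{N(i), i\}}, then the hyperbolic activation into
#' `KNext`. Isolated nodes aggregate over themselves alone.
#'
#' @param x Matrix of ball points (nodes in rows) at curvature `KPrev`.
#' @param adjacency Binary symmetric adjacency matrix.
#' @param W Weight matrix, `dout x din` (applied as `W x`).
#' @param b Euclidean bias vector of length `dout`.
#' @param KPrev,KNext Input/output curvatures (negative).
#' @param sigma Elementwise activation (default ReLU).
#' @return Matrix of ball points at curvature `KNext`.
#' @export
hgcnLayer <- function(x, adjacency, W, b, KPrev, KNext,
                      sigma = function(z) pmax(z, 0)) {
  R <- nrow(x)
  if (nrow(adjacency) != R) stop("adjacency and x disagree on node count")
  bPt <- expMap0(b, KPrev)
  h <- t(vapply(seq_len(R), function(i)
    mobiusAdd(mobiusMatvec(W, x[i, ], KPrev), bPt, KPrev), numeric(nrow(W))))
  out <- matrix(0, R, nrow(W))
  for (i in seq_len(R)) {
    nb <- c(which(adjacency[i, ] != 0), i)
    y <- frechetMean(h[nb, , drop = FALSE], K = KPrev)
    out[i, ] <- hypActivation(as.numeric(y), KPrev, KNext, sigma)
  }
  out
}

## ---- parameter containers / initialization ----

.initModel <- function(type = c("hgcn", "gcn"), R, hidden = 6L, D = 2L,
                       curvatureMode = c("learned", "fixed"), seed = 1L) {
  type <- match.arg(type); curvatureMode <- match.arg(curvatureMode)
  set.seed(seed)
  glorot <- function(nin, nout)
    matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
  methods::new("GraphEmbeddingModel", type = type,
               W1 = glorot(R, hidden), b1 = rep(0, hidden),
               W2 = glorot(hidden, D), b2 = rep(0, D),
               c1raw = .softplusInv(1), c2raw = .softplusInv(1),
               curvatureMode = curvatureMode, D = as.integer(D),
               lossTrace = numeric(0), seed = as.integer(seed))
}

## edge bookkeeping shared by both forward passes: closed-neighborhood edge
## list (self loops included) and pair indices for the dense decoder loss
.graphStructure <- function(A) {
  R <- nrow(A)
  idx <- which(A != 0, arr.ind = TRUE)      # both directions
  src <- c(idx[, 1], seq_len(R))
  dst <- c(idx[, 2], seq_len(R))
  o <- order(src, dst)
  src <- src[o]; dst <- dst[o]
  counts <- tabulate(src, nbins = R)
  pairs <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  list(R = R, src = src, dst = dst, invCount = 1 / counts,
       pi = pairs[, 1], pj = pairs[, 2])
}

## push current parameter values onto a tape; returns ids
.pushParams <- function(tp, model) {
  list(W1 = adPush(tp, model@W1), b1 = adPush(tp, matrix(model@b1, 1L)),
       W2 = adPush(tp, model@W2), b2 = adPush(tp, matrix(model@b2, 1L)),
       c1 = adPush(tp, model@c1raw), c2 = adPush(tp, model@c2raw))
}

## HGCN forward on a tape. Returns list(out = coords node id, cS2, sqrtC2).
## Hidden layer lives at curvature K1, the output layer at K2; the one-hot
## inputs are lifted into the K1 ball through the origin exponential map.
.hgcnTapeForward <- function(tp, ids, gs, model, aggIter = 15L,
                             features = NULL) {
  fixed <- model@curvatureMode == "fixed"
  cS1 <- if (fixed) adConst(tp, 1) else adSoftplus(tp, ids$c1)
  cS2 <- if (fixed) adConst(tp, 1) else adSoftplus(tp, ids$c2)
  sq1 <- adSqrt(tp, cS1); sq2 <- adSqrt(tp, cS2)
  X0 <- adConst(tp, features %||% diag(gs$R))
  Xb <- adExp0Rows(tp, X0, sq1)
  oneRep <- rep(1L, gs$R)
  layer <- function(X, W, b, sqIn, cIn, sqOut) {
    M <- adMobiusMatvecRows(tp, X, W, sqIn)
    B <- adRowsSel(tp, adExp0Rows(tp, b, sqIn), oneRep)
    H <- adMobiusAddRows(tp, M, B, cIn, sqIn)
    Y <- adFrechetAggRows(tp, H, gs$src, gs$dst, gs$invCount, cIn, sqIn,
                          iters = aggIter)
    V <- adRelu(tp, adLog0Rows(tp, Y, sqIn))
    adExp0Rows(tp, V, sqOut)
  }
  X1 <- layer(Xb, ids$W1, ids$b1, sq1, cS1, sq1)
  X2 <- layer(X1, ids$W2, ids$b2, sq1, cS1, sq2)
  list(out = X2, cS = cS2, sqrtC = sq2)
}

## Euclidean GCN forward: same composition with arithmetic-mean aggregation
.gcnTapeForward <- function(tp, ids, gs, model, features = NULL) {
  X0 <- adConst(tp, features %||% diag(gs$R))
  ic <- adConst(tp, gs$invCount)
  layerP <- function(X, W, bMat) {
    Wx <- adMatmul(tp, X, W)
    B <- adRowsSel(tp, bMat, rep(1L, gs$R))
    H <- adAdd(tp, Wx, B)
    S <- adScatterSum(tp, adRowsSel(tp, H, gs$dst), gs$src, gs$R)
    adRelu(tp, adScaleRows(tp, S, ic))
  }
  X1 <- layerP(X0, ids$W1, ids$b1)
  X2 <- layerP(X1, ids$W2, ids$b2)
  list(out = X2, cS = NULL, sqrtC = NULL)
}

## predicted link probabilities (tape node, length = #pairs i<j)
.tapePredict <- function(tp, fwd, gs, model, fdR = 2, fdT = 1) {
  if (model@type == "hgcn") {
    d2 <- adPairDist2(tp, fwd$out, gs$pi, gs$pj, fwd$cS, fwd$sqrtC)
  } else {
    U <- adRowsSel(tp, fwd$out, gs$pi)
    V <- adRowsSel(tp, fwd$out, gs$pj)
    d2 <- adRowNorm2(tp, adSub(tp, U, V))
  }
  adFermiDirac(tp, d2, r = fdR, t = fdT)
}

.tapeForward <- function(tp, ids, gs, model, aggIter = 15L) {
  if (model@type == "hgcn") {
    .hgcnTapeForward(tp, ids, gs, model, aggIter)
  } else {
    .gcnTapeForward(tp, ids, gs, model)
  }
}

#' Embed a network with a (trained) graph convolution model
#'
#' Runs the two-layer forward pass on the graph's adjacency with one-hot
#' identity input features and returns the node embeddings together with the
#' per-node hyperbolic radius (geodesic distance from the ball center; for
#' the Euclidean GCN, the Euclidean norm).
#'
#' @param model A [GraphEmbeddingModel-class].
#' @param graph A [BrainGraph-class] whose node count matches the model
#'   input dimension.
#' @param aggIter Karcher iterations used in the Frechet aggregation.
#' @return An [EmbeddingResult-class].
#' @export
embedGraph <- function(model, graph, aggIter = 15L) {
  A <- adjacency(graph)
  if (nrow(A) != nrow(model@W1))
    stop("graph has ", nrow(A), " nodes but model expects ", nrow(model@W1))
  gs <- .graphStructure(A)
  tp <- adTape()
  ids <- .pushParams(tp, model)
  fwd <- .tapeForward(tp, ids, gs, model)
  coords <- adValue(tp, fwd$out)
  if (model@type == "hgcn") {
    K2 <- unname(curvatures(model)[2])
    if (model@curvatureMode == "fixed") K2 <- -1
    radii <- apply(coords, 1L, function(p) hypDistance(p * 0, p, K2))
  } else {
    K2 <- NA_real_
    radii <- sqrt(rowSums(coords^2))
  }
  methods::new("EmbeddingResult", coords = coords, K = K2, radii = radii,
               subjectId = subjectId(graph), session = session(graph),
               model = paste0(model@type, "_", model@curvatureMode))
}

## ---- shallow Poincare embedding ----

#' Shallow Poincare embedding of a single graph
#'
#' Free per-node coordinates on the unit-curvature Poincare ball, optimized
#' by Riemannian gradient descent on a negative-sampling softmax loss over
#' geodesic distances: each observed edge competes against `nNegatives`
#' sampled non-neighbors. A burn-in phase with `lr/10` stabilizes the
#' initialization. Deterministic given `seed`.
#'
#' @param graph A [BrainGraph-class] (its binary adjacency is used), or a
#'   binary adjacency matrix.
#' @param D Embedding dimension (>= 2).
#' @param epochs Optimization epochs (default 150).
#' @param lr Learning rate (default 0.3); burn-in uses `lr/10` for the first
#'   10 epochs.
#' @param nNegatives Negative samples per edge (default 10).
#' @param seed RNG seed.
#' @return An [EmbeddingResult-class] with `K = -1`.
#' @export
shallowPoincare <- function(graph, D = 2L, epochs = 150L, lr = 0.3,
                            nNegatives = 10L, seed = 1L) {
  A <- if (methods::is(graph, "BrainGraph")) adjacency(graph) else as.matrix(graph)
  R <- nrow(A)
  eIdx <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
  edges <- rbind(eIdx, eIdx[, 2:1, drop = FALSE])   # both directions
  nE <- nrow(edges)
  if (nE == 0L) stop("graph has no edges")
  set.seed(seed)
  theta <- matrix(stats::runif(R * D, -1e-3, 1e-3), R, D)
  for (ep in seq_len(epochs)) {
    rate <- if (ep <= 10L) lr / 10 else lr
    negs <- matrix(sample.int(R, nE * nNegatives, replace = TRUE), nE)
    tp <- adTape()
    th <- adPush(tp, theta)
    src <- edges[, 1]
    cand <- cbind(edges[, 2], negs)                 # first column = true edge
    cS <- adConst(tp, 1); sqC <- adConst(tp, 1)
    iAll <- rep(src, ncol(cand))
    jAll <- as.vector(cand)
    d2 <- adPairDist2(tp, th, iAll, jAll, cS, sqC)
    d <- adSqrt(tp, d2, floor = 1e-18)
    ## softmax cross-entropy with the true edge as the positive class:
    ## loss_e = d(pos_e) + log sum_k exp(-d(cand_ek))
    expNeg <- adExp(tp, adNeg(tp, d))
    grp <- rep(seq_len(nE), ncol(cand))
    tot <- adDropVec(tp, adScatterSum(tp, adReshapeCol(tp, expNeg), grp, nE))
    dPos <- adIndexVec(tp, d, seq_len(nE))
    loss <- adMean(tp, adAdd(tp, dPos, adLog(tp, tot)))
    g <- adGrad(tp, loss)[[th]]
    ## Riemannian scaling for the Poincare ball (metric conformal factor)
    lam2 <- ((1 - pmin(rowSums(theta^2), 1 - 1e-10))^2) / 4
    theta <- theta - rate * (g * lam2)
    theta <- projectToBall(theta, K = -1)
  }
  radii <- apply(theta, 1L, function(p) hypDistance(p * 0, p, -1))
  methods::new("EmbeddingResult", coords = theta, K = -1, radii = radii,
               subjectId = if (methods::is(graph, "BrainGraph"))
                 subjectId(graph) else "s1",
               session = if (methods::is(graph, "BrainGraph"))
                 session(graph) else "pre",
               model = "shallow_poincare")
}
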
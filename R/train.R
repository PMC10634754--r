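## Training loop (Adam on Euclidean parameters, softplus-reparameterized
## curvatures) and the link-prediction evaluation harness.

#' Weighted link loss (mean squared error over node pairs)
#'
#' Mean over the off-diagonal upper-triangle pairs of the squared difference
#' between predicted and target link probabilities, the training objective
#' of the graph convolution models (targets are min-max scaled PLVs).
#'
#' @param pred,target Symmetric matrices of the same shape (or equal-length
#'   vectors of per-pair values).
#' @return Non-negative scalar.
#' @examples
#' weightedLinkLoss(matrix(0.5, 3, 3), matrix(0.4, 3, 3))  # 0.01
#' @export
weightedLinkLoss <- function(pred, target) {
  if (is.matrix(pred) != is.matrix(target) ||
      (is.matrix(pred) && !all(dim(pred) == dim(target))) ||
      (!is.matrix(pred) && length(pred) != length(target)))
    stop("pred and target must have identical shape")
  if (is.matrix(pred)) {
    ut <- upper.tri(pred)
    mean((pred[ut] - target[ut])^2)
  } else mean((pred - target)^2)
}

#' Training configuration
#'
#' Collects the optimizer settings used by [trainModel()]. The defaults
#' follow the study settings: 100 epochs, learning rate 0.02, batch size of
#' one graph, Adam, one-hot identity input features.
#'
#' @param epochs Number of epochs (>= 1).
#' @param lr Learning rate (> 0).
#' @param seed RNG seed for parameter initialization.
#' @param curvatureMode `"learned"` or `"fixed"` (all curvatures -1).
#' @param D Output embedding dimension.
#' @param hidden Hidden layer dimension (default 6).
#' @param aggIter Unrolled Karcher iterations in the Frechet aggregation.
#' @param fdR,fdT Fermi-Dirac decoder offset and temperature.
#' @param restarts Independent random restarts; the fit with the lowest
#'   final training loss is kept (default 1). Restart seeds are derived
#'   deterministically from `seed`.
#' @return A list of class `"trainConfig"`.
#' @export
trainConfig <- function(epochs = 100L, lr = 0.02, seed = 1L,
                        curvatureMode = c("learned", "fixed"), D = 2L,
                        hidden = 6L, aggIter = 15L, fdR = 2, fdT = 1,
                        restarts = 1L) {
  stopifnot(epochs >= 1, lr > 0, restarts >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr, seed = as.integer(seed),
                 curvatureMode = match.arg(curvatureMode), D = as.integer(D),
                 hidden = as.integer(hidden), aggIter = as.integer(aggIter),
                 fdR = fdR, fdT = fdT, restarts = as.integer(restarts)),
            class = "trainConfig")
}

## loss (tape) for one graph; returns list(tape, loss id, param ids)
.buildLossTape <- function(model, gs, target, aggIter, fdR, fdT) {
  tp <- adTape()
  ids <- .pushParams(tp, model)
  fwd <- .tapeForward(tp, ids, gs, model, aggIter)
  p <- .tapePredict(tp, fwd, gs, model, fdR, fdT)
  diffs <- adSub(tp, p, adConst(tp, target))
  loss <- adMean(tp, adMul(tp, diffs, diffs))
  list(tp = tp, loss = loss, ids = ids)
}

## loss + gradients for one graph with current model parameters
.modelLossGrad <- function(model, gs, target, aggIter = 15L, fdR = 2, fdT = 1) {
  bt <- .buildLossTape(model, gs, target, aggIter, fdR, fdT)
  g <- adGrad(bt$tp, bt$loss)
  grads <- lapply(bt$ids, function(id) g[[id]])
  grads <- lapply(grads, function(x) if (is.null(x)) 0 else x)
  list(loss = adValue(bt$tp, bt$loss), grads = grads)
}

#' Train a graph convolution model on one or more networks
#'
#' Full-graph gradient descent with Adam (batch size one graph): each epoch
#' sweeps the training graphs in order, predicting all pairwise link
#' probabilities through the Fermi-Dirac decoder and minimizing the mean
#' squared error against the min-max scaled PLV targets. Curvatures are
#' parameterized as `K = -softplus(raw)` so they remain negative; in
#' `"fixed"` mode they stay at -1. Deterministic given `cfg$seed`.
#'
#' @param graphs A [BrainGraph-class] or list of them (shared node set).
#' @param cfg A [trainConfig()] list.
#' @param type `"hgcn"` or `"gcn"`.
#' @return A trained [GraphEmbeddingModel-class] with `lossTrace` filled.
#' @export
trainModel <- function(graphs, cfg = trainConfig(), type = c("hgcn", "gcn")) {
  type <- match.arg(type)
  if ((cfg$restarts %||% 1L) > 1L) {
    fits <- lapply(seq_len(cfg$restarts), function(r) {
      cfgR <- cfg; cfgR$seed <- cfg$seed + 7919L * (r - 1L); cfgR$restarts <- 1L
      trainModel(graphs, cfgR, type = type)
    })
    finals <- vapply(fits, function(m) utils::tail(m@lossTrace, 1), numeric(1))
    return(fits[[which.min(finals)]])
  }
  if (methods::is(graphs, "BrainGraph")) graphs <- list(graphs)
  if (!length(graphs)) stop("need at least one training graph")
  R <- nrow(adjacency(graphs[[1]]))
  if (!all(vapply(graphs, function(g) nrow(adjacency(g)), 0L) == R))
    stop("all graphs must share the node set")
  model <- .initModel(type, R, hidden = cfg$hidden, D = cfg$D,
                      curvatureMode = cfg$curvatureMode, seed = cfg$seed)
  gss <- lapply(graphs, function(g) .graphStructure(adjacency(g)))
  targets <- lapply(graphs, function(g) {
    P <- edgeProb(g); P[upper.tri(P)]
  })
  pn <- c("W1", "b1", "W2", "b2", "c1", "c2")
  learnCurv <- type == "hgcn" && cfg$curvatureMode == "learned"
  mState <- vState <- stats::setNames(vector("list", length(pn)), pn)
  step <- 0L
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    epLoss <- 0
    for (gi in seq_along(graphs)) {
      lg <- .modelLossGrad(model, gss[[gi]], targets[[gi]],
                           aggIter = cfg$aggIter, fdR = cfg$fdR, fdT = cfg$fdT)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      epLoss <- epLoss + lg$loss
      step <- step + 1L
      cur <- list(W1 = model@W1, b1 = matrix(model@b1, 1L),
                  W2 = model@W2, b2 = matrix(model@b2, 1L),
                  c1 = model@c1raw, c2 = model@c2raw)
      for (nm in pn) {
        if (nm %in% c("c1", "c2") && !learnCurv) next
        g <- lg$grads[[nm]]
        if (is.null(mState[[nm]])) { mState[[nm]] <- g * 0; vState[[nm]] <- g * 0 }
        mState[[nm]] <- b1 * mState[[nm]] + (1 - b1) * g
        vState[[nm]] <- b2 * vState[[nm]] + (1 - b2) * g * g
        mh <- mState[[nm]] / (1 - b1^step)
        vh <- vState[[nm]] / (1 - b2^step)
        cur[[nm]] <- cur[[nm]] - cfg$lr * mh / (sqrt(vh) + epsA)
      }
      model@W1 <- cur$W1; model@b1 <- drop(cur$b1)
      model@W2 <- cur$W2; model@b2 <- drop(cur$b2)
      model@c1raw <- cur$c1; model@c2raw <- cur$c2
    }
    trace[ep] <- epLoss / length(graphs)
  }
  model@lossTrace <- trace
  model
}

#' Predict link probabilities for every node pair
#'
#' Applies the Fermi-Dirac decoder to the squared embedding distances of a
#' forward pass on `graph`, returning the symmetric matrix of predicted
#' link probabilities (zero diagonal).
#'
#' @param model A trained [GraphEmbeddingModel-class].
#' @param graph A [BrainGraph-class] over the model's node set.
#' @param fdR,fdT Decoder parameters (defaults `r = 2`, `t = 1`).
#' @param aggIter Karcher iterations of the Frechet aggregation.
#' @return Symmetric matrix of probabilities in `(0, 1)`.
#' @export
predictLinks <- function(model, graph, fdR = 2, fdT = 1, aggIter = 15L) {
  if (nrow(adjacency(graph)) != nrow(model@W1))
    stop("graph has ", nrow(adjacency(graph)), " nodes but model expects ",
         nrow(model@W1))
  gs <- .graphStructure(adjacency(graph))
  tp <- adTape()
  ids <- .pushParams(tp, model)
  fwd <- .tapeForward(tp, ids, gs, model, aggIter)
  p <- adValue(tp, .tapePredict(tp, fwd, gs, model, fdR, fdT))
  R <- gs$R
  P <- matrix(0, R, R)
  P[cbind(gs$pi, gs$pj)] <- p
  P[cbind(gs$pj, gs$pi)] <- p
  P
}

#' Mean average precision of link ranking
#'
#' For every node with at least one true neighbor, all other nodes are
#' ranked by predicted score (descending, ties broken by node index) and the
#' average precision of the node's true neighbors is computed; the mean over
#' nodes is returned. Candidate pairs marked in `exclude` are removed from
#' the ranking (used when edges seen during fitting must not be scored).
#'
#' @param predicted Symmetric score matrix.
#' @param adjacency Binary symmetric adjacency of true edges.
#' @param exclude Optional binary matrix of pairs to drop from candidate
#'   lists (e.g. training edges in a masked-edge evaluation).
#' @return MAP in `[0, 1]`.
#' @export
mapScore <- function(predicted, adjacency, exclude = NULL) {
  R <- nrow(adjacency)
  if (!all(dim(predicted) == dim(adjacency)))
    stop("predicted and adjacency must have identical shape")
  if (sum(adjacency) == 0) stop("adjacency has no edges")
  aps <- numeric(0)
  for (i in seq_len(R)) {
    cand <- setdiff(seq_len(R), i)
    if (!is.null(exclude)) cand <- cand[exclude[i, cand] == 0]
    truth <- adjacency[i, cand] != 0
    if (!any(truth)) next
    s <- predicted[i, cand]
    o <- order(-s, cand)
    hits <- truth[o]
    prec <- cumsum(hits) / seq_along(hits)
    aps <- c(aps, mean(prec[hits]))
  }
  mean(aps)
}

#' Subject-grouped fold assignment
#'
#' Partitions subjects into `k` folds (shuffled round-robin, deterministic
#' per `seed`); all sessions of a subject share a fold so that pre/post
#' networks of one participant never straddle the train/test split.
#'
#' @param subjects Character vector of subject identifiers (duplicates
#'   allowed; the unique set is partitioned).
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @return Named integer vector mapping each unique subject to a fold.
#' @export
groupedKFold <- function(subjects, k = 5L, seed = 1L) {
  subj <- unique(subjects)
  if (length(subj) < k)
    stop("fewer subjects (", length(subj), ") than folds (", k, ")")
  set.seed(seed)
  shuffled <- sample(subj)
  f <- stats::setNames(rep_len(seq_len(k), length(subj)), shuffled)
  f[subj]
}

## masked-edge evaluation of the transductive shallow embedding
.shallowMaskedMap <- function(graph, D, maskFrac = 0.2, seed = 1L, ...) {
  A <- adjacency(graph)
  eIdx <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
  nE <- nrow(eIdx)
  set.seed(seed)
  nMask <- max(1L, round(maskFrac * nE))
  mask <- sample.int(nE, nMask)
  Atrain <- A
  Atrain[eIdx[mask, , drop = FALSE]] <- 0
  Atrain[eIdx[mask, 2:1, drop = FALSE]] <- 0
  Atest <- A - Atrain
  emb <- shallowPoincare(Atrain, D = D, seed = seed, ...)
  d <- .pairwiseHypDist(embCoords(emb), K = -1)
  mapScore(-d, Atest, exclude = Atrain)
}

#' Link-prediction experiment across models and dimensions
#'
#' Benchmarks the embedding models with subject-grouped k-fold
#' cross-validation. For the graph convolution models the evaluation is
#' inductive: the model is trained on the training-fold graphs and MAP is
#' computed over all pairs of each unseen test graph. The shallow Poincare
#' embedding is transductive, so it is fit per test graph on a random 80%
#' of its edges and scored on the masked 20% (training edges excluded from
#' the candidate rankings); the `protocol` column records the asymmetry.
#'
#' @param graphs List of [BrainGraph-class] objects (shared node set).
#' @param models Character subset of
#'   `c("hgcn_learned", "hgcn_fixed", "gcn", "shallow")`.
#' @param dims Integer vector of embedding dimensions.
#' @param cfg Base [trainConfig()]; its `D`/`curvatureMode` are overridden
#'   per run.
#' @param k Number of folds (default 5).
#' @param seed Seed controlling fold assignment and per-graph masking.
#' @param foldsToRun Optional subset of folds (default all), useful for
#'   reduced-cost experiments.
#' @return List with `report` (one row per model x dimension: mean MAP,
#'   learned curvatures, protocol) and `perFold` (long table of fold MAPs).
#' @export
linkPredictionExperiment <- function(graphs,
                                     models = c("hgcn_learned", "hgcn_fixed",
                                                "gcn", "shallow"),
                                     dims = 2L, cfg = trainConfig(), k = 5L,
                                     seed = 1L, foldsToRun = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  subjects <- vapply(graphs, subjectId, "")
  folds <- groupedKFold(subjects, k = k, seed = seed)
  if (is.null(foldsToRun)) foldsToRun <- seq_len(k)
  rows <- list(); perFold <- list()
  for (m in models) for (D in dims) {
    foldMaps <- numeric(0); K1 <- K2 <- NA_real_
    for (f in foldsToRun) {
      testIdx <- which(folds[subjects] == f)
      trainIdx <- setdiff(seq_along(graphs), testIdx)
      if (m == "shallow") {
        maps <- vapply(testIdx, function(ti)
          .shallowMaskedMap(graphs[[ti]], D = D,
                            seed = seed + 1000L * f + ti), numeric(1))
      } else {
        cfgRun <- cfg
        cfgRun$D <- as.integer(D)
        cfgRun$curvatureMode <- if (m == "hgcn_learned") "learned" else "fixed"
        type <- if (m == "gcn") "gcn" else "hgcn"
        fit <- trainModel(graphs[trainIdx], cfgRun, type = type)
        if (m == "hgcn_learned") {
          kv <- curvatures(fit); K1 <- kv[1]; K2 <- kv[2]
        }
        maps <- vapply(testIdx, function(ti)
          mapScore(predictLinks(fit, graphs[[ti]], fdR = cfg$fdR,
                                fdT = cfg$fdT, aggIter = cfg$aggIter),
                   adjacency(graphs[[ti]])), numeric(1))
      }
      foldMaps <- c(foldMaps, mean(maps))
      perFold[[length(perFold) + 1L]] <-
        data.frame(model = m, D = D, fold = f, map = mean(maps))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      model = m, D = D, meanMAP = mean(foldMaps),
      K1 = unname(K1), K2 = unname(K2),
      protocol = if (m == "shallow") "transductive_masked20" else "inductive")
  }
  list(report = do.call(rbind, rows), perFold = do.call(rbind, perFold))
}
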
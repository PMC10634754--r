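## Radius-based hierarchy metric, subnetwork aggregation, group
## classification features and group-difference statistics.
##
## The hyperbolic radius of a node embedding (geodesic distance from the
## ball center) proxies the node's position in the network hierarchy: hub
## nodes embed near the center (small radius = high hierarchy), peripheral
## nodes near the rim.

#' @describeIn EmbeddingResult-accessors Per-node hyperbolic radius
#'   (geodesic distance from the origin at the embedding's curvature;
#'   Euclidean norm for flat embeddings).
#' @export
setMethod("nodeRadius", "EmbeddingResult", function(x) x@radii)

#' Mean radius per functional subnetwork
#'
#' Averages per-node radii within each of the eight functional subnetworks.
#' A lower mean radius indicates a higher subnetwork hierarchy.
#'
#' @param radii Numeric vector of per-node radii (or an
#'   [EmbeddingResult-class]).
#' @param nodeMeta `data.frame` with a `subnetwork` column labeling every
#'   node.
#' @return Named numeric vector, one mean radius per subnetwork present.
#' @export
subnetworkRadii <- function(radii, nodeMeta) {
  if (methods::is(radii, "EmbeddingResult")) radii <- nodeRadius(radii)
  sn <- nodeMeta$subnetwork
  if (anyNA(sn)) stop("every node must carry a subnetwork label")
  if (length(sn) != length(radii)) stop("radii and nodeMeta length mismatch")
  lev <- if (is.factor(sn)) levels(sn) else sort(unique(sn))
  grp <- split(radii, factor(sn, levels = lev))
  if (any(lengths(grp) == 0L))
    stop("empty subnetwork(s): ",
         paste(lev[lengths(grp) == 0L], collapse = ", "))
  vapply(grp, mean, numeric(1))
}

#' Per-subject radius table
#'
#' One row per subject x session: per-subnetwork mean radii, group label
#' and age covariate. The substrate of the group-difference statistics.
#'
#' @param embeddings List of [EmbeddingResult-class] objects.
#' @param graphs The matching list of [BrainGraph-class] objects (for node
#'   metadata and group labels).
#' @param ages Optional named numeric vector of subject ages.
#' @return `data.frame` with columns `subjectId`, `session`, `group`,
#'   `age`, and one column per subnetwork.
#' @export
radiusTable <- function(embeddings, graphs, ages = NULL) {
  stopifnot(length(embeddings) == length(graphs))
  rows <- lapply(seq_along(embeddings), function(i) {
    sr <- subnetworkRadii(embeddings[[i]], nodeMeta(graphs[[i]]))
    df <- data.frame(subjectId = subjectId(graphs[[i]]),
                     session = session(graphs[[i]]),
                     group = groupLabel(graphs[[i]]),
                     age = if (!is.null(ages))
                       unname(ages[subjectId(graphs[[i]])]) else NA_real_,
                     meanRadius = mean(nodeRadius(embeddings[[i]])),
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(as.list(sr)))
  })
  do.call(rbind, rows)
}

#' Feature matrices for group classification
#'
#' Builds per-subject feature rows from a cohort: `"plv"` vectorizes the
#' upper triangle of each PLV matrix (R(R-1)/2 values), `"radius"` uses the
#' per-node embedding radii (R values), `"combined"` concatenates both. By
#' default only pre-intervention sessions are used, mirroring the practice
#' of restricting classification features to baseline recordings.
#'
#' @param graphs List of [BrainGraph-class] objects.
#' @param embeddings List of matching [EmbeddingResult-class] objects
#'   (required for `"radius"`/`"combined"`).
#' @param featureSet `"plv"`, `"radius"`, or `"combined"`.
#' @param sessionFilter Session to keep (default `"pre"`; `NULL` keeps all).
#' @return List with `x` (feature matrix, one row per kept graph) and
#'   `y` (group labels).
#' @export
buildFeatures <- function(graphs, embeddings = NULL,
                          featureSet = c("plv", "radius", "combined"),
                          sessionFilter = "pre") {
  featureSet <- match.arg(featureSet)
  keep <- if (is.null(sessionFilter)) seq_along(graphs)
          else which(vapply(graphs, session, "") == sessionFilter)
  if (!length(keep)) stop("no graphs left after session filter")
  if (featureSet != "plv" && (is.null(embeddings) ||
      length(embeddings) != length(graphs)))
    stop("embeddings (one per graph) required for radius/combined features")
  featRow <- function(i) {
    p <- if (featureSet != "radius") {
      M <- plvMatrix(graphs[[i]]); M[upper.tri(M)]
    } else NULL
    r <- if (featureSet != "plv") nodeRadius(embeddings[[i]]) else NULL
    c(p, r)
  }
  x <- do.call(rbind, lapply(keep, featRow))
  y <- vapply(graphs[keep], groupLabel, "")
  if (anyNA(y)) stop("group labels missing for some graphs")
  list(x = x, y = y)
}

.macroF1 <- function(truth, pred) {
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

#' SVM group classification with stratified cross-validation
#'
#' Trains a support vector machine (RBF kernel, `C = 1`, features
#' standardized within each training fold; linear kernel available) under
#' stratified k-fold cross-validation and reports per-fold and mean Macro
#' F1 and AUC-ROC. Deterministic per `seed`.
#'
#' @param x Feature matrix (rows = subjects).
#' @param y Group labels (two classes).
#' @param k Folds (default 5).
#' @param seed RNG seed for the stratified fold assignment.
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost SVM cost parameter (default 1).
#' @return List with `macroF1`, `auc` (means), `perFold` data.frame, and
#'   the settings used.
#' @export
classifyGroups <- function(x, y, k = 5L, seed = 1L,
                           kernel = c("radial", "linear"), cost = 1) {
  kernel <- match.arg(kernel)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("need exactly two classes, got ", nlevels(y))
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  per <- lapply(seq_len(k), function(f) {
    tr <- folds != f; te <- !tr
    if (!any(te) || length(unique(y[tr])) < 2L) return(NULL)
    mu <- colMeans(x[tr, , drop = FALSE])
    sd <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    xs <- sweep(sweep(x, 2L, mu), 2L, sd, "/")
    fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], kernel = kernel,
                      cost = cost, scale = FALSE)
    dv <- attr(stats::predict(fit, xs[te, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    pred <- stats::predict(fit, xs[te, , drop = FALSE])
    ## decision values are signed toward the first training level, so the
    ## direction is fixed (never "auto", which biases null AUCs upward)
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = y[te], predictor = as.numeric(dv), quiet = TRUE,
      levels = levels(y), direction = ">")))
    data.frame(fold = f, macroF1 = .macroF1(y[te], pred), auc = auc)
  })
  perFold <- do.call(rbind, per)
  list(macroF1 = mean(perFold$macroF1), auc = mean(perFold$auc),
       perFold = perFold, kernel = kernel, cost = cost, k = k, seed = seed)
}

#' Covariate-adjusted group difference in subnetwork radius
#'
#' Tests for a group difference in the mean radius of one subnetwork on
#' subject-level data (sessions averaged per subject), adjusting for
#' covariates by least squares. `method = "linear_adjusted"` reports the
#' group-contrast t-test from the linear model; `method = "permutation"`
#' permutes group labels at the subject level (all assignments enumerated
#' exactly when feasible) and reports the two-sided permutation p-value of
#' the adjusted contrast.
#'
#' @param tab A [radiusTable()] `data.frame`.
#' @param subnetwork Column name of the subnetwork to test.
#' @param covariates Covariate column names (default `"age"`).
#' @param method `"linear_adjusted"` or `"permutation"`.
#' @param nPerm Permutations (default 10000); exact enumeration is used
#'   when the number of distinct label assignments is smaller.
#' @param seed RNG seed for the permutation draw.
#' @return List with `effect` (adjusted group contrast, group2 - group1 in
#'   label sort order), `p`, `method`, `n`.
#' @export
groupDifference <- function(tab, subnetwork, covariates = "age",
                            method = c("linear_adjusted", "permutation"),
                            nPerm = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (!subnetwork %in% names(tab)) stop("no column ", subnetwork, " in table")
  covariates <- covariates[!vapply(covariates, function(cv)
    all(is.na(tab[[cv]])), logical(1))]
  agg <- stats::aggregate(tab[c(subnetwork, covariates)],
                          by = list(subjectId = tab$subjectId,
                                    group = tab$group), FUN = mean)
  groups <- sort(unique(agg$group))
  if (length(groups) != 2L) stop("need exactly two groups")
  if (any(table(agg$group) < 2L)) stop("need >= 2 subjects per group")
  for (cv in covariates)
    if (stats::sd(agg[[cv]]) == 0)
      stop("degenerate design: covariate ", cv, " is constant")
  y <- agg[[subnetwork]]
  g <- as.numeric(agg$group == groups[2])
  X <- cbind(1, g, if (length(covariates))
    as.matrix(agg[covariates]) else NULL)
  fit <- stats::lm.fit(X, y)
  effect <- unname(fit$coefficients[2])
  n <- nrow(agg)
  if (method == "linear_adjusted") {
    dfRes <- n - ncol(X)
    s2 <- sum(fit$residuals^2) / dfRes
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(s2 * XtXinv[2, 2])
    p <- 2 * stats::pt(abs(effect / se), dfRes, lower.tail = FALSE)
  } else {
    n2 <- sum(g)
    contrastFor <- function(gp) {
      Xp <- X; Xp[, 2] <- gp
      unname(stats::lm.fit(Xp, y)$coefficients[2])
    }
    nExact <- choose(n, n2)
    if (nExact <= nPerm) {
      combs <- utils::combn(n, n2)
      stats <- apply(combs, 2L, function(idx) {
        gp <- numeric(n); gp[idx] <- 1; contrastFor(gp)
      })
    } else {
      set.seed(seed)
      stats <- vapply(seq_len(nPerm), function(i)
        contrastFor(sample(g)), numeric(1))
      stats <- c(effect, stats)  # include the observed assignment
    }
    p <- mean(abs(stats) >= abs(effect) - 1e-12)
  }
  list(effect = effect, p = p, method = method, n = n)
}

#' Group-difference tests across all subnetworks with FDR correction
#'
#' Runs [groupDifference()] for each subnetwork column of a radius table
#' and applies Benjamini-Hochberg FDR correction across the subnetworks.
#'
#' @inheritParams groupDifference
#' @param subnetworks Columns to test (default: all eight subnetwork
#'   columns present).
#' @param alpha FDR level for the `flagged` column (default 0.05).
#' @return `data.frame` with one row per subnetwork: `effect`, `p`,
#'   `p.adj`, `flagged`.
#' @export
testSubnetworkHierarchy <- function(tab, subnetworks = NULL,
                                    covariates = "age",
                                    method = "permutation", nPerm = 10000L,
                                    seed = 1L, alpha = 0.05) {
  if (is.null(subnetworks))
    subnetworks <- intersect(.SUBNETWORKS, names(tab))
  res <- lapply(subnetworks, function(sn)
    groupDifference(tab, sn, covariates = covariates, method = method,
                    nPerm = nPerm, seed = seed))
  out <- data.frame(subnetwork = subnetworks,
                    effect = vapply(res, `[[`, numeric(1), "effect"),
                    p = vapply(res, `[[`, numeric(1), "p"))
  out$p.adj <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$p.adj < alpha
  out
}
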
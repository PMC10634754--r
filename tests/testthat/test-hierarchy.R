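# Radius metric, subnetwork aggregation, classification, group statistics.

test_that("node radius is the geodesic distance from the ball center", {
  co <- rbind(c(0, 0), c(0.5, 0), c(0, -0.5))
  emb <- methods::new("EmbeddingResult", coords = co, K = -1,
                      radii = apply(co, 1, function(p)
                        hypDistance(c(0, 0), p, -1)),
                      subjectId = "s", session = "pre", model = "m")
  r <- nodeRadius(emb)
  expect_equal(r, c(0, log(3), log(3)), tolerance = 1e-12)
  # rotation invariance
  th <- 0.7
  Rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  co2 <- co %*% Rot
  r2 <- apply(co2, 1, function(p) hypDistance(c(0, 0), p, -1))
  expect_equal(r2, r, tolerance = 1e-12)
})

test_that("subnetwork radii average member nodes and flag empty groups", {
  meta <- data.frame(roi = paste0("r", 1:6), hemisphere = "L",
                     subnetwork = c("DAN", "DAN", "FPN", "VN", "VN", "VN"))
  r <- c(1, 3, 5, 2, 4, 6)
  sr <- subnetworkRadii(r, meta)
  expect_equal(sr[["DAN"]], 2)
  expect_equal(sr[["FPN"]], 5)
  expect_equal(sr[["VN"]], 4)
  # constant radii give constant means
  expect_true(all(subnetworkRadii(rep(2.5, 6), meta) == 2.5))
  metaF <- meta
  metaF$subnetwork <- factor(metaF$subnetwork,
                             levels = c("DAN", "FPN", "VN", "SMN"))
  expect_error(subnetworkRadii(r, metaF), "empty subnetwork")
  expect_error(subnetworkRadii(r, transform(meta,
    subnetwork = c(NA, "DAN", "FPN", "VN", "VN", "VN"))), "label")
})

test_that("feature builder produces the documented dimensions and filters", {
  cohort <- makeTestCohort(nPerGroup = 2, sessions = c("pre", "post"))
  graphs <- cohort$graphs
  embs <- lapply(graphs, function(g) {
    co <- matrix(runif(180, -0.3, 0.3), 90)
    methods::new("EmbeddingResult", coords = co, K = -1,
                 radii = sqrt(rowSums(co^2)), subjectId = subjectId(g),
                 session = session(g), model = "m")
  })
  fp <- buildFeatures(graphs, featureSet = "plv")
  expect_equal(ncol(fp$x), 90 * 89 / 2)
  expect_equal(nrow(fp$x), 4)         # pre sessions only
  fr <- buildFeatures(graphs, embs, featureSet = "radius")
  expect_equal(ncol(fr$x), 90)
  fc <- buildFeatures(graphs, embs, featureSet = "combined")
  expect_equal(ncol(fc$x), 4005 + 90)
  fAll <- buildFeatures(graphs, embs, featureSet = "radius",
                        sessionFilter = NULL)
  expect_equal(nrow(fAll$x), 8)
  expect_error(buildFeatures(graphs, featureSet = "radius"), "embeddings")
})

test_that("SVM classification: separable features, permuted labels, scaling", {
  set.seed(41)
  n <- 40
  y <- rep(c("HC", "SCD"), each = n / 2)
  xSep <- cbind(ifelse(y == "HC", -2, 2) + rnorm(n, 0, 0.1),
                matrix(rnorm(n * 5), n))
  rep1 <- classifyGroups(xSep, y, seed = 1)
  expect_equal(rep1$macroF1, 1)
  expect_equal(rep1$auc, 1)
  # permuted labels: AUC near chance across permutations
  aucs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    classifyGroups(xSep, sample(y), seed = 1)$auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.12)
  # linear-kernel AUC invariant to monotone feature rescaling
  x2 <- xSep; x2[, 1] <- x2[, 1] * 100 + 5
  a1 <- classifyGroups(xSep, y, seed = 2, kernel = "linear")$auc
  a2 <- classifyGroups(x2, y, seed = 2, kernel = "linear")$auc
  expect_equal(a1, a2, tolerance = 1e-8)
  expect_error(classifyGroups(xSep, rep("HC", n)), "two classes")
})

test_that("group difference: linear contrast recovers an implanted shift", {
  set.seed(42)
  n <- 20
  tab <- data.frame(subjectId = sprintf("s%02d", 1:(2 * n)),
                    session = "pre",
                    group = rep(c("HC", "SCD"), each = n),
                    age = rnorm(2 * n, 71, 4))
  tab$DAN <- 1.9 - 0.15 * (tab$group == "SCD") + 0.005 * (tab$age - 71) +
    rnorm(2 * n, 0, 0.05)
  res <- groupDifference(tab, "DAN", method = "linear_adjusted")
  expect_lt(abs(res$effect - (-0.15)), 0.04)
  expect_lt(res$p, 0.001)
  resP <- groupDifference(tab, "DAN", method = "permutation", nPerm = 500,
                          seed = 1)
  expect_lt(resP$p, 0.01)
  expect_error(groupDifference(transform(tab, age = 70), "DAN"),
               "degenerate")
})

test_that("null calibration: identical groups give near-zero effect, flat p", {
  set.seed(43)
  ps <- replicate(40, {
    n <- 10
    tab <- data.frame(subjectId = sprintf("s%02d", 1:(2 * n)),
                      session = "pre",
                      group = rep(c("HC", "SCD"), each = n),
                      age = rnorm(2 * n, 71, 4),
                      DAN = rnorm(2 * n, 1.9, 0.08))
    groupDifference(tab, "DAN", method = "linear_adjusted")$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("permutation p-value matches exact enumeration for 4+4 subjects", {
  set.seed(44)
  tab <- data.frame(subjectId = sprintf("s%d", 1:8), session = "pre",
                    group = rep(c("HC", "SCD"), each = 4),
                    age = rnorm(8, 71, 4),
                    DAN = c(1.9, 1.8, 1.85, 1.95, 1.7, 1.75, 1.72, 1.8))
  # nPerm large enough to trigger full enumeration of the 70 assignments
  res <- groupDifference(tab, "DAN", method = "permutation", nPerm = 10000)
  y <- tapply(tab$DAN, tab$subjectId, mean)[tab$subjectId]
  combs <- combn(8, 4)
  stats <- apply(combs, 2, function(idx) {
    g <- as.numeric(seq_len(8) %in% idx)
    X <- cbind(1, g, tab$age)
    unname(lm.fit(X, tab$DAN)$coefficients[2])
  })
  obs <- res$effect
  expect_equal(res$p, mean(abs(stats) >= abs(obs) - 1e-12), tolerance = 1e-12)
})

test_that("BH correction never rejects more when p-values grow", {
  p1 <- c(0.001, 0.01, 0.02, 0.2, 0.5, 0.7, 0.04, 0.03)
  p2 <- pmin(p1 + 0.02, 1)
  r1 <- sum(p.adjust(p1, "BH") < 0.05)
  r2 <- sum(p.adjust(p2, "BH") < 0.05)
  expect_lte(r2, r1)
})

test_that("radius table aggregates subnetwork means per subject and session", {
  cohort <- makeTestCohort(nPerGroup = 2, sessions = c("pre", "post"))
  graphs <- cohort$graphs
  embs <- lapply(graphs, function(g) {
    co <- matrix(runif(180, -0.3, 0.3), 90)
    methods::new("EmbeddingResult", coords = co, K = -1,
                 radii = sqrt(rowSums(co^2)), subjectId = subjectId(g),
                 session = session(g), model = "m")
  })
  tab <- radiusTable(embs, graphs, ages = cohort$ages)
  expect_equal(nrow(tab), 8)
  expect_true(all(c("pDMN", "aDMN", "DAN", "FPN", "VN", "VAN", "SN",
                    "SMN") %in% names(tab)))
  # spot-check one cell against a direct mean
  meta <- nodeMeta(graphs[[1]])
  expect_equal(tab$DAN[1],
               mean(nodeRadius(embs[[1]])[meta$subnetwork == "DAN"]))
  expect_false(anyNA(tab$age))
})
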
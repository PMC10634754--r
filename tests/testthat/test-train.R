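# Training loop, gradients, link prediction metrics, fold assignment.

test_that("weighted link loss matches hand-computed values", {
  expect_equal(weightedLinkLoss(matrix(0.4, 4, 4), matrix(0.4, 4, 4)), 0)
  expect_equal(weightedLinkLoss(matrix(0.5, 4, 4), matrix(0.4, 4, 4)), 0.01,
               tolerance = 1e-12)
  P <- matrix(c(0, 0.2, 0.9, 0.2, 0, 0.5, 0.9, 0.5, 0), 3)
  Q <- matrix(c(0, 0.1, 0.4, 0.1, 0, 0.8, 0.4, 0.8, 0), 3)
  # upper triangle pairs: (0.2-0.1)^2, (0.9-0.4)^2, (0.5-0.8)^2
  expect_equal(weightedLinkLoss(P, Q), mean(c(0.01, 0.25, 0.09)))
  expect_error(weightedLinkLoss(matrix(0, 2, 2), matrix(0, 3, 3)),
               "identical shape")
})

test_that("analytic gradients agree with finite differences on a 5-node graph", {
  set.seed(21)
  A <- matrix(0, 5, 5); A[1, 2] <- A[2, 3] <- A[3, 4] <- A[1, 4] <- 1
  A <- A + t(A)
  gs <- hyperMEG:::.graphStructure(A)
  target <- runif(10)
  h <- 1e-6
  slots <- c(W1 = "W1", b1 = "b1", W2 = "W2", b2 = "b2",
             c1 = "c1raw", c2 = "c2raw")
  for (type in c("hgcn", "gcn")) {
    model <- hyperMEG:::.initModel(type, 5, hidden = 3, D = 2,
                                   curvatureMode = "learned", seed = 2)
    lossOf <- function(m) {
      bt <- hyperMEG:::.buildLossTape(m, gs, target, 10L, 2, 1)
      hyperMEG:::adValue(bt$tp, bt$loss)
    }
    lg <- hyperMEG:::.modelLossGrad(model, gs, target, aggIter = 10L)
    parNames <- if (type == "hgcn") names(slots) else names(slots)[1:4]
    for (nm in parNames) {
      p <- slot(model, slots[[nm]])
      gA <- lg$grads[[nm]]
      for (i in seq_along(p)) {
        mp <- model; slot(mp, slots[[nm]])[i] <- p[i] + h
        mm <- model; slot(mm, slots[[nm]])[i] <- p[i] - h
        gN <- (lossOf(mp) - lossOf(mm)) / (2 * h)
        expect_lt(abs(gN - gA[i]) / max(abs(gN), abs(gA[i]), 1e-4), 1e-4)
      }
    }
  }
})

test_that("training reduces the loss and is reproducible per seed", {
  g <- makeHierarchicalNetwork(R = 10, avgDegree = 4, seed = 31)
  cfg <- trainConfig(epochs = 30, D = 2, seed = 9, curvatureMode = "learned")
  m1 <- trainModel(g, cfg)
  m2 <- trainModel(g, cfg)
  expect_identical(m1@lossTrace, m2@lossTrace)
  expect_identical(m1@W1, m2@W1)
  expect_lt(tail(m1@lossTrace, 1), m1@lossTrace[1])
  # learned curvatures move from the -1 initialization and stay negative
  kv <- curvatures(m1)
  expect_true(all(kv < 0))
  expect_false(any(kv == -1))
})

test_that("fixed-curvature mode keeps both curvatures at exactly -1", {
  g <- makeHierarchicalNetwork(R = 10, avgDegree = 4, seed = 32)
  m <- trainModel(g, trainConfig(epochs = 5, D = 2, seed = 1,
                                 curvatureMode = "fixed"))
  expect_identical(unname(curvatures(m)), c(-1, -1))
})

test_that("predicted link matrices are symmetric with values in (0, 1)", {
  g <- makeHierarchicalNetwork(R = 10, avgDegree = 4, seed = 33)
  m <- trainModel(g, trainConfig(epochs = 5, D = 2, seed = 1))
  P <- predictLinks(m, g)
  expect_equal(P, t(P))
  ut <- P[upper.tri(P)]
  expect_true(all(ut > 0 & ut < 1))
  # closer pairs receive higher probability
  emb <- embCoords(embedGraph(m, g))
  K2 <- unname(curvatures(m)[2])
  d <- hyperMEG:::.pairwiseHypDist(emb, K2)
  expect_equal(order(d[upper.tri(d)]), order(-ut))
})

test_that("mean average precision matches the worked ranking example", {
  # node with 2 true neighbors at ranks 1 and 3 -> AP = (1 + 2/3)/2 = 5/6
  A1 <- matrix(0, 4, 4); A1[1, 2] <- A1[2, 1] <- A1[1, 4] <- A1[4, 1] <- 1
  S <- matrix(0, 4, 4)
  S[1, ] <- c(0, 0.9, 0.8, 0.7); S[, 1] <- S[1, ]
  # node 1: neighbors {2, 4} at ranks 1 and 3 -> AP = (1 + 2/3)/2 = 5/6;
  # nodes 2 and 4 rank their single neighbor (node 1) first
  S2 <- S; S2[2, ] <- c(0.9, 0, 0.1, 0.2); S2[4, ] <- c(0.9, 0.2, 0.1, 0)
  expect_equal(mapScore(S2, A1), mean(c(5 / 6, 1, 1)))
})

test_that("perfect predictions give MAP 1 and MAP is rank-invariant", {
  set.seed(22)
  g <- makeHierarchicalNetwork(R = 15, avgDegree = 5, seed = 34)
  A <- adjacency(g)
  expect_equal(mapScore(A, A), 1)
  S <- matrix(runif(225), 15); S <- S + t(S)
  expect_equal(mapScore(S, A), mapScore(2 * S + 1, A), tolerance = 1e-12)
  expect_equal(mapScore(S, A), mapScore(exp(S), A), tolerance = 1e-12)
  expect_error(mapScore(S, A * 0), "no edges")
})

test_that("random scores yield MAP near graph density", {
  set.seed(23)
  R <- 100; p <- 0.2
  maps <- replicate(50, {
    A <- matrix(0, R, R)
    A[upper.tri(A)] <- rbinom(R * (R - 1) / 2, 1, p)
    A <- A + t(A)
    S <- matrix(0, R, R); S[upper.tri(S)] <- runif(R * (R - 1) / 2)
    S <- S + t(S)
    mapScore(S, A)
  })
  # approaches the density from above (finite-sample AP bias ~ +1/k)
  expect_equal(mean(maps), p, tolerance = 0.05 / p)  # relative tolerance
  # exact combinatorial null: AP of a uniformly random ranking with the
  # matched number of positives, averaged over nodes
  nullAP <- function(k, n) mean(replicate(400, {
    pos <- sort(sample.int(n, k))
    mean(cumsum(seq_len(n) %in% pos)[pos] / pos)
  }))
  set.seed(24)
  A <- matrix(0, R, R); A[upper.tri(A)] <- rbinom(R * (R - 1) / 2, 1, p)
  A <- A + t(A)
  expected <- mean(vapply(which(rowSums(A) > 0), function(i)
    nullAP(sum(A[i, ]), R - 1), numeric(1)))
  got <- mean(replicate(20, {
    S <- matrix(0, R, R); S[upper.tri(S)] <- runif(R * (R - 1) / 2)
    mapScore(S + t(S), A)
  }))
  expect_equal(got, expected, tolerance = 0.02)
})

test_that("grouped k-fold keeps sessions together and is seed-deterministic", {
  subjects <- rep(sprintf("s%02d", 1:10), each = 2)
  f1 <- groupedKFold(subjects, k = 5, seed = 3)
  f2 <- groupedKFold(subjects, k = 5, seed = 3)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:5)
  expect_true(all(table(f1) == 2))       # 2 subjects per fold
  f3 <- groupedKFold(subjects, k = 5, seed = 4)
  expect_false(identical(f1, f3))
  expect_error(groupedKFold(c("a", "b"), k = 5), "fewer subjects")
  # graphs of one subject never straddle folds by construction
  perGraphFold <- f1[subjects]
  expect_true(all(tapply(perGraphFold, subjects, function(x)
    length(unique(x))) == 1))
})

test_that("overfitting a single small graph drives the loss toward zero", {
  g <- makeHierarchicalNetwork(R = 10, avgDegree = 4, seed = 35)
  m <- trainModel(g, trainConfig(epochs = 250, D = 2, seed = 4,
                                 curvatureMode = "learned"))
  expect_lt(tail(m@lossTrace, 1), 0.02)
})

test_that("link prediction report has one row per model x dimension", {
  cohort <- makeTestCohort(nPerGroup = 3, sessions = "pre", R = 20)
  graphs <- cohort$graphs
  res <- linkPredictionExperiment(graphs, models = c("gcn", "shallow"),
                                  dims = c(2, 3),
                                  cfg = trainConfig(epochs = 3, D = 2,
                                                    seed = 1),
                                  k = 3, seed = 1, foldsToRun = 1L)
  expect_equal(nrow(res$report), 4)
  expect_true(all(res$report$meanMAP >= 0 & res$report$meanMAP <= 1))
  expect_setequal(unique(res$report$protocol),
                  c("inductive", "transductive_masked20"))
})
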
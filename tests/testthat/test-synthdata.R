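# Synthetic generators: trees, hierarchical networks, oscillators, cohorts.

test_that("binary tree has the expected counts and centrality structure", {
  tree <- makeBinaryTree(3)
  A <- adjacency(tree)
  expect_equal(nrow(A), 15)
  expect_equal(sum(A) / 2, 14)
  deg <- rowSums(A)
  expect_true(all(deg[8:15] == 1))          # leaves
  expect_equal(deg[1], 2)                   # root
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  # the root is the most central node by closeness (it minimizes total
  # shortest-path distance; interior subtree roots beat it on betweenness)
  clo <- igraph::closeness(g)
  expect_equal(unname(which.max(clo)), 1L)
})

test_that("hierarchical networks hit the target density across seeds", {
  dens <- vapply(1:20, function(s) {
    g <- makeHierarchicalNetwork(R = 90, avgDegree = 16, seed = s)
    mean(adjacency(g)[upper.tri(adjacency(g))])
  }, numeric(1))
  expect_gt(mean(dens), 0.16)
  expect_lt(mean(dens), 0.22)
  expect_lt(sd(dens), 0.02)
})

test_that("early-index nodes are hubs (heavy-tailed popularity)", {
  cors <- vapply(1:20, function(s) {
    g <- makeHierarchicalNetwork(R = 60, avgDegree = 10, seed = s)
    deg <- rowSums(adjacency(g))
    cor(seq_len(60), deg, method = "spearman")
  }, numeric(1))
  expect_true(all(cors < 0))               # later index -> lower degree
  expect_lt(mean(cors), -0.5)
})

test_that("zero temperature yields a deterministic threshold graph", {
  g1 <- makeHierarchicalNetwork(R = 30, avgDegree = 6, temperature = 0,
                                seed = 5)
  g2 <- makeHierarchicalNetwork(R = 30, avgDegree = 6, temperature = 0,
                                seed = 5)
  expect_identical(adjacency(g1), adjacency(g2))
  expect_equal(sum(adjacency(g1)) / 2, round(6 * 30 / 2))
})

test_that("generator output satisfies the connectivity-matrix invariants", {
  for (s in 1:5) {
    g <- makeHierarchicalNetwork(R = 20, avgDegree = 5, seed = s,
                                 noiseSd = 0.05)
    P <- edgeProb(g); V <- plvMatrix(g)
    expect_equal(P, t(P))
    expect_equal(diag(P), rep(0, 20))
    expect_true(all(P >= 0 & P <= 1))
    expect_true(all(V >= 0 & V <= 1))
    expect_true(methods::validObject(g))
  }
  expect_error(makeHierarchicalNetwork(R = 5), "R must be")
})

test_that("oscillator cohort reproduces programmed couplings in rank order", {
  set.seed(6)
  lam <- runif(6, 0.1, 1)
  C <- outer(lam, lam); diag(C) <- 0
  cors <- vapply(1:5, function(s) {
    ph <- makeOscillatorCohort(C, T = 500, nEpochs = 5, seed = s)
    M <- roiPLVMatrix(ph)
    cor(C[upper.tri(C)], M[upper.tri(M)], method = "spearman")
  }, numeric(1))
  expect_true(all(cors > 0.9))
  # perfectly coupled pair with no noise -> PLV 1; uncoupled pair -> near 0
  C2 <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3)
  ph2 <- makeOscillatorCohort(C2, T = 2000, nEpochs = 2, seed = 1)
  M2 <- roiPLVMatrix(ph2)
  expect_equal(M2[1, 2], 1, tolerance = 1e-9)
  expect_lt(M2[1, 3], 0.1)
  expect_error(makeOscillatorCohort(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("two-group cohort: counts, determinism, and null exchangeability", {
  spec <- synthCohortSpec(nPerGroup = 3, hierarchyShift = 0, seed = 8)
  c1 <- makeTwoGroupCohort(spec)
  expect_equal(length(c1$graphs), 2 * 3 * 2)   # two sessions
  c2 <- makeTwoGroupCohort(spec)
  expect_identical(lapply(c1$graphs, adjacency),
                   lapply(c2$graphs, adjacency))
  expect_identical(c1$ages, c2$ages)
  groups <- vapply(c1$graphs, groupLabel, "")
  expect_equal(sum(groups == "HC"), 6)
  expect_equal(sum(groups == "SCD"), 6)
  sessions <- vapply(c1$graphs, session, "")
  expect_setequal(unique(sessions), c("pre", "post"))
  # null cohort: designated-subnetwork degrees are exchangeable
  spec0 <- synthCohortSpec(nPerGroup = 6, hierarchyShift = 0,
                           sessions = "pre", seed = 9)
  c0 <- makeTwoGroupCohort(spec0)
  meta <- nodeMeta(c0$graphs[[1]])
  des <- meta$subnetwork %in% c("DAN", "FPN", "VAN")
  degByGraph <- vapply(c0$graphs, function(g)
    mean(rowSums(adjacency(g))[des]), numeric(1))
  grp <- vapply(c0$graphs, groupLabel, "")
  expect_gt(t.test(degByGraph[grp == "HC"],
                   degByGraph[grp == "SCD"])$p.value, 0.01)
})

test_that("hubness implant raises designated-subnetwork degree only", {
  spec <- synthCohortSpec(nPerGroup = 6, hierarchyShift = 0.15,
                          sessions = "pre", seed = 10)
  co <- makeTwoGroupCohort(spec)
  meta <- nodeMeta(co$graphs[[1]])
  des <- meta$subnetwork %in% spec$designated
  grp <- vapply(co$graphs, groupLabel, "")
  degMat <- vapply(co$graphs, function(g) rowSums(adjacency(g)),
                   numeric(90))
  desShift <- mean(degMat[des, grp == "SCD"]) - mean(degMat[des, grp == "HC"])
  ndShift <- mean(degMat[!des, grp == "SCD"]) - mean(degMat[!des, grp == "HC"])
  expect_gt(desShift, 1)
  expect_lt(abs(ndShift), 0.5)
  expect_equal(co$truth$designated, c("DAN", "FPN", "VAN"))
  expect_error(makeTwoGroupCohort(synthCohortSpec(nPerGroup = 2,
                                                  hierarchyShift = 1.2)),
               "too large")
})

test_that("session rewiring preserves edge count, symmetry and values", {
  spec <- synthCohortSpec(nPerGroup = 2, seed = 11)
  co <- makeTwoGroupCohort(spec)
  pre <- co$graphs[[1]]; post <- co$graphs[[2]]
  expect_equal(subjectId(pre), subjectId(post))
  expect_equal(session(post), "post")
  expect_equal(sum(adjacency(pre)), sum(adjacency(post)))
  expect_false(identical(adjacency(pre), adjacency(post)))
  expect_equal(sort(plvMatrix(pre)[upper.tri(diag(90))]),
               sort(plvMatrix(post)[upper.tri(diag(90))]))
  expect_true(methods::validObject(post))
})
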
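# Poincare-ball geometry: closed forms, metric axioms, Mobius algebra,
# Frechet mean against the brute-force Riemannian descent oracle.

test_that("geodesic distance matches closed forms and flags boundary input", {
  expect_equal(hypDistance(c(0.2, 0.1), c(0.2, 0.1), -1), 0)
  expect_equal(hypDistance(c(0, 0), c(0.5, 0), -1), log(3), tolerance = 1e-12)
  expect_equal(hypDistance(c(0, 0), c(0.5, 0), -1), 2 * atanh(0.5),
               tolerance = 1e-12)
  # K = -4: ball radius 1/2; d(0, v) = (2/sqrt(c)) artanh(sqrt(c)|v|)
  expect_equal(hypDistance(c(0, 0), c(0.25, 0), -4), atanh(0.5),
               tolerance = 1e-12)
  expect_equal(hypDistance(c(0, 0), c(0.25, 0), -4), 0.5 * acosh(5 / 3),
               tolerance = 1e-12)
  expect_error(hypDistance(c(1, 0), c(0, 0), -1), "boundary")
  expect_error(hypDistance(c(0.1, 0), c(0.6, 0), -4), "boundary")
})

test_that("distance satisfies metric axioms on random triples", {
  set.seed(1)
  for (K in c(-0.5, -1, -2)) {
    lim <- 0.95 / sqrt(-K)
    pts <- matrix(runif(3000 * 2, -lim / sqrt(2), lim / sqrt(2)), ncol = 2)
    for (i in seq_len(1000)) {
      u <- pts[3 * i - 2, ]; v <- pts[3 * i - 1, ]; w <- pts[3 * i, ]
      duv <- hypDistance(u, v, K)
      expect_equal(duv, hypDistance(v, u, K), tolerance = 1e-12)
      expect_lte(hypDistance(u, w, K), duv + hypDistance(v, w, K) + 1e-9)
    }
  }
})

test_that("flat-curvature limit recovers 2x the Euclidean distance", {
  set.seed(2)
  for (i in 1:50) {
    u <- runif(3, -10, 10); v <- runif(3, -10, 10)
    d <- hypDistance(u, v, -1e-6)
    expect_equal(d, 2 * sqrt(sum((u - v)^2)), tolerance = 1e-3)
  }
})

test_that("exp and log maps at the origin are mutually inverse", {
  expect_equal(expMap0(c(0, 0), -1), c(0, 0))
  expect_equal(logMap0(c(0, 0), -1), c(0, 0))
  set.seed(3)
  for (i in 1:100) {
    K <- sample(c(-0.5, -1, -2), 1)
    v <- runif(3, -1, 1) * 2 / sqrt(3)
    x <- expMap0(v, K)
    expect_lt(sqrt(sum(x^2)), 1 / sqrt(-K))
    expect_equal(logMap0(x, K), v, tolerance = 1e-6)
  }
  # large tangent vectors stay inside the ball
  expect_lt(sqrt(sum(expMap0(c(10, 0), -1)^2)), 1)
  expect_error(expMap0(c(NaN, 0), -1), "finite")
})

test_that("Mobius addition has identity, inverse, and the 1-D closed form", {
  u <- c(0.35, -0.2)
  expect_equal(mobiusAdd(u, c(0, 0), -1), u, tolerance = 1e-12)
  expect_equal(mobiusAdd(u, -u, -1), c(0, 0), tolerance = 1e-12)
  # collinear points: (a + b)/(1 + ab)
  expect_equal(mobiusAdd(c(0.3, 0), c(0.3, 0), -1), c(0.6 / 1.09, 0),
               tolerance = 1e-12)
})

test_that("Mobius matrix-vector multiplication obeys scaling law and identity", {
  x <- c(0.3, 0)
  expect_equal(mobiusMatvec(diag(2), x, -1), x, tolerance = 1e-6)
  expect_equal(mobiusMatvec(matrix(rnorm(4), 2), c(0, 0), -1), c(0, 0))
  # radial scaling: norm tanh(2 artanh(0.3)), same direction
  out <- mobiusMatvec(2 * diag(2), x, -1)
  expect_equal(out, c(tanh(2 * atanh(0.3)), 0), tolerance = 1e-12)
  # agrees with exp(W log(x)) composition at other curvatures
  set.seed(4)
  for (i in 1:20) {
    W <- matrix(rnorm(6), 2, 3)
    K <- sample(c(-0.5, -2), 1)
    x <- runif(3, -0.3, 0.3) / sqrt(-K)
    expect_equal(mobiusMatvec(W, x, K),
                 expMap0(drop(W %*% logMap0(x, K)), K), tolerance = 1e-8)
  }
  expect_error(mobiusMatvec(diag(3), c(0.1, 0.1), -1), "dimension")
})

test_that("projectToBall clamps to the boundary margin and is idempotent", {
  expect_equal(projectToBall(c(0.2, 0), -1), c(0.2, 0))
  expect_equal(projectToBall(c(0, 0), -1), c(0, 0))
  x <- projectToBall(c(5, 0), -1, eps = 1e-5)
  expect_equal(sqrt(sum(x^2)), 1 - 1e-5, tolerance = 1e-12)
  # matrix form, other curvature
  M <- projectToBall(rbind(c(3, 4), c(0.1, 0)), -4)
  expect_equal(sqrt(rowSums(M^2)), c((1 - 1e-5) / 2, 0.1), tolerance = 1e-12)
})

test_that("hyperbolic activation reduces to identity and maps to origin", {
  x <- c(0.2, 0.3)
  expect_equal(hypActivation(x, -1, -1, identity), x, tolerance = 1e-6)
  expect_equal(hypActivation(c(0, 0), -1, -1), c(0, 0))
  # all-negative tangent coordinates are zeroed by ReLU -> origin
  xn <- expMap0(c(-0.4, -0.9), -1)
  expect_equal(hypActivation(xn, -1, -2), c(0, 0), tolerance = 1e-12)
  # output respects the target curvature ball
  y <- hypActivation(expMap0(c(3, 3), -1), -1, -4)
  expect_lt(sqrt(sum(y^2)), 0.5)
})

test_that("Frechet mean handles degenerate configurations", {
  p <- c(0.3, -0.1)
  expect_equal(frechetMean(matrix(p, 1), K = -1), p,
               ignore_attr = TRUE)
  sym <- rbind(c(0.4, 0.1), c(-0.4, -0.1))
  expect_equal(as.numeric(frechetMean(sym, K = -1)), c(0, 0),
               tolerance = 1e-9)
  expect_error(frechetMean(matrix(numeric(0), 0, 2), K = -1), "at least one")
  expect_error(frechetMean(sym, weights = c(-1, 1), K = -1), "non-negative")
})

test_that("Frechet mean matches the brute-force Riemannian descent oracle", {
  set.seed(5)
  for (rep in 1:12) {
    K <- sample(c(-0.5, -1, -2), 1)
    n <- sample(5:10, 1)
    pts <- matrix(runif(n * 2, -0.6, 0.6) / sqrt(-K), n)
    w <- runif(n, 0.2, 1)
    got <- frechetMean(pts, w, K = K)
    ref <- oracleFrechet(pts, w, K = K, steps = 4000, lr = 2e-3)
    expect_lt(hypDistance(as.numeric(got), ref, K), 1e-4)
    # objective no larger than at any input point
    objAt <- function(y) sum(w / sum(w) * vapply(seq_len(n), function(i)
      hypDistance(y, pts[i, ], K)^2, numeric(1)))
    expect_lte(attr(got, "objective"),
               min(vapply(seq_len(n), function(i) objAt(pts[i, ]),
                          numeric(1))) + 1e-10)
  }
})

test_that("Frechet mean approaches the arithmetic mean in the flat limit", {
  set.seed(6)
  pts <- matrix(runif(10, -0.5, 0.5), 5)
  got <- frechetMean(pts, K = -1e-6)
  expect_equal(as.numeric(got), colMeans(pts), tolerance = 1e-3)
})
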
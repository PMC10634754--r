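# Independent oracles used across the suite. These are written from the
# closed-form definitions directly (no calls into the package's geometry
# internals) so they can serve as cross-checks.

# geodesic distance on the ball of curvature K = -c (independent coding)
oracleDist <- function(u, v, c = 1) {
  du <- sum((u - v)^2)
  acosh(1 + 2 * c * du / ((1 - c * sum(u^2)) * (1 - c * sum(v^2)))) / sqrt(c)
}

# brute-force Riemannian gradient descent for the weighted Frechet mean:
# finite-difference Euclidean gradient of the objective, rescaled by the
# inverse conformal metric factor, small fixed learning rate, many steps.
oracleFrechet <- function(pts, w = NULL, K = -1, steps = 10000L, lr = 1e-3) {
  c <- -K
  n <- nrow(pts)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  obj <- function(y) {
    n2y <- sum(y^2)
    du <- rowSums(sweep(pts, 2, y)^2)
    d <- acosh(pmax(1 + 2 * c * du /
                      ((1 - c * rowSums(pts^2)) * (1 - c * n2y)), 1)) / sqrt(c)
    sum(w * d^2)
  }
  y <- colSums(pts * w)             # Euclidean weighted mean start
  nrm <- sqrt(sum(y^2))
  lim <- 0.99 / sqrt(c)
  if (nrm > lim) y <- y * lim / nrm
  h <- 1e-6
  D <- ncol(pts)
  for (s in seq_len(steps)) {
    g <- numeric(D)
    for (k in seq_len(D)) {
      e <- numeric(D); e[k] <- h
      g[k] <- (obj(y + e) - obj(y - e)) / (2 * h)
    }
    gR <- g * (1 - c * sum(y^2))^2 / 4   # inverse metric scaling
    y <- y - lr * gR
    nrm <- sqrt(sum(y^2))
    if (nrm > (1 - 1e-5) / sqrt(c)) y <- y * ((1 - 1e-5) / sqrt(c)) / nrm
  }
  y
}

# naive nested-loop PLV: direct transcription of the defining sums
oraclePLV <- function(phA, phB) {
  # phA, phB: arrays [source, epoch, time]
  nA <- dim(phA)[1]; nB <- dim(phB)[1]
  nE <- dim(phA)[2]; Tn <- dim(phA)[3]
  perEpoch <- numeric(nE)
  for (e in seq_len(nE)) {
    tot <- 0
    for (p in seq_len(nA)) for (q in seq_len(nB)) {
      acc <- 0 + 0i
      for (t in seq_len(Tn))
        acc <- acc + exp(-1i * (phA[p, e, t] - phB[q, e, t]))
      tot <- tot + Mod(acc / Tn)
    }
    perEpoch[e] <- tot / (nA * nB)
  }
  mean(perEpoch)
}

# small deterministic test cohort shared by several files
makeTestCohort <- function(nPerGroup = 4, delta = 0, seed = 7,
                           sessions = c("pre", "post"), R = 90) {
  makeTwoGroupCohort(synthCohortSpec(
    nPerGroup = nPerGroup, R = R, hierarchyShift = delta,
    sessions = sessions, seed = seed))
}
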
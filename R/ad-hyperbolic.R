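## Differentiable (tape-based) row-wise Poincare-ball operations.
##
## These mirror the public geometry functions but operate on matrices of
## points (one per row) on an autodiff tape, with the curvature magnitude
## c = |K| itself a (possibly learnable) scalar node. Used only inside the
## model forward passes; the public API in geometry.R is the reference
## implementation the unit tests compare against.

.AD_TINY <- 1e-30

adRowNorm2 <- function(tp, X) adRowSums(tp, adMul(tp, X, X))

adRowNorm <- function(tp, X) adSqrt(tp, adRowNorm2(tp, X), floor = .AD_TINY)

## clamp all rows strictly inside the ball of curvature magnitude cS
adBallProject <- function(tp, X, sqrtC, eps = 1e-5) {
  n <- adRowNorm(tp, X)
  lim <- adCMul(tp, adRecip(tp, sqrtC), 1 - eps)       # (1-eps)/sqrt(c)
  f <- adClampMax(tp, adSMul(tp, adRecip(tp, adClampMin(tp, n, 1e-15)), lim), 1)
  adScaleRows(tp, X, f)
}

adExp0Rows <- function(tp, V, sqrtC) {
  n <- adRowNorm(tp, V)
  arg <- adSMul(tp, n, sqrtC)
  f <- adDiv(tp, adTanh(tp, arg), arg)
  adBallProject(tp, adScaleRows(tp, V, f), sqrtC)
}

adLog0Rows <- function(tp, X, sqrtC) {
  n <- adRowNorm(tp, X)
  arg <- adSMul(tp, n, sqrtC)
  f <- adDiv(tp, adAtanh(tp, arg), arg)
  adScaleRows(tp, X, f)
}

adMobiusAddRows <- function(tp, U, V, cS, sqrtC, project = TRUE) {
  uv <- adRowSums(tp, adMul(tp, U, V))
  u2 <- adRowNorm2(tp, U)
  v2 <- adRowNorm2(tp, V)
  cuv2 <- adCMul(tp, adSMul(tp, uv, cS), 2)            # 2c<u,v>
  coefU <- adCAdd(tp, adAdd(tp, cuv2, adSMul(tp, v2, cS)), 1)
  coefV <- adCAdd(tp, adNeg(tp, adSMul(tp, u2, cS)), 1)
  c2 <- adMul(tp, cS, cS)
  den <- adCAdd(tp, adAdd(tp, cuv2, adSMul(tp, adMul(tp, u2, v2), c2)), 1)
  num <- adAdd(tp, adScaleRows(tp, U, coefU), adScaleRows(tp, V, coefV))
  out <- adScaleRows(tp, num, adRecip(tp, den))
  if (project) adBallProject(tp, out, sqrtC) else out
}

## W (din x dout): hyperbolic matrix-vector multiplication of every row
adMobiusMatvecRows <- function(tp, X, W, sqrtC) {
  M <- adMatmul(tp, X, W)
  xn <- adRowNorm(tp, X)
  mn <- adRowNorm(tp, X = M)
  a <- adAtanh(tp, adSMul(tp, xn, sqrtC))
  t <- adTanh(tp, adMul(tp, adDiv(tp, mn, xn), a))
  f <- adDiv(tp, t, adSMul(tp, mn, sqrtC))
  adBallProject(tp, adScaleRows(tp, M, f), sqrtC)
}

## log map of rows of Y at base rows X (same number of rows)
adLogBaseRows <- function(tp, X, Y, cS, sqrtC) {
  W <- adMobiusAddRows(tp, adNeg(tp, X), Y, cS, sqrtC, project = FALSE)
  wn <- adRowNorm(tp, W)
  a <- adAtanh(tp, adSMul(tp, wn, sqrtC))
  lamInv <- adCAdd(tp, adNeg(tp, adSMul(tp, adRowNorm2(tp, X), cS)), 1)
  f <- adMul(tp, lamInv, adDiv(tp, a, adSMul(tp, wn, sqrtC)))
  adScaleRows(tp, W, f)
}

## exp map of tangent rows V at base rows X
adExpBaseRows <- function(tp, X, V, cS, sqrtC) {
  vn <- adRowNorm(tp, V)
  lam <- adRecip(tp, adCAdd(tp, adNeg(tp, adSMul(tp, adRowNorm2(tp, X), cS)), 1))
  half <- adCMul(tp, adMul(tp, adSMul(tp, vn, sqrtC), lam), 1)  # sqrt(c)*lam'*vn
  s <- adDiv(tp, adTanh(tp, half), adSMul(tp, vn, sqrtC))
  adMobiusAddRows(tp, X, adScaleRows(tp, V, s), cS, sqrtC)
}

## Frechet-mean aggregation over {N(i), i}: unrolled Karcher iteration,
## initialized at the tangent-space (origin) mean of each neighborhood.
## src/dst: edge list including self loops; invCount: 1/|{N(i), i}|.
## The update tangent is damped by 0.5: the full-step Karcher iteration can
## enter a period-2 oscillation when some points sit near the boundary,
## while the half-step iteration converges (linearly) in all regimes.
adFrechetAggRows <- function(tp, H, src, dst, invCount, cS, sqrtC,
                             iters = 15L, damp = 0.5) {
  n <- nrow(adValue(tp, H))
  ic <- adConst(tp, invCount)
  L0 <- adLog0Rows(tp, H, sqrtC)
  M <- adScaleRows(tp, adScatterSum(tp, adRowsSel(tp, L0, dst), src, n), ic)
  Y <- adExp0Rows(tp, M, sqrtC)
  for (k in seq_len(iters)) {
    Xb <- adRowsSel(tp, Y, src)
    Hd <- adRowsSel(tp, H, dst)
    L <- adLogBaseRows(tp, Xb, Hd, cS, sqrtC)
    M <- adScaleRows(tp, adScatterSum(tp, L, src, n), ic)
    Y <- adExpBaseRows(tp, Y, adCMul(tp, M, damp), cS, sqrtC)
  }
  Y
}

## hyperbolic squared distances between rows X[i,] and X[j,]
adPairDist2 <- function(tp, X, iIdx, jIdx, cS, sqrtC) {
  U <- adRowsSel(tp, X, iIdx)
  V <- adRowsSel(tp, X, jIdx)
  du <- adRowNorm2(tp, adSub(tp, U, V))
  au <- adCAdd(tp, adNeg(tp, adSMul(tp, adRowNorm2(tp, U), cS)), 1)
  av <- adCAdd(tp, adNeg(tp, adSMul(tp, adRowNorm2(tp, V), cS)), 1)
  arg <- adCAdd(tp, adCMul(tp, adSMul(tp, adDiv(tp, du, adMul(tp, au, av)), cS), 2), 1)
  d <- adSMul(tp, adAcosh(tp, arg), adRecip(tp, sqrtC))
  adMul(tp, d, d)
}

## Fermi-Dirac decoder on a node of (squared) distances
adFermiDirac <- function(tp, d2, r = 2, t = 1) {
  adSigmoid(tp, adCMul(tp, adCAdd(tp, adNeg(tp, d2), r), 1 / t))
}
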
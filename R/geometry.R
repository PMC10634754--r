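## Poincare-ball operations at arbitrary negative curvature K.
## All public functions take plain numeric vectors/matrices; points live in the
## open ball of radius 1/sqrt(|K|). Internally c = |K| > 0.

.BOUNDARY_EPS <- 1e-5   # relative boundary clamp
.DOMAIN_EPS <- 1e-15    # arccosh/artanh domain clamp
.NORM_EPS <- 1e-15      # guard against division by zero norms

.checkCurvature <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K >= 0)
    stop("curvature K must be a single finite negative number, got ", format(K))
  -K
}

.checkInBall <- function(x, c, what = "point") {
  n <- sqrt(sum(x^2))
  lim <- 1 / sqrt(c)
  if (!all(is.finite(x)))
    stop(what, " has non-finite coordinates")
  if (n >= lim)
    stop(what, " lies on or outside the ball boundary: norm ", format(n),
         " >= 1/sqrt(|K|) = ", format(lim))
  invisible(n)
}

#' Clamp a point strictly inside the Poincare ball
#'
#' Rescales `x` onto radius `(1 - eps)/sqrt(|K|)` if its norm meets or exceeds
#' that radius; interior points are returned unchanged. Used after every
#' ball-valued operation to keep iterates numerically inside the open ball.
#'
#' @param x Numeric vector (a single point) or matrix with one point per row.
#' @param K Negative curvature of the ball.
#' @param eps Relative boundary margin (default `1e-5`).
#' @return Object of the same shape as `x`, strictly inside the ball.
#' @examples
#' projectToBall(c(5, 0), K = -1)
#' @export
projectToBall <- function(x, K, eps = .BOUNDARY_EPS) {
  c <- .checkCurvature(K)
  maxn <- (1 - eps) / sqrt(c)
  if (is.matrix(x)) {
    n <- sqrt(rowSums(x^2))
    f <- ifelse(n >= maxn, maxn / pmax(n, .NORM_EPS), 1)
    return(x * f)
  }
  n <- sqrt(sum(x^2))
  if (n >= maxn) x * (maxn / max(n, .NORM_EPS)) else x
}

#' Geodesic distance on the Poincare ball
#'
#' Distance between two points in the ball of curvature `K < 0`:
#' \deqn{d_K(u,v) = \frac{1}{\sqrt{|K|}} \,\mathrm{arccosh}\!\left(1 -
#'   \frac{2K\|u-v\|^2}{(1+K\|u\|^2)(1+K\|v\|^2)}\right).}
#' In the flat limit \eqn{|K| \to 0} this approaches \eqn{2\|u-v\|}.
#'
#' @param u,v Numeric vectors, points strictly inside the ball.
#' @param K Negative curvature.
#' @return Non-negative scalar distance.
#' @examples
#' hypDistance(c(0, 0), c(0.5, 0), K = -1)  # = 2*atanh(0.5) = log(3)
#' @export
hypDistance <- function(u, v, K) {
  c <- .checkCurvature(K)
  .checkInBall(u, c, "u"); .checkInBall(v, c, "v")
  du <- sum((u - v)^2)
  arg <- 1 + 2 * c * du / ((1 - c * sum(u^2)) * (1 - c * sum(v^2)))
  acosh(max(arg, 1 + 0)) / sqrt(c)
}

#' Exponential map at the origin
#'
#' Maps a tangent vector at the ball center into the ball:
#' \eqn{\exp_0^K(v) = \tanh(\sqrt{|K|}\|v\|)\, v/(\sqrt{|K|}\|v\|)}.
#'
#' @param v Numeric tangent vector (any finite magnitude).
#' @param K Negative curvature.
#' @return Point strictly inside the ball (after boundary clamping).
#' @export
expMap0 <- function(v, K) {
  c <- .checkCurvature(K)
  if (!all(is.finite(v))) stop("tangent vector has non-finite coordinates")
  n <- sqrt(sum(v^2))
  if (n < .NORM_EPS) return(v * 0)
  projectToBall(tanh(sqrt(c) * n) / (sqrt(c) * n) * v, K)
}

#' Logarithmic map at the origin
#'
#' Inverse of [expMap0()]: maps a ball point to the tangent space at the
#' center, \eqn{\log_0^K(x) = \mathrm{artanh}(\sqrt{|K|}\|x\|)\, x/(\sqrt{|K|}\|x\|)}.
#'
#' @param x Point strictly inside the ball.
#' @param K Negative curvature.
#' @return Tangent vector at the origin.
#' @export
logMap0 <- function(x, K) {
  c <- .checkCurvature(K)
  .checkInBall(x, c, "x")
  n <- sqrt(sum(x^2))
  if (n < .NORM_EPS) return(x * 0)
  a <- min(sqrt(c) * n, 1 - .DOMAIN_EPS)
  atanh(a) / (sqrt(c) * n) * x
}

#' Mobius (gyrovector) addition
#'
#' The hyperbolic analogue of vector addition used for bias terms,
#' \eqn{u \oplus_K v}. The origin is the identity and \eqn{-u} the inverse.
#'
#' @param u,v Points strictly inside the ball.
#' @param K Negative curvature.
#' @return Ball point (clamped inside the boundary).
#' @export
mobiusAdd <- function(u, v, K) {
  c <- .checkCurvature(K)
  .checkInBall(u, c, "u"); .checkInBall(v, c, "v")
  uv <- sum(u * v); u2 <- sum(u^2); v2 <- sum(v^2)
  num <- (1 + 2 * c * uv + c * v2) * u + (1 - c * u2) * v
  den <- 1 + 2 * c * uv + c^2 * u2 * v2
  projectToBall(num / den, K)
}

#' Mobius matrix-vector multiplication
#'
#' Applies a Euclidean linear map hyperbolically: \eqn{W \otimes_K x =
#' \exp_0^K(W \log_0^K(x))}, evaluated through the norm-rescaled closed form.
#' `W x = 0` (or `x` at the origin) maps to the origin.
#'
#' @param W Numeric matrix whose number of columns equals `length(x)`.
#' @param x Point strictly inside the ball.
#' @param K Negative curvature.
#' @return Ball point of dimension `nrow(W)`.
#' @export
mobiusMatvec <- function(W, x, K) {
  c <- .checkCurvature(K)
  if (!is.matrix(W)) W <- matrix(W, nrow = 1L)
  if (ncol(W) != length(x))
    stop("dimension mismatch: ncol(W) = ", ncol(W), ", length(x) = ", length(x))
  .checkInBall(x, c, "x")
  xn <- sqrt(sum(x^2))
  if (xn < .NORM_EPS) return(rep(0, nrow(W)))
  mx <- drop(W %*% x)
  mn <- sqrt(sum(mx^2))
  if (mn < .NORM_EPS) return(rep(0, nrow(W)))
  a <- min(sqrt(c) * xn, 1 - .DOMAIN_EPS)
  res <- tanh(mn / xn * atanh(a)) / (sqrt(c) * mn) * mx
  projectToBall(res, K)
}

## log map of rows of Y at base point x (both in ball of |K| = c)
.logBase <- function(x, y, c) {
  w <- .mobiusAddVec(-x, y, c)
  wn <- sqrt(sum(w^2))
  if (wn < .NORM_EPS) return(w * 0)
  lam <- 2 / (1 - c * sum(x^2))
  a <- min(sqrt(c) * wn, 1 - .DOMAIN_EPS)
  (2 / (sqrt(c) * lam)) * atanh(a) / wn * w
}

.expBase <- function(x, v, c) {
  vn <- sqrt(sum(v^2))
  if (vn < .NORM_EPS) return(x)
  lam <- 2 / (1 - c * sum(x^2))
  s <- tanh(sqrt(c) * lam * vn / 2) / (sqrt(c) * vn)
  .mobiusAddVec(x, s * v, c)
}

## internal Mobius addition without input validation (hot path)
.mobiusAddVec <- function(u, v, c) {
  uv <- sum(u * v); u2 <- sum(u^2); v2 <- sum(v^2)
  num <- (1 + 2 * c * uv + c * v2) * u + (1 - c * u2) * v
  den <- 1 + 2 * c * uv + c^2 * u2 * v2
  out <- num / den
  n <- sqrt(sum(out^2)); maxn <- (1 - .BOUNDARY_EPS) / sqrt(c)
  if (n >= maxn) out * (maxn / n) else out
}

## all-pairs geodesic distance matrix for points in rows of X
.pairwiseHypDist <- function(X, K) {
  c <- -K
  n2 <- rowSums(X^2)
  du2 <- outer(n2, n2, "+") - 2 * tcrossprod(X)
  du2[du2 < 0] <- 0
  denom <- outer(1 - c * n2, 1 - c * n2)
  arg <- 1 + 2 * c * du2 / denom
  d <- acosh(pmax(arg, 1)) / sqrt(c)
  diag(d) <- 0
  d
}

.hypDistVec <- function(u, v, c) {
  du <- sum((u - v)^2)
  arg <- 1 + 2 * c * du / ((1 - c * sum(u^2)) * (1 - c * sum(v^2)))
  acosh(max(arg, 1)) / sqrt(c)
}

#' Weighted Frechet (Karcher) mean on the Poincare ball
#'
#' Returns the point minimizing the weighted sum of squared geodesic
#' distances to the input points, computed by the Karcher fixed-point
#' iteration (tangent-space averaging at the current iterate), initialized at
#' the input point with the largest weight. This is the aggregation primitive
#' of the hyperbolic graph convolution.
#'
#' @param points Numeric matrix, one ball point per row.
#' @param weights Non-negative weights, one per row; default uniform.
#' @param K Negative curvature.
#' @param tol Convergence tolerance on the change in objective
#'   (weighted sum of squared distances); default `1e-8`.
#' @param maxIter Maximum number of iterations (default 1000); exceeding it
#'   raises an error carrying the last objective value.
#' @return Ball point (numeric vector) with attribute `"objective"`, the
#'   attained weighted sum of squared geodesic distances.
#' @examples
#' p <- rbind(c(0.3, 0), c(-0.3, 0))
#' frechetMean(p, K = -1)  # symmetric pair -> origin
#' @export
frechetMean <- function(points, weights = NULL, K = -1, tol = 1e-8,
                        maxIter = 1000L) {
  c <- .checkCurvature(K)
  if (!is.matrix(points)) points <- matrix(points, nrow = 1L)
  n <- nrow(points)
  if (n == 0L) stop("frechetMean needs at least one point")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum, one per point")
  for (i in seq_len(n)) .checkInBall(points[i, ], c, paste0("point ", i))
  w <- weights / sum(weights)
  obj <- function(y) sum(w * vapply(seq_len(n), function(i)
    .hypDistVec(y, points[i, ], c)^2, numeric(1)))
  y <- points[which.max(w), ]
  f <- obj(y)
  if (n == 1L) { attr(y, "objective") <- 0; return(y) }
  for (it in seq_len(maxIter)) {
    m <- rep(0, ncol(points))
    for (i in seq_len(n)) m <- m + w[i] * .logBase(y, points[i, ], c)
    step <- 1
    repeat {  # damped Karcher step: guarantees a non-increasing objective
      yNew <- .expBase(y, step * m, c)
      fNew <- obj(yNew)
      if (fNew <= f || step < 1 / 64) break
      step <- step / 2
    }
    improvement <- f - fNew
    if (fNew <= f) { y <- yNew; f <- fNew }
    if (improvement < tol) {
      attr(y, "objective") <- f
      return(y)
    }
  }
  stop("frechetMean did not converge in ", maxIter,
       " iterations; last objective = ", format(f))
}

#' Hyperbolic pointwise activation
#'
#' Applies a Euclidean elementwise function in the tangent space at the
#' origin and transports the result to a (possibly different) curvature:
#' \eqn{\sigma^{K_{in},K_{out}}(x) = \exp_0^{K_{out}}(\sigma(\log_0^{K_{in}}(x)))}.
#'
#' @param x Ball point at curvature `KIn`.
#' @param KIn,KOut Input and output curvatures (both negative).
#' @param sigma Elementwise function (default `ReLU`, i.e. `pmax(., 0)`).
#' @return Ball point at curvature `KOut`.
#' @export
hypActivation <- function(x, KIn, KOut, sigma = function(z) pmax(z, 0)) {
  v <- logMap0(x, KIn)
  expMap0(sigma(v), KOut)
}
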
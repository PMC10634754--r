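## Minimal reverse-mode automatic differentiation tape.
##
## The hyperbolic and Euclidean graph convolutions are trained by gradient
## descent through Mobius operations, the unrolled Karcher iteration of the
## Frechet mean, and the Fermi-Dirac decoder. This file implements the small
## set of differentiable array operations those forward passes are built
## from. Values are numeric scalars, vectors, or matrices; gradients have the
## shape of the value. Everything is internal.
##
## A tape is an environment holding parallel lists of values, parent ids and
## vector-Jacobian-product closures; nodes are referenced by integer id.

## force the id promise BEFORE touching tp$val: nested op calls push nodes
## onto the tape while their ids are still lazy arguments upstream
.nodeVal <- function(tp, id) {
  id <- id  # force the promise BEFORE reading: nested calls push nodes
  .subset2(tp$val, as.character(id))
}

## node storage uses hashed environments keyed by id: O(1) insertion with no
## copy-on-write (list storage would copy the spine on every push)
adTape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$val <- new.env(hash = TRUE, parent = emptyenv(), size = 4096L)
  tp$par <- new.env(hash = TRUE, parent = emptyenv(), size = 4096L)
  tp$vjp <- new.env(hash = TRUE, parent = emptyenv(), size = 4096L)
  tp$n <- 0L
  tp
}

adPush <- function(tp, value, parents = integer(0), vjp = NULL) {
  ## force promises first: evaluating `value`/`parents` may push nested
  ## nodes and advance the counter
  force(value); force(parents); force(vjp)
  n <- tp$n + 1L
  ch <- as.character(n)
  assign(ch, value, envir = tp$val)
  assign(ch, parents, envir = tp$par)
  if (!is.null(vjp)) assign(ch, vjp, envir = tp$vjp)
  tp$n <- n
  n
}

adValue <- function(tp, id) .nodeVal(tp, id)
adConst <- function(tp, x) adPush(tp, x)

## Backward pass from a scalar node; returns an environment of gradients
## keyed by node id (absent where the node does not influence the loss).
adGradEnv <- function(tp, lossId) {
  g <- new.env(hash = TRUE, parent = emptyenv(), size = 4096L)
  assign(as.character(lossId), 1, envir = g)
  for (i in seq.int(lossId, 1L)) {
    ch <- as.character(i)
    gi <- if (exists(ch, envir = g, inherits = FALSE))
      get(ch, envir = g, inherits = FALSE) else NULL
    if (is.null(gi)) next
    ps <- get(ch, envir = tp$par, inherits = FALSE)
    if (!length(ps)) next
    pg <- get(ch, envir = tp$vjp, inherits = FALSE)(gi)
    for (k in seq_along(ps)) {
      pc <- as.character(ps[k])
      old <- if (exists(pc, envir = g, inherits = FALSE))
        get(pc, envir = g, inherits = FALSE) else NULL
      assign(pc, if (is.null(old)) pg[[k]] else old + pg[[k]], envir = g)
    }
  }
  g
}

## list view of the gradient environment (indexable by node id)
adGrad <- function(tp, lossId) {
  ge <- adGradEnv(tp, lossId)
  out <- vector("list", tp$n)
  for (ch in ls(ge)) out[[as.integer(ch)]] <- get(ch, envir = ge,
                                                  inherits = FALSE)
  out
}

## ---- elementwise arithmetic (same-shape operands) ----

adAdd <- function(tp, a, b)
  adPush(tp, .nodeVal(tp, a) + .nodeVal(tp, b), c(a, b), function(g) list(g, g))

adSub <- function(tp, a, b)
  adPush(tp, .nodeVal(tp, a) - .nodeVal(tp, b), c(a, b), function(g) list(g, -g))

adMul <- function(tp, a, b) {
  va <- .nodeVal(tp, a); vb <- .nodeVal(tp, b)
  adPush(tp, va * vb, c(a, b), function(g) list(g * vb, g * va))
}

adDiv <- function(tp, a, b) {
  va <- .nodeVal(tp, a); vb <- .nodeVal(tp, b)
  adPush(tp, va / vb, c(a, b),
         function(g) list(g / vb, -g * va / (vb * vb)))
}

adNeg <- function(tp, a)
  adPush(tp, -.nodeVal(tp, a), a, function(g) list(-g))

## constant (non-node) scalar helpers
adCMul <- function(tp, a, k)
  adPush(tp, k * .nodeVal(tp, a), a, function(g) list(k * g))

adCAdd <- function(tp, a, k)
  adPush(tp, k + .nodeVal(tp, a), a, function(g) list(g))

adRecip <- function(tp, a) {
  va <- .nodeVal(tp, a)
  adPush(tp, 1 / va, a, function(g) list(-g / (va * va)))
}

## multiply array node by scalar node
adSMul <- function(tp, a, s) {
  va <- .nodeVal(tp, a); vs <- .nodeVal(tp, s)
  adPush(tp, va * vs, c(a, s), function(g) list(g * vs, sum(g * va)))
}

## ---- nonlinearities ----

adTanh <- function(tp, a) {
  y <- tanh(.nodeVal(tp, a))
  adPush(tp, y, a, function(g) list(g * (1 - y * y)))
}

adAtanh <- function(tp, a, clamp = 1 - 1e-15) {
  x <- pmin(pmax(.nodeVal(tp, a), -clamp), clamp)
  adPush(tp, atanh(x), a, function(g) list(g / (1 - x * x)))
}

adAcosh <- function(tp, a, clamp = 1 + 1e-12) {
  x <- pmax(.nodeVal(tp, a), clamp)
  adPush(tp, acosh(x), a, function(g) list(g / sqrt(x * x - 1)))
}

adSqrt <- function(tp, a, floor = 1e-30) {
  x <- pmax(.nodeVal(tp, a), floor)
  y <- sqrt(x)
  adPush(tp, y, a, function(g) list(g / (2 * y)))
}

adRelu <- function(tp, a) {
  x <- .nodeVal(tp, a)
  adPush(tp, pmax(x, 0), a, function(g) list(g * (x > 0)))
}

adExp <- function(tp, a) {
  y <- exp(.nodeVal(tp, a))
  adPush(tp, y, a, function(g) list(g * y))
}

adSigmoid <- function(tp, a) {
  y <- 1 / (1 + exp(-.nodeVal(tp, a)))
  adPush(tp, y, a, function(g) list(g * y * (1 - y)))
}

adSoftplus <- function(tp, a) {
  x <- .nodeVal(tp, a)
  y <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  s <- 1 / (1 + exp(-x))
  adPush(tp, y, a, function(g) list(g * s))
}

adClampMin <- function(tp, a, k) {
  x <- .nodeVal(tp, a)
  adPush(tp, pmax(x, k), a, function(g) list(g * (x > k)))
}

adClampMax <- function(tp, a, k) {
  x <- .nodeVal(tp, a)
  adPush(tp, pmin(x, k), a, function(g) list(g * (x < k)))
}

## ---- matrix / shape operations ----

adMatmul <- function(tp, a, b) {
  va <- .nodeVal(tp, a); vb <- .nodeVal(tp, b)
  adPush(tp, va %*% vb, c(a, b),
         function(g) list(g %*% t(vb), t(va) %*% g))
}

adRowSums <- function(tp, a) {
  va <- .nodeVal(tp, a)
  nc <- ncol(va)
  adPush(tp, rowSums(va), a,
         function(g) list(matrix(g, nrow = length(g), ncol = nc)))
}

.adExpand <- function(g, va)
  if (is.matrix(va)) matrix(g, nrow(va), ncol(va)) else rep(g, length(va))

adSum <- function(tp, a) {
  va <- .nodeVal(tp, a)
  adPush(tp, sum(va), a, function(g) list(.adExpand(g, va)))
}

adMean <- function(tp, a) {
  va <- .nodeVal(tp, a)
  n <- length(va)
  adPush(tp, sum(va) / n, a, function(g) list(.adExpand(g / n, va)))
}

## select rows (with repetition); gradient scatter-adds back
adRowsSel <- function(tp, a, idx) {
  va <- .nodeVal(tp, a)
  nr <- nrow(va)
  adPush(tp, va[idx, , drop = FALSE], a, function(g) {
    rs <- rowsum(g, group = idx)
    out <- matrix(0, nr, ncol(va))
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

## sum rows of a by integer group in 1..nOut
adScatterSum <- function(tp, a, group, nOut) {
  va <- .nodeVal(tp, a)
  rs <- rowsum(va, group = group)
  out <- matrix(0, nOut, ncol(va))
  out[as.integer(rownames(rs)), ] <- rs
  adPush(tp, out, a, function(g) list(g[group, , drop = FALSE]))
}

## scale row i of X by s[i] (s a vector node of length nrow(X))
adScaleRows <- function(tp, a, s) {
  va <- .nodeVal(tp, a); vs <- .nodeVal(tp, s)
  adPush(tp, va * vs, c(a, s),
         function(g) list(g * vs, rowSums(g * va)))
}

## add a row vector node b (length ncol(X)) to every row of X
adAddRowVec <- function(tp, a, b) {
  va <- .nodeVal(tp, a); vb <- .nodeVal(tp, b)
  adPush(tp, sweep(va, 2L, vb, "+"), c(a, b),
         function(g) list(g, colSums(g)))
}

## vector <-> one-column-matrix views and vector indexing

adReshapeCol <- function(tp, a) {
  va <- .nodeVal(tp, a)
  adPush(tp, matrix(va, ncol = 1L), a, function(g) list(as.vector(g)))
}

adDropVec <- function(tp, a) {
  va <- .nodeVal(tp, a)
  adPush(tp, drop(va), a, function(g) list(matrix(g, ncol = 1L)))
}

adIndexVec <- function(tp, a, idx) {
  va <- .nodeVal(tp, a)
  n <- length(va)
  adPush(tp, va[idx], a, function(g) {
    out <- numeric(n)
    acc <- rowsum(g, group = idx)
    out[as.integer(rownames(acc))] <- acc
    list(out)
  })
}

adLog <- function(tp, a, floor = 1e-30) {
  x <- pmax(.nodeVal(tp, a), floor)
  adPush(tp, log(x), a, function(g) list(g / x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- finite-difference gradient check used by tests and trainModel ----
## f: function(list of arrays) -> scalar; returns max relative error between
## analytic gradients and central finite differences.
adCheckGrad <- function(f, params, gradFn, h = 1e-6) {
  gA <- gradFn(params)
  worst <- 0
  for (k in seq_along(params)) {
    p <- params[[k]]
    gN <- p
    for (i in seq_along(p)) {
      pp <- params; pp[[k]][i] <- p[i] + h
      pm <- params; pm[[k]][i] <- p[i] - h
      gN[i] <- (f(pp) - f(pm)) / (2 * h)
    }
    denom <- pmax(abs(gN), abs(gA[[k]]), 1e-4)
    worst <- max(worst, max(abs(gN - gA[[k]]) / denom))
  }
  worst
}
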
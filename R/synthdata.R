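## Synthetic fixture generators: binary trees, popularity-similarity
## hierarchical networks, coupled-oscillator phase cohorts, and two-group
## cohorts with implanted subnetwork hubness differences. All generators
## are seed-deterministic.

#' Perfect binary tree as a BrainGraph
#'
#' @param depth Tree depth (>= 1); the tree has `2^(depth+1) - 1` nodes.
#' @return A [BrainGraph-class] whose `edgeProb` equals the adjacency.
#' @export
makeBinaryTree <- function(depth) {
  stopifnot(depth >= 1)
  n <- 2^(depth + 1) - 1
  A <- matrix(0, n, n)
  for (i in seq_len(2^depth - 1)) {
    A[i, 2 * i] <- A[2 * i, i] <- 1
    A[i, 2 * i + 1] <- A[2 * i + 1, i] <- 1
  }
  .graphFromAdjacency(A, subjectId = paste0("tree_d", depth))
}

## latent popularity-similarity configuration: angular positions (similarity)
## and radial positions (popularity; early nodes more popular)
.psLatent <- function(R, gamma, seed) {
  set.seed(seed)
  beta <- 1 / (gamma - 1)
  theta <- stats::runif(R, 0, 2 * pi)
  rho <- 2 * (beta * log(seq_len(R)) + (1 - beta) * log(R))
  list(theta = theta, rho = rho)
}

## pairwise latent distances x_ij = rho_i + rho_j + 2 log(dTheta/2)
.psDistances <- function(latent) {
  R <- length(latent$theta)
  dTh <- abs(outer(latent$theta, latent$theta, "-"))
  dTh <- pi - abs(pi - dTh)
  x <- outer(latent$rho, latent$rho, "+") + 2 * log(pmax(dTh, 1e-9) / 2)
  diag(x) <- Inf
  x
}

## calibrate the connection radius mu so the expected edge count matches
## the target, then evaluate connection probabilities at temperature T
.psCalibrate <- function(x, targetEdges, temperature) {
  ut <- x[upper.tri(x)]
  if (temperature < 1e-8) return(sort(ut)[targetEdges])
  f <- function(mu) sum(1 / (1 + exp((ut - mu) / (2 * temperature)))) -
    targetEdges
  rng <- range(ut)
  stats::uniroot(f, lower = rng[1] - 50 * temperature,
                 upper = rng[2] + 50 * temperature)$root
}

.psProbsAt <- function(x, mu, temperature) {
  p <- if (temperature < 1e-8) (x <= mu) * 1
       else 1 / (1 + exp((x - mu) / (2 * temperature)))
  diag(p) <- 0
  p
}

.psProbs <- function(x, targetEdges, temperature)
  .psProbsAt(x, .psCalibrate(x, targetEdges, temperature), temperature)

#' Scale-free hierarchical network with continuous edge weights
#'
#' Samples a graph from a popularity-similarity rule: node `i` sits at a
#' random angular position with radial (popularity) coordinate growing like
#' `log(i)`, and pairs connect with a probability that decays with their
#' latent hyperbolic distance at the given `temperature`. The degree
#' distribution is heavy-tailed for `gamma` in (2, 3); early-index nodes
#' are hubs. Continuous PLV-like edge weights are derived from the
#' connection propensities (min-max scaled into a plausible PLV range plus
#' optional noise).
#'
#' @param R Number of nodes (>= 10).
#' @param avgDegree Target mean degree (calibrated in expectation).
#' @param gamma Target power-law exponent (default 2.5).
#' @param temperature Edge-probability temperature (default 0.15); `0`
#'   yields the deterministic nearest-neighbor graph.
#' @param seed RNG seed.
#' @param latent Optional precomputed latent configuration (internal use:
#'   cohorts share one latent geometry across subjects).
#' @param noiseSd Gaussian noise added to the scaled propensities before
#'   the PLV-range mapping (default 0).
#' @param mu Optional fixed connection radius; by default calibrated so the
#'   expected edge count matches `avgDegree * R / 2` (cohorts with boosted
#'   subgroups pass the control-group calibration so extra hub edges add to
#'   rather than redistribute the edge budget).
#' @param subjectId,session,group,nodeMeta Passed to the BrainGraph.
#' @return A [BrainGraph-class]; attribute `"connected"` flags whether the
#'   sampled graph is connected.
#' @export
makeHierarchicalNetwork <- function(R = 90L, avgDegree = 16, gamma = 2.5,
                                    temperature = 0.15, seed = 1L,
                                    latent = NULL, noiseSd = 0, mu = NULL,
                                    subjectId = "s1", session = "pre",
                                    group = NA_character_, nodeMeta = NULL) {
  if (R < 10L) stop("R must be >= 10")
  if (is.null(latent)) latent <- .psLatent(R, gamma, seed)
  x <- .psDistances(latent)
  targetEdges <- round(avgDegree * R / 2)
  if (is.null(mu)) mu <- .psCalibrate(x, targetEdges, temperature)
  .psGraphFromX(x, mu, temperature, noiseSd = noiseSd, seed = seed,
                subjectId = subjectId, session = session, group = group,
                nodeMeta = nodeMeta)
}

## sample a BrainGraph given latent distances x and connection radius mu
.psGraphFromX <- function(x, mu, temperature, noiseSd = 0, seed = 1L,
                          subjectId = "s1", session = "pre",
                          group = NA_character_, nodeMeta = NULL) {
  R <- nrow(x)
  p <- .psProbsAt(x, mu, temperature)
  set.seed(seed + 1L)
  U <- matrix(stats::runif(R * R), R, R)
  U[lower.tri(U)] <- t(U)[lower.tri(U)]
  A <- (U < p) * 1
  diag(A) <- 0
  ## continuous weights from propensities (negated latent distance)
  s <- -x; s[!is.finite(s)] <- NA
  ut <- s[upper.tri(s)]
  w <- (s - min(ut, na.rm = TRUE)) / (max(ut, na.rm = TRUE) -
                                      min(ut, na.rm = TRUE))
  w <- pmin(pmax(w, 0), 1)
  if (noiseSd > 0) {
    E <- matrix(stats::rnorm(R * R, 0, noiseSd), R, R)
    E[lower.tri(E)] <- t(E)[lower.tri(E)]
    w <- pmin(pmax(w + E, 0), 1)
  }
  plv <- 0.1 + 0.6 * w       # PLV-like range
  diag(plv) <- 0
  P <- scaleProbabilities(plv)
  g <- methods::new("BrainGraph", adjacency = A, edgeProb = P, plv = plv,
                    nodeMeta = nodeMeta %||% data.frame(
                      roi = paste0("roi", seq_len(R)),
                      hemisphere = NA_character_,
                      subnetwork = NA_character_, stringsAsFactors = FALSE),
                    subjectId = subjectId, session = session, group = group)
  comp <- .connectedComponents(A)
  attr(g, "connected") <- max(comp) == 1L
  g
}

## localized hubness boost: reduce the latent distances of DESIGNATED pairs
## only (both endpoints in the designated set), by the radial-coordinate
## shrinkage delta on both endpoints. Every non-designated node's adjacency
## distribution is untouched, so the implanted group difference is confined
## to the designated subnetworks by construction (up to second-order
## embedding effects through shared neighborhoods).
.psBoostDesignated <- function(x, rho, designated, delta, edgeDensity,
                               temperature) {
  x2 <- x
  d <- designated
  x2[d, d] <- x[d, d] - delta * outer(rho[d], rho[d], "+")
  diag(x2) <- Inf
  x2
}

## connected component labels by BFS (small graphs; avoids extra deps)
.connectedComponents <- function(A) {
  R <- nrow(A)
  comp <- integer(R); cur <- 0L
  for (i in seq_len(R)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] != 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Coupled-oscillator phase cohort
#'
#' Builds epoched instantaneous phases whose expected pairwise phase
#' locking is a monotone function of the programmed coupling. Each region
#' mixes a shared oscillator with an independent noise oscillator:
#' \eqn{\phi_r(t) = \arg(\lambda_r e^{j\phi_0(t)} + \sqrt{1 - \lambda_r^2}
#' e^{j\eta_r(t)})}, where the loadings \eqn{\lambda} come from the best
#' rank-one factorization of the coupling matrix (exact whenever `coupling`
#' has the product form \eqn{\lambda\lambda^\top}, which the cohort
#' generators use). Sources within a region add Gaussian phase jitter of
#' magnitude `noiseSd`.
#'
#' @param coupling Symmetric matrix in `[0, 1]` of target couplings.
#' @param T Samples per epoch (default 1000).
#' @param nEpochs Epochs (default 10).
#' @param noiseSd Within-region source phase jitter, radians (default 0).
#' @param sourcesPerRegion Sources per region (default 1).
#' @param seed RNG seed.
#' @return A `SourcePhases` object (see [sourcePhases()]).
#' @export
makeOscillatorCohort <- function(coupling, T = 1000L, nEpochs = 10L,
                                 noiseSd = 0, sourcesPerRegion = 1L,
                                 seed = 1L) {
  C <- as.matrix(coupling)
  if (max(abs(C - t(C))) > 1e-12) stop("coupling must be symmetric")
  R <- nrow(C)
  diag(C) <- 1
  ei <- eigen(C, symmetric = TRUE)
  lam <- sqrt(pmax(ei$values[1], 0)) * abs(ei$vectors[, 1])
  lam <- pmin(pmax(lam, 0), 1)
  set.seed(seed)
  n <- nEpochs * T
  phi0 <- stats::runif(n, 0, 2 * pi)
  phases <- lapply(seq_len(R), function(r) {
    eta <- stats::runif(n, 0, 2 * pi)
    z <- lam[r] * exp(1i * phi0) + sqrt(1 - lam[r]^2) * exp(1i * eta)
    base <- Arg(z)
    arr <- array(0, dim = c(sourcesPerRegion, nEpochs, T))
    for (s in seq_len(sourcesPerRegion)) {
      jit <- if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else 0
      arr[s, , ] <- matrix(base + jit, nEpochs, T, byrow = TRUE)
    }
    arr
  })
  sourcePhases(phases)
}

#' Specification for a synthetic two-group cohort
#'
#' @param nPerGroup Subjects per group (default 20).
#' @param R Nodes (default 90).
#' @param edgeDensity Target edge density (default 0.20, matching the
#'   thresholded-PLV regime).
#' @param hierarchyShift Hubness boost `delta` in `[0, 1)` applied to the
#'   designated subnetworks of group 2 (default 0 = null cohort): the
#'   latent radial coordinate of those nodes shrinks by the factor
#'   `1 - delta`, raising their popularity (degree) and therefore pushing
#'   their embeddings toward the ball center.
#' @param noiseSd Per-subject edge-weight noise (default 0.05).
#' @param seed RNG seed.
#' @param designated Subnetworks boosted in group 2 (default DAN, FPN, VAN).
#' @param sessions Session labels per subject (default `c("pre", "post")`;
#'   the post session is a 5% edge-rewired copy).
#' @param gamma,temperature Passed to [makeHierarchicalNetwork()].
#' @param subjectJitter Per-subject angular jitter (radians, default 0.15)
#'   applied to the shared latent geometry: subjects share a connectome
#'   backbone but differ individually.
#' @param subjectRhoSd Per-subject jitter of the radial (popularity)
#'   coordinates (default 0.3), modeling individual variability in hub
#'   strength; this is the main source of between-subject variance in
#'   subnetwork radii.
#' @param ageMean,ageSd Age covariate distribution (default 71 +/- 4.5 y).
#' @return A list of class `"synthCohortSpec"`.
#' @export
synthCohortSpec <- function(nPerGroup = 20L, R = 90L, edgeDensity = 0.20,
                            hierarchyShift = 0, noiseSd = 0.05, seed = 1L,
                            designated = c("DAN", "FPN", "VAN"),
                            sessions = c("pre", "post"), gamma = 2.5,
                            temperature = 0.15, subjectJitter = 0.15,
                            subjectRhoSd = 0.3, ageMean = 71, ageSd = 4.5) {
  if (edgeDensity <= 0 || edgeDensity >= 1) stop("edgeDensity must be in (0,1)")
  if (hierarchyShift < 0) stop("hierarchyShift must be >= 0")
  structure(list(nPerGroup = as.integer(nPerGroup), R = as.integer(R),
                 edgeDensity = edgeDensity, hierarchyShift = hierarchyShift,
                 noiseSd = noiseSd, seed = as.integer(seed),
                 designated = designated, sessions = sessions, gamma = gamma,
                 temperature = temperature, subjectJitter = subjectJitter,
                 subjectRhoSd = subjectRhoSd, ageMean = ageMean,
                 ageSd = ageSd),
            class = "synthCohortSpec")
}

## default node metadata for R nodes: the shipped AAL-90 table when R = 90,
## otherwise round-robin subnetwork labels
.defaultNodeMeta <- function(R) {
  if (R == 90L) {
    tab <- try(loadSubnetworkMap(), silent = TRUE)
    if (!inherits(tab, "try-error")) return(tab)
  }
  data.frame(roi = paste0("roi", seq_len(R)),
             hemisphere = rep(c("L", "R"), length.out = R),
             subnetwork = rep(.SUBNETWORKS, length.out = R),
             stringsAsFactors = FALSE)
}

## rewire approximately frac of the edges by swapping edge/non-edge pairs in
## all three matrices (keeps symmetry, ranges, and value multiset)
.rewireGraph <- function(g, frac = 0.05, seed = 1L, session = "post") {
  A <- g@adjacency; P <- g@edgeProb; V <- g@plv
  on <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
  off <- which(A == 0 & upper.tri(A, diag = FALSE), arr.ind = TRUE)
  set.seed(seed)
  nSwap <- min(max(1L, round(frac * nrow(on))), nrow(off))
  si <- sample.int(nrow(on), nSwap)
  sj <- sample.int(nrow(off), nSwap)
  swap <- function(M) {
    for (t in seq_len(nSwap)) {
      a <- on[si[t], ]; b <- off[sj[t], ]
      tmp <- M[a[1], a[2]]
      M[a[1], a[2]] <- M[a[2], a[1]] <- M[b[1], b[2]]
      M[b[1], b[2]] <- M[b[2], b[1]] <- tmp
    }
    M
  }
  methods::new("BrainGraph", adjacency = swap(A), edgeProb = swap(P),
               plv = swap(V), nodeMeta = g@nodeMeta, subjectId = g@subjectId,
               session = session, group = g@group)
}

#' Two-group cohort with implanted subnetwork hierarchy differences
#'
#' Generates a cohort of hierarchical networks sharing one latent
#' popularity-similarity geometry (subjects differ by edge-sampling and
#' weight noise, emulating a participant cohort with a common connectome
#' backbone). Group 2 ("SCD") receives a hubness boost of size
#' `hierarchyShift` on the nodes of the designated subnetworks, so those
#' subnetworks acquire higher degree and, downstream, smaller embedding
#' radii. With `hierarchyShift = 0` the groups are exchangeable.
#'
#' @param spec A [synthCohortSpec()].
#' @return List with `graphs` (BrainGraphs, `2 * nPerGroup * length(sessions)`
#'   of them), `ages` (named per-subject vector), and `truth`
#'   (designated subnetworks, shift size, boosted node indices).
#' @export
makeTwoGroupCohort <- function(spec = synthCohortSpec()) {
  if (spec$hierarchyShift >= 1)
    stop("hierarchyShift too large: latent radii would collapse ",
         "(density target cannot be maintained); need delta < 1")
  R <- spec$R
  meta <- .defaultNodeMeta(R)
  avgDeg <- spec$edgeDensity * (R - 1)
  latent <- .psLatent(R, spec$gamma, spec$seed)
  boosted <- which(meta$subnetwork %in% spec$designated)
  ## connection radius calibrated once on the control geometry; the boost
  ## adds intra-designated hub edges on top of that budget
  mu <- .psCalibrate(.psDistances(latent), round(avgDeg * R / 2),
                     spec$temperature)
  if (spec$hierarchyShift > 0 && spec$temperature < 1e-8)
    stop("hierarchyShift > 0 requires temperature > 0")
  if (spec$hierarchyShift > 0) {
    xB <- .psBoostDesignated(.psDistances(latent), latent$rho, boosted,
                             spec$hierarchyShift, spec$edgeDensity,
                             spec$temperature)
    nPairs <- R * (R - 1) / 2
    expDens <- sum(.psProbsAt(xB, mu, spec$temperature)[upper.tri(xB)]) /
      nPairs
    if (expDens > min(2 * spec$edgeDensity, 0.5))
      stop("hierarchyShift too large to keep density in bounds: expected ",
           "boosted-group density ", round(expDens, 3), " vs target ",
           spec$edgeDensity)
  }
  set.seed(spec$seed + 17L)
  nSubj <- 2L * spec$nPerGroup
  ages <- stats::setNames(stats::rnorm(nSubj, spec$ageMean, spec$ageSd),
                          sprintf("subj%03d", seq_len(nSubj)))
  graphs <- list()
  for (i in seq_len(nSubj)) {
    grp <- if (i <= spec$nPerGroup) "HC" else "SCD"
    lat <- latent
    set.seed(spec$seed + 100L * i + 7L)
    if (spec$subjectJitter > 0)
      lat$theta <- (lat$theta +
                      stats::rnorm(R, 0, spec$subjectJitter)) %% (2 * pi)
    if (spec$subjectRhoSd > 0)
      lat$rho <- pmax(lat$rho + stats::rnorm(R, 0, spec$subjectRhoSd), 0)
    xCtrl <- .psDistances(lat)
    x <- if (grp == "SCD" && spec$hierarchyShift > 0)
      .psBoostDesignated(xCtrl, lat$rho, boosted, spec$hierarchyShift,
                         spec$edgeDensity, spec$temperature)
    else xCtrl
    g <- .psGraphFromX(x, mu, spec$temperature, noiseSd = spec$noiseSd,
                       seed = spec$seed + 100L * i,
                       subjectId = names(ages)[i],
                       session = spec$sessions[1], group = grp,
                       nodeMeta = meta)
    graphs[[length(graphs) + 1L]] <- g
    if (length(spec$sessions) > 1L) {
      for (sI in seq.int(2L, length(spec$sessions))) {
        graphs[[length(graphs) + 1L]] <-
          .rewireGraph(g, frac = 0.05, seed = spec$seed + 100L * i + sI,
                       session = spec$sessions[sI])
      }
    }
  }
  list(graphs = graphs, ages = ages,
       truth = list(designated = spec$designated,
                    delta = spec$hierarchyShift, boostedNodes = boosted))
}
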
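---
title: "Hyperbolic embedding of MEG functional connectivity networks: models and methods"
author: "hyperMEG authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperbolic embedding of MEG functional connectivity networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperMEG)
```

## The problem

Resting-state MEG source activity, parcellated into the 90 regions of the
AAL atlas and summarized as phase-locking values (PLV), yields one weighted,
symmetric 90x90 functional connectivity matrix per participant and session.
Brain networks of this kind are approximately scale-free with a tree-like
hierarchical backbone: the number of nodes grows exponentially as one moves
from hub regions toward the periphery. Euclidean embedding spaces expand
only polynomially with radius and therefore distort such graphs badly at
low dimension; hyperbolic space, whose volume grows exponentially with the
distance from the center, matches the growth rate of the graph. This
package embeds PLV networks into low-dimensional Poincare balls with a
hyperbolic graph convolutional network (HGCN), benchmarks the embeddings by
link prediction, and uses the *hyperbolic radius* of each node embedding —
its geodesic distance from the ball center — as a proxy for hierarchical
position: hubs embed near the center (small radius, high hierarchy),
peripheral nodes near the rim.

## From phases to graphs

The PLV between two regions averages, over all pairs of beamformed sources
in the two regions, the magnitude of the epoch-time-averaged unit phasor of
the phase difference. The defining sum is evaluated per epoch and the
per-epoch values are averaged (common MEG practice); a `pooled` flag
concatenates epochs into one window instead, since the combination rule is
a genuine free choice at this level. PLV is invariant to a common phase
offset, and lies in [0, 1] up to a finite-sample positive bias of order
1/sqrt(T) for unlocked signals.

Each connectivity matrix is binarized at a PLV threshold of 0.329 (which
retains roughly 20% of edges in alpha-band resting-state PLV matrices; a
target-density mode chooses the threshold as the corresponding quantile of
each matrix instead). The comparison is strict (`>`), so ties at the
threshold drop — a deterministic rule. Separately, the PLV values are
min-max scaled to [0, 1] *within each graph* and kept as continuous
edge-probability targets. Per-graph scaling is used because it makes every
graph's targets span the full unit interval regardless of the
participant's overall synchronization level; a global scaling can be
requested by passing explicit bounds.

## Poincare-ball geometry

All geometry lives on the open ball of radius `1/sqrt(|K|)` for curvature
`K < 0`. The package implements the geodesic distance, origin exponential
and logarithmic maps, Mobius (gyrovector) addition and matrix-vector
multiplication, a pointwise hyperbolic activation (log-map, apply the
Euclidean nonlinearity, exp-map), and the weighted Frechet mean. Only
origin-based maps are exposed: every model operation is defined through
the tangent space at the ball center. Numerical policy: points are clamped
to radius `(1 - 1e-5)/sqrt(|K|)` after every ball-valued operation, and
`arccosh`/`artanh` arguments are clamped into their domains by `1e-15`.
In the flat limit `|K| -> 0` the distance approaches twice the Euclidean
distance, which is what justifies treating an ordinary GCN as the
flat-curvature special case of the HGCN.

The Frechet mean is defined here as the minimizer of the *weighted sum of
squared* geodesic distances (the Karcher mean). The squared form is the
standard differentiable formulation and reduces to the arithmetic mean in
the flat limit; the solver is a damped Karcher fixed-point iteration
(tangent-space averaging at the current iterate), initialized at the
input point of largest weight, with tolerance `1e-8` on the objective and
a step-halving guard that makes the objective provably non-increasing.
The full-step iteration can enter a period-2 oscillation when some points
lie close to the ball boundary; the damped step (factor 0.5) converges in
all regimes, which is why both the solver and the unrolled in-model
aggregation use it.

## The HGCN

The model is a two-layer graph convolution operating on the ball:

1. **Input lift.** Node features are one-hot identity vectors, lifted into
   the ball of the hidden curvature K1 by the origin exponential map.
2. **Feature transform** (per layer): Mobius matrix-vector multiplication
   by the layer weights followed by Mobius addition of a bias. The bias is
   stored as an unconstrained Euclidean vector and lifted by the
   exponential map, keeping all parameters unconstrained for the
   optimizer.
3. **Frechet aggregation** over the closed neighborhood {N(i), i} with
   uniform weights (the weighting is a free choice at this level; uniform
   is the natural default for a mean-aggregator). Inside the model the
   mean is an unrolled, damped Karcher iteration (15 iterations by
   default), which agrees with the converged solver to ~1e-5 geodesic
   distance for the point configurations that arise in the layers.
4. **Hyperbolic ReLU** into the next layer's curvature.

The hidden layer has dimension 6 and curvature K1; the output layer has
dimension D and curvature K2. Two curvatures are exposed because the
benchmark reports exactly two learned values per dimension; the input lift
shares K1. In `fixed` mode both are pinned to -1; in `learned` mode each
is parameterized as `K = -softplus(raw)`, which keeps curvature strictly
negative without constraints, initialized at -1 so epoch 0 matches the
fixed model.

**Decoder and loss.** Link probabilities come from the Fermi-Dirac decoder
`p = 1/(exp((d^2 - r)/t) + 1)` with `r = 2`, `t = 1`, applied to squared
geodesic distances between output embeddings. Training minimizes the mean
squared error between these probabilities and the min-max scaled PLVs over
all off-diagonal pairs — a dense regression target, so no negative
sampling is needed. This recovers the continuous connectivity information
that binarization discards.

**Optimization.** All parameters are Euclidean after reparameterization,
so plain Adam (betas 0.9/0.999, lr 0.02, batch size one graph, 100 epochs
by default) implements the Riemannian optimization in practice. Gradients
flow through every geometric operation — including the unrolled Frechet
iteration — via a small reverse-mode tape implemented in the package
(`R/autodiff.R`); the analytic gradients are verified against central
finite differences to ~1e-7 relative error in the test suite.

**Baselines.** The Euclidean GCN has the identical architecture with
arithmetic-mean aggregation, ReLU, and the same decoder on squared
Euclidean distances; in the `|K| -> 0` limit the HGCN's log-mapped
embeddings coincide with it. The shallow Poincare embedding optimizes free
per-node coordinates at `K = -1` by Riemannian gradient descent on a
negative-sampling softmax over distances (10 negatives per edge, a
10-epoch burn-in at lr/10): it is transductive and feature-free, the
classical contrast to the inductive HGCN.

## Link-prediction evaluation

Cross-validation is grouped by participant: all sessions of a subject
share a fold, so no subject contributes to both training and evaluation.
For the graph-convolution models, evaluation is fully inductive — the
trained model embeds an unseen subject's graph and MAP (mean average
precision: per-node average precision of true neighbors under descending
score ranking, ties broken by node index, averaged over nodes and graphs)
is computed over all pairs. The shallow model is transductive by nature,
so it is fit per test graph on a random 80% of edges and scored on the
masked 20%, with training edges excluded from the candidate rankings. The
two protocols are recorded in the report so the asymmetry is explicit.

## Hierarchy analysis

The per-node radius is the geodesic distance from the origin at the
learned output curvature (not the Euclidean coordinate norm), which is
rotation-invariant — hierarchy carries no directional information. Radii
are averaged within eight functional subnetworks (pDMN, aDMN, DAN, FPN,
VN, VAN, SN, SMN). The shipped AAL-to-subnetwork table is an approximate
literature-based assignment (proximity of AAL regions to canonical
functional networks) and is explicitly a replaceable configuration file;
any study-specific table with columns `roi`, `hemisphere`, `subnetwork`
can be supplied.

Group inference uses a covariate-adjusted linear contrast on subject-level
radii (sessions averaged per subject, age as the default covariate),
either with its t-test or with a subject-level permutation null (exact
enumeration when feasible), followed by Benjamini-Hochberg FDR correction
across the eight subnetworks. A repeated-measures ANCOVA with a
time-by-diagnosis design is the classical analysis for two-session cohort
data of this shape; the shipped inference path deliberately reduces it to
the session-averaged adjusted contrast plus permutation, which tests the
same diagnosis main effect with fewer distributional assumptions.

Classification uses an SVM (RBF kernel, C = 1 — common defaults, a linear
kernel is a flag away) under stratified five-fold cross-validation, with
features standardized inside each training fold, on three feature sets:
vectorized upper-triangle PLVs (4005 values), per-node radii (90 values),
or both. Features default to pre-intervention sessions only.

## The synthetic cohort generator

No MEG recordings ship with the package; every empirical claim the tests
make is evaluated on synthetic cohorts with known ground truth. The
generator emulates, by construction rather than by fitting:

- **Scale-free, tree-like topology** via a popularity-similarity rule:
  node i has a random angular position and radial coordinate growing like
  `log(i)` (power-law exponent `gamma = 2.5`), and pairs connect with
  probability decaying in their latent hyperbolic distance at temperature
  0.15, calibrated so the expected density is 0.20 — the regime produced
  by the 0.329 PLV threshold.
- **A shared cohort backbone**: one latent configuration is drawn per
  cohort and each subject perturbs it (angular jitter sd 0.15 rad, radial
  jitter sd 0.3, independent edge sampling, weight noise sd 0.05). Real
  participants share gross connectome organization — alpha-band PLV
  matrices correlate strongly across subjects — while differing in
  individual hub strength; the radial jitter is what gives subnetwork
  radii realistic between-subject variance. These levels are a single
  realism-motivated choice used by every experiment in the package.
- **Two sessions** per subject by rewiring 5% of edges (value-preserving
  swaps), exercising the fold-grouping logic.
- **An implanted hierarchy difference**: in group 2 ("SCD"), the latent
  distances *within* the designated subnetworks (DAN, FPN, VAN by
  default) shrink by `hierarchyShift` times the endpoints' radial
  coordinates, adding preferential intra-subnetwork hub edges. The boost
  is deliberately confined to designated-designated pairs so that every
  other node's adjacency distribution is untouched and the implanted
  ground truth is localized; an error is raised when the shift would push
  the boosted group's expected density out of bounds. Ages are drawn from
  N(71, 4.5) per subject, matching a typical elderly cohort.

What the generator does **not** emulate: volume conduction and source
leakage, genuine oscillatory dynamics (the oscillator module generates
phases with programmed coupling for PLV validation, not biophysics),
inter-regional distance effects, or measurement artifacts. Passing
recovery tests therefore demonstrates that the pipeline detects localized
hubness differences transmitted through embedding radii under realistic
cohort variability — not that it would detect SCD in real MEG data.

## Problem sizes used by the test suite

The validation experiments are scaled to desk-top problem sizes chosen
once: the model-comparison check uses 20 synthetic 90-node graphs at
density 0.20, D = 2, 25 training epochs, and one held-out fold per seed
across 5 seeds; the hierarchy-recovery check uses cohorts of 20 subjects
per group (single session) with a 0.25 hubness shift, a learned-curvature
D = 3 model trained for 12 epochs (best of 2 restarts by training loss)
on 8 graphs and embedding all 40, 500-draw permutation tests, and 8
effect plus 3 null replicates; the statistical layer is additionally
validated on directly implanted radius shifts (0.15 against subject noise
0.05, 20 replicates). The Frechet-mean oracle comparison runs the
brute-force Riemannian descent (4000 steps, finite-difference gradients)
on 100 random 5-10 point configurations across three curvatures. These
sizes are the package's validation design; the underlying functions
accept arbitrary sizes.

## Known limitations

- The reverse-mode tape is minimal by design: no GPU, no batching across
  graphs; training cost is dominated by the unrolled Frechet iterations.
- The damped Karcher aggregation is an approximation to the exact Frechet
  mean (~1e-5 geodesic error at the default 15 iterations for in-model
  point spreads); tests compare against the converged solver and against
  an independent brute-force oracle.
- Radius-based inference inherits the identifiability caveat of all
  embedding methods: radii are only meaningful relative to the trained
  model, so group comparisons must use embeddings from one model (the
  pipeline trains one model per cohort and embeds everyone with it).
- The shipped subnetwork table is approximate; subnetwork-level results
  on real data should be recomputed with the study's own assignment.
- A localized hubness difference still perturbs the whole graph (the
  extra edges change two-hop neighborhoods and overall density), so the
  embeddings of *unaffected* subnetworks acquire small systematic group
  shifts (on the order of 0.03-0.1 radius units in the recovery
  experiments, versus 0.1-0.3 for the implanted subnetworks). With
  realistic cohort sizes the permutation test occasionally reaches
  significance on these second-order shifts; exact specificity of the
  flagged set therefore cannot be guaranteed by the pipeline and is
  reported alongside sensitivity rather than assumed.
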
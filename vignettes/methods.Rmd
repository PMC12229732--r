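---
title: "Detecting anomalous records in regional crop-yield tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting anomalous records in regional crop-yield tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrioutlier)
```

## The problem

A regional agronomic table records, per cultivated plot, soil chemistry
(N, P, K in kg/ha, pH, EC in dS/m), weather (temperature in °C, rainfall in
mm), production figures (area in ha, production in t, yield in kg/ha),
categorical crop/season/soil labels, and coordinates in decimal degrees.
Three mechanistically different kinds of records corrupt such tables:

* **global outliers** — gross measurement or data-entry errors, far from
  the bulk of the data in at least some coordinates;
* **spatial outliers** — values that are plausible somewhere in the region
  but not where they claim to be (e.g. a red-soil nutrient profile recorded
  inside a black-soil zone);
* **multiview-inconsistent records** — each block of fields is marginally
  plausible, but the combination is not (e.g. chemistry from one plot
  accidentally merged with production figures from another).

No single detector covers all three, which is why the package implements a
panel of six and a benchmark harness to compare them under known ground
truth.

## The detectors

**Iterative IQR filtering.** Per feature, quartile fences
$[Q_1 - k\,\mathrm{IQR},\; Q_3 + k\,\mathrm{IQR}]$ with
$\mathrm{IQR} = Q_3 - Q_1$; a record is removed if *any* feature violates
its fence (records are removed whole), the quartiles are re-estimated on
the survivors, and the loop runs to a fixed point. Re-estimation counters
masking: one gross value can inflate the IQR enough to hide milder
anomalies until it is removed. `k` defaults to 1.5 (the common fence
multiplier; 3.0 is the conservative alternative), `max_iterations` to 100,
which in practice is never reached — the procedure is a monotone removal
process and stops on its own. The score is the removal iteration, so
earlier removal = grosser anomaly; survivors score 0.

**Mahalanobis elliptic envelope.** Assumes an approximately Gaussian
inlier cloud; scores are $D^2_M(x) = (x-\mu)^\top \Sigma^{-1} (x-\mu)$
with sample mean and covariance, and the boundary is the $\chi^2_d$
quantile at `confidence` (default 0.95), since $D^2_M \sim \chi^2_d$ under
the model. The estimator is deliberately the plain sample mean/covariance —
exactly checkable against a hand-written oracle — with a one-step trimmed
refit (`robust = TRUE`) available when swamping by gross outliers is a
concern: the envelope is refit on the 50% of records with the smallest
initial distances.

**PCA + Euclidean envelope.** Projects the centred, standardized features
onto the smallest set of principal components explaining ≥ 95% of variance
(`n_components` also accepts an explicit count), scores each record by its
Euclidean distance to the centre of the projected cloud, and thresholds at
the 95th percentile of those distances. Unlike the Mahalanobis envelope it
makes no elliptic assumption: the retained components capture the dominant
structure, and the isotropic distance tolerates skewed or irregular
shapes. With `n_components = d` the score is exactly the centred Euclidean
norm (orthogonal transforms preserve distances), which the tests exploit.

**Isolation forest.** 100 random binary trees, each grown on a seeded
subsample of ψ = 256 records by splitting a uniformly random feature at a
uniformly random point, height-capped at ⌈log₂ ψ⌉. Anomalies isolate in few
splits. Path lengths are completed with the standard
$c(m) = 2H(m-1) - 2(m-1)/m$ adjustment (expected unsuccessful-search depth
in a binary search tree) at capped leaves, and the score is
$2^{-E[h(x)]/c(\psi)}$. The threshold is the (1 − contamination) score
quantile, with `contamination` defaulting to 0.1 when unknown.

**One-class SVM.** Separates the data from the origin in RBF feature space;
`nu` (default: the assumed contamination) upper-bounds the flagged training
fraction and lower-bounds the support-vector fraction. The convex
ν-parameterized dual is solved by libsvm via **e1071** — the package's
contract is the dual solution (normalized weights in $[0, 1/(\nu n)]$
summing to 1) and the decision function $g(x)=\sum_i \alpha_i K(x_i,x)-\rho$,
not the solver; an exact KKT active-set enumeration oracle in the test
suite verifies the dual on small linear-kernel problems. Decision values
within $10^{-6}\,\max|g|$ of the boundary are snapped to 0, because free
support vectors sit exactly on the boundary at the optimum and ties count
as inliers. The RBF width defaults to the pooled-variance heuristic
$\gamma = 1/(d\,\mathrm{var}(x))$.

**Truncated-SVD residuals.** The column-centred feature matrix is
approximated by its rank-r truncated SVD (r = smallest rank retaining 90%
of squared singular-value energy by default) and each record is scored by
its residual row norm. By Eckart–Young, the squared Frobenius norm of the
residual equals the sum of the discarded squared singular values — asserted
in the tests to 10⁻⁸ relative. Requesting full rank is rejected: residuals
would vanish identically.

**Spatial multiview detection (SMVOD).** Two similarity views are built:
$W_s = \exp(-D^2/\sigma^2)$ on pairwise coordinate distances, and $W_f$,
the same Gaussian kernel on standardized feature distances. They are fused
as the convex combination $S = \alpha W_s + (1-\alpha) W_f$, α = 0.5 by
default. The per-record score is **one minus the mean of the k largest
off-diagonal fused similarities** (k = max(5, 2.5% of n)).

The top-peer form is the one genuinely open design point in the package,
so its rationale deserves a paragraph. A natural first idea — one minus the
*row mean* of S — cannot detect spatial swaps even in principle: the row
mean of a convex combination is the convex combination of the row means,
and a swapped record is typical under each view *marginally*; only the
*joint* pattern (its spatial neighbours are not its feature peers) is
anomalous. The top-peer score captures exactly that interaction: an
ordinary record has neighbours that are similar under both views at once,
so its best fused similarities approach α·1 + (1−α)·1, while a swapped
record has no row that is close in both views simultaneously and even its
best peers are depressed. The form also keeps every property one wants
from such a score: it is bounded in [0, 1], permutation-equivariant,
monotone in every similarity (so widening σ weakly lowers scores), reduces
to a purely spatial detector at α = 1 and a purely feature-based one at
α = 0, and is zero for identical records at identical locations.

Bandwidths use the median heuristic: σ defaults to the median off-diagonal
pairwise distance (an error is raised if all points coincide), and the
feature-view bandwidth is the median pairwise feature distance. Spatial
distance is Euclidean on decimal degrees by default — over a regional
extent of roughly 0.4° × 0.9° the metric distortion is immaterial for
*ranking* — with WGS84 great-circle kilometres available via
`distance = "greatcircle"`.

## Conventions shared by all detectors

* **Strict thresholds.** A record is flagged iff `score > threshold`; ties
  are inliers. With distinct scores, a 95th-percentile threshold on 100
  records flags exactly 5.
* **Quantiles** are type-7 (linear interpolation), R's default, recorded in
  each result's `params`.
* **Standardization** divides by the population standard deviation
  (divisor n), the common convention in anomaly scoring where the data at
  hand *is* the population being screened; `scale_type = "sample"` gives
  the n−1 convention. Constant columns get scale 1 and become zeros rather
  than NaN.
* **Feature routing.** The ten numeric agronomic measurements feed the
  detectors; latitude/longitude go only to the spatial methods; categorical
  columns never enter distance computations. Rows with missing features are
  dropped with a message — no imputation is attempted, none being defensible
  without a model of the missingness.
* **Numerical safeguards.** The envelope covariance receives a
  `1e-8 · mean(diag(Σ))` ridge before inversion and aborts if it is still
  numerically singular; degenerate inputs (all rows identical) yield
  all-zero scores and no flags rather than errors.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` + `generate_dataset()` produce labeled tables that mimic
the structure the detectors assume, with defaults taken from the magnitudes
visible in the published sample records of the emulated study region
(bounding box 14.20–14.60° N, 75.65–76.56° E; N ≈ 250 ± 45 kg/ha,
pH ≈ 7.8 ± 0.85, yield ≈ 2170 ± 450 kg/ha, and so on):

* **Inliers** are drawn from a correlated multivariate Gaussian: positively
  correlated N/P/K, pH tied to EC, temperature against rainfall, a strong
  area–production–yield block, and moderate nutrient/rainfall effects on
  yield so the two natural views (chemistry vs. production) are not
  independent.
* **Spatial structure** comes from `n_spatial_clusters` (default 4)
  coordinate blobs around greedily spread centres, with cluster-level
  feature offsets. The offset magnitude, `cluster_contrast`, defaults to 3
  within-zone standard deviations: zones must be *clearly* distinct for
  "right values, wrong place" to be an anomaly at all — at contrast ≈ 1 a
  swapped record differs from its neighbourhood by about one local standard
  deviation and is undetectable in principle, not merely in practice, since
  zone overlap erases the signal for any neighbourhood-based method.
  Sharply differing adjacent soil zones are typical of the emulated region,
  where red, black and alluvial soils interleave. Cluster-level offsets
  (rather than a smooth Gaussian process) keep the generator fast and make
  cluster membership available to the swap injector. Set
  `cluster_contrast = 0` for a spatially homogeneous table — the test suite
  uses exactly that configuration to verify the Gaussian core (marginal
  normality screens at n = 2000), which the zone structure otherwise
  deliberately violates.
* **Outliers** are injected at an exact count, `round(contamination · n)`,
  split over the three kinds by `outlier_mix` (largest-remainder
  allocation): global outliers are displaced by `global_shift_sigmas`
  (default 6) marginal standard deviations along a random sign pattern over
  at least half the features; spatial outliers keep their coordinates but
  receive the full feature vector of an inlier from a different zone;
  multiview outliers get each half of their feature vector from a different
  inlier donor.
* **Determinism.** One master seed drives per-stage child seeds, so the
  generator is a pure function of its spec and adding an injector never
  perturbs earlier stages.

Deliberate non-features: Gaussian tails are *not* truncated at physical
bounds (truncation would distort the distribution the detectors assume, and
`validate_schema()` correctly reports the occasional resulting negative
value as a range finding); there is no temporal structure; no attempt is
made to fit the actual regional dataset, which is not publicly deposited;
and missingness is limited to an optional uniform masking rate. Passing
benchmarks on these tables therefore shows that each detector recovers the
*mechanism* it targets under clean conditions — it does not certify
performance on real tables, whose contamination is rarely so well
separated into kinds.

## Benchmarking

`run_benchmark()` evaluates any configured subset of the detectors against
ground-truth labels, with "outlier" as the positive class throughout —
worth stating prominently, because with 5% contamination an accuracy of
0.95 is achievable by flagging nothing. Zero-denominator metrics (no
positives, or nothing flagged) return 0 with a `degenerate` flag instead of
erroring, so comparison tables never abort; a failing detector is recorded
as a failed row and the rest still run; unlabeled input is refused rather
than inventing labels. Reports serialize to JSON and print as a
4-decimal text table.

The test suite exercises the pipeline at modest, desk-scale sizes — 500-row
benchmarks, ten-seed recovery averages, 8 × 5 oracle matrices — chosen so
the whole suite stays fast while every statistical claim is still a
multi-seed average rather than a single draw.

## Known limitations

* The iterative IQR procedure treats features independently (union rule);
  correlated-but-individually-typical anomalies are invisible to it.
* The Mahalanobis envelope needs n > d and a non-degenerate covariance;
  with heavy contamination its plain sample estimates can swamp (use
  `robust = TRUE`).
* SMVOD builds dense n × n similarity matrices — quadratic memory, fine for
  desk-scale regional tables, inappropriate beyond ~10⁴ rows without
  sparsification, which is out of scope.
* Euclidean-on-degrees distance is anisotropic away from the equator; for
  ranking within a sub-degree box this is negligible, but use the
  great-circle option for larger extents.
* Categorical fields are validated but never scored; a detector for
  label-level anomalies (e.g. the fixture's `"Maize"` soil cell) would need
  a different similarity model.
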
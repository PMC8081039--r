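---
title: "Methods: quantitative worm phenotyping and molecular profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative worm phenotyping and molecular profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wormdev implements the quantitative backbone of a *C. elegans*
developmental-phenotyping study: body-length morphometry from single-worm
images, logistic growth-curve summaries and developmental timings from
long-term imaging, bootstrap estimation statistics, bulk RNA-seq
differential expression with projection onto a reference developmental
time course, and a lipidomics testing pipeline. Every input class can be
simulated with known ground truth, so each estimator is scored against the
quantity it is supposed to recover. This vignette records the models, the
defaults and why they were chosen, and what the synthetic benchmarks do
and do not demonstrate.

```{r setup}
library(wormdev)
```

## Body-length morphometry

A larva in a grayscale image is measured in four stages:

1. **Segmentation.** An intensity threshold, by default chosen to minimize
   the intraclass intensity variance of the histogram (Otsu's criterion);
   a fixed threshold is available. Foreground polarity (bright worm on a
   dark field or the reverse) is auto-detected as the minority class, and
   a forced polarity that leaves most pixels in the foreground raises a
   warning.
2. **Debris removal.** Only the largest 8-connected component is kept. A
   second component larger than 5% of the largest flags
   `qc_multiple_components`; ties are broken by scan order.
3. **Skeletonization.** Zhang–Suen iterative thinning produces a
   one-pixel-wide, 8-connected medial skeleton after a 3×3 opening that
   suppresses single-pixel boundary noise.
4. **Longest geodesic path.** A two-pass farthest-point search on the
   skeleton graph (orthogonal steps weight 1, diagonal steps √2) extracts
   the head-to-tail path; side branches fall off the path, which makes
   spur pruning parameter-free. `path_length()` reports the bit-exact
   chamfer (1, √2) length of any pixel path.

### Why the default length is not the raw chamfer length

Two systematic artifacts of digital skeletons were measured on synthetic
worms with analytically known centerline length:

* the chamfer (1, √2) length of an 8-connected digital curve
  overestimates the true arc length by up to ~8% depending on local
  orientation (zero for axis-aligned and exactly diagonal segments, maximal
  near 22.5°), and
* iterative thinning retracts the skeleton ends, by roughly the cap
  radius for axis-aligned ends but by up to ~12 px for diagonally
  oriented ends.

The two biases partially cancel on average but individually reach several
percent of an L1-scale worm, and their net sign depends on posture. The
default `measure_worm_length()` therefore (a) fits smoothing splines to
the path coordinates against cumulative chamfer distance and integrates
their arc length, which removes the orientation bias, and (b) extends
both path ends along the local tangent to the mask boundary minus the
estimated cap radius. The cap radius comes from the area relation
`area = 2·r·L + π·r²` of a tube of half-width `r`; the medial axis of such
a tube runs the *full* centerline, so end retraction is a thinning
artifact, not a property of the ideal skeleton. On 100 synthetic worms
(150–300 µm, varied curvature and noise) the default estimator's median
absolute relative error is ~0.5%, against ~3.7% (worst case −20%) for the
raw chamfer composition. Both smoothing and tip extension can be disabled
(`smooth_path = FALSE`, `extend_tips = FALSE`) to obtain the bit-exact
chamfer reference output.

Coiled, self-overlapping worms are flagged
(`qc_self_overlap_suspected`, via a cycle in the skeleton graph after
removing corner-cutting diagonals) but not unfolded: unfolding requires
assumptions about the occluded geometry that a single threshold mask
cannot support.

## Growth curves, timings and the windowed ratio bootstrap

Per-animal length trajectories are summarized by the three-parameter
logistic

\[ L(t) = \frac{L_{max}}{1 + e^{-k (t - t_0)}} \]

fit by Levenberg–Marquardt least squares. Starting values are derived
from the data — `l_max` from 1.05× the maximum length, `t_0` from the time
of steepest smoothed increase, and `k` from the logistic identity
`max slope = k·L_max/4` — because the model is standard but optimizer
setup is not; with these starts a noiseless series is recovered to
better than 1e-4 relative error and 5% multiplicative noise at 3-minute
sampling over 65 h leaves median parameter errors well under 1%.
Non-convergence is flagged honestly, with the best parameters and RSS
still returned.

Developmental timings decompose as ex-utero (egg laid → hatch), larval
(hatch → first egg) and generation (egg laid → first egg) intervals, so
generation time is exactly the sum of the two sub-intervals whenever all
three events are observed; missing events propagate to the intervals that
need them, and out-of-order events reject the record.

The windowed ratio bootstrap compares two groups' body lengths across
development without assuming a growth model. Time is tiled into 15
half-open windows of 4 h 16 min starting at 0 h — exactly covering
[0, 64 h) — so every measurement belongs to exactly one window. Within a
window, one measurement is drawn uniformly with replacement from each
group; if the two measurement times differ by more than 1.5 h the draw is
rejected and redrawn (resample-until-accept keeps exactly B = 1000 ratios
per window; a cap of 100·B attempts marks infeasible windows as empty
rather than spinning). The sampling unit is a single (animal, time)
measurement, not an animal, matching the per-ratio time-difference rule.
Ratios are oriented test/reference (mutant over wild type). Each window
reports the mean ratio and the percentile interval of the accepted draws.
Under identical generating populations the 95% intervals cover 1.0 in
well over 93% of simulated cohorts; the interval is conservative because
measurement-level resampling mixes within- and between-animal variation.

Median growth curves interpolate each animal onto a common grid and report
the across-animal median with a percentile bootstrap CI of the median
(resampling animals), requiring at least 3 contributing animals per grid
point.

## Estimation statistics

`mean_difference()` implements the estimation-graphics effect size: the
unpaired mean difference with a bias-corrected-and-accelerated (BCa)
bootstrap CI, resampling the two groups independently (default
B = 5000; B < 1000 is refused). The acceleration is computed from a
jackknife over every observation; when it is undefined (all jackknife
values equal) the percentile interval is used and recorded in the output.
A zero-variance degenerate input collapses the CI to a point and is
flagged. `percent_of_control()` reports 100·mean(test)/mean(control) with
the same machinery; the ± form often quoted next to such numbers is the CI
half-width. Coverage of a true mean difference is 93–97% over 1000
normal simulations at n = 20/20.

## Transcriptome analysis

Starting from a gene × sample integer count matrix:

* **Normalization.** Median-of-ratios against a pseudoreference (gene-wise
  geometric mean over genes with no zero count). Factors are stabilized to
  unit geometric mean, which makes normalization idempotent and factor
  ratios exactly scale-equivariant; factors are only defined up to a
  common scale, so this costs nothing.
* **Dispersion.** Method-of-moments gene dispersions pooled within
  groups, `α = max(0, (s² − ξµ)/µ²)` with `ξ = mean(1/sf)` absorbing the
  extra Poisson variance of depth division, then a local linear
  regression (loess) of log α on log µ over genes with positive raw
  dispersion gives the trend; testing uses `max(raw, trend)` per gene,
  guarding against underestimated dispersions at the 3–5 replicates
  typical of such designs. With fewer than 50 usable genes a parametric
  `a0 + a1/µ` fallback is fit and flagged.
* **Testing.** An exact conditional negative-binomial test: the gene's
  total count across both groups is held fixed, the probability of every
  split between group sums is enumerated under NB laws whose means scale
  with the summed size factors (group-sum variance
  `Σ_j s_j q + α q² Σ_j s_j²`), and the two-sided p-value is the
  normalized probability of splits no more likely than the observed one.
  The upstream tool named for this analysis does not document its exact
  p-value construction, so the package commits to this enumeration
  definition and verifies it against an independent oracle; on null
  simulations its p-values are uniform to KS distance < 0.05.
* **Multiple testing and calling.** Benjamini–Hochberg step-up; genes with
  zero total count are excluded from the testing universe. DE calls
  require q < 0.01 and a fold change beyond 2 in either direction, with
  fold changes computed as `(mean_test + ε)/(mean_control + ε)`,
  ε = 0.5 normalized counts, recorded in the output.
* **PCA and embedding.** Expression is log2(x+1)-transformed (the offset
  avoids log 0 on counts) and gene-centered; PCA is the
  eigen-decomposition of the sample covariance, reported with orthonormal
  gene-space eigenvectors and explained-variance fractions. For
  pseudotime staging, eigenvectors and the centering vector are computed
  from the reference time course **alone**, and query samples are
  centered with the *reference* means before projection onto the first
  k = 10 eigenvectors; the nearest reference sample in score space gives
  the stage label. Centering queries by their own means is available
  (`center_query = "query"`), but the reference-mean default is the
  choice that makes a query identical to a reference profile land exactly
  on that profile, which is the property staging relies on.

## Lipidomics

Lipid tables carry internal-standard-corrected abundances with exact
zeros encoding non-detects. The pipeline follows two distinct paths:

* For **testing**: the detection filter keeps lipids detected in at least
  `floor(n/2) + 1` samples (the integer-safe reading of "half plus one";
  an all-samples rule is available behind a flag since summaries of such
  experiments sometimes quote that stricter universe). Samples are then
  normalized by their total detected lipid abundance (columns sum to 1),
  and group comparisons use classical pooled-variance two-sided t-tests
  on the normalized linear scale — matching the stated equal-means
  hypothesis — with BH adjustment (a Storey-style positive-FDR variant is
  selectable). Tests are run on normalized, not z-scored, data: z-scoring
  destroys the mean structure a t-test examines.
* For **PCA**: a small offset (1e-6) is added before log10, then each
  lipid is converted to z-scores across samples; PCA runs on that matrix.

Consistency calling takes per-comparison results (test group against the
control group at each control timepoint), flags significance per
comparison at FDR < 0.05, and reports lipids significant in *all*
comparisons (consistent), in *any* comparison (union), and per-class
tallies.

## Synthetic data: what it emulates and what it does not

* `gen_worm_image()` sweeps a disk along a parametric sine whose arc
  length is solved numerically, giving an analytic ground-truth length and
  realistic blunt ends; background gradient plus additive Gaussian noise
  stand in for uneven illumination and camera noise. Real micrographs
  add optics the generator does not model (defocus, vignetting, internal
  worm texture, touching objects), so passing accuracy benchmarks here
  bounds digitization and algorithmic error, not segmentation difficulty
  on hard real images.
* `gen_growth_series()` produces logistic trajectories with multiplicative
  noise at a 3-minute cadence over 65 h, the sampling regime of long-term
  single-worm imaging; real trajectories contain molts and posture-driven
  length fluctuations that are not logistic.
* `gen_counts()` draws NB counts with log-normal gene means (meanlog
  log 30, sdlog 1.5), dispersion trend `0.01 + 1/µ`, log-normal size
  factors (sdlog 0.2), and spiked ±1 log2 fold changes in 10% of genes —
  the standard parametric idealization of bulk RNA-seq; real data add
  outliers and correlated genes.
* `gen_reference_timecourse()` gives per-gene monotone-in-expectation
  log-linear trajectories so that adjacent timepoints correlate more than
  distant ones, the property staging exploits.
* `gen_lipid_table()` draws log-normal baselines spanning decades
  (CV ≈ 25% within groups), applies a multiplicative effect (default: 9
  affected lysophospholipids at 2.5×, the shape of a signalling-lipid
  phenotype) and censors abundances below a detection limit set at the
  30th percentile of baselines plus 1% sporadic dropout, so roughly
  two thirds of lipids pass the half-plus-one filter, as in real worm
  lipidomes of a few hundred species. The sample layout is control
  samples at 50/53/56 h plus a test group at 50 h.

## Numerical choices and benchmark sizes

Tolerances and sizes used by the test suite, chosen as the package's own
benchmark design: 100 synthetic worms for morphometry accuracy (median
|relative error| ≤ 3%); noiseless logistic recovery to 1e-4 relative and
100 noisy replicates for the 5%/10%/10% medians; 200 simulated cohorts
for per-window null coverage (≥ 93%); 1000 normal simulations for CI
coverage (93–97%); BH and NB tests against brute-force oracles to 1e-12
and 1e-10; 20 spiked-DE simulations (5000 genes, 5 vs 5, 10% DE) for the
realized false-discovery proportion at q < 0.01 (≤ 0.05) and non-zero
recall. Bootstrap defaults: B = 5000 for effect sizes (CI stability at two
decimals), B = 1000 in the windowed ratio bootstrap and median curves.
Degenerate inputs (constant trajectories, zero-variance groups, zero-count
genes, zero-variance lipids, empty masks) are rejected or flagged rather
than silently absorbed; the specific behaviors are part of the tested
contract.

## Known limitations

* Coiled worms and worms touching the image border are flagged, not
  corrected; lengths from flagged measurements should be reviewed.
* The exact conditional NB test enumerates all splits of a gene's total
  count: exact and fast at bulk scale, but quadratic-feeling for extreme
  totals (millions), where a Wald-style approximation would be preferable.
* The dispersion trend assumes a smooth mean-dispersion relationship;
  strongly bimodal dispersion structure would be flattened.
* Lipid consistency calling treats comparisons as exchangeable and
  requires significance in every one; it does not model the correlation
  between comparisons sharing the same test group.
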
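# wormdev

Quantitative phenotyping and molecular profiling of *C. elegans*
development, as one tested, reusable R pipeline. The package is aimed at
worm labs (and anyone with similar data shapes) who need to go from raw
measurements — single-worm micrographs, length-versus-time tables from
long-term imaging, gene × sample count matrices, lipid abundance tables —
to the statistics such studies report: body lengths in µm, logistic
growth parameters, developmental timings, bootstrap effect sizes with
confidence intervals, differentially expressed gene sets, developmental
stage estimates, and consistently affected lipids. Every input class can
also be **simulated with known ground truth**, so the whole pipeline is
testable end to end without any external download.

## What it computes

* **Morphometry** — worm body length from a grayscale image: Otsu
  threshold segmentation, largest-component debris removal, Zhang–Suen
  thinning to a medial skeleton, longest geodesic path under the chamfer
  (1, √2) metric, then spline smoothing and tip-retraction compensation.
  Median |relative error| on synthetic worms of known centerline length is
  ~0.5%.
* **Growth and development** — per-animal logistic fits
  L(t) = L_max / (1 + e^(−k(t − t₀))); median growth curves with
  bootstrap CIs of the median; ex-utero / larval / generation timings;
  and a windowed bootstrap of between-group length ratios (15 half-open
  windows of 4 h 16 min tiling [0, 64 h), B = 1000 ratios per window,
  pairs rejected when the two measurement times differ by > 1.5 h).
* **Estimation statistics** — Gardner–Altman-style bootstrap mean
  differences and percent-of-control with BCa confidence intervals;
  hatch-rate summaries.
* **Transcriptome** — median-of-ratios (pseudoreference) size factors; a
  local-regression dispersion trend over method-of-moments gene
  dispersions; an exact conditional negative-binomial test (oracle-tested
  enumeration over splits of each gene's total count); Benjamini–Hochberg
  adjustment; DE calls at FDR < 0.01 and > 2-fold change; PCA; and
  projection of query samples onto the top-10 eigenvectors of a reference
  developmental time course for pseudotime staging.
* **Lipidomics** — half-plus-one detection filtering, total-abundance
  normalization, log10 + z-score transform for PCA, pooled-variance
  t-tests with FDR, and cross-timepoint consistency calling.

## Worked example

```r
library(wormdev)

# simulate a 210 um worm and measure it back
w <- gen_worm_image(210, amplitude_um = 12, period_um = 130, seed = 7)
measure_worm_length(w$image)
#> # A tibble: 1 x 5
#>   length_um n_foreground_px qc_multiple_components qc_touching_border ...
#> 1      209.            1606 FALSE                  FALSE
```

The measured 209 µm against the true 210 µm is a 0.4% error; the QC
columns flag debris, border clipping and suspected coiling.

```r
# logistic growth summary of a noisy trajectory (truth: 1000, 0.1, 30)
tr <- gen_growth_series(l_max_um = 1000, rate_per_h = 0.1, shift_h = 30,
                        noise_sd = 0.05, seed = 2)$trajectory
fit_logistic(tr)
#> <logistic_fit> l_max = 1001 um, rate = 0.09989 /h, shift = 29.95 h
#>   (rss 1.247e+06, converged)

# bootstrap mean difference between two groups of generation times (h)
ctrl <- c(62, 58, 64, 60, 59, 63, 61, 60)
mut  <- c(59, 57, 60, 58, 56, 61, 58, 59)
mean_difference(ctrl, mut, seed = 1)
#> <effect_size> mean_difference = -2.375, CI95% [-4.031, -0.75] (bca, B = 5000)
```

The mutant group develops on average 2.4 h faster, with a 95% BCa
interval of [−4.0, −0.75] h that excludes zero. `tidy()`, `glance()` and
`autoplot()` methods give tabular and graphical views of fits, effect
sizes and PCA models; `plot_growth_curves()`, `plot_gardner_altman()` and
`plot_ma()` produce the standard displays.

Batch runs are available through `run_pipeline()` (stages: `simulate`,
`measure-length`, `growth-fit`, `timings`, `ratio-bootstrap`,
`effect-size`, `rnaseq-de`, `embed`, `lipids`) or the thin CLI wrapper
`inst/scripts/wormdev-cli.R`, driven either by flags or a YAML config;
each run writes a JSON-lines log of its configuration and outputs.

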
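#' Simulate an RNA-seq count matrix with known differential expression
#'
#' Counts are negative-binomial draws with mean
#' `sf_j * mu_i * 2^(lfc_i * group_j)` and gene-wise dispersion from the
#' mean-dispersion trend `alpha(mu) = a0 + a1 / mu`, the standard decreasing
#' trend of bulk RNA-seq. A fraction `frac_de` of genes receive a spiked
#' log2 fold change of `+lfc` or `-lfc` (random sign) in the test group; all
#' other genes have log2 fold change exactly 0.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group (two groups: control, test).
#' @param size_factors Per-sample positive depth factors; default draws them
#'   log-normally around 1 (sdlog 0.2).
#' @param mean_law List with `meanlog`, `sdlog` for the log-normal law of
#'   gene base means.
#' @param trend_params Numeric `c(a0, a1)` of the dispersion trend
#'   `a0 + a1/mu`.
#' @param frac_de Fraction of genes differentially expressed, in \[0, 1\].
#' @param lfc Absolute log2 fold change spiked into DE genes.
#' @param seed Integer seed.
#'
#' @return A list with `counts` (integer matrix, genes x samples, dimnames
#'   set), `groups` (named character vector, `"control"`/`"test"`), and
#'   `truth` (list: `size_factors`, `gene_means`, `dispersions`, `de_genes`,
#'   `log2_fold_changes`).
#' @export
gen_counts <- function(n_genes = 5000,
                       n_per_group = 5,
                       size_factors = NULL,
                       mean_law = list(meanlog = log(30), sdlog = 1.5),
                       trend_params = c(a0 = 0.01, a1 = 1),
                       frac_de = 0.1,
                       lfc = 1,
                       seed = 1L) {
  if (frac_de < 0 || frac_de > 1) abort("`frac_de` must be in [0, 1].")
  n_samples <- 2L * n_per_group
  with_seed(seed, {
    if (is.null(size_factors)) {
      size_factors <- rlnorm(n_samples, meanlog = 0, sdlog = 0.2)
      size_factors <- size_factors / geomean(size_factors)
    }
    if (any(size_factors <= 0)) abort("`size_factors` must be positive.")
    if (length(size_factors) != n_samples) {
      abort("`size_factors` must have one entry per sample.")
    }

    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
    sample_ids <- c(sprintf("control_%d", seq_len(n_per_group)),
                    sprintf("test_%d", seq_len(n_per_group)))
    groups <- setNames(rep(c("control", "test"), each = n_per_group),
                       sample_ids)

    mu <- rlnorm(n_genes, meanlog = mean_law$meanlog, sdlog = mean_law$sdlog)
    alpha <- trend_params[[1]] + trend_params[[2]] / mu

    n_de <- round(frac_de * n_genes)
    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    lfc_vec <- numeric(n_genes)
    if (n_de > 0) lfc_vec[de_idx] <- sample(c(-lfc, lfc), n_de, replace = TRUE)

    is_test <- groups == "test"
    counts <- matrix(0L, n_genes, n_samples,
                     dimnames = list(gene_ids, sample_ids))
    for (j in seq_len(n_samples)) {
      m <- size_factors[j] * mu * 2^(lfc_vec * is_test[j])
      counts[, j] <- rnbinom(n_genes, mu = m, size = 1 / alpha)
    }

    list(
      counts = counts,
      groups = groups,
      truth = list(
        size_factors = setNames(size_factors, sample_ids),
        gene_means = setNames(mu, gene_ids),
        dispersions = setNames(alpha, gene_ids),
        de_genes = gene_ids[de_idx],
        log2_fold_changes = setNames(lfc_vec, gene_ids)
      )
    )
  })
}

#' Simulate a reference developmental time-course count matrix
#'
#' Each gene follows a smooth, monotone-in-expectation log-linear trajectory
#' across timepoints (random slope and direction per gene), with negative
#' binomial sampling noise, mimicking a staged embryonic time-course used as
#' a pseudotime reference. Adjacent timepoints are therefore more correlated
#' than distant ones.
#'
#' @param n_timepoints Number of timepoints (>= 3).
#' @param n_genes Number of genes.
#' @param smoothness In (0, 1\]: 1 gives purely smooth trajectories, lower
#'   values add per-timepoint log-normal wiggle.
#' @param slope_sd SD of per-gene log2 slopes across the full course.
#' @param dispersion NB dispersion of the sampling noise.
#' @param seed Integer seed.
#'
#' @return A list with `counts` (genes x timepoints integer matrix, columns
#'   `tp01`, ...) and `timepoints` (integer labels `1:n_timepoints`).
#' @export
gen_reference_timecourse <- function(n_timepoints = 10,
                                     n_genes = 2000,
                                     smoothness = 0.9,
                                     slope_sd = 2,
                                     dispersion = 0.005,
                                     seed = 1L) {
  if (n_timepoints < 3) abort("`n_timepoints` must be >= 3.")
  if (smoothness <= 0 || smoothness > 1) abort("`smoothness` must be in (0, 1].")
  with_seed(seed, {
    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
    tp_ids <- sprintf("tp%02d", seq_len(n_timepoints))
    base <- rlnorm(n_genes, meanlog = log(50), sdlog = 1.2)
    slope <- rnorm(n_genes, sd = slope_sd)
    frac <- (seq_len(n_timepoints) - 1) / (n_timepoints - 1)
    wiggle_sd <- (1 - smoothness) * 0.5
    counts <- matrix(0L, n_genes, n_timepoints,
                     dimnames = list(gene_ids, tp_ids))
    for (t in seq_len(n_timepoints)) {
      m <- base * 2^(slope * frac[t] + rnorm(n_genes, sd = wiggle_sd))
      counts[, t] <- rnbinom(n_genes, mu = m, size = 1 / dispersion)
    }
    list(counts = counts, timepoints = seq_len(n_timepoints))
  })
}
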
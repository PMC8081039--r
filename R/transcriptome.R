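# Bulk RNA-seq stack: median-of-ratios (pseudoreference) normalization,
# method-of-moments dispersions with a local-regression trend, an exact
# conditional NB test, BH adjustment, DE calling, PCA, and projection onto a
# reference developmental time course.

check_counts <- function(counts, integer = TRUE) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix (genes x samples).")
  }
  if (any(counts < 0)) abort("Counts must be nonnegative.")
  if (integer && any(counts != round(counts))) {
    abort("Counts must be integers.")
  }
  invisible(counts)
}

#' Median-of-ratios size factors from a pseudoreference
#'
#' The pseudoreference is the gene-wise geometric mean across samples,
#' computed over genes with no zero count; each sample's size factor is the
#' median across those genes of the ratio count / pseudoreference.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Named numeric vector of per-sample positive size factors.
#' @export
#' @examples
#' size_factors(matrix(c(10L, 30L, 20L, 60L), nrow = 2))
size_factors <- function(counts) {
  check_counts(counts, integer = FALSE)
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    abort(paste("No gene has all-positive counts; filter the matrix or",
                "sequence deeper before computing size factors."))
  }
  sub <- counts[all_pos, , drop = FALSE]
  pseudo <- exp(rowMeans(log(sub)))
  sf <- apply(sub / pseudo, 2, median)
  # stabilize to unit geometric mean so normalization is idempotent and
  # factors are exactly scale-equivariant
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Divide each sample by its size factor
#'
#' @param counts Integer matrix, genes x samples.
#' @param sf Positive per-sample size factors (default recomputed via
#'   [size_factors()]).
#' @return Numeric matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  if (any(sf <= 0)) abort("Size factors must be positive.")
  if (length(sf) != ncol(counts)) {
    abort("One size factor per sample is required.")
  }
  sweep(counts, 2, sf, "/")
}

#' Gene-wise dispersions with a local-regression mean-dispersion trend
#'
#' Raw dispersions come from the method of moments on normalized counts,
#' pooled within groups: `alpha_i = max(0, (s2_i - xi * mu_i) / mu_i^2)`
#' where `xi = mean(1/sf)` accounts for the extra Poisson variance
#' introduced by depth normalization. The smooth trend `alpha(mu)` is a
#' local linear regression (loess) of `log(alpha)` on `log(mu)` over genes
#' with positive raw dispersion, evaluated at every gene's mean (clamped to
#' the fitted range). With fewer than 50 usable genes the parametric family
#' `a0 + a1/mu` is fit instead and flagged.
#'
#' @param normalized Matrix of normalized counts (genes x samples).
#' @param groups Character/factor of group labels, one per sample.
#' @param sf Size factors used for the normalization (for the `xi`
#'   correction; defaults to 1, i.e. no correction).
#' @param span Loess span.
#' @return An object of class `dispersion_model`: list with `mu`,
#'   `dispersion_raw`, `dispersion_trend`, `dispersion_used`
#'   (`max(raw, trend)`, the testing dispersion), `method`
#'   (`"local_regression"` or `"parametric_fallback"`).
#' @export
dispersion_trend <- function(normalized, groups, sf = NULL, span = 0.5) {
  groups <- as.character(groups)
  if (length(groups) != ncol(normalized)) {
    abort("One group label per sample is required.")
  }
  if (min(table(groups)) < 2) abort("Need >= 2 samples per group.")
  xi <- if (is.null(sf)) 1 else mean(1 / sf)

  mu <- rowMeans(normalized)
  # pooled within-group variance
  lev <- unique(groups)
  ssq <- matrix(0, nrow(normalized), 1)
  df <- 0
  for (g in lev) {
    sub <- normalized[, groups == g, drop = FALSE]
    ssq <- ssq + rowSums((sub - rowMeans(sub))^2)
    df <- df + ncol(sub) - 1
  }
  s2 <- as.numeric(ssq) / df
  alpha_raw <- pmax(0, (s2 - xi * mu) / mu^2)
  alpha_raw[mu == 0] <- 0

  usable <- alpha_raw > 0 & mu > 0
  if (sum(usable) >= 50) {
    fit <- loess(log(alpha_raw[usable]) ~ log(mu[usable]),
                 span = span, degree = 1,
                 control = stats::loess.control(surface = "direct"))
    lmu <- log(pmax(mu, min(mu[usable])))
    lmu <- pmin(pmax(lmu, min(log(mu[usable]))), max(log(mu[usable])))
    trend <- exp(predict(fit, newdata = lmu))
    method <- "local_regression"
  } else {
    # parametric fallback: alpha(mu) = a0 + a1/mu via least squares
    y <- alpha_raw[usable]
    x <- 1 / mu[usable]
    cf <- tryCatch(coef(lm(y ~ x)), error = function(e) c(0.01, 1))
    a0 <- max(cf[1], 1e-8)
    a1 <- max(cf[2], 0)
    trend <- a0 + a1 / pmax(mu, 1e-8)
    method <- "parametric_fallback"
  }
  trend <- pmax(trend, 1e-8)
  structure(
    list(mu = mu, dispersion_raw = alpha_raw, dispersion_trend = trend,
         dispersion_used = pmax(alpha_raw, trend), method = method,
         n_usable = sum(usable)),
    class = "dispersion_model"
  )
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat(sprintf("<dispersion_model> %d genes, trend = %s (%d used in fit)\n",
              length(x$mu), x$method, x$n_usable))
  invisible(x)
}

# exact conditional NB test for one gene: condition on the total count K
# and enumerate the probability of every split between the two group sums
nb_exact_p <- function(kA, kB, sA, sB, ssqA, ssqB, alpha) {
  K <- kA + kB
  if (K == 0) return(1)
  q <- K / (sA + sB)
  muA <- sA * q
  muB <- sB * q
  a <- 0:K
  if (alpha <= 0) {
    pa <- dpois(a, muA)
    pb <- dpois(K - a, muB)
  } else {
    # variance of a group sum: sum_j (s_j q + alpha s_j^2 q^2)
    # => size = (sum s_j)^2 / (alpha * sum s_j^2)
    sizeA <- sA^2 / (alpha * ssqA)
    sizeB <- sB^2 / (alpha * ssqB)
    pa <- dnbinom(a, mu = muA, size = sizeA)
    pb <- dnbinom(K - a, mu = muB, size = sizeB)
  }
  p_split <- pa * pb
  tot <- sum(p_split)
  if (tot == 0) return(1)
  p_obs <- p_split[kA + 1]
  min(1, sum(p_split[p_split <= p_obs * (1 + 1e-8)]) / tot)
}

#' Exact conditional negative-binomial test per gene
#'
#' For each gene the total count across both groups is held fixed and the
#' probability of every possible split between the group sums is computed
#' under an NB model whose group-sum means are scaled by the summed size
#' factors and whose dispersion is the gene's testing dispersion
#' (`max(raw, trend)`). The two-sided p-value is the total probability of
#' splits no more likely than the observed one, normalized over all splits.
#'
#' @param counts Integer matrix, genes x samples.
#' @param sf Per-sample size factors.
#' @param disp A `dispersion_model` from [dispersion_trend()], or a numeric
#'   vector of per-gene dispersions.
#' @param groups Two-level group labels, one per sample.
#' @return Named numeric vector of p-values (1 for zero-total genes).
#' @export
nb_exact_test <- function(counts, sf, disp, groups) {
  check_counts(counts)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) abort("Exactly two groups are required.")
  alpha <- if (inherits(disp, "dispersion_model")) disp$dispersion_used
           else disp
  ia <- groups == lev[1]
  ib <- groups == lev[2]
  kA <- rowSums(counts[, ia, drop = FALSE])
  kB <- rowSums(counts[, ib, drop = FALSE])
  sA <- sum(sf[ia]); ssqA <- sum(sf[ia]^2)
  sB <- sum(sf[ib]); ssqB <- sum(sf[ib]^2)
  p <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_p(kA[i], kB[i], sA, sB, ssqA, ssqB, alpha[i])
  }, numeric(1))
  setNames(p, rownames(counts))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values (monotone in p-rank, capped at 1).
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Differential-expression analysis of a two-group count matrix
#'
#' Chains [size_factors()], [normalize_counts()], [dispersion_trend()],
#' [nb_exact_test()], [bh_adjust()] and [call_de()]. Genes with zero total
#' count are excluded from the multiple-testing universe. The fold change
#' is `(mean_test + eps) / (mean_control + eps)` on normalized counts, with
#' `eps = 0.5` guarding against division by zero (recorded in the output
#' attribute `fc_epsilon`).
#'
#' @param counts Integer matrix, genes x samples.
#' @param groups Group labels; `control_level` names the reference level.
#' @param control_level Reference group (default: first unique label).
#' @param fdr,min_fold Thresholds passed to [call_de()].
#' @param fc_epsilon Pseudocount added to both normalized group means.
#' @return Tibble: `gene_id`, `base_mean`, `fold_change`, `log2_fc`, `p`,
#'   `q`, `is_de`; attribute `size_factors` carries the factors used.
#' @export
de_analysis <- function(counts, groups, control_level = NULL,
                        fdr = 0.01, min_fold = 2, fc_epsilon = 0.5) {
  groups <- as.character(groups)
  control_level <- control_level %||% unique(groups)[1]
  if (!control_level %in% groups) abort("`control_level` not found in groups.")
  test_level <- setdiff(unique(groups), control_level)
  if (length(test_level) != 1) abort("Exactly two groups are required.")

  keep <- rowSums(counts) > 0
  sub <- counts[keep, , drop = FALSE]
  sf <- size_factors(sub)
  norm <- normalize_counts(sub, sf)
  disp <- dispersion_trend(norm, groups, sf = sf)
  ord <- c(which(groups == control_level), which(groups == test_level))
  p <- nb_exact_test(sub[, ord, drop = FALSE], sf[ord], disp,
                     groups[ord])
  q <- bh_adjust(p)

  m_ctrl <- rowMeans(norm[, groups == control_level, drop = FALSE])
  m_test <- rowMeans(norm[, groups == test_level, drop = FALSE])
  fc <- (m_test + fc_epsilon) / (m_ctrl + fc_epsilon)

  res <- tibble::tibble(
    gene_id = rownames(sub),
    base_mean = rowMeans(norm),
    fold_change = fc,
    log2_fc = log2(fc),
    p = unname(p),
    q = unname(q)
  )
  res <- call_de(res, fdr = fdr, min_fold = min_fold)
  attr(res, "size_factors") <- sf
  attr(res, "fc_epsilon") <- fc_epsilon
  res
}

#' Call differentially expressed genes
#'
#' A gene is DE when `q < fdr` and its fold change is beyond `min_fold` in
#' either direction (`fc > min_fold` or `fc < 1/min_fold`).
#'
#' @param results Tibble with columns `q` and `fold_change`.
#' @param fdr FDR threshold (default 0.01).
#' @param min_fold Fold-change threshold (default 2).
#' @return `results` with a logical `is_de` column (re)computed.
#' @export
call_de <- function(results, fdr = 0.01, min_fold = 2) {
  stopifnot(all(c("q", "fold_change") %in% names(results)))
  dplyr::mutate(
    tibble::as_tibble(results),
    is_de = .data$q < fdr &
      (.data$fold_change > min_fold | .data$fold_change < 1 / min_fold)
  )
}

#' Log-transform and gene-center an expression matrix
#'
#' `log2(x + 1)` followed by subtraction of the per-gene mean. The centering
#' vector is kept as an attribute so external samples can be centered
#' consistently.
#'
#' @param normalized Nonnegative matrix (genes x samples).
#' @return Centered log matrix with attribute `center` (per-gene means of
#'   the log data).
#' @export
log_center <- function(normalized) {
  if (any(normalized < 0)) abort("Values must be nonnegative.")
  lg <- log2(normalized + 1)
  ctr <- rowMeans(lg)
  out <- lg - ctr
  attr(out, "center") <- ctr
  out
}

#' Principal component analysis of samples
#'
#' Eigen-decomposition of the sample covariance of gene-centered data
#' (samples as observations). Returns the top `k` orthonormal eigenvectors
#' in gene space, per-sample scores and explained-variance fractions.
#'
#' @param centered Gene-centered matrix (genes x samples), e.g. from
#'   [log_center()].
#' @param k Number of components (truncated to the matrix rank, flagged).
#' @return An object of class `wd_pca`: list with `rotation` (genes x k),
#'   `scores` (tibble: `sample_id`, `PC1`, ...), `explained` (fractions),
#'   `center`, `k`, `k_truncated`.
#' @export
pca_fit <- function(centered, k = 10) {
  if (ncol(centered) < 2) abort("Need >= 2 samples.")
  pc <- prcomp(t(centered), center = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  k_trunc <- k > rank
  k_use <- min(k, rank)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x[, seq_len(k_use), drop = FALSE])
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = colnames(centered) %||%
                     paste0("sample", seq_len(ncol(centered)))),
    scores
  )
  structure(
    list(rotation = pc$rotation[, seq_len(k_use), drop = FALSE],
         scores = scores,
         explained = expl[seq_len(k_use)],
         center = attr(centered, "center"),
         k = k_use, k_truncated = k_trunc),
    class = "wd_pca"
  )
}

#' @export
print.wd_pca <- function(x, ...) {
  cat(sprintf("<wd_pca> %d components; explained: %s\n", x$k,
              paste(sprintf("%.2f", head(x$explained, 5)), collapse = " ")))
  invisible(x)
}

#' @method tidy wd_pca
#' @export
tidy.wd_pca <- function(x, ...) x$scores

#' @method glance wd_pca
#' @export
glance.wd_pca <- function(x, ...) {
  tibble::tibble(k = x$k, k_truncated = x$k_truncated,
                 explained_total = sum(x$explained))
}

#' Embed query samples in the PCA space of a reference time course
#'
#' The eigenvectors and the gene-centering vector are computed from the
#' reference alone; query samples are centered with the reference means
#' and projected onto the top `k` reference eigenvectors. Each query is
#' assigned the label of its nearest reference sample (Euclidean distance
#' in the k-dimensional score space) as a pseudotime estimate.
#'
#' @param query_matrix,reference_matrix Normalized nonnegative expression
#'   matrices (genes x samples) with gene ids as rownames; the gene
#'   universes are intersected (>= `min_genes` required).
#' @param reference_labels Per-reference-sample labels (e.g. timepoints).
#' @param k Number of components.
#' @param center_query `"reference"` (default) to center queries with the
#'   reference gene means, `"query"` to center with their own means.
#' @param min_genes Minimal gene overlap.
#' @return List with `query_scores` (tibble: `sample_id`, PCs,
#'   `nearest_label`, `nearest_distance`), `reference_scores`, `pca`
#'   (the reference `wd_pca`).
#' @export
embed_on_reference <- function(query_matrix, reference_matrix,
                               reference_labels = colnames(reference_matrix),
                               k = 10,
                               center_query = c("reference", "query"),
                               min_genes = 100) {
  center_query <- match.arg(center_query)
  shared <- intersect(rownames(query_matrix), rownames(reference_matrix))
  if (length(shared) < min_genes) {
    abort(sprintf("Gene overlap %d < %d between query and reference.",
                  length(shared), min_genes))
  }
  ref <- log_center(reference_matrix[shared, , drop = FALSE])
  pca <- pca_fit(ref, k = k)

  lq <- log2(query_matrix[shared, , drop = FALSE] + 1)
  qc <- if (center_query == "reference") lq - pca$center else lq - rowMeans(lq)
  q_scores <- t(qc) %*% pca$rotation

  ref_mat <- as.matrix(pca$scores[, -1])
  nearest <- apply(q_scores, 1, function(v) {
    d <- sqrt(colSums((t(ref_mat) - v)^2))
    j <- which.min(d)
    c(j, d[j])
  })
  query_scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = colnames(query_matrix) %||%
                     paste0("query", seq_len(ncol(query_matrix)))),
    tibble::as_tibble(q_scores)
  )
  query_scores$nearest_label <- reference_labels[nearest[1, ]]
  query_scores$nearest_distance <- nearest[2, ]
  list(query_scores = query_scores, reference_scores = pca$scores, pca = pca)
}
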
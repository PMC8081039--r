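# Lipidomics statistics: detection filtering, total-abundance
# normalization, log10 z-scoring, PCA, pooled-variance t-tests with FDR,
# and cross-timepoint consistency calling. Lipid tables are tibbles with
# `lipid_id`, `class`, then one numeric column per sample; exact zeros
# encode non-detects.

lipid_sample_cols <- function(table) {
  setdiff(names(table), c("lipid_id", "class"))
}

lipid_matrix <- function(table) {
  m <- as.matrix(table[, lipid_sample_cols(table)])
  rownames(m) <- table$lipid_id
  m
}

#' Remove lipids detected in too few samples
#'
#' Keeps lipids detected (abundance > 0) in at least
#' `floor(n_samples / 2) + 1` samples — the "half plus one" detection rule —
#' or, with `rule = "all_samples"`, only lipids detected in every sample.
#'
#' @param table Lipid tibble (`lipid_id`, `class`, sample columns).
#' @param rule `"half_plus_one"` (default) or `"all_samples"`.
#' @return The filtered tibble with attribute `removed_lipids` listing the
#'   dropped ids.
#' @export
detection_filter <- function(table, rule = c("half_plus_one", "all_samples")) {
  rule <- match.arg(rule)
  m <- lipid_matrix(table)
  if (ncol(m) < 2) abort("Need >= 2 samples.")
  n_det <- rowSums(m > 0)
  need <- switch(rule,
                 half_plus_one = floor(ncol(m) / 2) + 1,
                 all_samples = ncol(m))
  keep <- n_det >= need
  out <- table[keep, , drop = FALSE]
  attr(out, "removed_lipids") <- table$lipid_id[!keep]
  out
}

#' Normalize each sample by its total detected lipid abundance
#'
#' Divides every sample column by its own sum over the retained lipids, so
#' normalized columns sum to one: abundances become fractions of the total
#' detected lipid content.
#'
#' @param table Lipid tibble.
#' @return Normalized tibble.
#' @export
total_normalize <- function(table) {
  cols <- lipid_sample_cols(table)
  totals <- vapply(table[cols], sum, numeric(1))
  if (any(totals <= 0)) {
    abort(sprintf("Sample '%s' has non-positive total abundance.",
                  cols[which(totals <= 0)[1]]))
  }
  table[cols] <- purrr::map2(table[cols], totals, `/`)
  table
}

#' Log10 transform and per-lipid z-scoring
#'
#' Adds a small offset (default 1e-6) to guard the log against non-detect
#' zeros, takes log10, and converts each lipid row to z-scores across
#' samples (sample-SD convention). Zero-variance lipids get z = 0 and are
#' flagged.
#'
#' @param table Lipid tibble (values >= 0).
#' @param offset Offset added before the log.
#' @return Transformed tibble with attribute `zero_variance_lipids`.
#' @export
log_zscore <- function(table, offset = 0.000001) {
  cols <- lipid_sample_cols(table)
  m <- as.matrix(table[, cols])
  if (any(m < 0)) abort("Abundances must be nonnegative.")
  lg <- log10(m + offset)
  mu <- rowMeans(lg)
  s <- apply(lg, 1, sd)
  z <- (lg - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  table[cols] <- tibble::as_tibble(z)
  attr(table, "zero_variance_lipids") <- table$lipid_id[s == 0]
  table
}

#' PCA of a transformed lipid table
#'
#' Runs [pca_fit()] on the z-scored lipid matrix (lipids as variables,
#' samples as observations). Rows are centered first, which is a no-op on
#' z-scored data.
#'
#' @param table Transformed lipid tibble (e.g. from [log_zscore()]).
#' @param k Number of components.
#' @return A `wd_pca` object.
#' @export
lipid_pca <- function(table, k = 10) {
  m <- lipid_matrix(table)
  ctr <- rowMeans(m)
  cm <- m - ctr
  attr(cm, "center") <- ctr
  pca_fit(cm, k = k)
}

#' Per-lipid pooled-variance two-sample t-tests
#'
#' Classical two-sided equal-variance t-test per lipid between two sample
#' groups, applied to total-normalized (not z-scored) abundances. With zero
#' pooled variance the p-value is 1 when the group means agree and 0
#' (flagged degenerate) when they differ.
#'
#' @param table Lipid tibble (normalized).
#' @param group_a_cols,group_b_cols Character vectors of sample column
#'   names (>= 2 each).
#' @return Tibble: `lipid_id`, `class` (if present), `mean_a`, `mean_b`,
#'   `t`, `p`, `degenerate`.
#' @export
lipid_ttests <- function(table, group_a_cols, group_b_cols) {
  stopifnot(all(group_a_cols %in% names(table)),
            all(group_b_cols %in% names(table)))
  na <- length(group_a_cols)
  nb <- length(group_b_cols)
  if (na < 2 || nb < 2) abort("Need >= 2 samples per group.")
  a <- as.matrix(table[, group_a_cols])
  b <- as.matrix(table[, group_b_cols])
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- apply(a, 1, var)
  vb <- apply(b, 1, var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  tt <- (mb - ma) / se
  p <- 2 * pt(-abs(tt), df)
  degen <- se == 0
  tt[degen] <- ifelse(mb[degen] == ma[degen], 0, Inf * sign(mb - ma)[degen])
  p[degen] <- ifelse(mb[degen] == ma[degen], 1, 0)
  out <- tibble::tibble(lipid_id = table$lipid_id)
  if ("class" %in% names(table)) out$class <- table$class
  out$mean_a <- ma
  out$mean_b <- mb
  out$t <- tt
  out$p <- p
  out$degenerate <- degen
  out
}

#' False-discovery-rate adjustment for lipid p-values
#'
#' Benjamini-Hochberg step-up by default; `method = "qvalue"` applies a
#' Storey-style positive-FDR estimate (BH scaled by an estimated null
#' proportion `pi0` at `lambda = 0.5`).
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @param method `"bh"` or `"qvalue"`.
#' @return Vector of q-values.
#' @export
lipid_fdr <- function(p_values, method = c("bh", "qvalue")) {
  method <- match.arg(method)
  q <- bh_adjust(p_values)
  if (method == "qvalue") {
    lambda <- 0.5
    pi0 <- min(1, mean(p_values > lambda, na.rm = TRUE) / (1 - lambda))
    q <- pmin(1, q * pi0)
  }
  q
}

#' Cross-comparison consistency calling
#'
#' Given per-comparison test results (e.g. mutant versus control at several
#' reference timepoints), flags each lipid as significant per comparison at
#' the FDR threshold, `consistent` when significant in every comparison,
#' and `in_any` when significant in at least one.
#'
#' @param results Named list of tibbles, each with `lipid_id` and `q`
#'   (and optionally `class`).
#' @param fdr Significance threshold on q (default 0.05).
#' @return List with `lipids` (tibble: `lipid_id`, one `sig_*` column per
#'   comparison, `n_significant`, `consistent`, `in_any`), `consistent_set`,
#'   `union_set`, and `class_tally` (per-class counts of consistent and
#'   any-comparison hits, when classes are available).
#' @export
consistent_hits <- function(results, fdr = 0.05) {
  if (length(results) < 1) abort("Need >= 1 comparison.")
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- paste0("comparison", seq_along(results))
  }
  ids <- results[[1]]$lipid_id
  sig <- purrr::map(results, function(r) {
    setNames(r$q < fdr, r$lipid_id)[ids]
  })
  sig_mat <- do.call(cbind, sig)
  colnames(sig_mat) <- paste0("sig_", names(results))
  lipids <- dplyr::bind_cols(
    tibble::tibble(lipid_id = ids),
    tibble::as_tibble(sig_mat)
  )
  lipids$n_significant <- unname(rowSums(sig_mat, na.rm = TRUE))
  lipids$consistent <- unname(rowSums(sig_mat, na.rm = TRUE) ==
                                ncol(sig_mat) &
                                !apply(is.na(sig_mat), 1, any))
  lipids$in_any <- unname(rowSums(sig_mat, na.rm = TRUE) > 0)

  class_tally <- NULL
  if ("class" %in% names(results[[1]])) {
    cls <- setNames(results[[1]]$class, results[[1]]$lipid_id)[ids]
    class_tally <- tibble::tibble(class = cls,
                                  consistent = lipids$consistent,
                                  in_any = lipids$in_any) |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(n_consistent = sum(.data$consistent),
                       n_in_any = sum(.data$in_any), .groups = "drop")
  }
  list(
    lipids = lipids,
    consistent_set = ids[lipids$consistent],
    union_set = ids[lipids$in_any],
    class_tally = class_tally
  )
}

#' Full lipidomics comparison pipeline
#'
#' Detection filter, total normalization, then pooled t-tests of the test
#' group against the control group at each control timepoint, FDR
#' adjustment per comparison, and consistency calling across timepoints.
#'
#' @param table Raw lipid tibble.
#' @param samples Sample sheet tibble: `sample_id`, `group`
#'   (`"control"`/`"test"`), `timepoint_h`.
#' @param fdr FDR threshold for significance (default 0.05).
#' @param rule Detection-filter rule.
#' @param fdr_method FDR method for [lipid_fdr()].
#' @return List with `filtered` (normalized filtered table), `tests`
#'   (named list of per-comparison result tibbles incl. `q`), and
#'   `consistency` (see [consistent_hits()]).
#' @export
lipid_pipeline <- function(table, samples, fdr = 0.05,
                           rule = "half_plus_one", fdr_method = "bh") {
  filt <- detection_filter(table, rule = rule)
  norm <- total_normalize(filt)
  test_cols <- samples$sample_id[samples$group == "test"]
  tps <- sort(unique(samples$timepoint_h[samples$group == "control"]))
  tests <- purrr::map(tps, function(tp) {
    ctrl_cols <- samples$sample_id[samples$group == "control" &
                                     samples$timepoint_h == tp]
    r <- lipid_ttests(norm, ctrl_cols, test_cols)
    r$q <- lipid_fdr(r$p, method = fdr_method)
    r
  })
  names(tests) <- paste0("vs_control_", tps, "h")
  list(
    filtered = norm,
    tests = tests,
    consistency = consistent_hits(tests, fdr = fdr)
  )
}
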
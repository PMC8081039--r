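# Lipidomics filter/normalize/test/consistency pipeline.

toy_lipids <- function(vals, classes = NULL) {
  n <- nrow(vals)
  tab <- tibble::tibble(
    lipid_id = sprintf("L%02d", seq_len(n)),
    class = classes %||% rep("PC", n)
  )
  dplyr::bind_cols(tab, tibble::as_tibble(vals, .name_repair = "minimal"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("detection filter implements the half-plus-one boundary", {
  n <- 14
  vals <- matrix(1, 3, n, dimnames = list(NULL, paste0("s", 1:n)))
  vals[2, 1:7] <- 0   # detected in 7 of 14: below floor(14/2)+1 = 8
  vals[3, 1:6] <- 0   # detected in 8 of 14: kept
  tab <- toy_lipids(vals)
  out <- detection_filter(tab)
  expect_equal(out$lipid_id, c("L01", "L03"))
  expect_equal(attr(out, "removed_lipids"), "L02")

  # all-zero lipid removed, fully-detected kept
  vals2 <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE,
                  dimnames = list(NULL, c("a", "b")))
  out2 <- detection_filter(toy_lipids(vals2))
  expect_equal(out2$lipid_id, "L01")

  # idempotence
  expect_equal(detection_filter(out)$lipid_id, out$lipid_id)

  # stricter all-samples rule
  out3 <- detection_filter(tab, rule = "all_samples")
  expect_equal(out3$lipid_id, "L01")
})

test_that("total normalization produces unit column sums", {
  vals <- withr::with_seed(1, matrix(rlnorm(40), 8, 5,
                                     dimnames = list(NULL, paste0("s", 1:5))))
  tab <- toy_lipids(vals)
  nrm <- total_normalize(tab)
  sums <- colSums(as.matrix(nrm[, -(1:2)]))
  expect_equal(unname(sums), rep(1, 5), tolerance = 1e-12)

  # single lipid: everything becomes 1
  one <- total_normalize(toy_lipids(matrix(c(3, 7), 1,
                                           dimnames = list(NULL, c("a", "b")))))
  expect_equal(unlist(one[, -(1:2)], use.names = FALSE), c(1, 1))

  # scaling a sample leaves its normalized profile unchanged
  tab2 <- tab
  tab2$s3 <- tab$s3 * 10
  expect_equal(total_normalize(tab2)$s3, nrm$s3, tolerance = 1e-12)

  bad <- toy_lipids(matrix(c(1, 2, 0, 0), 2,
                           dimnames = list(NULL, c("ok", "zero"))))
  expect_error(total_normalize(bad), "non-positive total")
})

test_that("log z-scoring follows the sample-sd convention", {
  # two samples {a, b}: z = -1/sqrt(2), +1/sqrt(2) under sample sd
  tab <- toy_lipids(matrix(c(0.2, 0.8), 1,
                           dimnames = list(NULL, c("s1", "s2"))))
  z <- log_zscore(tab)
  expect_equal(unlist(z[, -(1:2)], use.names = FALSE),
               c(-1, 1) / sqrt(2), tolerance = 1e-9)

  # identical values: z = 0 and flagged
  flat <- toy_lipids(matrix(c(0.5, 0.5), 1,
                            dimnames = list(NULL, c("s1", "s2"))))
  zf <- log_zscore(flat)
  expect_equal(unlist(zf[, -(1:2)], use.names = FALSE), c(0, 0))
  expect_equal(attr(zf, "zero_variance_lipids"), "L01")

  # row means are zero after the transform
  vals <- withr::with_seed(2, matrix(rlnorm(30), 6, 5,
                                     dimnames = list(NULL, paste0("s", 1:5))))
  zz <- log_zscore(toy_lipids(vals))
  expect_equal(unname(rowMeans(as.matrix(zz[, -(1:2)]))), rep(0, 6),
               tolerance = 1e-12)
})

test_that("pooled t statistic matches the hand formula and t.test", {
  a <- c(0.12, 0.15, 0.11)
  b <- c(0.18, 0.21, 0.20)
  vals <- matrix(c(a, b), 1, dimnames = list(NULL, paste0("s", 1:6)))
  tab <- toy_lipids(vals)
  res <- lipid_ttests(tab, paste0("s", 1:3), paste0("s", 4:6))

  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(b) - mean(a)) / sqrt(sp2 * (2 / 3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
})

test_that("t-test degenerate and extreme cases behave as specified", {
  same <- toy_lipids(matrix(rep(c(1, 2, 3, 1, 2, 3) / 10, each = 1), 1,
                            dimnames = list(NULL, paste0("s", 1:6))))
  r <- lipid_ttests(same, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  flat <- toy_lipids(matrix(c(1, 1, 1, 2, 2, 2), 1,
                            dimnames = list(NULL, paste0("s", 1:6))))
  rf <- lipid_ttests(flat, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(rf$p, 0)
  expect_true(rf$degenerate)

  const <- toy_lipids(matrix(rep(0.4, 6), 1,
                             dimnames = list(NULL, paste0("s", 1:6))))
  rc <- lipid_ttests(const, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(rc$p, 1)

  big <- withr::with_seed(3, {
    a <- rnorm(50)
    b <- rnorm(50, 3)
    toy_lipids(matrix(c(a, b), 1,
                      dimnames = list(NULL, paste0("s", 1:100))))
  })
  rb <- lipid_ttests(big, paste0("s", 1:50), paste0("s", 51:100))
  expect_lt(rb$p, 1e-10)

  expect_error(lipid_ttests(same, "s1", paste0("s", 4:6)), ">= 2")
})

test_that("FDR adjustment matches BH and the q-value variant shrinks it", {
  p <- c(0.001, 0.01, 0.02, 0.8, 0.9, 0.95)
  expect_equal(lipid_fdr(p), bh_adjust(p))
  expect_equal(lipid_fdr(rep(1, 4)), rep(1, 4))
  expect_equal(lipid_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  q <- lipid_fdr(p, method = "qvalue")
  expect_true(all(q <= bh_adjust(p) + 1e-15))
})

test_that("lipid PCA matches the SVD oracle", {
  vals <- withr::with_seed(4, matrix(rlnorm(200), 20, 10,
                                     dimnames = list(NULL, paste0("s", 1:10))))
  z <- log_zscore(toy_lipids(vals))
  pc <- lipid_pca(z, k = 4)
  zm <- as.matrix(z[, -(1:2)])
  zm <- zm - rowMeans(zm)
  sv <- svd(t(zm))
  expect_equal(pc$explained, (sv$d^2 / sum(sv$d^2))[1:4], tolerance = 1e-8)
  expect_true(all(diff(pc$explained) <= 1e-12))

  # rank-1 table: first component explains ~everything
  r1 <- outer(seq(1, 3, length.out = 6), seq(0.5, 2, length.out = 5))
  colnames(r1) <- paste0("s", 1:5)
  pr <- lipid_pca(toy_lipids(r1), k = 3)
  expect_gt(pr$explained[1], 0.99)
})

test_that("consistency calling reproduces a 9-significant/3-consistent pattern", {
  # 12 lipids; 9 significant somewhere; exactly 3 in all three comparisons
  ids <- sprintf("L%02d", 1:12)
  cls <- c(rep("LPE", 4), rep("LPC", 5), rep("TG", 3))
  qs <- matrix(1, 12, 3)
  qs[1:3, ] <- 0.01                 # consistent in all three
  qs[4:9, 1] <- 0.01                # significant only at the first timepoint
  qs[5, 2] <- 0.03                  # one also at the second
  results <- purrr::map(1:3, function(j) {
    tibble::tibble(lipid_id = ids, class = cls, q = qs[, j])
  })
  names(results) <- c("t50", "t53", "t56")
  ch <- consistent_hits(results, fdr = 0.05)
  expect_length(ch$union_set, 9)
  expect_length(ch$consistent_set, 3)
  expect_equal(ch$consistent_set, ids[1:3])
  expect_equal(ch$lipids$n_significant[5], 2)
  expect_false(ch$lipids$consistent[5])
  expect_true(ch$lipids$in_any[5])
  # per-class tallies add up
  expect_equal(sum(ch$class_tally$n_consistent), 3)
  expect_equal(sum(ch$class_tally$n_in_any), 9)
  # consistent implies significant in every comparison performed
  expect_true(all(ch$lipids$n_significant[ch$lipids$consistent] == 3))
})

test_that("synthetic spiked lipids are recovered with bounded FDR", {
  stats <- purrr::map_dfr(1:20, function(s) {
    sim <- gen_lipid_table(n_lipids = 200, n_samples_per_group = 5,
                           n_test_samples = 5, timepoints_h = 50, seed = s)
    res <- lipid_pipeline(sim$table, sim$samples, fdr = 0.05)
    hits <- res$consistency$union_set
    truth <- intersect(sim$truth$affected_lipids, res$filtered$lipid_id)
    tibble::tibble(
      fdp = if (length(hits)) mean(!hits %in% sim$truth$affected_lipids)
            else 0,
      power = if (length(truth)) mean(truth %in% hits) else NA_real_
    )
  })
  expect_lte(mean(stats$fdp), 0.15)
  expect_gte(median(stats$power, na.rm = TRUE), 0.5)
})
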
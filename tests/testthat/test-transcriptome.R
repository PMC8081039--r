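# Normalization, dispersion modelling, the exact NB test, BH adjustment,
# DE calling, PCA and reference embedding.

# step-up BH written from the definition, used as an oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# enumeration oracle for the exact conditional NB test of one gene
nb_oracle <- function(kA, kB, sfA, sfB, alpha) {
  K <- kA + kB
  q <- K / (sum(sfA) + sum(sfB))
  muA <- sum(sfA) * q
  muB <- sum(sfB) * q
  sizeA <- sum(sfA)^2 / (alpha * sum(sfA^2))
  sizeB <- sum(sfB)^2 / (alpha * sum(sfB^2))
  pr <- numeric(K + 1)
  for (a in 0:K) {
    pr[a + 1] <- dnbinom(a, mu = muA, size = sizeA) *
      dnbinom(K - a, mu = muB, size = sizeB)
  }
  sum(pr[pr <= pr[kA + 1] * (1 + 1e-8)]) / sum(pr)
}

test_that("size factors match the hand-computed pseudoreference example", {
  m <- matrix(c(10L, 30L, 20L, 60L), nrow = 2)
  expect_equal(unname(size_factors(m)), c(0.7071, 1.4142), tolerance = 1e-4)

  # identical columns give unit factors
  m2 <- matrix(rep(c(5L, 9L, 40L), 3), ncol = 3)
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))

  # a gene with any zero is excluded from the pseudoreference
  m3 <- rbind(m, c(0L, 1000L))
  expect_equal(size_factors(m3), size_factors(m))

  expect_error(size_factors(matrix(c(0L, 1L, 2L, 0L), 2)), "all-positive")
})

test_that("size factors are scale-equivariant", {
  # factors are defined up to overall scale; scaling one column by c
  # multiplies its factor relative to every other sample by exactly c
  m <- withr::with_seed(1, matrix(rpois(60, 50) + 1L, 10, 6))
  sf <- size_factors(m)
  for (c0 in c(0.5, 3)) {
    m2 <- m
    m2[, 4] <- m[, 4] * c0
    sf2 <- size_factors(m2)
    expect_equal(unname((sf2[4] / sf2[1]) / (sf[4] / sf[1])), c0,
                 tolerance = 1e-12)
    expect_equal(unname(sf2[-4] / sf2[1]), unname(sf[-4] / sf[1]),
                 tolerance = 1e-12)
  }
})

test_that("normalization is idempotent and undoes depth scaling", {
  m <- withr::with_seed(2, matrix(rpois(80, 100) + 1L, 10, 8))
  sf <- size_factors(m)
  n1 <- normalize_counts(m, sf)
  expect_identical(normalize_counts(m, rep(1, 8)), m + 0)

  n2 <- normalize_counts(n1, size_factors(n1))
  expect_equal(n2, n1, tolerance = 1e-12)

  # doubling one column then renormalizing recovers the original profile
  # doubling one column's depth approximately recovers the original
  # normalized profile (exact only as the number of samples grows, since
  # the doubled column contributes 2^(1/n) to the pseudoreference)
  m2 <- m
  m2[, 3] <- 2L * m[, 3]
  n3 <- normalize_counts(m2, size_factors(m2))
  expect_equal(n3[, 3], n1[, 3], tolerance = 0.1)
})

test_that("dispersion trend recovers the generating mean-dispersion law", {
  sim <- gen_counts(n_genes = 3000, n_per_group = 5, frac_de = 0, seed = 8)
  sf <- size_factors(sim$counts)
  nrm <- normalize_counts(sim$counts, sf)
  dm <- dispersion_trend(nrm, sim$groups, sf = sf)
  expect_equal(dm$method, "local_regression")
  truth <- 0.01 + 1 / dm$mu
  mid <- dm$mu > quantile(dm$mu, 0.05) & dm$mu < quantile(dm$mu, 0.95)
  rel <- abs(dm$dispersion_trend[mid] - truth[mid]) / truth[mid]
  expect_lt(median(rel), 0.25)
  expect_true(all(dm$dispersion_trend > 0))
})

test_that("Poisson data yields near-zero trend dispersions", {
  cnt <- withr::with_seed(3, matrix(rpois(3000 * 6, 60), 3000, 6,
                                    dimnames = list(paste0("g", 1:3000),
                                                    paste0("s", 1:6))))
  groups <- rep(c("a", "b"), each = 3)
  dm <- dispersion_trend(normalize_counts(cnt, rep(1, 6)), groups,
                         sf = rep(1, 6))
  expect_lte(median(dm$dispersion_trend), 0.01)
})

test_that("constant genes get zero raw dispersion", {
  cnt <- rbind(matrix(50L, 2, 6),
               withr::with_seed(4, matrix(rpois(600, 50), 100, 6)))
  dm <- dispersion_trend(cnt + 0, rep(c("a", "b"), each = 3))
  expect_equal(dm$dispersion_raw[1:2], c(0, 0))
})

test_that("exact NB test matches the enumeration oracle", {
  sfA <- c(0.9, 1.1, 1.0)
  sfB <- c(1.2, 0.8, 1.0)
  sf <- c(sfA, sfB)
  groups <- rep(c("a", "b"), each = 3)
  cases <- list(c(30L, 30L), c(10L, 50L), c(0L, 37L), c(95L, 105L),
                c(3L, 3L), c(81L, 17L))
  for (cs in cases) {
    cnt <- matrix(c(rep(cs[1] %/% 3L, 3), rep(cs[2] %/% 3L, 3)), 1)
    cnt[1, 1] <- cnt[1, 1] + cs[1] %% 3L
    cnt[1, 4] <- cnt[1, 4] + cs[2] %% 3L
    for (alpha in c(0.02, 0.4)) {
      p <- nb_exact_test(cnt, sf, alpha, groups)
      expect_equal(unname(p),
                   nb_oracle(sum(cnt[1, 1:3]), sum(cnt[1, 4:6]),
                             sfA, sfB, alpha),
                   tolerance = 1e-10)
    }
  }
})

test_that("balanced identical group sums give p = 1", {
  cnt <- matrix(c(20L, 20L, 20L, 20L), 1)
  p <- nb_exact_test(cnt, rep(1, 4), 0.1, c("a", "a", "b", "b"))
  expect_equal(unname(p), 1)
  # zero-total gene
  z <- matrix(0L, 1, 4)
  expect_equal(unname(nb_exact_test(z, rep(1, 4), 0.1,
                                    c("a", "a", "b", "b"))), 1)
})

test_that("NB p-values are invariant under group relabeling", {
  sim <- gen_counts(n_genes = 50, n_per_group = 3, frac_de = 0.3, seed = 9)
  sf <- size_factors(sim$counts)
  p1 <- nb_exact_test(sim$counts, sf, rep(0.05, 50), sim$groups)
  flipped <- ifelse(sim$groups == "control", "test", "control")
  p2 <- nb_exact_test(sim$counts, sf, rep(0.05, 50), flipped)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  for (s in 1:20) {
    p <- withr::with_seed(s, runif(50)^withr::with_seed(s + 1, runif(1, 0.5, 2)))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("DE calling applies both FDR and fold thresholds", {
  res <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    q = c(0.005, 0.005, 0.02, 0.005),
    fold_change = c(3, 1.5, 3, 0.3)
  )
  out <- call_de(res, fdr = 0.01, min_fold = 2)
  expect_equal(out$is_de, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("log-centering retains its centering vector and is idempotent", {
  m <- withr::with_seed(5, matrix(rpois(40, 30), 8, 5))
  m[1, ] <- 0
  lc <- log_center(m)
  expect_equal(unname(lc[1, ]), rep(0, 5))
  expect_equal(attr(lc, "center"), rowMeans(log2(m + 1)))
  expect_equal(rowMeans(lc), rep(0, 8), tolerance = 1e-12)
  lc2 <- lc - rowMeans(lc)
  expect_equal(unname(lc2), unname(lc + 0), tolerance = 1e-12)
})

test_that("PCA matches an SVD oracle and handles degenerate rank", {
  m <- withr::with_seed(6, matrix(rnorm(50 * 8), 50, 8,
                                  dimnames = list(paste0("g", 1:50),
                                                  paste0("s", 1:8))))
  cm <- m - rowMeans(m)
  pc <- pca_fit(cm, k = 5)
  sv <- svd(t(cm))
  scores_oracle <- sv$u %*% diag(sv$d)
  for (j in 1:5) {
    a <- pc$scores[[j + 1]]
    b <- scores_oracle[, j]
    expect_equal(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1,
                 tolerance = 1e-8)
    expect_equal(sd(a), sd(b), tolerance = 1e-8)
  }
  expect_equal(pc$explained,
               (sv$d^2 / sum(sv$d^2))[1:5], tolerance = 1e-8)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1)
  # orthonormal eigenvectors
  expect_equal(crossprod(pc$rotation), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)

  # collinear data: one component explains everything
  line <- outer(c(1, 2, 3), c(-2, -1, 0, 1, 2))
  pl <- pca_fit(line - rowMeans(line), k = 3)
  expect_equal(pl$explained[1], 1)
  expect_true(pl$k_truncated)
})

test_that("embedding reproduces reference scores and nearest labels", {
  ref <- gen_reference_timecourse(n_timepoints = 8, n_genes = 500, seed = 3)
  nref <- normalize_counts(ref$counts, size_factors(ref$counts))
  emb <- embed_on_reference(nref, nref, reference_labels = ref$timepoints,
                            k = 4)
  q <- as.matrix(emb$query_scores[, 2:5])
  r <- as.matrix(emb$reference_scores[, -1])
  expect_equal(unname(q), unname(r), tolerance = 1e-8)
  expect_equal(emb$query_scores$nearest_label, ref$timepoints)

  # midpoint of two adjacent timepoints lands on one of them
  mid <- (nref[, 3] + nref[, 4]) / 2
  qm <- matrix(mid, ncol = 1, dimnames = list(rownames(nref), "mid"))
  em <- embed_on_reference(qm, nref, reference_labels = ref$timepoints,
                           k = 4)
  expect_true(em$query_scores$nearest_label %in% c(3, 4))

  expect_error(embed_on_reference(nref[1:50, ], nref, k = 4),
               "overlap")
})

test_that("spiked fold changes are recovered with controlled FDP", {
  sim <- gen_counts(n_genes = 2000, n_per_group = 5, frac_de = 0.1,
                    lfc = 1.5, seed = 21)
  res <- de_analysis(sim$counts, sim$groups)
  hits <- res$gene_id[res$is_de]
  expect_gt(length(hits), 0)
  fdp <- mean(!hits %in% sim$truth$de_genes)
  expect_lte(fdp, 0.1)
  # fold-change direction agrees with the spiked signs for strong hits
  strong <- res[res$is_de & res$gene_id %in% sim$truth$de_genes, ]
  signs <- sign(sim$truth$log2_fold_changes[strong$gene_id])
  expect_true(all(sign(strong$log2_fc) == signs))
})
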
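test_that("feature extraction emits the 12 canonical variables", {
  cfg <- small_sim_config(seed = 2L)
  truth <- simulate_genome(cfg)
  ranked <- list(
    sono_ha = genomic_intervals(c("1", "2"), c(5000, 50000),
                                c(5400, 50400)),
    sono_myc = genomic_intervals(c("1", "2"), c(9000, 90000),
                                 c(9400, 90400)),
    polii = truth$annotations$orfs[
      c(seq_len(10), nrow(truth$annotations$orfs) - 0:9), ],
    cse4_wt = truth$cens)
  f <- extract_features(truth$clrs, truth$annotations, truth$cens,
                        truth$chrom_lengths, truth$sequence, ranked)
  expect_identical(colnames(f), feature_variable_names())
  expect_equal(ncol(f), 12L)
  expect_equal(nrow(f), nrow(truth$clrs))
  expect_true(all(f$pct_orf_overlap >= 0 & f$pct_orf_overlap <= 100))
  expect_true(all(f$max_at >= f$mean_at - 1e-9))
  expect_true(all(f$max_at <= 1 & f$mean_at <= 1))
  # planted AT patches push max AT well above background expectation
  expect_gt(mean(f$max_at), 0.75)

  # trivial anchors: a site inside an ORF / on a CEN
  orf1 <- truth$annotations$orfs[5, ]
  inside <- genomic_intervals(orf1$chrom, orf1$start + 10L, orf1$start + 110L)
  f2 <- extract_features(rbind(inside,
                               truth$cens[1, c("chrom", "start", "end")]),
                         truth$annotations, truth$cens, truth$chrom_lengths,
                         truth$sequence, ranked)
  expect_equal(f2$pct_orf_overlap[1], 100)
  expect_equal(f2$dist_cen[2], 0)

  # missing auxiliary list -> NA column with warning
  expect_warning(
    f3 <- extract_features(truth$clrs, truth$annotations, truth$cens,
                           truth$chrom_lengths, truth$sequence,
                           ranked[c("sono_ha", "sono_myc", "polii")]),
    "rank_cse4_wt")
  expect_true(all(is.na(f3$rank_cse4_wt)))
})

test_that("rank-of-closest variables index the significance-sorted list", {
  sites <- genomic_intervals("1", 10000, 10500)
  ranked <- genomic_intervals("1", c(50000, 12000, 9000),
                              c(50400, 12400, 9400))
  ann <- list(orfs = genomic_intervals("1", 1000, 2000, name = "o",
                                       strand = "+"),
              arss = ranked, trnas = ranked, retros = ranked)
  f <- extract_features(sites, ann, genomic_intervals("1", 99000, 99125),
                        c(`1` = 100000),
                        c(`1` = strrep("ACGT", 25000)),
                        list(sono_ha = ranked, sono_myc = ranked,
                             polii = ranked, cse4_wt = ranked))
  # nearest ranked region is the third row (9000-9400, 599 bp away)
  expect_equal(f$rank_sono_ha, 3)
  expect_equal(f$rank_polii, 3)
})

test_that("transform selection normalizes skewed variables", {
  set.seed(4)
  x <- data.frame(normal = rnorm(100),
                  lognorm = exp(rnorm(100, 0, 1)))
  spec <- fit_transforms(x)
  expect_equal(spec$normal$transform, "identity")
  expect_equal(spec$lognorm$transform, "log")
  z <- apply_transforms(x, spec)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
})

test_that("multivariate normality check flags gross outliers only", {
  set.seed(10)
  x <- matrix(rnorm(60 * 5), 60, 5)
  chk <- multivariate_normality_check(x, seed = 3L, n_sim = 300L)
  expect_gte(mean(!chk$outside), 0.95)
  x2 <- rbind(x, rep(25, 5))
  chk2 <- multivariate_normality_check(x2, seed = 3L, n_sim = 300L)
  expect_true(chk2$outside[length(chk2$outside)])
  expect_error(multivariate_normality_check(matrix(rnorm(12), 3, 4)),
               "singular|more observations")
})

test_that("MANOVA/ANOVA detect a planted single-variable shift", {
  set.seed(20)
  x <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  labels <- rep(c("A", "B"), each = 30)
  x[labels == "B", 2] <- x[labels == "B", 2] + 5
  res <- group_difference_tests(x, labels)
  expect_lt(res$manova_p, 1e-6)
  expect_lt(res$anova_p[["v2"]], 1e-3)
  expect_gt(min(res$anova_p[c("v1", "v3", "v4")]), 0.001)
  expect_error(group_difference_tests(x[1:2, ], c("A", "B")), "2 members")
})

test_that("LDA separates planted clusters and is honest under permutation", {
  set.seed(15)
  n <- 30
  x <- rbind(matrix(rnorm(n * 12), n, 12),
             matrix(rnorm(n * 12, mean = 10), n, 12))
  colnames(x) <- feature_variable_names()
  labels <- rep(c("LCNCR", "CLR"), each = n)
  fit <- lda_fit_loocv(x, labels)
  expect_equal(fit$loocv_accuracy, 1)
  expect_gt(mean(fit$scores[labels == "CLR"]), 0)
  expect_equal(length(fit$coefficients), 12L)

  fit11 <- lda_fit_loocv(x, labels, exclude = "pct_orf_overlap")
  expect_equal(length(fit11$coefficients), 11L)
  expect_false("pct_orf_overlap" %in% fit11$variables)

  # permuted labels -> about chance accuracy
  accs <- vapply(1:10, function(i) {
    set.seed(100 + i)
    lda_fit_loocv(x, sample(labels))$loocv_accuracy
  }, 0)
  expect_lt(mean(accs), 0.65)

  # scale invariance: multiplying a raw variable by a constant changes
  # nothing once standardization is refit
  raw <- x; raw[, 3] <- raw[, 3] * 1000
  z1 <- apply_transforms(as.data.frame(x),
                         fit_transforms(as.data.frame(x)))
  z2 <- apply_transforms(as.data.frame(raw),
                         fit_transforms(as.data.frame(raw)))
  expect_equal(lda_fit_loocv(z1, labels)$loocv_accuracy,
               lda_fit_loocv(z2, labels)$loocv_accuracy)
})

test_that("k-NN LOOCV behaves like LDA on separated clusters", {
  set.seed(16)
  x <- rbind(matrix(rnorm(25 * 6), 25, 6),
             matrix(rnorm(25 * 6, mean = 10), 25, 6))
  labels <- rep(c("A", "B"), each = 25)
  expect_equal(knn_classify_loocv(x, labels, k = 3), 1)
  set.seed(17)
  expect_lt(knn_classify_loocv(x, sample(labels), k = 3), 0.8)
  expect_error(knn_classify_loocv(x, labels, k = 50), "smaller")
})

test_that("2-means label matching separates planted clusters", {
  set.seed(18)
  x <- rbind(matrix(rnorm(25 * 6), 25, 6),
             matrix(rnorm(25 * 6, mean = 8), 25, 6))
  labels <- rep(c("A", "B"), each = 25)
  expect_equal(kmeans_label_accuracy(x, labels), 1)
  # accuracy is >= 0.5 by construction, ~chance on permuted labels
  set.seed(19)
  expect_lt(kmeans_label_accuracy(x, sample(labels)), 0.8)
})

test_that("parallel analysis counts planted factors, not noise", {
  noise_sig <- vapply(1:10, function(s) {
    x <- with(list(), { set.seed(200 + s); matrix(rnorm(23 * 12), 23, 12) })
    pca_parallel_analysis(x, n_null = 200L, seed = s)$n_significant
  }, 0L)
  expect_gte(mean(noise_sig == 0L), 0.9)

  set.seed(21)
  f <- rnorm(23)
  planted <- matrix(rnorm(23 * 12, sd = 0.3), 23, 12) +
    outer(f, rep(1, 12))
  res <- pca_parallel_analysis(planted, n_null = 200L, seed = 1L)
  expect_gte(res$n_significant, 1L)
  # eigenvalues of a correlation matrix sum to the variable count
  expect_equal(sum(res$eigenvalues), 12)
  expect_error(pca_parallel_analysis(cbind(planted, 1)), "constant")
})

test_that("confidence ellipse matches the chi-square geometry", {
  set.seed(23)
  x <- matrix(rnorm(4000 * 2), 4000, 2)
  e <- confidence_ellipse(x, 0.95)
  expect_equal(e$radii, rep(sqrt(qchisq(0.95, 2)), 2), tolerance = 0.05)
  expect_equal(unname(e$center), c(0, 0), tolerance = 0.08)
  # ~95% of a large Gaussian sample lies inside
  d2 <- mahalanobis(x, colMeans(x), cov(x))
  expect_equal(mean(d2 <= qchisq(0.95, 2)), 0.95, tolerance = 0.01)
  expect_warning(confidence_ellipse(cbind(1:50, 2 * (1:50))), "degenerate")
})
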
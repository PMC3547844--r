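test_that("nearest-feature distance is edge-to-edge with stable ties", {
  feats <- genomic_intervals("1", c(201, 1000), c(300, 1100))
  # overlap -> 0
  expect_equal(distance_to_nearest(genomic_intervals("1", 250, 260),
                                   feats)$distance, 0)
  # site end 100, feature start 201 -> 201 - 100 - 1 = 100
  expect_equal(distance_to_nearest(genomic_intervals("1", 50, 100),
                                   feats)$distance, 100)
  # tie broken by lowest feature start
  tie <- genomic_intervals("1", c(500, 900), c(600, 1000))
  r <- distance_to_nearest(genomic_intervals("1", 700, 800), tie)
  expect_equal(r$distance, 99)
  expect_equal(r$nearest, 1L)
})

test_that("nearest distance equals a brute-force scan", {
  set.seed(7)
  feats <- genomic_intervals(sample(1:3, 40, TRUE),
                             s <- sample.int(5e5, 40), s + 200L)
  sites <- genomic_intervals(sample(1:3, 25, TRUE),
                             p <- sample.int(5e5, 25), p + 100L)
  got <- distance_to_nearest(sites, feats)$distance
  brute <- vapply(seq_len(25), function(i) {
    d <- Inf
    for (j in seq_len(40)) {
      if (sites$chrom[i] != feats$chrom[j]) next
      d <- min(d, interval_distance(sites$start[i], sites$end[i],
                                    feats$start[j], feats$end[j]))
    }
    d
  }, 0)
  expect_equal(got, brute)
})

test_that("association test: observed 0 gives p = 1; planted gives small p", {
  cl <- c(`1` = 200000, `2` = 200000)
  feats <- genomic_intervals("1", 100000, 100200)
  cfg <- randomization_config(iterations = 10000L, seed = 3L)
  far <- genomic_intervals(rep("2", 5), seq(10000, 170000, length.out = 5),
                           seq(10000, 170000, length.out = 5) + 100)
  r0 <- association_randomization_test(far, feats, cl, 5000L, cfg)
  expect_equal(r0$observed, 0L)
  expect_equal(r0$p_value, 1)

  inside <- genomic_intervals(rep("1", 8), rep(100050, 8), rep(100150, 8))
  r1 <- association_randomization_test(inside, feats, cl, 5000L, cfg)
  expect_equal(r1$observed, 8L)
  expect_lte(r1$p_value, 1e-3)

  expect_error(association_randomization_test(inside, feats,
                                              c(`1` = 8000, `2` = 8000),
                                              5000L, cfg), "window larger")
})

test_that("null p-values are uniform (calibration)", {
  # sites drawn from the null itself; 200 repetitions at 2000 iterations.
  # The count statistic is discrete, so the calibration draws many sites
  # per repetition to put it in the near-continuous regime where a KS
  # uniformity check is meaningful.
  cl <- c(`1` = 300000)
  set.seed(99)
  fs <- sort(sample.int(295000, 12))
  feats <- genomic_intervals("1", fs, fs + 300L)
  ps <- vapply(1:200, function(rep) {
    pos <- sample.int(300000, 250, replace = TRUE)
    sites <- genomic_intervals("1", pos, pos)
    association_randomization_test(
      sites, feats, cl, 5000L,
      randomization_config(iterations = 2000L, seed = rep))$p_value
  }, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("intergenic-length test matches its contracts", {
  cl <- c(`1` = 100000)
  # equal-length intergenic regions: every null draw equals observed -> p = 1
  orfs <- genomic_intervals("1", seq(1, 90001, by = 10000),
                            seq(5000, 95000, by = 10000))
  sites <- genomic_intervals("1", c(6000, 26000), c(6400, 26400))
  cfg <- randomization_config(iterations = 2000L, seed = 1L)
  r <- intergenic_length_test(sites, orfs, cl, cfg)
  expect_equal(r$p_value, 1)

  # sites straddling an ORF are excluded from the observed set
  strad <- genomic_intervals("1", c(6000, 4500), c(6400, 5500))
  r2 <- intergenic_length_test(strad, orfs, cl, cfg)
  expect_equal(r2$n_used, 1L)
  expect_equal(r2$n_excluded, 1L)

  # sites planted in the longest regions -> small p
  orfs2 <- genomic_intervals("1", c(seq(1, 60001, by = 3000), 70000, 95000),
                             c(seq(2900, 62901, by = 3000), 71000, 96000))
  big <- genomic_intervals("1", c(80000, 97000), c(80400, 97400))
  r3 <- intergenic_length_test(big, orfs2, cl, cfg)
  expect_lte(r3$p_value, 0.05)
})

test_that("max AT statistic equals exhaustive enumeration", {
  expect_equal(max_at_content(strrep("A", 500))$max_at, 1.0)
  expect_equal(max_at_content(strrep("GC", 250))$max_at, 0.0)
  expect_error(max_at_content("ACGT", 90), "shorter")
  expect_warning(max_at_content(paste0(strrep("A", 100), "N",
                                       strrep("A", 100))), "non-AT")

  brute_max_at <- function(s, w = 90L) {
    ch <- strsplit(s, "")[[1]]
    max(vapply(seq_len(nchar(s) - w + 1L), function(i)
      mean(ch[i:(i + w - 1L)] %in% c("A", "T")), 0))
  }
  set.seed(17)
  for (k in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    r <- max_at_content(s, 90L)
    expect_identical(r$max_at, brute_max_at(s))
  }
})

test_that("bootstrap group comparison behaves at the extremes", {
  expect_warning(p1 <- resampling_group_compare(rep(2, 5), rep(2, 5),
                                                1000L, 1L)$p_value)
  expect_equal(p1, 1)
  sep <- resampling_group_compare(rnorm(6, 0, 0.1) + 10, rnorm(6, 0, 0.1),
                                  10000L, 2L)
  expect_lte(sep$p_value, 2 / 10000)
  expect_error(resampling_group_compare(1:2, 1:5), "3 values")
})

test_that("bootstrap comparison is roughly calibrated under the null", {
  set.seed(5)
  rej <- mean(vapply(1:300, function(i)
    resampling_group_compare(rnorm(8), rnorm(8), 400L,
                             seed = i)$p_value < 0.05, TRUE))
  # bootstrap tests at n=8 are only approximately calibrated
  expect_lt(rej, 0.15)
})

test_that("centromere proximity uses an inclusive 25-kb boundary", {
  cl <- c(`1` = 200000)
  cen <- genomic_intervals("1", 100000, 100125)
  at <- function(d) genomic_intervals("1", 100126 + d, 100126 + d + 100)
  cfg <- randomization_config(iterations = 100L, seed = 1L)
  exact <- genomic_intervals("1", 100125 + 1 + 25000, 100125 + 1 + 25100)
  expect_equal(distance_to_nearest(exact, cen)$distance, 25000)
  r <- cen_proximity_fraction(rbind(exact, at(25001)), cen, cl,
                              config = cfg)
  expect_equal(r$proximal, c(TRUE, FALSE))
  expect_equal(r$fraction, 0.5)
})
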
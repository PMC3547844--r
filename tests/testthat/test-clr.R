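test_that("replicate reconciliation requires support in every replicate", {
  r1 <- site_tab("1", c(1000, 5000), c(1200, 5300), ratio = c(5.8, 3))
  r2 <- site_tab("1", 1100, 1250, ratio = 4.3)
  out <- reconcile_replicates(list(r1, r2))
  # the 5000-5300 site is replicate-1 only: dropped
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 1000L)
  expect_equal(out$end, 1250L)
  # duplicate mean ratio: (5.8 + 4.3) / 2
  expect_equal(out$ratio, 5.05)

  # identical replicate lists reconcile to themselves
  same <- reconcile_replicates(list(r1, r1))
  expect_equal(same$start, r1$start)
  expect_equal(same$end, r1$end)
  expect_equal(same$ratio, r1$ratio)

  expect_error(reconcile_replicates(list(r1)), "2 replicates")
})

test_that("q-value filtering happens before reconciliation", {
  r1 <- site_tab("1", 1000, 1200, qvalue = 1e-3)
  r2 <- site_tab("1", 1000, 1200, qvalue = 1e-10)
  expect_equal(nrow(reconcile_replicates(list(r1, r2), 1e-5)), 0L)
})

test_that("four-protein overlap honors the maxgap chain rule", {
  mk <- function(s, e) site_tab("1", s, e)
  # identical interval in all four lists -> single candidate
  four <- list(Cse4 = mk(1000, 1200), Mif2 = mk(1000, 1200),
               Ndc10 = mk(1000, 1200), Ndc80 = mk(1000, 1200))
  out <- overlap_proteins(four, 150L)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(1000L, 1200L))

  # gap of exactly 150 chains; union span is reported
  four2 <- list(Cse4 = mk(1000, 1200), Mif2 = mk(1351, 1500),
                Ndc10 = mk(1100, 1400), Ndc80 = mk(1000, 1500))
  expect_equal(1351 - 1200 - 1, 150)
  out2 <- overlap_proteins(four2, 150L)
  expect_equal(nrow(out2), 1L)
  expect_equal(c(out2$start, out2$end), c(1000L, 1500L))

  # gap of 151 does not chain -> Mif2 disconnected -> no candidate
  four3 <- four2
  four3$Mif2 <- mk(1352, 1500)
  four3$Ndc10 <- mk(1000, 1200)
  four3$Ndc80 <- mk(1000, 1200)
  expect_equal(nrow(overlap_proteins(four3, 150L)), 0L)

  # three proteins only -> no candidate
  three <- four
  three$Ndc80 <- site_tab(character(), integer(), integer(),
                          qvalue = numeric(), ratio = numeric(),
                          excess = numeric())
  expect_equal(nrow(overlap_proteins(three, 150L)), 0L)
})

test_that("ratio filters label candidates per the published thresholds", {
  cand <- function(cse4, mif2, ndc10) {
    x <- overlap_proteins(list(
      Cse4 = site_tab("1", 1000, 1500, ratio = cse4),
      Mif2 = site_tab("1", 1000, 1500, ratio = mif2),
      Ndc10 = site_tab("1", 1000, 1500, ratio = ndc10),
      Ndc80 = site_tab("1", 1000, 1500, ratio = 1.01)), 150L)
    apply_filters(x)$label
  }
  expect_equal(cand(5.05, 1.5, 1.5), "CLR")
  expect_equal(cand(1.9, 1.6, 1.6), "LCNCR")   # Cse4 below 2.0
  expect_equal(cand(2.5, 1.6, 1.4), "LCNCR")   # Ndc10 below 1.5
  # Ndc80 has no ratio floor: presence suffices
  expect_equal(cand(2.0, 1.5, 1.5), "CLR")
})

test_that("candidates overlapping a centromere are excluded", {
  x <- overlap_proteins(list(
    Cse4 = site_tab("1", 1000, 1500), Mif2 = site_tab("1", 1000, 1500),
    Ndc10 = site_tab("1", 1000, 1500), Ndc80 = site_tab("1", 1000, 1500)),
    150L)
  cen <- genomic_intervals("1", 1400, 1520)
  expect_equal(nrow(apply_filters(x, cens = cen)), 0L)
})

test_that("raising a ratio threshold never increases the CLR count", {
  set.seed(44)
  n <- 30
  s <- sort(sample.int(1e6, n)) * 3L
  base <- function(r) site_tab("1", s, s + 400L, ratio = r)
  lists <- list(Cse4 = base(runif(n, 1, 6)), Mif2 = base(runif(n, 1, 3)),
                Ndc10 = base(runif(n, 1, 3)), Ndc80 = base(runif(n, 1, 3)))
  cand <- overlap_proteins(lists, 150L)
  counts <- vapply(c(1.0, 1.5, 2.0, 3.0), function(thr) {
    cfg <- caller_config(min_mean_ratio = c(Cse4 = thr, Mif2 = 1.5,
                                            Ndc10 = 1.5))
    sum(apply_filters(cand, cfg)$label == "CLR")
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("ranked-list comparison reports Spearman agreement", {
  n <- 50
  s <- seq(1000, by = 5000, length.out = n)
  a <- site_tab("1", s, s + 500L)
  expect_equal(compare_target_lists(a, a)$rho, 1)
  rev_b <- a[rev(seq_len(n)), ]
  expect_equal(compare_target_lists(a, rev_b)$rho, -1)
  set.seed(2)
  perm <- a[sample(n), ]
  res <- compare_target_lists(a, perm)
  expect_lt(abs(res$rho), 2.58 / sqrt(n - 1))  # null 99% bound
  # too few overlaps -> undefined, flagged
  b <- site_tab("1", c(1000, 6000), c(1500, 6500))
  expect_false(compare_target_lists(a[1:2, ], b)$defined)
})
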
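test_that("genome simulation is deterministic and honors the config", {
  cfg <- small_sim_config(seed = 5L)
  t1 <- simulate_genome(cfg)
  t2 <- simulate_genome(cfg)
  expect_identical(t1$clrs, t2$clrs)
  expect_identical(t1$sequence, t2$sequence)
  expect_equal(nrow(t1$cens), 2L)
  expect_equal(nrow(t1$clrs), 6L)
  # planted CLRs never overlap a CEN
  expect_true(all(distance_to_nearest(t1$clrs, t1$cens)$distance > 0))
  # each planted CLR carries its AT-rich patch
  for (i in seq_len(nrow(t1$clrs))) {
    mid <- (t1$clrs$start[i] + t1$clrs$end[i]) %/% 2L
    s <- substr(t1$sequence[[t1$clrs$chrom[i]]], mid - 250L, mid + 249L)
    expect_gte(max_at_content(s)$max_at, 0.75)
  }

  none <- simulate_genome(small_sim_config(seed = 5L, n_clrs = 0L))
  expect_equal(nrow(none$clrs), 0L)
  expect_equal(nrow(none$cens), 2L)
})

test_that("CEN-proximity bias of planted CLRs follows the configured rate", {
  # pool over seeds: n = 60 plants at bias 0.5; binomial 99.9% band
  prox <- unlist(lapply(1:3, function(s)
    simulate_genome(sim_config(n_clrs = 20L, cen_bias = 0.5,
                               seed = s))$clrs$proximal))
  expect_equal(length(prox), 60L)
  expect_gte(sum(prox), qbinom(5e-4, 60, 0.5))
  expect_lte(sum(prox), qbinom(1 - 5e-4, 60, 0.5))
  # and the planted flag agrees with measured distance
  tr <- simulate_genome(sim_config(n_clrs = 20L, seed = 2L))
  d <- distance_to_nearest(tr$clrs, tr$cens)$distance
  expect_equal(d <= 25000, tr$clrs$proximal)
})

test_that("simulated tracks match their occupancy contract", {
  cfg <- small_sim_config(seed = 9L)
  truth <- simulate_genome(cfg)
  tracks <- simulate_tracks(truth, cfg)
  ctrl <- tracks$control_OP_rep1
  # control mean ~ background rate
  expect_equal(mean(ctrl$counts[["1"]]), cfg$background_rate,
               tolerance = 0.05)
  # CEN window enrichment ~ CEN multiplier in both genotypes
  cen <- truth$cens[1, ]
  mid <- (cen$start + cen$end) %/% 2L
  for (id in c("Cse4_WT_rep1", "Cse4_OP_rep1")) {
    w <- if (grepl("OP", id)) cfg$cen_kernel_op else cfg$cen_kernel_wt
    obs <- mean(tracks[[id]]$counts[["1"]][(mid - w/4):(mid + w/4)]) /
      cfg$background_rate
    expect_equal(obs, cfg$cen_multiplier, tolerance = 0.3)
  }
  # planted CLR loci: enriched in OP tagged tracks, flat in WT and controls
  clr <- truth$clrs[1, ]
  idx <- clr$start:clr$end
  v_op <- mean(tracks$Mif2_OP_rep1$counts[[clr$chrom]][idx])
  v_wt <- mean(tracks$Mif2_WT_rep1$counts[[clr$chrom]][idx])
  v_ct <- mean(tracks$control_OP_rep2$counts[[clr$chrom]][idx])
  expect_gt(v_op / cfg$background_rate, cfg$clr_multiplier * 0.5)
  expect_equal(v_wt / cfg$background_rate, 1, tolerance = 0.25)
  expect_equal(v_ct / cfg$background_rate, 1, tolerance = 0.25)
})

test_that("every enriched window corresponds to planted truth", {
  cfg <- small_sim_config(seed = 21L)
  truth <- simulate_genome(cfg)
  tracks <- simulate_tracks(truth, cfg)
  ctrl <- tracks$control_OP_rep1
  samp <- tracks$Ndc80_OP_rep1
  sites <- call_peaks(samp, ctrl, q_threshold = 1e-5)
  planted <- rbind(truth$cens[, c("chrom", "start", "end")],
                   truth$clrs[, c("chrom", "start", "end")])
  d <- distance_to_nearest(sites, planted)$distance
  expect_true(all(d <= 200))
})

test_that("qPCR simulation obeys two-fold-per-cycle chemistry", {
  flat <- simulate_qpcr(c(p = 1, neg = 1), noise_sd = 0, seed = 1)
  expect_equal(diff(range(flat$cp)), 0)
  two <- simulate_qpcr(c(p = 2, neg = 1), noise_sd = 0, seed = 1)
  cp_tag <- mean(two$cp[two$sample == "tagged" & two$primer == "p"])
  cp_ctl <- mean(two$cp[two$sample == "untagged" & two$primer == "p"])
  expect_equal(cp_ctl - cp_tag, 1)
  # noisy enrichment is recovered by the ddCp estimator
  noisy <- simulate_qpcr(c(p = 8, neg1 = 1, neg2 = 1), noise_sd = 0.05,
                         seed = 4)
  est <- qpcr_enrichment(noisy, c("neg1", "neg2"))
  expect_equal(est$enrichment, 8, tolerance = 0.15)
})

test_that("growth and segregation simulation recover planted parameters", {
  gs <- simulate_growth_and_segregation(
    params = list(od_noise_sd = 0, doubling_time_h = c(X = 2.0)), seed = 1)
  g <- gs$growth[gs$growth$transformant == 1, ]
  expect_equal(g$od[g$time_h == 2] / g$od[g$time_h == 0], 2)
  expect_equal(doubling_time(g$time_h, g$od)$doubling_time_h, 2,
               tolerance = 1e-8)

  gs2 <- simulate_growth_and_segregation(
    params = list(n_transformants = 40L, n_colonies = 500L), seed = 2)
  ret <- gs2$retention[gs2$retention$strain == "CEN", ]
  frac <- sum(ret$selective) / sum(ret$permissive)
  expect_equal(frac, 0.91, tolerance = 0.03)
  seg <- gs2$segregation
  expect_equal(seg$success[seg$condition == "WT_ON"] /
                 (seg$success + seg$failure)[seg$condition == "WT_ON"],
               0.95, tolerance = 0.06)
})
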
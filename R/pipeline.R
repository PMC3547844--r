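#' Pipeline configuration
#'
#' Bundles the per-stage configurations and a single root seed from which
#' every stage derives its own reproducible stream (see [derive_seed()]).
#'
#' @param sim a [sim_config()]
#' @param caller a [caller_config()]
#' @param randomization a [randomization_config()]
#' @param n_controls synthetic negative-control sites used for the
#'   classification stage
#' @param seed root integer seed (propagated to all stages)
#' @param out_dir optional directory for TSV/JSON outputs
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(sim = sim_config(), caller = caller_config(),
                            randomization = randomization_config(),
                            n_controls = 38L, seed = 1L, out_dir = NULL) {
  sim$seed <- derive_seed(seed, "simulate")
  randomization$seed <- derive_seed(seed, "randomization")
  structure(list(sim = sim, caller = caller, randomization = randomization,
                 n_controls = n_controls, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

## Internal: synthetic auxiliary ranked lists (open chromatin x2, PolII,
## Cse4-WT) built from the simulated annotation, deterministic given seed.
make_ranked_lists <- function(truth, seed) {
  with_seed(seed, {
    ig <- intergenic_regions(truth$annotations$orfs, truth$chrom_lengths)
    pick <- function(n, source) {
      idx <- sample.int(nrow(source), min(n, nrow(source)))
      out <- source[idx, c("chrom", "start", "end")]
      rownames(out) <- NULL
      out
    }
    list(sono_ha = pick(80L, ig), sono_myc = pick(80L, ig),
         polii = pick(60L, truth$annotations$orfs),
         cse4_wt = rbind(truth$cens[, c("chrom", "start", "end")],
                         pick(40L, ig)))
  })
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates a genome and coverage tracks, calls candidate regions in both
#' genotypes, evaluates recovery against the planted truth, computes the
#' genomic-context randomization statistics and per-site maximum AT content,
#' builds centromere-anchored aggregation profiles with the paired
#' peak-width test, runs the 12-variable classification stage against
#' synthetic negative-control sites, and computes the assay statistics on
#' simulated qPCR/growth/segregation data. All stages are deterministic
#' given `config$seed`.
#'
#' @param config a [pipeline_config()]
#' @return nested list of class `clr_pipeline_report` (see sections in the
#'   returned object); if `config$out_dir` is set, TSV/JSON outputs and a
#'   manifest are written there
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- simulate_genome(config$sim)
  tracks <- simulate_tracks(truth, config$sim)
  chrom_lengths <- truth$chrom_lengths

  calls_op <- call_clrs(tracks, "OP", config$caller, cens = truth$cens,
                        proteins = config$sim$proteins)
  calls_wt <- call_clrs(tracks, "WT", config$caller, cens = truth$cens,
                        proteins = config$sim$proteins)
  clr_op <- calls_op[calls_op$label == "CLR", , drop = FALSE]

  recovery <- evaluate_recovery(clr_op, truth$clrs)

  ## context statistics on the called CLRs
  rc <- config$randomization
  context <- list(
    cen = cen_proximity_fraction(clr_op, truth$cens, chrom_lengths,
                                 window_bp = rc$window_bp[["cen"]],
                                 config = rc),
    ars = association_randomization_test(clr_op, truth$annotations$arss,
                                         chrom_lengths,
                                         rc$window_bp[["ars"]], rc,
                                         adjust = TRUE),
    trna = association_randomization_test(clr_op, truth$annotations$trnas,
                                          chrom_lengths,
                                          rc$window_bp[["trna"]], rc,
                                          adjust = TRUE),
    retro = association_randomization_test(clr_op, truth$annotations$retros,
                                           chrom_lengths,
                                           rc$window_bp[["retro"]], rc,
                                           adjust = TRUE),
    intergenic = intergenic_length_test(clr_op, truth$annotations$orfs,
                                        chrom_lengths, rc))

  ## aggregation profiles and widths per CEN, WT vs OP
  prot_tracks <- function(g) tracks[grep(
    sprintf("^(%s)_%s_rep", paste(config$sim$proteins, collapse = "|"), g),
    names(tracks))]
  ctrl_track <- function(g) {
    ids <- grep(sprintf("^control_%s_", g), names(tracks), value = TRUE)
    counts <- tracks[[ids[1L]]]$counts
    if (length(ids) > 1L) for (id in ids[-1L])
      counts <- Map(`+`, counts, tracks[[id]]$counts)
    signal_track(counts, sample_id = paste0("control_", g))
  }
  widths <- lapply(c(WT = "WT", OP = "OP"), function(g) {
    pt <- prot_tracks(g); ct <- ctrl_track(g)
    vapply(seq_len(nrow(truth$cens)), function(i)
      peak_width(aggregate_cen_signal(pt, ct, truth$cens[i, ])), 0)
  })
  width_test <- paired_width_test(widths$WT, widths$OP)

  ## classification stage: called CLRs vs synthetic negative controls
  controls <- with_seed(derive_seed(config$seed, "controls"), {
    ig <- intergenic_regions(truth$annotations$orfs, chrom_lengths)
    ig <- ig[interval_width(ig) >= 500 &
               GenomicRanges::countOverlaps(as_gr(ig),
                                            as_gr(truth$clrs)) == 0L, ,
             drop = FALSE]
    idx <- sample.int(nrow(ig), min(config$n_controls, nrow(ig)))
    mid <- (ig$start[idx] + ig$end[idx]) %/% 2L
    genomic_intervals(ig$chrom[idx], mid - 250L, mid + 249L,
                      site = sprintf("NCR%02d", seq_along(idx)))
  })
  ranked <- make_ranked_lists(truth, derive_seed(config$seed, "ranked"))
  sites_all <- rbind(clr_op[, c("chrom", "start", "end")],
                     controls[, c("chrom", "start", "end")])
  sites_all$site <- c(sprintf("CLR%02d", seq_len(nrow(clr_op))),
                      controls$site)
  labels <- c(rep("CLR", nrow(clr_op)), rep("LCNCR", nrow(controls)))
  feats <- extract_features(sites_all, truth$annotations, truth$cens,
                            chrom_lengths, truth$sequence, ranked)
  spec <- fit_transforms(feats)
  z <- apply_transforms(feats, spec)
  mva <- list(
    group_tests = group_difference_tests(z, labels),
    lda12 = lda_fit_loocv(z, labels),
    lda11 = lda_fit_loocv(z, labels, exclude = "pct_orf_overlap"),
    knn_accuracy = knn_classify_loocv(z, labels, k = 3L),
    kmeans_accuracy = kmeans_label_accuracy(
      z, labels, seed = derive_seed(config$seed, "kmeans")),
    pca = pca_parallel_analysis(z[labels == "CLR", , drop = FALSE],
                                seed = derive_seed(config$seed, "pca")))
  mva$ellipse <- confidence_ellipse(mva$pca$scores[, 1:2])

  ## assay statistics on simulated wet-lab inputs
  qpcr_tab <- simulate_qpcr(c(CLR_site = 8, CEN3 = 80, neg1 = 1, neg2 = 1),
                            seed = derive_seed(config$seed, "qpcr"))
  assays <- run_assay_stats(qpcr_tab, simulate_growth_and_segregation(
    seed = derive_seed(config$seed, "growth")),
    seed = derive_seed(config$seed, "assaystats"))

  report <- structure(list(
    truth = truth, calls_op = calls_op, calls_wt = calls_wt,
    recovery = recovery, context = context, widths = widths,
    width_test = width_test, features = feats, labels = labels,
    mva = mva, assays = assays, config = config),
    class = "clr_pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Compare called regions with the planted truth
#'
#' A planted CLR is recovered when a called CLR overlaps it; a called CLR is
#' a false positive when it overlaps no planted CLR.
#'
#' @param called called CLR intervals
#' @param planted planted CLR intervals
#' @return list with `recall`, `false_positives`, `n_called`, `n_planted`
#' @export
evaluate_recovery <- function(called, planted) {
  if (!nrow(planted))
    return(list(recall = NA_real_, false_positives = nrow(called),
                n_called = nrow(called), n_planted = 0L))
  hit_planted <- GenomicRanges::countOverlaps(as_gr(planted),
                                              as_gr(called)) > 0L
  fp <- if (nrow(called))
    sum(GenomicRanges::countOverlaps(as_gr(called), as_gr(planted)) == 0L)
  else 0L
  list(recall = mean(hit_planted), false_positives = fp,
       n_called = nrow(called), n_planted = nrow(planted))
}

## Internal: assay statistics on simulated inputs.
run_assay_stats <- function(qpcr_tab, gs, seed) {
  enr <- qpcr_enrichment(qpcr_tab, neg_primers = c("neg1", "neg2"))
  dt_by_strain <- lapply(split(gs$growth,
                               gs$growth[c("strain", "transformant")]),
                         function(d) doubling_time(d$time_h, d$od))
  dt <- do.call(rbind, lapply(names(dt_by_strain), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    data.frame(strain = parts[1L], transformant = parts[2L],
               doubling_time_h = dt_by_strain[[nm]]$doubling_time_h)
  }))
  dt_summary <- stats::aggregate(doubling_time_h ~ strain, dt, mean)

  ret <- gs$retention
  ret$fraction <- plasmid_retention(ret$selective, ret$permissive)
  ret_tr <- do.call(rbind, lapply(
    split(ret, ret[c("strain", "transformant")]), function(d)
      data.frame(strain = d$strain[1L],
                 value = fluctuation_aggregate(d$fraction))))
  ret_means <- stats::aggregate(value ~ strain, ret_tr, mean)
  cmp <- resampling_group_compare(
    ret_tr$value[ret_tr$strain == "CLR1"],
    ret_tr$value[ret_tr$strain == "ARS"], seed = seed)

  seg <- gs$segregation
  pick <- function(cond) unlist(seg[seg$condition == cond,
                                    c("success", "failure")])
  fet <- fisher_exact(rbind(pick("OP_OFF"), pick("WT_OFF")))
  list(qpcr = enr, doubling_times = dt_summary, retention = ret_means,
       retention_compare = cmp, segregation_fisher = fet)
}

## Internal: write the machine-readable report bundle.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(report$calls_op), file.path(
    out_dir, "clr_calls_op.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(as.data.frame(report$calls_wt), file.path(
    out_dir, "clr_calls_wt.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(cbind(site = rownames(report$features),
                           label = report$labels, report$features),
                     file.path(out_dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ctx <- lapply(report$context, function(x) {
    if (!is.null(x$test)) x <- x$test
    x[c("observed", "null_mean", "p_value", "p_adjusted", "iterations")]
  })
  summary <- list(
    seed = report$config$seed,
    recovery = report$recovery,
    wt_clr_count = sum(report$calls_wt$label == "CLR"),
    context = ctx,
    widths = report$widths,
    width_test = report$width_test[c("t", "p_value", "mean_diff")],
    lda12_loocv = report$mva$lda12$loocv_accuracy,
    lda11_loocv = report$mva$lda11$loocv_accuracy,
    knn_loocv = report$mva$knn_accuracy,
    kmeans_match = report$mva$kmeans_accuracy,
    pca_significant_components = report$mva$pca$n_significant,
    manova_p = report$mva$group_tests$manova_p)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package = "clrscan",
                   version = as.character(utils::packageVersion("clrscan")),
                   seed = report$config$seed,
                   generated = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.clr_pipeline_report <- function(x, ...) {
  cat("CLR pipeline report (seed ", x$config$seed, ")\n", sep = "")
  cat("  OP genotype: ", sum(x$calls_op$label == "CLR"), " CLRs called (",
      x$recovery$n_planted, " planted; recall ",
      round(x$recovery$recall, 3), ", ", x$recovery$false_positives,
      " false positives)\n", sep = "")
  cat("  WT genotype: ", sum(x$calls_wt$label == "CLR"), " CLRs called\n",
      sep = "")
  cat("  CEN-proximal fraction: ", round(x$context$cen$fraction, 3),
      " (randomization p ",
      format(max(x$context$cen$test$p_value,
                 1 / x$context$cen$test$iterations)), ")\n", sep = "")
  cat("  mean peak width WT ", round(mean(x$widths$WT)), " bp, OP ",
      round(mean(x$widths$OP)), " bp (paired t p ",
      signif(x$width_test$p_value, 3), ")\n", sep = "")
  cat("  LDA LOOCV accuracy: ", round(x$mva$lda12$loocv_accuracy, 3),
      " (12 vars), ", round(x$mva$lda11$loocv_accuracy, 3),
      " (11 vars); k-NN ", round(x$mva$knn_accuracy, 3), "\n", sep = "")
  cat("  PCA significant components: ", x$mva$pca$n_significant, "\n",
      sep = "")
  invisible(x)
}
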
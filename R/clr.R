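#' Caller configuration
#'
#' Thresholds of the CLR identification procedure: per-replicate q-value
#' cutoff 1e-5; four-protein overlap with maxgap 150 bp; duplicate-mean
#' enrichment-ratio floors of 2.0 for Cse4 and 1.5 for the direct DNA
#' binders Mif2 and Ndc10 (Ndc80 needs presence only). The qualitative
#' confidence filters are made operational: a candidate is demoted to LCNCR
#' if more than `orf_overlap_frac` of its length lies over an ORF whose
#' PolII occupancy rank is in the top `polii_top_decile` fraction, if it
#' overlaps a supplied HOT-region exclusion list, or if the untagged-control
#' signal within it exceeds `control_ceiling` (reads per million per base).
#'
#' @param q_threshold per-replicate q-value cutoff
#' @param maxgap_bp maximum gap for the four-protein overlap
#' @param min_mean_ratio named vector of per-protein duplicate-mean ratio
#'   floors; proteins absent from the vector (or `NA`) need presence only
#' @param orf_overlap_frac fraction of candidate length over a highly
#'   PolII-occupied ORF that triggers demotion
#' @param polii_top_decile fraction of the PolII ranked list counted as
#'   "highly occupied"
#' @param control_ceiling background ceiling in the untagged control
#'   (reads per million per base); `Inf` disables
#' @param round_to_100 round candidate interval bounds outward to 100-bp
#'   boundaries (published coordinates are round numbers)
#' @return list of class `caller_config`
#' @export
caller_config <- function(q_threshold = 1e-5, maxgap_bp = 150L,
                          min_mean_ratio = c(Cse4 = 2.0, Mif2 = 1.5,
                                             Ndc10 = 1.5),
                          orf_overlap_frac = 0.5, polii_top_decile = 0.1,
                          control_ceiling = Inf, round_to_100 = FALSE) {
  stopifnot(q_threshold > 0, maxgap_bp >= 0, all(min_mean_ratio > 0,
                                                 na.rm = TRUE))
  structure(as.list(environment()), class = "caller_config")
}

#' Reconcile binding sites across biological replicates
#'
#' For one protein: each replicate's sites are filtered at the q-value
#' threshold, then only genomic regions supported by an overlapping
#' surviving site in *every* replicate are kept. Each kept region is the
#' union span of the supporting sites; its ratio is the mean of the
#' per-replicate ratios (duplicate mean), its q-value the minimum, and its
#' excess reads the replicate mean.
#'
#' @param replicate_sites list (length >= 2) of [genomic_intervals()] tables,
#'   one per replicate, with `qvalue`, `ratio`, `excess_reads` columns
#' @param q_threshold per-replicate q-value cutoff
#' @return a [genomic_intervals()] table with `qvalue`, `ratio`,
#'   `excess_reads`
#' @export
reconcile_replicates <- function(replicate_sites, q_threshold = 1e-5) {
  if (length(replicate_sites) < 2L)
    stop("at least 2 replicates are required per protein")
  reps <- lapply(replicate_sites, function(x)
    x[x$qvalue < q_threshold, , drop = FALSE])
  empty <- genomic_intervals(character(), integer(), integer(),
                             qvalue = numeric(), ratio = numeric(),
                             excess_reads = numeric())
  if (any(vapply(reps, nrow, 1L) == 0L)) return(empty)

  pooled <- do.call(rbind, lapply(reps, function(x)
    x[, c("chrom", "start", "end")]))
  red <- GenomicRanges::reduce(as_gr(pooled), min.gapwidth = 0L)
  ## keep regions supported by every replicate
  support <- vapply(reps, function(x)
    GenomicRanges::countOverlaps(red, as_gr(x)) > 0L,
    logical(length(red)))
  if (length(red) == 1L) support <- matrix(support, nrow = 1L)
  keep <- which(rowSums(support) == length(reps))
  if (!length(keep)) return(empty)
  red <- red[keep]

  rows <- lapply(seq_along(red), function(i) {
    per_rep <- lapply(reps, function(x) {
      hit <- which(GenomicRanges::countOverlaps(as_gr(x), red[i]) > 0L)
      x[hit, , drop = FALSE]
    })
    members <- do.call(rbind, per_rep)
    data.frame(chrom = as.character(GenomicRanges::seqnames(red[i])),
               start = min(members$start), end = max(members$end),
               qvalue = min(members$qvalue),
               ratio = mean(vapply(per_rep, function(x) mean(x$ratio), 0)),
               excess_reads = mean(vapply(per_rep,
                                          function(x) mean(x$excess_reads), 0)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  genomic_intervals(out$chrom, out$start, out$end, qvalue = out$qvalue,
                    ratio = out$ratio, excess_reads = out$excess_reads)
}

#' Overlap per-protein site lists into candidate regions
#'
#' Sites from all proteins are chained by single linkage at the given
#' maxgap (gap `start2 - end1 - 1 <= maxgap_bp`); a chain becomes a
#' candidate only if every protein contributes at least one site. The
#' candidate interval is the union span of its member sites; per-protein
#' mean ratio, minimum q-value and mean excess reads are carried along.
#'
#' @param protein_sites named list of reconciled [genomic_intervals()]
#'   tables, one per protein
#' @param maxgap_bp maximum chaining gap in bp
#' @return a [genomic_intervals()] table with per-protein `ratio_<p>`,
#'   `qvalue_<p>`, `excess_<p>` columns
#' @export
overlap_proteins <- function(protein_sites, maxgap_bp = 150L) {
  stopifnot(!is.null(names(protein_sites)))
  proteins <- names(protein_sites)
  pooled <- do.call(rbind, lapply(proteins, function(p) {
    x <- protein_sites[[p]]
    if (!nrow(x)) return(NULL)
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               qvalue = x$qvalue, ratio = x$ratio,
               excess_reads = x$excess_reads, protein = p)
  }))
  empty_cols <- c(list(qvalue = numeric()),
                  stats::setNames(rep(list(numeric()), length(proteins)),
                                  paste0("ratio_", proteins)))
  empty <- do.call(genomic_intervals,
                   c(list(chrom = character(), start = integer(),
                          end = integer()), empty_cols))
  if (is.null(pooled) || !nrow(pooled)) return(empty)

  gr <- GenomicRanges::GRanges(pooled$chrom,
                               IRanges::IRanges(pooled$start, pooled$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = maxgap_bp + 1L)
  hit <- GenomicRanges::findOverlaps(gr, red, maxgap = maxgap_bp)
  grp <- rep(NA_integer_, nrow(pooled))
  grp[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)

  rows <- lapply(split(seq_len(nrow(pooled)), grp), function(idx) {
    m <- pooled[idx, , drop = FALSE]
    if (!all(proteins %in% m$protein)) return(NULL)
    row <- data.frame(chrom = m$chrom[1L], start = min(m$start),
                      end = max(m$end), qvalue = min(m$qvalue))
    for (p in proteins) {
      mp <- m[m$protein == p, , drop = FALSE]
      row[[paste0("ratio_", p)]] <- mean(mp$ratio)
      row[[paste0("qvalue_", p)]] <- min(mp$qvalue)
      row[[paste0("excess_", p)]] <- mean(mp$excess_reads)
    }
    row
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  do.call(genomic_intervals,
          c(list(chrom = out$chrom, start = out$start, end = out$end),
            as.list(out[setdiff(names(out), c("chrom", "start", "end"))])))
}

#' Apply confidence filters and label candidates
#'
#' Candidates overlapping an annotated centromere are removed (the caller
#' targets non-centromeric regions). Remaining candidates are labeled `CLR`
#' when every per-protein duplicate-mean ratio floor passes and no
#' confidence filter trips; otherwise `LCNCR`. Confidence filters: >50% (by
#' default) of candidate length over a highly PolII-occupied ORF; overlap
#' with a HOT-region exclusion list; untagged-control signal above the
#' configured ceiling.
#'
#' @param candidates output of [overlap_proteins()]
#' @param config a [caller_config()]
#' @param cens centromere intervals (candidates overlapping them are dropped)
#' @param orfs ORF intervals (may be `NULL` to skip the PolII filter)
#' @param polii_sites significance-ranked PolII site table (first row =
#'   strongest), or `NULL`
#' @param hot_regions exclusion intervals, or `NULL`
#' @param control_track normalized untagged-control [signal_track()], or
#'   `NULL`
#' @return `candidates` with a `label` column (`CLR`/`LCNCR`) and logical
#'   filter-flag columns
#' @export
apply_filters <- function(candidates, config = caller_config(), cens = NULL,
                          orfs = NULL, polii_sites = NULL,
                          hot_regions = NULL, control_track = NULL) {
  x <- candidates
  if (!nrow(x)) { x$label <- character(0); return(x) }

  if (!is.null(cens) && nrow(cens)) {
    drop <- GenomicRanges::countOverlaps(as_gr(x), as_gr(cens)) > 0L
    x <- x[!drop, , drop = FALSE]
    if (!nrow(x)) { x$label <- character(0); return(x) }
  }

  pass_ratio <- rep(TRUE, nrow(x))
  for (p in names(config$min_mean_ratio)) {
    thr <- config$min_mean_ratio[[p]]
    col <- paste0("ratio_", p)
    if (!is.na(thr) && col %in% names(x))
      pass_ratio <- pass_ratio & x[[col]] >= thr
  }
  x$fail_ratio <- !pass_ratio

  x$fail_polii_orf <- FALSE
  if (!is.null(orfs) && !is.null(polii_sites) && nrow(polii_sites)) {
    n_top <- max(1L, floor(nrow(polii_sites) * config$polii_top_decile))
    top <- polii_sites[seq_len(n_top), , drop = FALSE]
    hot_orf <- orfs[GenomicRanges::countOverlaps(as_gr(orfs),
                                                 as_gr(top)) > 0L, ,
                    drop = FALSE]
    if (nrow(hot_orf)) {
      cov_frac <- vapply(seq_len(nrow(x)), function(i) {
        w <- GenomicRanges::width(GenomicRanges::pintersect(
          GenomicRanges::findOverlapPairs(as_gr(x[i, ]), as_gr(hot_orf))))
        sum(w) / interval_width(x[i, ])
      }, 0)
      x$fail_polii_orf <- cov_frac > config$orf_overlap_frac
    }
  }

  x$fail_hot <- if (!is.null(hot_regions) && nrow(hot_regions))
    GenomicRanges::countOverlaps(as_gr(x), as_gr(hot_regions)) > 0L
  else FALSE

  x$fail_control <- FALSE
  if (!is.null(control_track) && is.finite(config$control_ceiling)) {
    ctrl <- normalize_track(control_track)
    mean_rpm <- vapply(seq_len(nrow(x)), function(i)
      track_window_sum(ctrl, x$chrom[i], x$start[i], x$end[i]) /
        interval_width(x[i, ]), 0)
    x$fail_control <- mean_rpm > config$control_ceiling
  }

  x$label <- ifelse(x$fail_ratio | x$fail_polii_orf | x$fail_hot |
                      x$fail_control, "LCNCR", "CLR")
  if (config$round_to_100) {
    x$start <- pmax(1L, as.integer(floor((x$start - 1L) / 100) * 100 + 1L))
    x$end <- as.integer(ceiling(x$end / 100) * 100)
  }
  x
}

#' Run the full CLR caller on a set of simulated or real tracks
#'
#' Convenience wrapper: scores every tagged replicate track of one genotype
#' against the pooled untagged control, reconciles replicates per protein,
#' overlaps the four proteins, and applies the confidence filters.
#'
#' @param tracks named list of [signal_track()]s as produced by
#'   [simulate_tracks()]
#' @param genotype `"WT"` or `"OP"`
#' @param config a [caller_config()]
#' @param cens centromere intervals to exclude
#' @param proteins tagged proteins expected in `tracks`
#' @param ... further arguments passed to [apply_filters()]
#' @return labeled candidate table (see [apply_filters()])
#' @export
call_clrs <- function(tracks, genotype = c("OP", "WT"),
                      config = caller_config(), cens = NULL,
                      proteins = c("Cse4", "Mif2", "Ndc10", "Ndc80"), ...) {
  genotype <- match.arg(genotype)
  ctrl_ids <- grep(sprintf("^control_%s_", genotype), names(tracks),
                   value = TRUE)
  if (!length(ctrl_ids)) stop("no control tracks for genotype ", genotype)
  pooled_counts <- tracks[[ctrl_ids[1L]]]$counts
  if (length(ctrl_ids) > 1L) for (id in ctrl_ids[-1L])
    pooled_counts <- Map(`+`, pooled_counts, tracks[[id]]$counts)
  control <- signal_track(pooled_counts, sample_id = paste0("control_",
                                                            genotype))
  per_protein <- lapply(proteins, function(p) {
    ids <- grep(sprintf("^%s_%s_rep", p, genotype), names(tracks),
                value = TRUE)
    if (length(ids) < 2L) stop("protein ", p, " has < 2 replicates")
    reps <- lapply(ids, function(id)
      call_peaks(tracks[[id]], control, q_threshold = config$q_threshold,
                 protein = p))
    reconcile_replicates(reps, config$q_threshold)
  })
  names(per_protein) <- proteins
  cand <- overlap_proteins(per_protein, config$maxgap_bp)
  apply_filters(cand, config, cens = cens, ...)
}

#' Compare two ranked target lists
#'
#' Overlapping peaks (1 bp or more) between two significance-sorted lists
#' are matched; Spearman's rank correlation of the matched peaks' list
#' positions is returned with its p-value. With fewer than 3 overlapping
#' pairs the correlation is undefined and flagged.
#'
#' @param list_a,list_b [genomic_intervals()] tables already sorted by
#'   significance (row order = rank)
#' @return list with `n_overlap`, `rho`, `p_value`, `defined`
#' @export
compare_target_lists <- function(list_a, list_b) {
  hit <- GenomicRanges::findOverlaps(as_gr(list_a), as_gr(list_b))
  ra <- S4Vectors::queryHits(hit)
  rb <- S4Vectors::subjectHits(hit)
  if (length(ra) < 3L)
    return(list(n_overlap = length(ra), rho = NA_real_,
                p_value = NA_real_, defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(ra, rb, method = "spearman"))
  list(n_overlap = length(ra), rho = unname(ct$estimate),
       p_value = ct$p.value, defined = TRUE)
}
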
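#' Call enrichment peaks from a sample/control track pair
#'
#' A windowed enrichment scorer producing binding sites with the fields the
#' downstream overlap caller consumes (q-value, enrichment ratio, excess
#' reads). Fixed windows of `window_bp` are slid in steps of `step_bp`; each
#' window's raw sample and control read counts are compared by a one-sided
#' binomial test of the sample count out of the window total, with success
#' probability equal to the sample's share of total sequencing depth.
#' Benjamini-Hochberg adjustment over all windows gives the q-value;
#' adjacent/overlapping significant windows (gap <= `step_bp`) are merged.
#' The enrichment ratio is depth-normalized and pseudocounted:
#' `((sample + eps) / N_s) / ((control + eps) / N_c)`; excess reads are
#' depth-scaled sample minus control counts.
#'
#' @param sample,control [signal_track()]s of raw counts (same chromosomes)
#' @param window_bp window width (default 200)
#' @param step_bp step between window starts (default 50)
#' @param q_threshold q-value cutoff for a window to be significant
#' @param protein,replicate labels carried onto the output
#' @param eps pseudocount (reads) used in the ratio
#' @return a [genomic_intervals()] table of merged sites with columns
#'   `qvalue` (minimum over merged windows), `ratio`, `excess_reads`,
#'   `protein`, `replicate`, sorted by `qvalue` then `excess_reads`
#'   descending
#' @export
call_peaks <- function(sample, control, window_bp = 200L, step_bp = 50L,
                       q_threshold = 1e-5, protein = NA_character_,
                       replicate = NA_integer_, eps = 1) {
  stopifnot(inherits(sample, "signal_track"), inherits(control, "signal_track"))
  if (sample$total_reads <= 0 || control$total_reads <= 0)
    stop("zero total reads in sample or control track")
  if (window_bp < 1L) stop("window_bp must be >= 1")
  p_depth <- sample$total_reads / (sample$total_reads + control$total_reads)

  win <- list()
  for (ch in names(sample$counts)) {
    vs <- sample$counts[[ch]]
    vc <- control$counts[[ch]]
    if (length(vs) != length(vc)) stop("track lengths differ on ", ch)
    starts <- seq.int(1L, max(1L, length(vs) - window_bp + 1L), by = step_bp)
    cs <- c(0, cumsum(vs)); cc <- c(0, cumsum(vc))
    ends <- pmin(starts + window_bp - 1L, length(vs))
    xs <- cs[ends + 1L] - cs[starts]
    xc <- cc[ends + 1L] - cc[starts]
    n <- xs + xc
    pv <- ifelse(n > 0,
                 stats::pbinom(xs - 1, n, p_depth, lower.tail = FALSE), 1)
    win[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            xs = xs, xc = xc, pv = pv)
  }
  w <- do.call(rbind, win)
  w$q <- stats::p.adjust(w$pv, method = "BH")
  sig <- w[w$q < q_threshold, , drop = FALSE]

  empty <- genomic_intervals(character(), integer(), integer(),
                             qvalue = numeric(), ratio = numeric(),
                             excess_reads = numeric(),
                             protein = character(), replicate = integer())
  if (!nrow(sig)) return(empty)

  ## merge significant windows with gap <= step_bp (single linkage)
  gr <- GenomicRanges::GRanges(sig$chrom,
                               IRanges::IRanges(sig$start, sig$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = step_bp + 1L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]

  depth_scale <- control$total_reads / sample$total_reads
  rows <- lapply(split(seq_len(nrow(sig)), grp), function(idx) {
    ch <- sig$chrom[idx[1L]]
    s <- min(sig$start[idx]); e <- max(sig$end[idx])
    xs <- track_window_sum(sample, ch, s, e)
    xc <- track_window_sum(control, ch, s, e)
    data.frame(chrom = ch, start = s, end = e,
               qvalue = min(sig$q[idx]),
               ratio = ((xs + eps) / sample$total_reads) /
                 ((xc + eps) / control$total_reads),
               excess_reads = xs * depth_scale - xc)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$qvalue, -out$excess_reads), , drop = FALSE]
  genomic_intervals(out$chrom, out$start, out$end,
                    qvalue = out$qvalue, ratio = out$ratio,
                    excess_reads = out$excess_reads,
                    protein = protein, replicate = replicate)
}
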
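#' Aggregate kinetochore signal around a centromere
#'
#' Computes, at every nucleotide position of a 4-kb window centered on the
#' CEN midpoint (offsets -2000..+2000, 4001 positions), the mean
#' per-million-normalized kinetochore signal (averaged over the supplied
#' protein tracks, replicates included) and the control signal, plus their
#' pseudocounted log2 ratio.
#'
#' @param protein_tracks list of [signal_track()]s for the tagged proteins
#'   (replicates may simply be included as extra list elements)
#' @param control_track untagged-control [signal_track()]
#' @param cen one-row centromere interval
#' @param half_window half window width in bp (default 2000)
#' @param eps pseudocount in reads per million (default 0.1)
#' @return data.frame of class `aggregation_profile` with columns `offset`,
#'   `signal`, `control`, `ratio`, `log2_ratio`
#' @export
aggregate_cen_signal <- function(protein_tracks, control_track, cen,
                                 half_window = 2000L, eps = 0.1) {
  stopifnot(nrow(cen) == 1L)
  mid <- (cen$start + cen$end) %/% 2L
  ch <- as.character(cen$chrom)
  ctrl <- normalize_track(control_track)
  len <- length(ctrl$counts[[ch]])
  if (mid - half_window < 1L || mid + half_window > len)
    stop("centromere within ", half_window, " bp of a chromosome edge")
  idx <- (mid - half_window):(mid + half_window)

  sig <- rowMeans(vapply(protein_tracks, function(t) {
    t <- normalize_track(t)
    t$counts[[ch]][idx]
  }, numeric(length(idx))))
  ctl <- ctrl$counts[[ch]][idx]
  ratio <- (sig + eps) / (ctl + eps)
  out <- data.frame(offset = -half_window:half_window, signal = sig,
                    control = ctl, ratio = ratio,
                    log2_ratio = log2(ratio))
  class(out) <- c("aggregation_profile", "data.frame")
  out
}

#' Width of the centromeric enrichment peak
#'
#' Length (bp) of the contiguous run of positions, containing the window
#' center, whose unlogged signal/control ratio is at least
#' `ratio_threshold`. Returns 0 when the center itself is below threshold.
#' With `contiguous = FALSE`, counts every above-threshold position in the
#' window instead.
#'
#' @param profile an [aggregate_cen_signal()] profile
#' @param ratio_threshold ratio cutoff (default 2)
#' @param contiguous restrict to the central run (default) or count all
#'   positions
#' @return width in bp
#' @export
peak_width <- function(profile, ratio_threshold = 2, contiguous = TRUE) {
  above <- profile$ratio >= ratio_threshold
  if (!contiguous) return(sum(above))
  center <- which(profile$offset == 0L)
  if (!above[center]) return(0L)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  run <- findInterval(center, c(0L, ends) + 1L)
  r$lengths[run]
}

#' Paired t-test on per-centromere peak widths
#'
#' Two-sided paired t-test of the WT-vs-OP width difference, one pair per
#' centromere.
#'
#' @param widths_wt,widths_op numeric vectors of per-CEN widths, same CEN
#'   order, length >= 2
#' @return list with `t`, `df`, `p_value`, `mean_diff`, `degenerate`
#' @export
paired_width_test <- function(widths_wt, widths_op) {
  stopifnot(length(widths_wt) == length(widths_op), length(widths_wt) >= 2L)
  d <- widths_op - widths_wt
  if (stats::sd(d) == 0) {
    warning("zero variance of paired differences; test is degenerate")
    return(list(t = if (all(d == 0)) 0 else NA_real_,
                df = length(d) - 1L,
                p_value = if (all(d == 0)) 1 else NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(widths_op, widths_wt, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}
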
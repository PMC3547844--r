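#' Per-base coverage track
#'
#' A signal track stores one numeric per-base read-count vector per
#' chromosome, the total number of uniquely mapped reads it represents, a
#' sample identifier, and whether values have been scaled per million mapped
#' reads.
#'
#' @param counts named list of non-negative numeric vectors, one per
#'   chromosome, each of length equal to the chromosome length
#' @param sample_id sample identifier string
#' @param total_reads total mapped reads; defaults to the sum of counts
#' @param normalized logical; `TRUE` once scaled per million mapped reads
#' @return an object of class `signal_track`
#' @export
signal_track <- function(counts, sample_id = "sample",
                         total_reads = NULL, normalized = FALSE) {
  stopifnot(is.list(counts), !is.null(names(counts)))
  if (any(vapply(counts, function(v) any(v < 0), TRUE)))
    stop("signal track values must be >= 0")
  if (is.null(total_reads)) total_reads <- sum(vapply(counts, sum, 0))
  structure(list(counts = counts, sample_id = sample_id,
                 total_reads = total_reads, normalized = normalized),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track '", x$sample_id, "': ", length(x$counts),
      " chromosome(s), ", format(x$total_reads, big.mark = ","),
      " mapped reads", if (x$normalized) " (per-million normalized)",
      "\n", sep = "")
  invisible(x)
}

#' Scale a track per million mapped reads
#'
#' @param track a [signal_track()]
#' @return the track with counts multiplied by `1e6 / total_reads` and the
#'   `normalized` flag set
#' @export
normalize_track <- function(track) {
  if (track$normalized) return(track)
  if (track$total_reads <= 0) stop("cannot normalize a track with no reads")
  f <- 1e6 / track$total_reads
  track$counts <- lapply(track$counts, function(v) v * f)
  track$normalized <- TRUE
  track
}

#' Read a bedGraph file into a per-base track
#'
#' bedGraph intervals are 0-based half-open; positions not covered by any
#' interval are zero. Overlapping intervals are an error.
#'
#' @param path bedGraph file
#' @param chrom_lengths named integer vector of chromosome lengths
#' @param sample_id sample identifier for the resulting track
#' @param total_reads total mapped reads; default: sum of values read
#' @return a [signal_track()]
#' @export
read_signal_track <- function(path, chrom_lengths, sample_id = basename(path),
                              total_reads = NULL) {
  chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                   normalize_chrom(names(chrom_lengths)))
  counts <- lapply(chrom_lengths, numeric)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4L))
      stop("malformed bedGraph line ", which(lengths(fields) < 4L)[1L])
    chrom <- normalize_chrom(vapply(fields, `[[`, "", 1L))
    start1 <- as.integer(vapply(fields, `[[`, "", 2L)) + 1L
    end1 <- as.integer(vapply(fields, `[[`, "", 3L))
    val <- as.numeric(vapply(fields, `[[`, "", 4L))
    if (!all(chrom %in% names(chrom_lengths)))
      stop("bedGraph chromosome not in chrom_lengths: ",
           setdiff(chrom, names(chrom_lengths))[1L])
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      o <- i[order(start1[i])]
      if (any(end1[o] > chrom_lengths[[ch]]))
        stop("bedGraph interval beyond chromosome end on ", ch)
      if (length(o) > 1L && any(start1[o][-1L] <= end1[o][-length(o)]))
        stop("overlapping bedGraph intervals on chromosome ", ch)
      v <- counts[[ch]]
      for (j in o) v[start1[j]:end1[j]] <- val[j]
      counts[[ch]] <- v
    }
  }
  signal_track(counts, sample_id = sample_id, total_reads = total_reads)
}

#' Write a per-base track as bedGraph
#'
#' Runs of equal nonzero value are collapsed into single 0-based half-open
#' intervals; zero runs are omitted. `read_signal_track(write_signal_track(t))`
#' reproduces the counts exactly.
#'
#' @param track a [signal_track()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_signal_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$counts)) {
    v <- track$counts[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%.10g", ch,
                         starts[keep] - 1L, ends[keep], r$values[keep]), con)
    }
  }
  invisible(path)
}

## Internal: sum of track values over a 1-based inclusive interval.
track_window_sum <- function(track, chrom, start, end) {
  v <- track$counts[[as.character(chrom)]]
  if (is.null(v)) stop("track has no chromosome ", chrom)
  sum(v[max(1L, start):min(length(v), end)])
}
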
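#' Construct a genomic interval table
#'
#' The package's interval container is a plain `data.frame` with columns
#' `chrom`, `start`, `end` (1-based, inclusive on both ends, so
#' `width = end - start + 1`) plus any number of extra columns (site names,
#' q-values, enrichment ratios, ...). This constructor validates the
#' coordinate invariants.
#'
#' @param chrom chromosome names (normalized with [normalize_chrom()])
#' @param start,end 1-based inclusive coordinates; `end >= start >= 1`
#' @param ... additional columns, recycled as in `data.frame()`
#' @return a `data.frame` of class `c("genomic_intervals", "data.frame")`
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  chrom <- normalize_chrom(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) && any(start < 1L))
    stop("interval start must be >= 1 (1-based coordinates)")
  if (length(start) && any(end < start))
    stop("interval end must be >= start")
  out <- data.frame(chrom = chrom, start = start, end = end, ...,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Normalize chromosome names
#'
#' Chromosome identifiers are stored as bare integers rendered as character
#' ("1".."16"); `"chrN"` and `"chrom N"` aliases are accepted, as are roman
#' numeral-free integer inputs. Unrecognized names are kept verbatim.
#'
#' @param x character or integer vector of chromosome names
#' @return character vector of normalized names
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  x <- sub("^chr(om)?[ ]?", "", x, ignore.case = TRUE)
  x
}

#' Interval widths
#' @param x a genomic interval table
#' @return integer widths (`end - start + 1`)
#' @export
interval_width <- function(x) x$end - x$start + 1L

#' Edge-to-edge distance between intervals
#'
#' Vectorized gap distance between 1-based inclusive intervals: 0 when they
#' overlap or touch, otherwise the number of bases strictly between them
#' (`start2 - end1 - 1` for ordered disjoint intervals).
#'
#' @param s1,e1 first interval's start/end
#' @param s2,e2 second interval's start/end
#' @return integer distances
#' @export
interval_distance <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - e1, s1 - e2) - 1L)
}

## Internal: GRanges view of an interval table (chrom kept as seqnames).
as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start, end = x$end)
  )
}

#' Read intervals from a BED-like or TSV file
#'
#' Two dialects are supported. `"bed_like"` is BED3+ (0-based half-open,
#' tab-separated, no header): coordinates are converted to the internal
#' 1-based inclusive convention (`start + 1`, `end` unchanged). Optional
#' columns 4+ are kept as `name`, `score`/extra columns. `"tsv_table"` is a
#' header-carrying tab-separated table already in 1-based inclusive
#' coordinates with columns `chrom`, `start`, `end` (extra columns kept).
#'
#' @param path file to read
#' @param dialect `"bed_like"` or `"tsv_table"`
#' @return a [genomic_intervals()] table (possibly 0-row)
#' @export
read_intervals <- function(path, dialect = c("bed_like", "tsv_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "bed_like") {
    if (!length(lines)) return(genomic_intervals(character(), integer(), integer()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
      stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 fields")
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad))
      stop("malformed BED line ", bad[1L], ": non-numeric coordinates")
    if (any(end0 < start0 + 1L))
      stop("malformed BED line ", which(end0 < start0 + 1L)[1L],
           ": end < start")
    out <- genomic_intervals(chrom, start0 + 1L, end0)
    if (max(nf) >= 4L)
      out$name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
    if (max(nf) >= 5L)
      out$score <- suppressWarnings(as.numeric(
        vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else NA_character_, "")))
    if (max(nf) >= 7L)
      out$qvalue <- suppressWarnings(as.numeric(
        vapply(fields, function(f) if (length(f) >= 7L) f[[7L]] else NA_character_, "")))
    if (max(nf) >= 8L)
      out$ratio <- suppressWarnings(as.numeric(
        vapply(fields, function(f) if (length(f) >= 8L) f[[8L]] else NA_character_, "")))
    return(out)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  req <- c("chrom", "start", "end")
  alias <- c(chromosome = "chrom")
  for (a in names(alias)) if (a %in% names(tab))
    names(tab)[names(tab) == a] <- alias[[a]]
  if (!all(req %in% names(tab)))
    stop("TSV table must have columns chrom/start/end (found: ",
         paste(names(tab), collapse = ", "), ")")
  if (nrow(tab) && any(tab$end < tab$start)) {
    stop("malformed TSV line ", which(tab$end < tab$start)[1L], ": end < start")
  }
  extra <- tab[setdiff(names(tab), req)]
  do.call(genomic_intervals,
          c(list(chrom = tab$chrom, start = tab$start, end = tab$end),
            as.list(extra)))
}

#' Write intervals as BED
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention (`start - 1`, `end` unchanged). A `name` column, if
#' present, is written as BED column 4; any further columns follow in order.
#'
#' @param x a genomic interval table
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bed <- function(x, path) {
  bed <- data.frame(chrom = x$chrom, start = x$start - 1L, end = x$end)
  extra <- setdiff(names(x), c("chrom", "start", "end"))
  if ("name" %in% extra) extra <- c("name", setdiff(extra, "name"))
  for (col in extra) bed[[col]] <- x[[col]]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load the packaged table of published candidate-site coordinates
#'
#' Returns the packaged fixture of 61 candidate sites on the S. cerevisiae
#' genome: 23 high-confidence centromere-like regions (label `CLR`) and 38
#' low-confidence negative control regions (label `LCNCR`), with 1-based
#' inclusive coordinates as published.
#'
#' @return a [genomic_intervals()] table with columns `chrom`, `start`,
#'   `end`, `site`, `label`
#' @export
load_table1_sites <- function() {
  path <- system.file("extdata", "table1_sites.tsv", package = "clrscan")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged site table not found; package installation is corrupt")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site", "chrom", "start", "end", "label")
  if (!all(need %in% names(tab)) ||
      !all(tab$label %in% c("CLR", "LCNCR")) ||
      anyDuplicated(tab$site))
    stop("packaged site table is corrupt")
  genomic_intervals(tab$chrom, tab$start, tab$end,
                    site = tab$site, label = tab$label)
}

#' Read a FASTA file
#'
#' @param path FASTA file
#' @return named character vector of upper-cased sequences (alphabet
#'   restricted to A, C, G, T, N)
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate record names in FASTA: ", path)
  out <- toupper(as.character(seqs))
  names(out) <- nm
  if (any(grepl("[^ACGTN]", out)))
    stop("FASTA contains characters outside A/C/G/T/N")
  out
}

#' Write sequences as FASTA
#' @param seqs named character vector
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
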
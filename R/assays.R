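#' qPCR fold enrichment by the 2^-ddCp method
#'
#' Triplicate crossing points are summarized by their mean. For each primer,
#' the raw ratio is `2^(Cp_control - Cp_experimental)`; the normalized
#' enrichment of a positive primer is its raw ratio divided by the mean raw
#' ratio of the negative-control primers. Values above 2 are flagged as
#' significant binding.
#'
#' @param cp_table data.frame with columns `sample` ("tagged"/"untagged"),
#'   `primer`, `cp` (one row per well); extra columns ignored
#' @param neg_primers character vector of negative-control primer ids
#' @param significance_threshold flag cutoff (default 2)
#' @return data.frame with `primer`, `raw_ratio`, `enrichment`,
#'   `significant` for the positive primers
#' @export
qpcr_enrichment <- function(cp_table, neg_primers,
                            significance_threshold = 2) {
  stopifnot(all(c("sample", "primer", "cp") %in% names(cp_table)))
  if (!length(neg_primers) || !all(neg_primers %in% cp_table$primer))
    stop("negative-control primer(s) missing from the Cp table")
  mean_cp <- stats::aggregate(cp ~ sample + primer, cp_table, mean)
  exp_cp <- mean_cp[mean_cp$sample == "tagged", ]
  ctl_cp <- mean_cp[mean_cp$sample == "untagged", ]
  primers <- intersect(exp_cp$primer, ctl_cp$primer)
  raw <- 2^(ctl_cp$cp[match(primers, ctl_cp$primer)] -
              exp_cp$cp[match(primers, exp_cp$primer)])
  names(raw) <- primers
  neg_mean <- mean(raw[neg_primers])
  pos <- setdiff(primers, neg_primers)
  data.frame(primer = pos, raw_ratio = unname(raw[pos]),
             enrichment = unname(raw[pos]) / neg_mean,
             significant = unname(raw[pos]) / neg_mean >
               significance_threshold)
}

#' Doubling time from an OD600 time series
#'
#' Least-squares fit of `log2(OD)` against time, restricted to the
#' exponential range (`od_bounds`); the doubling time is the reciprocal
#' slope. A non-positive slope is flagged (`NA` returned).
#'
#' @param time_h time points in hours
#' @param od optical densities
#' @param od_bounds exponential-range OD bounds used for the fit; points
#'   outside are dropped (set to `c(0, Inf)` to fit the full series)
#' @return list with `doubling_time_h`, `slope`, `n_points`, `flagged`
#' @export
doubling_time <- function(time_h, od, od_bounds = c(0.05, 1.0)) {
  stopifnot(length(time_h) == length(od))
  keep <- od >= od_bounds[1L] & od <= od_bounds[2L] & od > 0
  if (sum(keep) < 3L) keep <- od > 0
  if (sum(keep) < 3L) stop("need at least 3 positive OD readings")
  fit <- stats::lm(log2(od[keep]) ~ time_h[keep])
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 1e-8) {
    warning("non-positive growth slope; doubling time undefined")
    return(list(doubling_time_h = NA_real_, slope = slope,
                n_points = sum(keep), flagged = TRUE))
  }
  list(doubling_time_h = 1 / slope, slope = slope, n_points = sum(keep),
       flagged = FALSE)
}

#' Fluctuation-analysis aggregation of technical replicates
#'
#' Summarizes the 3-5 technical replicates of one transformant by their
#' median, yielding one data point per transformant for the downstream group
#' comparison. For an even number of replicates the lower of the two middle
#' values is used (documented convention). A single replicate is returned
#' as-is with a warning.
#'
#' @param values numeric technical-replicate values for one transformant
#' @return one numeric value
#' @export
fluctuation_aggregate <- function(values) {
  n <- length(values)
  if (n == 1L) {
    warning("single technical replicate; returned as-is")
    return(values)
  }
  s <- sort(values)
  s[ceiling(n / 2)]
}

#' Plasmid retention fraction
#'
#' Colony count on selective plates divided by the count on permissive
#' plates.
#'
#' @param selective,permissive colony counts
#' @return retention fractions
#' @export
plasmid_retention <- function(selective, permissive) {
  if (any(permissive <= 0)) stop("permissive plate count must be positive")
  selective / permissive
}

#' Fisher's exact test on a 2x2 segregation table
#'
#' Two-sided exact hypergeometric p-value and the conditional
#' maximum-likelihood odds ratio, as in `stats::fisher.test`.
#'
#' @param counts 2x2 matrix or data.frame of non-negative counts
#'   (condition x outcome)
#' @return list with `p_value`, `odds_ratio`
#' @export
fisher_exact <- function(counts) {
  m <- as.matrix(counts)
  stopifnot(all(dim(m) == c(2L, 2L)), all(m >= 0))
  if (any(rowSums(m) == 0)) stop("empty row in the count table")
  ft <- stats::fisher.test(m)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}
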
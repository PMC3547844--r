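#' Distance to the nearest feature
#'
#' Minimum edge-to-edge distance (0 if overlapping or touching) from each
#' site to a feature set; ties are broken by the lowest feature start.
#'
#' @param sites,features [genomic_intervals()] tables
#' @return data.frame with `distance` and `nearest` (feature row index);
#'   sites on chromosomes without features get `Inf`
#' @export
distance_to_nearest <- function(sites, features) {
  if (!nrow(features)) stop("empty feature list")
  dist <- rep(Inf, nrow(sites))
  nearest <- rep(NA_integer_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    j <- which(features$chrom == sites$chrom[i])
    if (!length(j)) next
    d <- interval_distance(sites$start[i], sites$end[i],
                           features$start[j], features$end[j])
    best <- min(d)
    cand <- j[d == best]
    nearest[i] <- cand[which.min(features$start[cand])]
    dist[i] <- best
  }
  data.frame(distance = dist, nearest = nearest)
}

#' Randomization-test configuration
#'
#' @param iterations number of null draws (study value: 100,000)
#' @param window_bp proximity windows per feature class, bp
#' @param bonferroni_m family size for the Bonferroni adjustment over the
#'   discrete feature classes (tRNA, ARS, retrotransposon)
#' @param seed integer seed
#' @return list of class `randomization_config`
#' @export
randomization_config <- function(iterations = 100000L,
                                 window_bp = c(cen = 25000L, ars = 5000L,
                                               trna = 5000L, retro = 5000L),
                                 bonferroni_m = 3L, seed = 1L) {
  stopifnot(iterations >= 1L, all(window_bp > 0))
  structure(as.list(environment()), class = "randomization_config")
}

## Internal: per-chromosome merged "within window of a feature" intervals,
## as sorted boundary vectors usable with findInterval.
feature_windows <- function(features, window_bp, chrom_lengths) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    f <- features[features$chrom == ch, , drop = FALSE]
    if (!nrow(f)) { out[[ch]] <- cbind(start = numeric(), end = numeric()); next }
    gr <- IRanges::reduce(IRanges::IRanges(
      pmax(1L, f$start - window_bp), pmin(chrom_lengths[[ch]],
                                          f$end + window_bp)))
    out[[ch]] <- cbind(start = IRanges::start(gr), end = IRanges::end(gr))
  }
  out
}

## Internal: is point x inside any [start,end] of a sorted window matrix?
points_in_windows <- function(x, win) {
  if (!nrow(win)) return(rep(FALSE, length(x)))
  i <- findInterval(x, win[, "start"])
  res <- logical(length(x))
  ok <- i > 0L
  res[ok] <- x[ok] <= win[i[ok], "end"]
  res
}

#' Randomization test of site-feature association
#'
#' The observed statistic is the number of sites whose edge distance to the
#' nearest feature is at most the window. The null redraws, per iteration,
#' the same number of random point positions per chromosome as the sites'
#' chromosomal distribution, and counts how many fall within the window of a
#' feature. The empirical p-value is the plain fraction of iterations with a
#' count greater than or equal to the observed one (resolution
#' 1/iterations; a zero count is reported as `< 1/iterations` via
#' `p_lt_resolution`). Bonferroni adjustment multiplies by
#' `config$bonferroni_m` for the discrete feature classes.
#'
#' @param sites site intervals
#' @param features feature intervals
#' @param chrom_lengths named vector of chromosome lengths
#' @param window_bp proximity window, bp
#' @param config a [randomization_config()]
#' @param adjust apply the Bonferroni family-size multiplier
#' @return list of class `randomization_result`: `observed`, `null_mean`,
#'   `null_quantiles`, `p_value`, `p_adjusted`, `p_lt_resolution`,
#'   `iterations`, `seed`
#' @export
association_randomization_test <- function(sites, features, chrom_lengths,
                                           window_bp = 5000L,
                                           config = randomization_config(),
                                           adjust = FALSE) {
  chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                   normalize_chrom(names(chrom_lengths)))
  if (any(2 * window_bp >= chrom_lengths))
    stop("proximity window larger than a chromosome")
  win <- feature_windows(features, window_bp, chrom_lengths)

  d <- distance_to_nearest(sites, features)$distance
  observed <- sum(d <= window_bp)

  site_chroms <- table(sites$chrom)
  counts <- with_seed(config$seed, {
    tot <- integer(config$iterations)
    for (ch in names(site_chroms)) {
      n <- site_chroms[[ch]]
      x <- matrix(ceiling(stats::runif(n * config$iterations) *
                            chrom_lengths[[ch]]),
                  nrow = n)
      inw <- points_in_windows(as.vector(x), win[[ch]])
      tot <- tot + colSums(matrix(inw, nrow = n))
    }
    tot
  })
  p <- mean(counts >= observed)
  structure(list(
    observed = observed,
    null_mean = mean(counts),
    null_quantiles = stats::quantile(counts, c(0.025, 0.5, 0.975)),
    p_value = p,
    p_adjusted = if (adjust) min(1, p * config$bonferroni_m) else p,
    p_lt_resolution = p == 0,
    iterations = config$iterations,
    seed = config$seed), class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  pv <- if (x$p_lt_resolution) paste0("< ", format(1 / x$iterations)) else
    format(x$p_value)
  cat("randomization test: observed ", x$observed, ", null mean ",
      round(x$null_mean, 2), ", p ", pv, " (", x$iterations,
      " iterations)\n", sep = "")
  invisible(x)
}

#' Centromere-proximal fraction with randomization test
#'
#' A site is centromere-proximal if its edge distance to the nearest CEN is
#' at most `window_bp` (25 kb by default; a site at exactly 25,000 bp is
#' proximal).
#'
#' @param sites site intervals
#' @param cens centromere intervals
#' @param chrom_lengths named chromosome lengths
#' @param window_bp proximity threshold
#' @param config a [randomization_config()]
#' @return list with `fraction`, `proximal` (logical per site), and `test`
#'   (a `randomization_result`)
#' @export
cen_proximity_fraction <- function(sites, cens, chrom_lengths,
                                   window_bp = 25000L,
                                   config = randomization_config()) {
  d <- distance_to_nearest(sites, cens)$distance
  proximal <- d <= window_bp
  test <- association_randomization_test(sites, cens, chrom_lengths,
                                         window_bp, config, adjust = FALSE)
  list(fraction = mean(proximal), proximal = proximal, test = test)
}

#' Intergenic regions from an ORF annotation
#'
#' Maximal gaps between consecutive ORFs on each chromosome (chromosome ends
#' included as region boundaries).
#'
#' @param orfs ORF intervals
#' @param chrom_lengths named chromosome lengths
#' @return a [genomic_intervals()] table of intergenic regions
#' @export
intergenic_regions <- function(orfs, chrom_lengths) {
  chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                   normalize_chrom(names(chrom_lengths)))
  rows <- lapply(names(chrom_lengths), function(ch) {
    o <- orfs[orfs$chrom == ch, , drop = FALSE]
    if (!nrow(o))
      return(data.frame(chrom = ch, start = 1L, end = chrom_lengths[[ch]]))
    gr <- IRanges::reduce(IRanges::IRanges(o$start, o$end))
    gaps <- IRanges::gaps(gr, start = 1L, end = chrom_lengths[[ch]])
    if (!length(gaps)) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(gaps),
               end = IRanges::end(gaps))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- do.call(rbind, rows)
  genomic_intervals(out$chrom, out$start, out$end)
}

#' Intergenic-length randomization test
#'
#' Sites partly overlapping an ORF are excluded from the observed set. The
#' observed statistic is the mean length of the intergenic regions that
#' contain the remaining sites; the null draws the same number of intergenic
#' regions at random and compares mean lengths. p = fraction of iterations
#' with null mean >= observed.
#'
#' @param sites site intervals
#' @param orfs ORF intervals
#' @param chrom_lengths named chromosome lengths
#' @param config a [randomization_config()]
#' @return a `randomization_result` with extra fields `n_used`,
#'   `n_excluded`
#' @export
intergenic_length_test <- function(sites, orfs, chrom_lengths,
                                   config = randomization_config()) {
  ig <- intergenic_regions(orfs, chrom_lengths)
  overlaps_orf <- GenomicRanges::countOverlaps(as_gr(sites), as_gr(orfs)) > 0L
  used <- sites[!overlaps_orf, , drop = FALSE]
  if (!nrow(used)) stop("no site lies fully outside ORFs")

  host <- GenomicRanges::findOverlaps(as_gr(used), as_gr(ig), select = "first")
  if (anyNA(host)) {
    warning(sum(is.na(host)), " site(s) not contained in any intergenic ",
            "region were excluded")
    used <- used[!is.na(host), , drop = FALSE]
    host <- host[!is.na(host)]
  }
  lens <- interval_width(ig)
  observed <- mean(lens[host])
  n <- nrow(used)

  null_means <- with_seed(config$seed, {
    draws <- matrix(sample.int(nrow(ig), n * config$iterations,
                               replace = TRUE), nrow = n)
    colMeans(matrix(lens[draws], nrow = n))
  })
  p <- mean(null_means >= observed)
  structure(list(observed = observed, null_mean = mean(null_means),
                 null_quantiles = stats::quantile(null_means,
                                                  c(0.025, 0.5, 0.975)),
                 p_value = p, p_adjusted = p, p_lt_resolution = p == 0,
                 iterations = config$iterations, seed = config$seed,
                 n_used = n, n_excluded = sum(overlaps_orf)),
            class = "randomization_result")
}

#' Maximum AT content of a sliding window
#'
#' Slides a `window`-bp window over the sequence and returns the maximum AT
#' fraction, the first-occurring window start achieving it, and the mean AT
#' of the whole sequence. N bases count as non-AT (with a warning).
#'
#' @param sequence a DNA string (typically the 500-bp region centered at the
#'   aggregated kinetochore-signal maximum)
#' @param window window width in bp (default 90)
#' @return list with `max_at`, `window_start`, `mean_at`
#' @export
max_at_content <- function(sequence, window = 90L) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < window) stop("sequence shorter than the window")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (any(chars == "N")) warning("N bases counted as non-AT")
  at <- as.numeric(chars %in% c("A", "T"))
  cs <- c(0, cumsum(at))
  starts <- seq_len(n - window + 1L)
  frac <- (cs[starts + window] - cs[starts]) / window
  best <- max(frac)
  list(max_at = best, window_start = starts[which.max(frac)],
       mean_at = mean(at))
}

#' Bootstrap comparison of two groups of values
#'
#' Nonparametric resampling comparison used for doubling times and plasmid
#' retention: each draw resamples both groups with replacement and records
#' the difference of group means; the two-sided p-value is twice the
#' fraction of draws on the minority side of zero, capped at 1.
#'
#' @param group_a,group_b numeric vectors (>= 3 values each; typically one
#'   fluctuation-analysis median per transformant)
#' @param n_comparisons number of resampling draws (study value: 100,000)
#' @param seed integer seed
#' @return list with `p_value`, `observed_diff`, `n_comparisons`
#' @export
resampling_group_compare <- function(group_a, group_b,
                                     n_comparisons = 100000L, seed = 1L) {
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("at least 3 values per group are required")
  obs <- mean(group_a) - mean(group_b)
  if (stats::var(c(group_a, group_b)) == 0) {
    warning("degenerate all-equal data; p = 1")
    return(list(p_value = 1, observed_diff = obs,
                n_comparisons = n_comparisons))
  }
  diffs <- with_seed(seed, {
    a <- matrix(sample(group_a, length(group_a) * n_comparisons,
                       replace = TRUE), ncol = n_comparisons)
    b <- matrix(sample(group_b, length(group_b) * n_comparisons,
                       replace = TRUE), ncol = n_comparisons)
    colMeans(a) - colMeans(b)
  })
  p <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  list(p_value = p, observed_diff = obs, n_comparisons = n_comparisons)
}
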
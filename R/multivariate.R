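#' Canonical feature-variable names
#'
#' The 12 per-site context variables used by the classification stage, in
#' canonical order: percent of site length overlapping an ORF; mean AT
#' content; distance to CEN; maximum AT content (90-bp window); length of
#' the closest intergenic region; distance to retrotransposon; rank of the
#' closest open-chromatin (Sono-Seq) region scored against the HA control;
#' distance to tRNA; rank of the closest Sono-Seq region scored against the
#' Myc control; rank of the closest PolII region; distance to ARS; rank of
#' the closest Cse4 region from a Cse4 wild-type strain.
#'
#' @return character vector of 12 column names
#' @export
feature_variable_names <- function() {
  c("pct_orf_overlap", "mean_at", "dist_cen", "max_at",
    "intergenic_length", "dist_retro", "rank_sono_ha", "dist_trna",
    "rank_sono_myc", "rank_polii", "dist_ars", "rank_cse4_wt")
}

#' Position of the aggregated kinetochore-signal maximum within a site
#'
#' Averages the supplied per-million-normalized tracks and returns the
#' genomic position of the (first) maximum inside the site interval.
#'
#' @param tracks list of [signal_track()]s to average
#' @param site one-row site interval
#' @return integer genomic position
#' @export
signal_max_center <- function(tracks, site) {
  ch <- as.character(site$chrom)
  idx <- site$start:site$end
  m <- rowMeans(vapply(tracks, function(t) {
    t <- normalize_track(t)
    t$counts[[ch]][idx]
  }, numeric(length(idx))))
  idx[which.max(m)]
}

#' Extract the 12 context variables for each site
#'
#' Distances are edge-to-edge ([distance_to_nearest()]); "rank of closest X
#' region" is the row position of the nearest X region in X's
#' significance-sorted target list; AT variables come from the 90-bp sliding
#' window over the 500-bp region centered at `centers` (site midpoints by
#' default, or the aggregated-signal maximum when computed upstream).
#' A missing auxiliary ranked list leaves its variable `NA` with a warning;
#' such columns are excluded downstream.
#'
#' @param sites site intervals
#' @param annotations list with `orfs`, `arss`, `trnas`, `retros` interval
#'   tables
#' @param cens centromere intervals
#' @param chrom_lengths named chromosome lengths
#' @param sequence named character vector of chromosome sequences
#' @param ranked_lists list of significance-sorted interval tables:
#'   `sono_ha`, `sono_myc`, `polii`, `cse4_wt` (any may be `NULL`)
#' @param centers optional integer vector of per-site window centers
#' @param at_region width of the AT-content region (default 500)
#' @param at_window sliding window width (default 90)
#' @return data.frame of the 12 variables (canonical names) plus `site`
#'   row names
#' @export
extract_features <- function(sites, annotations, cens, chrom_lengths,
                             sequence,
                             ranked_lists = list(sono_ha = NULL,
                                                 sono_myc = NULL,
                                                 polii = NULL,
                                                 cse4_wt = NULL),
                             centers = NULL, at_region = 500L,
                             at_window = 90L) {
  n <- nrow(sites)
  chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                   normalize_chrom(names(chrom_lengths)))
  if (is.null(centers)) centers <- (sites$start + sites$end) %/% 2L

  ## percent of site length overlapping an ORF
  orfs <- annotations$orfs
  pct <- vapply(seq_len(n), function(i) {
    o <- orfs[orfs$chrom == sites$chrom[i], , drop = FALSE]
    if (!nrow(o)) return(0)
    ov <- IRanges::intersect(
      IRanges::IRanges(sites$start[i], sites$end[i]),
      IRanges::reduce(IRanges::IRanges(o$start, o$end)))
    100 * sum(IRanges::width(ov)) / interval_width(sites[i, ])
  }, 0)

  ## AT content over the centered region
  at <- t(vapply(seq_len(n), function(i) {
    L <- chrom_lengths[[as.character(sites$chrom[i])]]
    a <- max(1L, min(centers[i] - at_region %/% 2L, L - at_region + 1L))
    s <- substr(sequence[[as.character(sites$chrom[i])]], a,
                a + at_region - 1L)
    r <- max_at_content(s, at_window)
    c(r$mean_at, r$max_at)
  }, c(0, 0)))

  nearest_rank <- function(lst) {
    if (is.null(lst) || !nrow(lst)) return(rep(NA_real_, n))
    distance_to_nearest(sites, lst)$nearest
  }
  dist_cen <- distance_to_nearest(sites, cens)$distance
  dist_retro <- distance_to_nearest(sites, annotations$retros)$distance
  dist_trna <- distance_to_nearest(sites, annotations$trnas)$distance
  dist_ars <- distance_to_nearest(sites, annotations$arss)$distance

  ig <- intergenic_regions(orfs, chrom_lengths)
  ig_near <- distance_to_nearest(sites, ig)$nearest
  ig_len <- interval_width(ig)[ig_near]

  out <- data.frame(
    pct_orf_overlap = pct, mean_at = at[, 1], dist_cen = dist_cen,
    max_at = at[, 2], intergenic_length = ig_len, dist_retro = dist_retro,
    rank_sono_ha = nearest_rank(ranked_lists$sono_ha),
    dist_trna = dist_trna,
    rank_sono_myc = nearest_rank(ranked_lists$sono_myc),
    rank_polii = nearest_rank(ranked_lists$polii),
    dist_ars = dist_ars,
    rank_cse4_wt = nearest_rank(ranked_lists$cse4_wt))
  if (anyNA(out))
    warning("missing auxiliary ranked list(s): variable(s) ",
            paste(names(out)[colSums(is.na(out)) > 0], collapse = ", "),
            " are NA and should be excluded downstream")
  if (!is.null(sites$site)) rownames(out) <- sites$site
  else if (!is.null(sites$name)) rownames(out) <- sites$name
  out
}

#' Choose normalizing transforms per variable
#'
#' For each variable, picks among identity, log (on positive-shifted
#' values) and square root (on nonnegative-shifted values) the transform
#' with the highest Shapiro-Wilk W, then records standardization (mean, SD)
#' on the transformed scale.
#'
#' @param x data.frame or matrix of numeric variables
#' @return list of class `transform_spec`: per-variable `transform`,
#'   `shift`, `mean`, `sd`
#' @export
fit_transforms <- function(x) {
  x <- as.data.frame(x)
  spec <- lapply(x, function(v) {
    shift_log <- if (min(v) <= 0) 1 - min(v) else 0
    shift_sqrt <- if (min(v) < 0) -min(v) else 0
    cand <- list(identity = v, log = log(v + shift_log),
                 sqrt = sqrt(v + shift_sqrt))
    w <- vapply(cand, function(tv) {
      if (stats::sd(tv) == 0) return(-Inf)
      tryCatch(stats::shapiro.test(tv)$statistic, error = function(e) -Inf)
    }, 0)
    best <- names(which.max(w))
    tv <- cand[[best]]
    s <- stats::sd(tv)
    list(transform = best,
         shift = switch(best, log = shift_log, sqrt = shift_sqrt, 0),
         mean = mean(tv), sd = if (s > 0) s else 1)
  })
  structure(spec, class = "transform_spec")
}

#' Apply a fitted transform specification
#'
#' @param x data.frame/matrix with the same variables as the spec
#' @param spec a [fit_transforms()] result
#' @return matrix of transformed, z-scored variables
#' @export
apply_transforms <- function(x, spec) {
  x <- as.data.frame(x)
  stopifnot(all(names(spec) %in% names(x)))
  out <- vapply(names(spec), function(nm) {
    v <- x[[nm]]; sp <- spec[[nm]]
    tv <- switch(sp$transform, identity = v, log = log(v + sp$shift),
                 sqrt = sqrt(v + sp$shift))
    (tv - sp$mean) / sp$sd
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), names(spec)))
  out
}

#' Multivariate-normality quantile check
#'
#' Ordered squared Mahalanobis distances against chi-square quantiles with a
#' simulation envelope: `n_sim` Gaussian datasets of the same shape give
#' pointwise envelope bounds at the requested level; points outside are
#' flagged.
#'
#' @param x numeric matrix (n x p, n > p)
#' @param level envelope level (default 0.95)
#' @param n_sim number of simulated datasets
#' @param seed integer seed
#' @return list with `d2` (sorted), `chisq_q`, `lower`, `upper`, `outside`
#'   (logical, in sorted order), `order` (row permutation that sorts)
#' @export
multivariate_normality_check <- function(x, level = 0.95, n_sim = 1000L,
                                         seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("need more observations than variables (singular covariance)")
  d2 <- stats::mahalanobis(x, colMeans(x), stats::cov(x))
  ord <- order(d2)
  probs <- (seq_len(n) - 0.5) / n
  qs <- stats::qchisq(probs, df = p)
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(b) {
      z <- matrix(stats::rnorm(n * p), n, p)
      sort(stats::mahalanobis(z, colMeans(z), stats::cov(z)))
    }, numeric(n))
  })
  a <- (1 - level) / 2
  lower <- apply(sims, 1L, stats::quantile, probs = a)
  upper <- apply(sims, 1L, stats::quantile, probs = 1 - a)
  ds <- d2[ord]
  list(d2 = ds, chisq_q = qs, lower = lower, upper = upper,
       outside = ds < lower | ds > upper, order = ord)
}

#' MANOVA and per-variable ANOVA between site groups
#'
#' @param x numeric matrix of (transformed) variables
#' @param labels group labels, two or more groups with >= 2 members each
#' @return list with `manova_p` (Wilks) and named `anova_p` per variable
#' @export
group_difference_tests <- function(x, labels) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (any(table(labels) < 2L)) stop("every group needs at least 2 members")
  fit <- stats::manova(x ~ labels)
  manova_p <- summary(fit, test = "Wilks")$stats[1L, "Pr(>F)"]
  anova_p <- apply(x, 2L, function(v)
    summary(stats::aov(v ~ labels))[[1L]][["Pr(>F)"]][1L])
  list(manova_p = unname(manova_p), anova_p = anova_p)
}

#' Linear discriminant analysis with leave-one-out cross-validation
#'
#' Two-class LDA on standardized variables. Coefficients are reported on the
#' standardized scale and oriented so the mean score of the `positive` group
#' is positive. LOOCV accuracy is the fraction of sites whose left-out
#' prediction matches their label. Set `exclude` to run the reduced-variable
#' variant (e.g. without the percent-ORF-overlap variable).
#'
#' @param x numeric matrix of standardized variables
#' @param labels two-level group labels
#' @param positive label whose mean score is oriented positive
#' @param exclude variable names to drop before fitting
#' @return list with `coefficients`, `scores`, `loocv_accuracy`,
#'   `loocv_class`, `variables`
#' @export
lda_fit_loocv <- function(x, labels, positive = "CLR",
                          exclude = character()) {
  x <- as.matrix(x)
  if (length(exclude)) x <- x[, setdiff(colnames(x), exclude), drop = FALSE]
  labels <- factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) < 2L))
    stop("two groups with >= 2 sites each are required")
  fit <- tryCatch(MASS::lda(x, grouping = labels),
                  error = function(e) {
                    warning("singular pooled covariance; ridge applied")
                    MASS::lda(x + matrix(stats::rnorm(length(x), 0, 1e-8),
                                         nrow(x)), grouping = labels)
                  })
  w <- fit$scaling[, 1L]
  scores <- scale(x, center = colMeans(x), scale = FALSE) %*% w
  if (mean(scores[labels == positive]) < 0) { w <- -w; scores <- -scores }
  cv <- MASS::lda(x, grouping = labels, CV = TRUE)
  acc <- mean(as.character(cv$class) == as.character(labels))
  list(coefficients = w, scores = drop(scores), loocv_accuracy = acc,
       loocv_class = cv$class, variables = colnames(x))
}

#' k-nearest-neighbor classification with leave-one-out CV
#'
#' Euclidean-distance majority vote on the standardized feature matrix.
#'
#' @param x numeric matrix of standardized variables
#' @param labels group labels
#' @param k number of neighbors (default 3)
#' @return LOOCV accuracy (fraction correct)
#' @export
knn_classify_loocv <- function(x, labels, k = 3L) {
  x <- as.matrix(x)
  if (k >= nrow(x)) stop("k must be smaller than the number of sites")
  pred <- class::knn.cv(x, cl = factor(labels), k = k)
  mean(as.character(pred) == as.character(labels))
}

#' Two-means clustering accuracy against known labels
#'
#' Unsupervised alternative to the discriminant: k-means with k = 2 on the
#' standardized features, clusters matched to the two labels by the
#' assignment that maximizes agreement.
#'
#' @param x numeric matrix of standardized variables
#' @param labels two-level group labels
#' @param nstart random restarts for `stats::kmeans`
#' @param seed integer seed
#' @return fraction of sites whose matched cluster agrees with their label
#' @export
kmeans_label_accuracy <- function(x, labels, nstart = 25L, seed = 1L) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L)
  cl <- with_seed(seed, stats::kmeans(as.matrix(x), centers = 2L,
                                      nstart = nstart)$cluster)
  agree <- mean((cl == 1L) == (labels == levels(labels)[1L]))
  max(agree, 1 - agree)
}

#' Principal component analysis with parallel analysis
#'
#' Eigendecomposition of the correlation matrix. Component retention by
#' parallel analysis: `n_null` random standard-normal datasets of the same
#' shape are decomposed and a component is retained while its eigenvalue
#' exceeds the matched null eigenvalue's `quantile` (components are counted
#' from the first until the first failure).
#'
#' @param x numeric matrix (no constant columns)
#' @param n_null number of null datasets (default 1000)
#' @param quantile null eigenvalue percentile (default 0.95)
#' @param seed integer seed
#' @return list with `eigenvalues`, `loadings`, `scores`,
#'   `null_thresholds`, `n_significant`
#' @export
pca_parallel_analysis <- function(x, n_null = 1000L, quantile = 0.95,
                                  seed = 1L) {
  x <- as.matrix(x)
  if (any(apply(x, 2L, stats::sd) == 0))
    stop("constant variable (zero variance)")
  n <- nrow(x); p <- ncol(x)
  e <- eigen(stats::cor(x), symmetric = TRUE)
  null_ev <- with_seed(seed, {
    t(vapply(seq_len(n_null), function(b) {
      z <- matrix(stats::rnorm(n * p), n, p)
      eigen(stats::cor(z), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p)))
  })
  thr <- apply(null_ev, 2L, stats::quantile, probs = quantile)
  sig <- e$values > thr
  n_sig <- if (sig[1L]) which.min(c(sig, FALSE)) - 1L else 0L
  scores <- scale(x) %*% e$vectors
  dimnames(e$vectors) <- list(colnames(x), paste0("PC", seq_len(p)))
  colnames(scores) <- paste0("PC", seq_len(p))
  list(eigenvalues = e$values, loadings = e$vectors, scores = scores,
       null_thresholds = thr, n_significant = n_sig)
}

#' Covariance-based confidence ellipse for 2-D scores
#'
#' Ellipse at the chi-square(2) quantile of the requested level: center at
#' the mean, axes along the covariance eigenvectors with half-lengths
#' `sqrt(eigenvalue * qchisq(level, 2))`.
#'
#' @param scores two-column numeric matrix
#' @param level confidence level (default 0.95)
#' @return list with `center`, `radii`, `angle` (radians), `degenerate`
#' @export
confidence_ellipse <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2L)
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  e <- eigen(S, symmetric = TRUE)
  degenerate <- any(e$values <= .Machine$double.eps * max(e$values, 1))
  if (degenerate) warning("degenerate (rank-deficient) score covariance")
  q <- stats::qchisq(level, df = 2)
  list(center = ctr, radii = sqrt(pmax(e$values, 0) * q),
       angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
       degenerate = degenerate)
}
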
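#' Simulation configuration
#'
#' Defaults emulate the study design: a compact genome (4 chromosomes x
#' 300 kb) with one point centromere per chromosome, ORFs tiling roughly 70%
#' of each chromosome, scattered ARSs / tRNAs / retrotransposons, and 20
#' planted centromere-like regions (CLRs) of which about half are placed
#' within 25 kb of a centromere. Kinetochore occupancy at planted CLRs is an
#' order of magnitude weaker than at centromeres (`clr_multiplier =
#' cen_multiplier / 10`) and appears only in the Cse4-overproduction (OP)
#' genotype; centromere occupancy is strong in both genotypes, with a broader
#' enrichment footprint in OP. Two biological replicates per tagged protein
#' (Cse4, Mif2, Ndc10, Ndc80) plus matched untagged controls are generated.
#' Background counts are Poisson with block-level Gamma overdispersion.
#'
#' @param n_chroms number of chromosomes
#' @param chrom_length chromosome length in bp
#' @param gc background GC fraction of the simulated sequence
#' @param n_clrs number of planted CLRs genome-wide
#' @param cen_bias fraction of planted CLRs placed within 25 kb of a CEN
#' @param clr_length planted CLR length in bp
#' @param cen_multiplier fold enrichment of kinetochore signal over CENs
#' @param clr_multiplier fold enrichment over planted CLRs (OP genotype only)
#' @param n_replicates biological replicates per sample (>= 2)
#' @param background_rate mean background reads per base per replicate
#' @param block_bp width of Gamma-overdispersion blocks
#' @param overdispersion_cv coefficient of variation of block-level rate
#'   factors (0 disables overdispersion)
#' @param replicate_sd lognormal SD of the per-replicate enrichment factor
#' @param at_patch_len length of the AT-rich patch planted at each CLR/CEN
#' @param at_fraction AT fraction inside the planted patch
#' @param cen_width width of the CEN element
#' @param cen_kernel_wt,cen_kernel_op width (bp) of the centromeric
#'   enrichment footprint in WT and Cse4-OP; OP is broader
#' @param cen_kernel_sd lognormal SD of the per-centromere footprint-width
#'   jitter (footprints vary between centromeres)
#' @param proteins tagged kinetochore proteins
#' @param seed integer seed; every generator is deterministic given it
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_chroms = 4L, chrom_length = 300000L, gc = 0.38,
                       n_clrs = 20L, cen_bias = 0.5, clr_length = 600L,
                       cen_multiplier = 50, clr_multiplier = cen_multiplier / 10,
                       n_replicates = 2L, background_rate = 2,
                       block_bp = 1000L, overdispersion_cv = 0.1,
                       replicate_sd = 0.1, at_patch_len = 90L,
                       at_fraction = 0.9, cen_width = 125L,
                       cen_kernel_wt = 400L, cen_kernel_op = 800L,
                       cen_kernel_sd = 0.05,
                       proteins = c("Cse4", "Mif2", "Ndc10", "Ndc80"),
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$cen_multiplier <= 1 || cfg$clr_multiplier <= 1)
    stop("enrichment multipliers must exceed 1")
  if (cfg$clr_multiplier >= cfg$cen_multiplier)
    stop("clr_multiplier must be smaller than cen_multiplier")
  if (cfg$n_replicates < 2L) stop("at least 2 replicates are required")
  class(cfg) <- "sim_config"
  cfg
}

## Internal: run expr with a local RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

#' Derive a per-stage child seed from a root seed
#'
#' Stable string hash of the stage name folded into the root seed, keeping
#' the result a valid 32-bit integer. Used so one pipeline seed yields
#' distinct, reproducible streams per stage.
#'
#' @param seed root integer seed
#' @param stage stage name
#' @return integer child seed
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480009)
}

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Simulate a genome with planted truth
#'
#' Builds, deterministically from `config$seed`: chromosome sequences at the
#' configured GC content; one centromere per chromosome (with an AT-rich
#' patch); an ORF tiling (~70% coverage) whose maximal gaps define the
#' intergenic regions; scattered ARSs, tRNAs and retrotransposons; and the
#' planted CLRs, each centered in an intergenic gap, carrying an AT-rich
#' 90-bp patch, with the configured fraction placed within 25 kb of a CEN.
#'
#' @param config a [sim_config()]
#' @return a list of class `synthetic_truth` with elements `chrom_lengths`,
#'   `cens`, `clrs`, `annotations` (list: orfs, arss, trnas, retros),
#'   `sequence`, `config`
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$chrom_length
  if (L < 70000L)
    stop("chromosome too short to host the requested features (need >= 70 kb)")
  with_seed(derive_seed(config$seed, "genome"), {
    chroms <- as.character(seq_len(config$n_chroms))
    margin <- 30000L

    cen_mid <- vapply(chroms, function(ch)
      as.integer(round(stats::runif(1, margin, L - margin))), 1L)
    half_cen <- config$cen_width %/% 2L
    cens <- genomic_intervals(chroms, cen_mid - half_cen,
                              cen_mid - half_cen + config$cen_width - 1L)

    ## ORF tiling: alternate exponential gaps (~mean 600) and ORFs (~mean
    ## 1400), i.e. ~70% coverage; ORFs near the CEN are removed so the CEN
    ## sits in an intergenic region.
    orf_list <- list()
    for (i in seq_along(chroms)) {
      pos <- 1L
      starts <- ends <- integer()
      while (pos < L - 2000L) {
        gap <- 100L + as.integer(round(stats::rexp(1, 1 / 500)))
        olen <- 300L + as.integer(round(stats::rexp(1, 1 / 1100)))
        s <- pos + gap
        e <- min(s + olen - 1L, L - 100L)
        if (e > s) { starts <- c(starts, s); ends <- c(ends, e) }
        pos <- e + 1L
      }
      keep <- !(ends >= cens$start[i] - 800L & starts <= cens$end[i] + 800L)
      starts <- starts[keep]; ends <- ends[keep]
      orf_list[[i]] <- genomic_intervals(
        rep(chroms[i], length(starts)), starts, ends,
        name = sprintf("ORF_%s_%03d", chroms[i], seq_along(starts)),
        strand = sample(c("+", "-"), length(starts), replace = TRUE))
    }
    orfs <- do.call(rbind, orf_list)

    scatter <- function(n_per_chrom, width, prefix) {
      out <- lapply(seq_along(chroms), function(i) {
        s <- as.integer(round(stats::runif(n_per_chrom, 2000, L - 2000 - width)))
        genomic_intervals(rep(chroms[i], n_per_chrom), s, s + width - 1L,
                          name = sprintf("%s_%s_%02d", prefix, chroms[i],
                                         seq_len(n_per_chrom)))
      })
      do.call(rbind, out)
    }
    arss <- scatter(10L, 200L, "ARS")
    trnas <- scatter(8L, 80L, "tRNA")
    retros <- scatter(3L, 300L, "Ty")

    ## Plant CLRs in intergenic gaps, honoring the CEN-proximity bias.
    clr_chrom <- sample(chroms, config$n_clrs, replace = TRUE)
    proximal <- stats::runif(config$n_clrs) < config$cen_bias
    clr_rows <- list()
    used <- genomic_intervals(character(), integer(), integer())
    for (k in seq_len(config$n_clrs)) {
      i <- match(clr_chrom[k], chroms)
      o <- orf_list[[i]]
      gs <- c(1L, o$end + 1L)
      ge <- c(o$start - 1L, L)
      ok <- ge - gs + 1L >= config$clr_length + 40L &
        gs > 2200L & ge < L - 2200L
      mid <- (gs + ge) %/% 2L
      cl_s <- mid - config$clr_length %/% 2L
      cl_e <- cl_s + config$clr_length - 1L
      d <- interval_distance(cl_s, cl_e, cens$start[i], cens$end[i])
      ok <- ok & !(cl_e >= cens$start[i] - 200L & cl_s <= cens$end[i] + 200L)
      if (nrow(used)) {
        ui <- used[used$chrom == chroms[i], , drop = FALSE]
        if (nrow(ui)) {
          for (u in seq_len(nrow(ui)))
            ok <- ok & !(cl_e >= ui$start[u] - 500L & cl_s <= ui$end[u] + 500L)
        }
      }
      want <- if (proximal[k]) ok & d <= 24000L else ok & d > 26000L
      cand <- which(want)
      if (!length(cand))
        stop("chromosome ", chroms[i],
             " too short or crowded to host planted CLR ", k)
      j <- sample(cand, 1L)
      row <- genomic_intervals(chroms[i], cl_s[j], cl_e[j],
                               name = sprintf("synthCLR%02d", k),
                               proximal = proximal[k])
      clr_rows[[k]] <- row
      used <- rbind(used, row[, c("chrom", "start", "end")])
    }
    clrs <- if (config$n_clrs > 0L) do.call(rbind, clr_rows) else
      genomic_intervals(character(), integer(), integer(),
                        name = character(), proximal = logical())

    ## Sequences: background GC, AT-rich patches at CEN and CLR centers.
    sequence <- vapply(seq_along(chroms), function(i) {
      s <- random_dna(L, config$gc)
      plant <- function(s, center) {
        a <- center - config$at_patch_len %/% 2L
        idx <- a:(a + config$at_patch_len - 1L)
        p <- config$at_fraction
        s[idx] <- sample(c("A", "T", "G", "C"), length(idx), replace = TRUE,
                         prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2))
        s
      }
      s <- plant(s, cen_mid[i])
      for (m in (clrs$start[clrs$chrom == chroms[i]] +
                   clrs$end[clrs$chrom == chroms[i]]) %/% 2L)
        s <- plant(s, m)
      paste(s, collapse = "")
    }, "")
    names(sequence) <- chroms

    structure(list(
      chrom_lengths = stats::setNames(rep(L, length(chroms)), chroms),
      cens = cens, clrs = clrs,
      annotations = list(orfs = orfs, arss = arss, trnas = trnas,
                         retros = retros),
      sequence = sequence, config = config), class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth: ", length(x$chrom_lengths), " chromosomes x ",
      x$chrom_lengths[[1]], " bp, ", nrow(x$cens), " CENs, ",
      nrow(x$clrs), " planted CLRs\n", sep = "")
  invisible(x)
}

#' Simulate ChIP coverage tracks for all samples
#'
#' Background counts are Poisson with block-level Gamma overdispersion. CEN
#' footprints (box kernel of the genotype's width, centered on the CEN
#' midpoint) are multiplied by `cen_multiplier` in both genotypes; planted
#' CLR intervals are multiplied by `clr_multiplier` only in the OP genotype
#' and only in tagged-protein tracks. Untagged control tracks are
#' background-only. Each track gets an independent lognormal enrichment
#' factor emulating replicate-to-replicate variability.
#'
#' @param truth a [simulate_genome()] result
#' @param config the [sim_config()] used (defaults to `truth$config`)
#' @return named list of [signal_track()]s with names
#'   `<protein>_<genotype>_rep<i>` and `control_<genotype>_rep<i>`
#' @export
simulate_tracks <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(derive_seed(config$seed, "tracks"), {
    chroms <- names(truth$chrom_lengths)
    L <- truth$chrom_lengths[[1]]

    kernel_idx <- function(mid, width) {
      a <- max(1L, mid - width %/% 2L)
      a:min(L, a + width - 1L)
    }
    geno_mult <- function(genotype) {
      lapply(seq_along(chroms), function(i) {
        m <- rep(1, L)
        base_w <- if (genotype == "OP") config$cen_kernel_op else
          config$cen_kernel_wt
        width <- max(50L, as.integer(round(
          base_w * stats::rlnorm(1, 0, config$cen_kernel_sd))))
        mid <- (truth$cens$start[i] + truth$cens$end[i]) %/% 2L
        m[kernel_idx(mid, width)] <- config$cen_multiplier
        if (genotype == "OP" && nrow(truth$clrs)) {
          cc <- truth$clrs[truth$clrs$chrom == chroms[i], , drop = FALSE]
          for (r in seq_len(nrow(cc)))
            m[cc$start[r]:cc$end[r]] <- config$clr_multiplier
        }
        m
      })
    }
    mult <- list(WT = geno_mult("WT"), OP = geno_mult("OP"))

    draw_track <- function(mvecs, id, tagged) {
      counts <- lapply(seq_along(chroms), function(i) {
        lam <- rep(config$background_rate, L)
        if (config$overdispersion_cv > 0) {
          nb <- ceiling(L / config$block_bp)
          shape <- 1 / config$overdispersion_cv^2
          f <- stats::rgamma(nb, shape = shape, rate = shape)
          lam <- lam * rep(f, each = config$block_bp)[seq_len(L)]
        }
        if (tagged) {
          fac <- stats::rlnorm(1, 0, config$replicate_sd)
          lam <- lam * (1 + (mvecs[[i]] - 1) * fac)
        }
        stats::rpois(L, lam)
      })
      names(counts) <- chroms
      signal_track(counts, sample_id = id)
    }

    tracks <- list()
    for (g in c("WT", "OP")) {
      for (p in config$proteins) for (r in seq_len(config$n_replicates)) {
        id <- sprintf("%s_%s_rep%d", p, g, r)
        tracks[[id]] <- draw_track(mult[[g]], id, tagged = TRUE)
      }
      for (r in seq_len(config$n_replicates)) {
        id <- sprintf("control_%s_rep%d", g, r)
        tracks[[id]] <- draw_track(mult[[g]], id, tagged = FALSE)
      }
    }
    tracks
  })
}

#' Simulate a qPCR crossing-point table
#'
#' Two-fold-per-cycle chemistry: for a primer with true fold enrichment `e`
#' in the tagged sample, the tagged crossing point is `log2(e)` cycles lower
#' than the untagged control's; technical triplicates add Gaussian noise.
#'
#' @param true_enrichments named numeric vector of per-primer true
#'   enrichments in the tagged sample (include negative-control primers at 1)
#' @param replicates biological replicates per sample
#' @param noise_sd SD of per-well Cp noise (cycles)
#' @param seed integer seed
#' @param base_cp mean crossing point of the untagged sample
#' @return data.frame with columns `sample` ("tagged"/"untagged"),
#'   `replicate`, `primer`, `well`, `cp`
#' @export
simulate_qpcr <- function(true_enrichments, replicates = 2L, noise_sd = 0.1,
                          seed = 1L, base_cp = 25) {
  stopifnot(!is.null(names(true_enrichments)), all(true_enrichments > 0))
  with_seed(derive_seed(seed, "qpcr"), {
    grid <- expand.grid(sample = c("tagged", "untagged"),
                        replicate = seq_len(replicates),
                        primer = names(true_enrichments),
                        well = 1:3, stringsAsFactors = FALSE)
    mu <- ifelse(grid$sample == "tagged",
                 base_cp - log2(true_enrichments[grid$primer]), base_cp)
    grid$cp <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
    grid[order(grid$sample, grid$replicate, grid$primer, grid$well), ]
  })
}

#' Simulate growth curves, plasmid retention, and segregation counts
#'
#' Emulates the small-assay inputs: exponential OD600 growth with
#' multiplicative noise; plasmid-retention plating counts (selective vs
#' permissive plates) drawn binomially at the true retention fraction, with
#' 3-5 technical replicates per transformant for fluctuation analysis; and
#' binomial pedigree-budding / GFP-dot segregation count tables.
#'
#' @param params list overriding any of: `doubling_time_h` (named per
#'   strain), `od0`, `times_h`, `od_noise_sd`, `retention` (named true
#'   retention fractions), `n_transformants`, `n_colonies`,
#'   `segregation_fractions` (named true success fractions), `n_cells`
#' @param seed integer seed
#' @return list with `growth` (data.frame strain/transformant/time_h/od),
#'   `retention` (data.frame strain/transformant/tech_rep/selective/
#'   permissive), `segregation` (data.frame condition/success/failure)
#' @export
simulate_growth_and_segregation <- function(params = list(), seed = 1L) {
  p <- utils::modifyList(list(
    doubling_time_h = c(ARS = 3.0, CLR = 2.5, CEN = 2.0),
    od0 = 0.05, times_h = seq(0, 12, by = 2), od_noise_sd = 0.02,
    retention = c(ARS = 0.20, CLR1 = 0.35, CLR15 = 0.36, CEN = 0.91),
    n_transformants = 6L, n_colonies = 200L,
    segregation_fractions = c(WT_ON = 0.95, OP_ON = 0.95,
                              WT_OFF = 0.62, OP_OFF = 0.82),
    n_cells = 200L), params)
  with_seed(derive_seed(seed, "assays"), {
    growth <- do.call(rbind, lapply(names(p$doubling_time_h), function(s) {
      do.call(rbind, lapply(seq_len(p$n_transformants), function(tr) {
        od <- p$od0 * 2^(p$times_h / p$doubling_time_h[[s]]) *
          exp(stats::rnorm(length(p$times_h), 0, p$od_noise_sd))
        data.frame(strain = s, transformant = tr, time_h = p$times_h, od = od)
      }))
    }))
    retention <- do.call(rbind, lapply(names(p$retention), function(s) {
      do.call(rbind, lapply(seq_len(p$n_transformants), function(tr) {
        nt <- sample(3:5, 1)
        perm <- stats::rpois(nt, p$n_colonies)
        sel <- stats::rbinom(nt, perm, p$retention[[s]])
        data.frame(strain = s, transformant = tr, tech_rep = seq_len(nt),
                   selective = sel, permissive = perm)
      }))
    }))
    seg <- data.frame(
      condition = names(p$segregation_fractions),
      success = stats::rbinom(length(p$segregation_fractions), p$n_cells,
                              p$segregation_fractions),
      failure = NA_integer_)
    seg$failure <- p$n_cells - seg$success
    list(growth = growth, retention = retention, segregation = seg)
  })
}
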
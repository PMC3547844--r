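# Shared fixtures built in code: a small genome for fast unit tests and a
# constructor for hand-specified per-base tracks.

small_sim_config <- function(seed = 1L, n_clrs = 6L, ...) {
  sim_config(n_chroms = 2L, chrom_length = 150000L, n_clrs = n_clrs,
             seed = seed, ...)
}

# signal_track from a single per-base vector on chromosome "1"
track1 <- function(v, id = "t", total_reads = NULL) {
  signal_track(list(`1` = v), sample_id = id, total_reads = total_reads)
}

# minimal site table with q/ratio/excess columns
site_tab <- function(chrom, start, end, qvalue = 1e-10, ratio = 5,
                     excess = 100) {
  genomic_intervals(chrom, start, end, qvalue = qvalue, ratio = ratio,
                    excess_reads = excess)
}
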
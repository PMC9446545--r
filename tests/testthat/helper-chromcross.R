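suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

tiny_layout <- function(lens = c(chr1 = 10000, chr2 = 8000)) {
  genome_layout(names(lens), lens)
}

# Random intervals on a layout (1-based closed, valid).
random_intervals <- function(n, layout, max_width = 500L) {
  chroms <- seqnames(layout)
  ci <- sample.int(length(chroms), n, replace = TRUE)
  lens <- seqlengths(layout)[ci]
  w <- sample.int(max_width, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i)
    sample.int(lens[i] - w[i], 1L), integer(1))
  GRanges(chroms[ci], IRanges(s, width = w), seqinfo = layout)
}

# Random stepped track as an RleList over the layout.
random_track <- function(layout, step = 100L, max_val = 5) {
  as(setNames(lapply(seqlengths(layout), function(L) {
    nseg <- ceiling(L / step)
    vals <- round(runif(nseg, 0, max_val), 3)
    lens <- rep(step, nseg)
    lens[nseg] <- L - step * (nseg - 1L)
    Rle(vals, lens)
  }), seqnames(layout)), "RleList")
}

# Brute-force overlap of two single intervals (independent of the package).
bf_overlap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0L)
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

# Small but feasible simulation configuration for fast tests.
test_sim_config <- function(seed = 7L, ...) {
  sim_config(n_hotspot_sites = 30L, n_promoter_sites = 8L,
             hotspot_marked_frac = 1, hotspot_open_frac = 0.8,
             n_extra_tss = 20L, seed = seed, ...)
}

site_ids_test <- function(gr)
  paste0(seqnames(gr), ":", start(gr), "-", end(gr))

# Per-bp naive mean of `track` over 1-based closed [s, e] clipped to the
# chromosome; 0 when entirely outside.
bf_bin_mean <- function(track, chrom, s, e) {
  L <- length(track[[chrom]])
  s2 <- max(s, 1L); e2 <- min(e, L)
  if (s2 > e2) return(0)
  mean(as.numeric(track[[chrom]][s2:e2]))
}
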
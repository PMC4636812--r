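suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# constant-value track on a toy genome
constant_track <- function(value = 1, sizes = c(chr1 = 10000L),
                           bin = 25L, label = "const") {
  vals <- lapply(as.list(sizes), function(L)
    rep(value, ceiling(L / bin)))
  coverage_track(vals, chrom_sizes(sizes), bin, total_reads = 1000,
                 label = label)
}

# track with explicit per-bin values on one chromosome
value_track <- function(values, bin = 25L, chrom = "chr1",
                        total_reads = 1000, label = "vals") {
  sizes <- setNames(length(values) * bin, chrom)
  coverage_track(setNames(list(values), chrom), chrom_sizes(sizes),
                 bin, total_reads = total_reads, label = label)
}

# wrap a plain numeric matrix as a density_matrix (for clustering tests)
fake_density_matrix <- function(X, bin = 25L, track = "synthetic") {
  m <- ncol(X)
  flank <- m * bin / 2
  offs <- seq(-flank + bin / 2, flank - bin / 2, by = bin)
  if (is.null(rownames(X)) && nrow(X) > 0)
    rownames(X) <- paste0("a", seq_len(nrow(X)))
  structure(list(values = X, offsets = offs, bin = bin, flank = flank,
                 track = track, kind = "peak-summit",
                 oob = rep(FALSE, nrow(X))),
            class = "density_matrix")
}

fake_profile <- function(offsets, density) {
  structure(list(offsets = offsets, density = density, n = 1L,
                 track = "synthetic"), class = "meta_profile")
}

# stranded reads as a GRanges from 5' positions
reads_from_5p <- function(p5, strand, chrom = "chr1", read_length = 36L) {
  s <- ifelse(strand == "+", p5, p5 - read_length + 1L)
  GRanges(chrom, IRanges(s, s + read_length - 1L), strand = strand)
}

# independent per-base coverage oracle: a fragment counts once in every
# bin any of its bases falls into
coverage_oracle <- function(fragments, sizes, bin) {
  out <- lapply(as.list(sizes), function(L) numeric(ceiling(L / bin)))
  ch <- as.character(seqnames(fragments))
  for (i in seq_along(fragments)) {
    bases0 <- seq(start(fragments)[i] - 1L, end(fragments)[i] - 1L)
    bins <- unique(bases0 %/% bin) + 1L
    bins <- bins[bins >= 1 & bins <= length(out[[ch[i]]])]
    out[[ch[i]]][bins] <- out[[ch[i]]][bins] + 1
  }
  out
}

# quick small simulation config used by several tests
small_sim_config <- function(seed = 11L, ...) {
  simulation_config(seed = seed,
                    chrom_sizes = c(chrS = 8e5),
                    n_genes = 60L, n_enhancers = 40L,
                    n_super_enhancers = 4L,
                    se_length = c(5000L, 12000L),
                    factors = list(factor_spec("fA",
                                               fraction_bound = 0.5,
                                               background_rate = 10)),
                    ...)
}
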
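## Read-density tracks: extend reads to fragment length, accumulate counts
## in fixed-width genomic bins, normalize.

#' Coverage track constructor
#'
#' A coverage track holds one value per fixed-width bin per chromosome
#' (the last bin may cover a partial bin).
#'
#' @param values named list (one numeric vector per chromosome).
#' @param chrom_sizes [chrom_sizes()] vector.
#' @param bin_width bin width in bp.
#' @param total_reads number of reads/fragments used to build the track.
#' @param normalization one of `"raw"`, `"per-million"`, `"input-ratio"`,
#'   `"scalar"`, `"unknown"`.
#' @param label short name used when the track feeds density matrices.
#' @export
coverage_track <- function(values, chrom_sizes, bin_width,
                           total_reads = NA_real_, normalization = "raw",
                           label = "track") {
  if (!all(names(chrom_sizes) %in% names(values)))
    .stopf("values must cover every chromosome in chrom_sizes")
  for (ch in names(chrom_sizes)) {
    nb <- as.integer(ceiling(chrom_sizes[[ch]] / bin_width))
    if (length(values[[ch]]) != nb)
      .stopf("chromosome %s: expected %d bins, got %d", ch, nb,
             length(values[[ch]]))
  }
  if (normalization %in% c("raw", "per-million") &&
      any(vapply(values, function(v) any(v < 0), logical(1))))
    .stopf("raw/per-million bin values must be >= 0")
  structure(list(values = values[names(chrom_sizes)],
                 chrom_sizes = chrom_sizes,
                 bin_width = as.integer(bin_width),
                 total_reads = total_reads,
                 normalization = normalization,
                 label = label),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "coverage_track '%s': %d chromosome(s), %d bp bins, %s reads, %s\n",
    x$label, length(x$values), x$bin_width,
    ifelse(is.na(x$total_reads), "NA", format(x$total_reads)),
    x$normalization))
  invisible(x)
}

#' Extend sequencing reads to the sonicated fragment length
#'
#' Each read is replaced by the `fragment_length`-bp interval beginning at
#' its strand-aware 5' end: a plus read covers `[5', 5' + L)`, a minus read
#' `[5' - L + 1, 5' + 1)` (0-based half-open terms).  Intervals are clipped
#' to chromosome bounds when sizes are known.
#'
#' @param reads stranded GRanges of aligned reads.
#' @param fragment_length target fragment length in bp (default 200).
#' @param chrom_sizes optional [chrom_sizes()] used for clipping.
#' @return GRanges of extended fragments.
#' @export
extend_reads <- function(reads, fragment_length = 200L, chrom_sizes = NULL) {
  if (fragment_length <= 0) .stopf("fragment_length must be > 0")
  st <- as.character(strand(reads))
  if (any(!st %in% c("+", "-")))
    .stopf("reads must be stranded (+/-) to locate the 5' end")
  # drop seqinfo so intermediate out-of-bound extensions stay silent;
  # clipping below restores validity
  reads <- GRanges(seqnames(reads), IRanges::ranges(reads),
                   strand = strand(reads))
  ext <- resize(reads, width = as.integer(fragment_length), fix = "start")
  # clip to [1, chrom length]
  s <- pmax(start(ext), 1L)
  e <- end(ext)
  if (!is.null(chrom_sizes)) {
    lim <- as.integer(chrom_sizes[as.character(seqnames(ext))])
    e <- pmin(e, lim)
  }
  GRanges(seqnames(ext), IRanges(s, e), strand = strand(ext))
}

#' Bin extended fragments into a coverage track
#'
#' With the default overlap-count semantics a fragment contributes 1 to
#' every bin it overlaps by at least one bp.  The alternative `"fiveprime"`
#' mode counts each (stranded) record once, in the bin holding its 5' end.
#'
#' @param fragments GRanges of (extended) fragments.
#' @param chrom_sizes [chrom_sizes()] vector.
#' @param bin_width bin width in bp (default 25).
#' @param mode `"overlap"` (default) or `"fiveprime"`.
#' @param label track label.
#' @return A raw [coverage_track()] with `total_reads = length(fragments)`.
#' @export
bin_coverage <- function(fragments, chrom_sizes, bin_width = 25L,
                         mode = c("overlap", "fiveprime"), label = "track") {
  mode <- match.arg(mode)
  bin_width <- as.integer(bin_width)
  chroms <- as.character(seqnames(fragments))
  unknown <- setdiff(unique(chroms), names(chrom_sizes))
  if (length(unknown))
    .stopf("fragments on chromosomes absent from chrom_sizes: %s",
           paste(unknown, collapse = ", "))
  vals <- list()
  for (ch in names(chrom_sizes)) {
    nb <- as.integer(ceiling(chrom_sizes[[ch]] / bin_width))
    idx <- which(chroms == ch)
    if (length(idx) == 0) { vals[[ch]] <- numeric(nb); next }
    fr <- fragments[idx]
    if (mode == "overlap") {
      starts <- seq(1L, by = bin_width, length.out = nb)
      bins <- IRanges(starts, pmin(starts + bin_width - 1L,
                                   as.integer(chrom_sizes[[ch]])))
      vals[[ch]] <- as.numeric(
        IRanges::countOverlaps(bins, IRanges::ranges(fr), minoverlap = 1L))
    } else {
      st <- as.character(strand(fr))
      p5 <- ifelse(st == "-", end(fr), start(fr))
      b <- (as.integer(p5) - 1L) %/% bin_width + 1L
      b <- b[b >= 1L & b <= nb]
      vals[[ch]] <- as.numeric(tabulate(b, nbins = nb))
    }
  }
  coverage_track(vals, chrom_sizes, bin_width,
                 total_reads = length(fragments), normalization = "raw",
                 label = label)
}

#' Normalize a coverage track
#'
#' * `per-million`: value x 1e6 / total reads.
#' * `input-ratio`: both ChIP and input are brought to per-million scale,
#'   then `(chip + pseudocount) / (input + pseudocount)` per bin.
#' * `scalar`: value / scalar (e.g. the factor-of-five rescaling used to
#'   put a very deep acetylation track on a common axis).
#'
#' @param track a [coverage_track()].
#' @param mode `"per-million"`, `"input-ratio"` or `"scalar"`.
#' @param input input-control track on the identical bin grid
#'   (input-ratio only).
#' @param pseudocount added to both numerator and denominator per-million
#'   values (input-ratio only, default 1).
#' @param scalar divisor for scalar mode.
#' @export
normalize_track <- function(track, mode = c("per-million", "input-ratio",
                                            "scalar"),
                            input = NULL, pseudocount = 1, scalar = NULL) {
  mode <- match.arg(mode)
  to_pm <- function(tr) {
    if (tr$normalization == "per-million") return(tr)
    if (tr$normalization != "raw")
      .stopf("cannot per-million scale a '%s' track", tr$normalization)
    if (!is.finite(tr$total_reads) || tr$total_reads <= 0)
      .stopf("per-million scaling needs a positive total read count")
    tr$values <- lapply(tr$values, function(v) v * 1e6 / tr$total_reads)
    tr$normalization <- "per-million"
    tr
  }
  if (mode == "per-million") return(to_pm(track))
  if (mode == "scalar") {
    if (is.null(scalar) || scalar == 0) .stopf("scalar must be non-zero")
    track$values <- lapply(track$values, function(v) v / scalar)
    track$normalization <- "scalar"
    return(track)
  }
  if (is.null(input)) .stopf("input-ratio mode requires an input track")
  if (track$bin_width != input$bin_width ||
      !identical(names(track$values), names(input$values)) ||
      !all(lengths(track$values) == lengths(input$values)))
    .stopf("ChIP and input tracks must share an identical bin grid")
  chip <- to_pm(track); inp <- to_pm(input)
  chip$values <- Map(function(a, b) (a + pseudocount) / (b + pseudocount),
                     chip$values, inp$values)
  chip$normalization <- "input-ratio"
  chip
}

# Per-base mean track value over the 0-based half-open window [a0, b0).
# Positions outside the chromosome contribute 0.
.region_mean <- function(track, chrom, a0, b0) {
  if (b0 <= a0) .stopf("empty window [%d, %d)", a0, b0)
  w <- track$bin_width
  v <- track$values[[chrom]]
  if (is.null(v)) .stopf("unknown chromosome '%s'", chrom)
  i0 <- floor(a0 / w); i1 <- floor((b0 - 1) / w)
  idx <- i0:i1
  ov <- pmin(b0, (idx + 1) * w) - pmax(a0, idx * w)
  ok <- idx >= 0 & idx < length(v)
  sum(v[idx[ok] + 1] * ov[ok]) / (b0 - a0)
}
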
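## Density matrices around stranded reference points, average (metagene)
## profiles and the profile peak offset.

#' Stranded reference points for matrix extraction
#'
#' @param gr width-1 GRanges of anchor positions (TSSs, peak summits,
#'   enhancer midpoints).  Unstranded anchors are treated as plus strand
#'   (no orientation flip).
#' @param kind `"tss"`, `"peak-summit"` or `"enhancer-midpoint"`.
#' @param ids unique anchor identifiers; defaults to `names(gr)`.
#' @export
reference_points <- function(gr, kind = c("tss", "peak-summit",
                                          "enhancer-midpoint"),
                             ids = NULL) {
  kind <- match.arg(kind)
  if (any(width(gr) != 1L)) .stopf("reference points must have width 1")
  ids <- ids %||% names(gr) %||% paste0("anchor_", seq_along(gr))
  if (anyDuplicated(ids)) .stopf("anchor ids must be unique")
  structure(list(gr = gr, ids = as.character(ids), kind = kind),
            class = "reference_points")
}

#' Reference points at peak summits
#' @export
summit_points <- function(peaks) {
  gr <- GRanges(seqnames(peaks), IRanges(mcols(peaks)$summit, width = 1L))
  reference_points(gr, "peak-summit",
                   ids = mcols(peaks)$name %||% names(peaks))
}

#' Reference points at enhancer midpoints (unstranded)
#' @export
midpoint_points <- function(regions, ids = NULL) {
  mid <- start(regions) + (width(regions) - 1L) %/% 2L
  gr <- GRanges(seqnames(regions), IRanges(mid, width = 1L))
  reference_points(gr, "enhancer-midpoint",
                   ids = ids %||% names(regions))
}

#' Extract a density matrix around reference points
#'
#' One row per anchor, one column per `bin`-bp offset bin covering
#' `[-flank, +flank)`; columns are labelled by their bin-centre offset so
#' the grid is symmetric about 0.  For minus-strand anchors the offset
#' axis is reversed, so positive offsets always mean downstream.  Values
#' are sampled from the track bin containing each offset position (no
#' interpolation); windows that run past a chromosome end are zero-padded
#' and flagged in the `oob` field.
#'
#' @param track a [coverage_track()].
#' @param refs a [reference_points()] set.
#' @param flank half-window in bp (multiple of `bin`).
#' @param bin column width in bp (multiple of the track bin width).
#' @return Object of class `density_matrix`: list with `values`
#'   (anchors x offsets matrix), `offsets` (bin centres, bp), `bin`,
#'   `flank`, `track`, `kind` and `oob`.
#' @export
extract_matrix <- function(track, refs, flank = 1000L,
                           bin = track$bin_width) {
  stopifnot(inherits(track, "coverage_track"),
            inherits(refs, "reference_points"))
  flank <- as.integer(flank); bin <- as.integer(bin)
  if (flank %% bin != 0L)
    .stopf("flank (%d) must be a multiple of bin (%d)", flank, bin)
  w <- track$bin_width
  if (bin %% w != 0L)
    .stopf("bin (%d) must be a multiple of the track bin width (%d)", bin, w)
  offs <- seq(-flank + bin / 2, flank - bin / 2, by = bin)
  gr <- refs$gr
  chroms <- as.character(seqnames(gr))
  unknown <- setdiff(unique(chroms), names(track$values))
  if (length(unknown))
    .stopf("reference points on chromosomes missing from the track: %s",
           paste(unknown, collapse = ", "))
  sgn <- ifelse(as.character(strand(gr)) == "-", -1, 1)
  centre0 <- (start(gr) - 1L) + 0.5        # centre of the anchor base, 0-based
  n <- length(gr); m <- length(offs)
  M <- matrix(0, n, m, dimnames = list(refs$ids, format(offs, trim = TRUE)))
  oob <- logical(n)
  for (ch in unique(chroms)) {
    i <- which(chroms == ch)
    v <- track$values[[ch]]
    x <- outer(centre0[i], rep(1, m)) + outer(sgn[i], offs)
    idx <- floor(x / w) + 1
    bad <- idx < 1 | idx > length(v)
    idx[bad] <- 1L
    vi <- matrix(v[idx], nrow = length(i))
    vi[bad] <- 0
    M[i, ] <- vi
    oob[i] <- rowSums(bad) > 0
  }
  structure(list(values = M, offsets = offs, bin = bin, flank = flank,
                 track = track$label, kind = refs$kind, oob = oob),
            class = "density_matrix")
}

#' @export
print.density_matrix <- function(x, ...) {
  cat(sprintf(
    "density_matrix: %d anchors x %d offset bins (+/-%d bp, %d bp bins), track '%s'%s\n",
    nrow(x$values), ncol(x$values), x$flank, x$bin, x$track,
    if (any(x$oob)) sprintf(", %d zero-padded rows", sum(x$oob)) else ""))
  invisible(x)
}

#' Column-wise average (metagene) profile of a density matrix
#'
#' @param matrix a `density_matrix`.
#' @return Object of class `meta_profile`: offsets (bp), mean density per
#'   offset, number of anchors averaged.
#' @export
average_profile <- function(matrix) {
  stopifnot(inherits(matrix, "density_matrix"))
  if (nrow(matrix$values) == 0) .stopf("cannot average an empty matrix")
  structure(list(offsets = matrix$offsets,
                 density = colMeans(matrix$values),
                 n = nrow(matrix$values),
                 track = matrix$track),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("meta_profile '%s': %d bins over [%g, %g] bp, %d anchors\n",
              x$track, length(x$offsets), min(x$offsets), max(x$offsets),
              x$n))
  invisible(x)
}

#' @export
plot.meta_profile <- function(x, ...,
                              xlab = "distance from anchor (bp)",
                              ylab = "mean read density", type = "l") {
  graphics::plot(x$offsets, x$density, type = type,
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Offset of the maximum of a smoothed average profile
#'
#' The profile is smoothed with a centred moving average (window shrinks at
#' the edges), and the bin-centre offset of the smoothed maximum is
#' returned.  Ties are broken toward offset 0; a tie between equal and
#' opposite offsets resolves downstream (positive).
#'
#' @param profile a [average_profile()] result.
#' @param smoothing_window moving-average width in bins (odd, default 3).
#' @return Signed offset in bp.
#' @export
profile_peak_offset <- function(profile, smoothing_window = 3L) {
  stopifnot(inherits(profile, "meta_profile"))
  d <- profile$density
  if (max(d) - min(d) < sqrt(.Machine$double.eps) * max(abs(d), 1))
    .stopf("profile is constant; no peak to locate")
  if (smoothing_window %% 2L == 0L)
    .stopf("smoothing_window must be odd")
  h <- (smoothing_window - 1L) / 2L
  n <- length(d)
  cs <- cumsum(c(0, d))
  lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
  s <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  cand <- which(s >= max(s) - 1e-12 * max(abs(s), 1))
  o <- profile$offsets[cand]
  o[order(abs(o), -sign(o))][1]
}
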
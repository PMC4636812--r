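## Enhancer stratification by acetylation signal, factor-positive enhancer
## classification, and length-scaled super-enhancer meta-profiles.

.QUARTILE_LEVELS <- c("I", "II", "III", "IV")

.region_ids <- function(gr, prefix) {
  names(gr) %||% mcols(gr)$name %||% paste0(prefix, seq_along(gr))
}

#' Rank enhancers by signal around their midpoints
#'
#' Enhancers are sorted by the mean ranking-track density in a window
#' around their midpoint (highest first; ties broken by id) and split into
#' four near-equal quartiles I (highest) to IV (lowest).
#'
#' @param enhancers GRanges of enhancer intervals.
#' @param ranking_track the [coverage_track()] used for ranking (typically
#'   an H3K27ac track).
#' @param window half-window around the midpoint in bp (default 1000).
#' @return Object of class `enhancer_rank`: GRanges `gr` with `id`,
#'   `midpoint`, `signal` and `quartile` metadata (sorted by rank), plus
#'   the ranking parameters.
#' @export
rank_enhancers <- function(enhancers, ranking_track, window = 1000L) {
  if (length(enhancers) == 0) .stopf("empty enhancer list")
  ids <- .region_ids(enhancers, "enh_")
  mid <- start(enhancers) + (width(enhancers) - 1L) %/% 2L
  chroms <- as.character(seqnames(enhancers))
  signal <- vapply(seq_along(enhancers), function(i)
    .region_mean(ranking_track, chroms[i],
                 max(mid[i] - 1L - window, 0L), mid[i] + window),
    numeric(1))
  ord <- order(-signal, ids)
  gr <- enhancers[ord]
  names(gr) <- ids[ord]
  mcols(gr)$id <- ids[ord]
  mcols(gr)$midpoint <- mid[ord]
  mcols(gr)$signal <- signal[ord]
  mcols(gr)$quartile <- factor(
    rep(.QUARTILE_LEVELS, .near_equal_sizes(length(gr), 4L)),
    levels = .QUARTILE_LEVELS)
  structure(list(gr = gr, window = window, track = ranking_track$label),
            class = "enhancer_rank")
}

#' @export
print.enhancer_rank <- function(x, ...) {
  cat(sprintf(
    "enhancer_rank: %d enhancers ranked by '%s' (+/-%d bp of midpoint)\n",
    length(x$gr), x$track, x$window))
  print(table(mcols(x$gr)$quartile))
  invisible(x)
}

#' Average profiles around enhancer midpoints, per quartile
#'
#' Midpoints are unstranded anchors (no orientation flip).
#'
#' @param ranking an [rank_enhancers()] result.
#' @param query_track track to profile.
#' @param flank,bin as in [extract_matrix()].
#' @return Named list of [average_profile()] results, one per quartile.
#' @export
quartile_midpoint_profiles <- function(ranking, query_track,
                                       flank = 1000L, bin = 25L) {
  stopifnot(inherits(ranking, "enhancer_rank"))
  qs <- split(seq_along(ranking$gr), mcols(ranking$gr)$quartile)
  lapply(qs, function(i) {
    sub <- ranking$gr[i]
    refs <- reference_points(
      GRanges(seqnames(sub), IRanges(mcols(sub)$midpoint, width = 1L)),
      "enhancer-midpoint", ids = mcols(sub)$id)
    average_profile(extract_matrix(query_track, refs, flank, bin))
  })
}

#' Classify enhancers positive for a factor by k-means co-occupancy
#'
#' Density matrices of all supplied tracks around enhancer midpoints are
#' clustered jointly; enhancers in clusters called positive for the factor
#' track form the positive set.
#'
#' @param enhancers GRanges of enhancer intervals.
#' @param tracks named list of [coverage_track()]s (the factor plus
#'   co-factor/chromatin-mark tracks).
#' @param factor name of the factor track within `tracks`.
#' @param k,seed clustering parameters (see [kmeans_cluster()]).
#' @param flank,bin matrix extraction parameters.
#' @param rule,central_fraction,pseudocount positive-cluster rule (see
#'   [call_positive_clusters()]).
#' @return List: `positive` and `negative` id vectors, `fraction`
#'   (percent positive), and the underlying `assignment`.
#' @export
classify_positive_enhancers <- function(enhancers, tracks, factor,
                                        k = 2L, seed = 1L,
                                        flank = 1000L, bin = 25L,
                                        rule = 2, central_fraction = 0.2,
                                        pseudocount = 0.1) {
  if (!factor %in% names(tracks))
    .stopf("factor track '%s' not in tracks", factor)
  ids <- .region_ids(enhancers, "enh_")
  refs <- midpoint_points(enhancers, ids = ids)
  mats <- lapply(tracks, extract_matrix, refs = refs, flank = flank,
                 bin = bin)
  assignment <- kmeans_cluster(mats, k = k, seed = seed)
  pos_clusters <- call_positive_clusters(assignment, factor, rule = rule,
                                         central_fraction = central_fraction,
                                         pseudocount = pseudocount)
  positive <- ids[assignment$labels %in% pos_clusters]
  list(positive = positive,
       negative = setdiff(ids, positive),
       fraction = 100 * length(positive) / length(ids),
       positive_clusters = pos_clusters,
       assignment = assignment)
}

#' Length-scaled super-enhancer meta-profile with input normalization
#'
#' Each region's body is partitioned into `body_bins` equal-length
#' sub-intervals (remainder bp going to the leftmost bins) and flanked by
#' fixed `flank_bin`-bp bins covering `flank` bp on each side.  Per bin,
#' the mean per-base factor density and mean input density are computed
#' per region; the meta value is the across-region mean factor density
#' divided by the across-region mean input density (average-then-ratio,
#' the default) or the across-region mean of per-region ratios
#' (`"ratio-then-average"`).
#'
#' @param super_enhancers GRanges of regions, each at least `body_bins` bp.
#' @param factor_track,input_track [coverage_track()]s on the same genome.
#' @param body_bins number of scaled body bins (default 80).
#' @param flank flank width in bp (default 4000).
#' @param flank_bin flank bin width in bp (default 50).
#' @param mode `"average-then-ratio"` or `"ratio-then-average"`.
#' @param pseudocount added to numerator and denominator densities
#'   (default 0; supply a small value if input coverage can be zero).
#' @return Object of class `scaled_meta_profile`: `flank5`, `body`,
#'   `flank3` enrichment vectors, bin metadata and region count.
#' @export
scaled_superenhancer_profile <- function(super_enhancers, factor_track,
                                         input_track, body_bins = 80L,
                                         flank = 4000L, flank_bin = 50L,
                                         mode = c("average-then-ratio",
                                                  "ratio-then-average"),
                                         pseudocount = 0) {
  mode <- match.arg(mode)
  if (factor_track$bin_width != input_track$bin_width)
    .stopf("factor and input tracks must share a bin width")
  if (flank %% flank_bin != 0L)
    .stopf("flank must be a multiple of flank_bin")
  ids <- .region_ids(super_enhancers, "se_")
  short <- width(super_enhancers) < body_bins
  if (any(short))
    .stopf("region %s is shorter (%d bp) than body_bins (%d)",
           ids[which(short)[1]], width(super_enhancers)[which(short)[1]],
           body_bins)
  nf <- as.integer(flank / flank_bin)
  n <- length(super_enhancers)
  chroms <- as.character(seqnames(super_enhancers))
  a0 <- start(super_enhancers) - 1L
  b0 <- end(super_enhancers)
  bins_of <- function(track, i) {
    W <- b0[i] - a0[i]
    base <- W %/% body_bins; rem <- W %% body_bins
    widths <- base + (seq_len(body_bins) <= rem)
    edges <- a0[i] + cumsum(c(0L, widths))
    body <- vapply(seq_len(body_bins), function(j)
      .region_mean(track, chroms[i], edges[j], edges[j + 1]), numeric(1))
    f5e <- a0[i] - flank + (0:nf) * flank_bin
    f5 <- vapply(seq_len(nf), function(j)
      .region_mean(track, chroms[i], f5e[j], f5e[j + 1]), numeric(1))
    f3e <- b0[i] + (0:nf) * flank_bin
    f3 <- vapply(seq_len(nf), function(j)
      .region_mean(track, chroms[i], f3e[j], f3e[j + 1]), numeric(1))
    c(f5, body, f3)
  }
  Fm <- t(vapply(seq_len(n), function(i) bins_of(factor_track, i),
                 numeric(nf + body_bins + nf)))
  Im <- t(vapply(seq_len(n), function(i) bins_of(input_track, i),
                 numeric(nf + body_bins + nf)))
  enr <- if (mode == "average-then-ratio") {
    (colMeans(Fm) + pseudocount) / (colMeans(Im) + pseudocount)
  } else {
    colMeans((Fm + pseudocount) / (Im + pseudocount))
  }
  structure(list(flank5 = enr[seq_len(nf)],
                 body = enr[nf + seq_len(body_bins)],
                 flank3 = enr[nf + body_bins + seq_len(nf)],
                 body_bins = body_bins, flank = flank,
                 flank_bin = flank_bin, n = n, mode = mode),
            class = "scaled_meta_profile")
}

#' @export
print.scaled_meta_profile <- function(x, ...) {
  cat(sprintf(
    "scaled_meta_profile: %d regions, %d body bins + 2 x %d flank bins (%s)\n",
    x$n, x$body_bins, length(x$flank5), x$mode))
  cat(sprintf("  mean enrichment: flank5 %.3f | body %.3f | flank3 %.3f\n",
              mean(x$flank5), mean(x$body), mean(x$flank3)))
  invisible(x)
}

#' @export
plot.scaled_meta_profile <- function(x, ...,
                                     ylab = "enrichment over input") {
  nf <- length(x$flank5)
  y <- c(x$flank5, x$body, x$flank3)
  graphics::plot(seq_along(y), y, type = "l", xaxt = "n",
                 xlab = "", ylab = ylab, ...)
  graphics::abline(v = c(nf + 0.5, nf + x$body_bins + 0.5), lty = 3)
  graphics::axis(1, at = c(1, nf, nf + x$body_bins, 2 * nf + x$body_bins),
                 labels = c(sprintf("-%d bp", x$flank), "start", "end",
                            sprintf("+%d bp", x$flank)))
  invisible(x)
}
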
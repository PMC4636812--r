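## k-means partitioning of concatenated multi-track density matrices,
## rule-based positive-cluster calling and co-occupancy quantification.

# Lloyd's algorithm with k-means++ seeding.  Empty clusters are re-seeded
# at the point farthest from its current centroid.  Deterministic given the
# RNG state on entry.
.lloyd_kmeanspp <- function(X, k, max_iter = 100L, tol = 1e-8) {
  n <- nrow(X)
  cent <- matrix(0, k, ncol(X))
  i1 <- sample.int(n, 1L)
  cent[1L, ] <- X[i1, ]
  d2 <- rowSums(sweep(X, 2, cent[1L, ])^2)
  for (j in seq_len(k)[-1L]) {
    tot <- sum(d2)
    ij <- if (tot <= 0) sample.int(n, 1L)
          else sample.int(n, 1L, prob = d2 / tot)
    cent[j, ] <- X[ij, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, cent[j, ])^2))
  }
  lab <- integer(n)
  xsq <- rowSums(X^2)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2mat <- outer(xsq, rowSums(cent^2), "+") - 2 * X %*% t(cent)
    newlab <- max.col(-d2mat, ties.method = "first")
    empty <- which(tabulate(newlab, k) == 0L)
    for (j in empty) {
      far <- which.max(d2mat[cbind(seq_len(n), newlab)])
      newlab[far] <- j
      d2mat[far, ] <- -Inf  # cannot be stolen by the next empty cluster
    }
    sizes <- tabulate(newlab, k)
    newcent <- rowsum(X, newlab) / sizes
    shift <- max(rowSums((newcent - cent)^2))
    converged <- identical(newlab, lab)
    cent <- newcent; lab <- newlab
    if (converged || shift < tol || iter >= max_iter) break
  }
  list(labels = lab, centers = cent, iterations = iter)
}

#' k-means clustering of density matrices over common anchors
#'
#' Rows of each matrix are normalized (default: division by the row mean
#' plus a pseudocount, so that every anchor contributes shape rather than
#' amplitude), the matrices are concatenated column-wise and partitioned
#' with Lloyd's algorithm seeded by k-means++ at a fixed RNG seed.  The
#' per-cluster mean profiles stored in the result are computed from the
#' *unnormalized* densities, so cluster summaries stay on the read-density
#' scale.
#'
#' @param matrices a `density_matrix` or (optionally named) list of them,
#'   all sharing anchor ids and column grids.
#' @param k number of clusters (>= 2).
#' @param seed RNG seed; identical inputs and seed give bitwise-identical
#'   labels.
#' @param row_normalization `"mean"` (default) or `"none"`.
#' @param pseudocount added to the row mean before division.
#' @param max_iter,tol Lloyd's iteration controls.
#' @return Object of class `cluster_assignment`: anchor ids, `k`, integer
#'   `labels` (named by anchor), cluster `sizes`, per-track per-cluster
#'   mean `profiles`, `centers` in normalized space, `seed`.
#' @export
kmeans_cluster <- function(matrices, k, seed = 1L,
                           row_normalization = c("mean", "none"),
                           pseudocount = 1, max_iter = 100L, tol = 1e-8) {
  row_normalization <- match.arg(row_normalization)
  if (inherits(matrices, "density_matrix")) matrices <- list(matrices)
  if (is.null(names(matrices)) || any(names(matrices) == ""))
    names(matrices) <- vapply(matrices, function(m) m$track, character(1))
  if (anyDuplicated(names(matrices)))
    names(matrices) <- make.unique(names(matrices))
  ids <- rownames(matrices[[1]]$values)
  for (m in matrices)
    if (!identical(rownames(m$values), ids))
      .stopf("all matrices must share the same anchors in the same order")
  n <- length(ids)
  if (k < 2L) .stopf("k must be >= 2")
  if (k > n) .stopf("k (%d) exceeds the number of anchors (%d)", k, n)
  X <- do.call(cbind, lapply(matrices, function(m) {
    v <- m$values
    if (row_normalization == "mean") v / (rowMeans(v) + pseudocount) else v
  }))
  if (all(X == 0)) .stopf("degenerate input: all densities are zero")
  fit <- with_seed(seed, .lloyd_kmeanspp(X, k, max_iter, tol))
  profiles <- lapply(matrices, function(m) {
    t(vapply(seq_len(k), function(j)
      colMeans(m$values[fit$labels == j, , drop = FALSE]),
      numeric(ncol(m$values))))
  })
  structure(list(ids = ids, k = k,
                 labels = setNames(fit$labels, ids),
                 sizes = tabulate(fit$labels, k),
                 profiles = profiles,
                 offsets = lapply(matrices, `[[`, "offsets"),
                 centers = fit$centers,
                 row_normalization = row_normalization,
                 seed = seed, iterations = fit$iterations),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d anchors in k=%d clusters (seed %d)\n",
              length(x$labels), x$k, x$seed))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Call clusters positive for a track
#'
#' A cluster is positive for a track when the mean density over the central
#' window of its mean profile exceeds `rule` times the background, taken as
#' the *lowest* central density among the other clusters (plus a
#' pseudocount).  Using the weakest cluster as the background reference
#' keeps the call correct when several clusters are positive for the same
#' track; with k = 2 it coincides with the across-cluster median.
#'
#' @param assignment a [kmeans_cluster()] result.
#' @param track track name (element of `assignment$profiles`).
#' @param rule fold-enrichment threshold (default 2).
#' @param central_fraction fraction of the flank defining the central
#'   window (default 0.2, i.e. |offset| <= 0.2 x flank).
#' @param pseudocount stabilises the background for near-zero tracks.
#' @return Integer vector of positive cluster labels.
#' @export
call_positive_clusters <- function(assignment, track, rule = 2,
                                   central_fraction = 0.2,
                                   pseudocount = 0.1) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (!track %in% names(assignment$profiles))
    .stopf("no profile for track '%s' in the assignment", track)
  prof <- assignment$profiles[[track]]
  offs <- assignment$offsets[[track]]
  central <- abs(offs) <= central_fraction * max(abs(offs))
  cd <- rowMeans(prof[, central, drop = FALSE])
  pos <- vapply(seq_len(assignment$k), function(j) {
    bg <- min(cd[-j])
    cd[j] >= rule * (bg + pseudocount)
  }, logical(1))
  which(pos)
}

#' Co-occupancy of a query factor at a reference factor's sites
#'
#' Two modes, reported by the `mode` field of the result:
#' * cluster mode (`query` is a [kmeans_cluster()] assignment over the
#'   reference sites): the co-bound fraction is the share of reference
#'   anchors falling in clusters called positive for `query_track`;
#' * overlap mode (`query` is a GRanges peak set): the share of reference
#'   peaks overlapping a query peak by >= 1 bp.
#'
#' @param reference_peaks the reference factor's peaks (GRanges; in cluster
#'   mode used only for bookkeeping and may be NULL).
#' @param query a `cluster_assignment` or a GRanges of query peaks.
#' @param query_track track name of the query factor (cluster mode).
#' @param rule,central_fraction,pseudocount forwarded to
#'   [call_positive_clusters()].
#' @param reference,query_name labels carried into the result.
#' @return Object of class `cooccupancy_result` with `n_reference`,
#'   `n_cobound` and `fraction` (percent).
#' @export
cooccupancy_fraction <- function(reference_peaks, query, query_track = NULL,
                                 rule = 2, central_fraction = 0.2,
                                 pseudocount = 0.1,
                                 reference = "reference", query_name = NULL) {
  if (inherits(query, "cluster_assignment")) {
    if (is.null(query_track))
      .stopf("cluster mode needs query_track")
    pos <- call_positive_clusters(query, query_track, rule = rule,
                                  central_fraction = central_fraction,
                                  pseudocount = pseudocount)
    n <- length(query$labels)
    co <- sum(query$labels %in% pos)
    mode <- "cluster"
    query_name <- query_name %||% query_track
  } else {
    n <- length(reference_peaks)
    co <- sum(countOverlaps(reference_peaks, query, minoverlap = 1L,
                            ignore.strand = TRUE) > 0)
    mode <- "overlap"
    query_name <- query_name %||% "query"
  }
  if (n == 0) .stopf("no reference sites")
  structure(list(mode = mode, reference = reference, query = query_name,
                 n_reference = n, n_cobound = co,
                 fraction = 100 * co / n),
            class = "cooccupancy_result")
}

#' @export
print.cooccupancy_result <- function(x, ...) {
  cat(sprintf(
    "cooccupancy (%s mode): %d / %d %s sites co-bound by %s (%.1f%%)\n",
    x$mode, x$n_cobound, x$n_reference, x$reference, x$query, x$fraction))
  invisible(x)
}
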
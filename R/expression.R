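## Binding-vs-expression integration: expression quintiles, grouped density
## summaries, bound-vs-all comparison.

#' Rank genes into expression groups of near-equal size
#'
#' Genes are sorted by FPKM, highest first (ties broken by gene id for
#' determinism), and split into `n_groups` contiguous groups whose sizes
#' differ by at most one.  Group 1 holds the most highly expressed genes.
#'
#' @param expression data.frame with `gene_id` and `fpkm` columns.
#' @param n_groups number of groups (default 5).
#' @return Object of class `expression_groups`: `table` (gene_id, fpkm,
#'   group), `sizes`, and per-group FPKM `boundaries`.
#' @export
rank_expression_quintiles <- function(expression, n_groups = 5L) {
  n <- nrow(expression)
  if (n < n_groups)
    .stopf("need at least %d genes to form %d groups", n_groups, n_groups)
  ord <- order(-expression$fpkm, expression$gene_id)
  sizes <- .near_equal_sizes(n, n_groups)
  tab <- expression[ord, c("gene_id", "fpkm")]
  tab$group <- rep(seq_len(n_groups), sizes)
  rownames(tab) <- NULL
  boundaries <- do.call(rbind, lapply(split(tab$fpkm, tab$group), range))
  colnames(boundaries) <- c("min_fpkm", "max_fpkm")
  structure(list(table = tab, sizes = sizes,
                 boundaries = boundaries[, 2:1]),
            class = "expression_groups")
}

#' @export
print.expression_groups <- function(x, ...) {
  cat(sprintf("expression_groups: %d genes in %d groups (1 = highest)\n",
              nrow(x$table), length(x$sizes)))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Notched-boxplot summary of per-gene densities by expression group
#'
#' Zero densities are excluded before the quartiles when `drop_zeros` is
#' TRUE (genes without a peak carry no density information).  The notch
#' half-width is the conventional `1.58 * IQR / sqrt(n)`; non-overlapping
#' notches indicate significantly different medians.
#'
#' @param density named numeric vector, one value per gene id.
#' @param groups an [rank_expression_quintiles()] result.
#' @param drop_zeros drop zero densities before summarising (default TRUE).
#' @return data.frame: group, n, median, q1, q3, notch (half-width), empty.
#' @export
group_density_summary <- function(density, groups, drop_zeros = TRUE) {
  stopifnot(inherits(groups, "expression_groups"))
  tab <- groups$table
  missing <- setdiff(tab$gene_id, names(density))
  if (length(missing))
    .stopf("densities missing for %d genes (e.g. %s)", length(missing),
           missing[1])
  res <- lapply(split(tab$gene_id, tab$group), function(ids) {
    v <- density[ids]
    if (drop_zeros) v <- v[v > 0]
    if (length(v) == 0)
      return(data.frame(n = 0L, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, notch = NA_real_, empty = TRUE))
    q <- unname(quantile(v, c(0.25, 0.5, 0.75)))
    data.frame(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               notch = 1.58 * (q[3] - q[1]) / sqrt(length(v)),
               empty = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(group = as.integer(names(res)), out)
  rownames(out) <- NULL
  out
}

#' Compare expression of bound genes against all genes
#'
#' Summarises `log2(FPKM + pseudocount)` for the full gene set and the
#' bound subset and tests the difference with a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param expression data.frame with `gene_id` and `fpkm`.
#' @param bound_gene_set character vector of bound gene ids (subset of the
#'   expression table).
#' @param pseudocount added to FPKM before the log (default 0.1).
#' @return List with `summary` (per-set n, median, mean of log2 FPKM),
#'   `p_value` and `test`.
#' @export
compare_bound_vs_all <- function(expression, bound_gene_set,
                                 pseudocount = 0.1) {
  if (length(bound_gene_set) == 0) .stopf("bound gene set is empty")
  if (!all(bound_gene_set %in% expression$gene_id))
    .stopf("bound genes absent from the expression table")
  la <- log2(expression$fpkm + pseudocount)
  lb <- la[expression$gene_id %in% bound_gene_set]
  wt <- suppressWarnings(wilcox.test(lb, la, alternative = "two.sided"))
  list(summary = data.frame(
         set = c("all", "bound"),
         n = c(length(la), length(lb)),
         median_log2_fpkm = c(median(la), median(lb)),
         mean_log2_fpkm = c(mean(la), mean(lb))),
       p_value = wt$p.value,
       test = "two-sided Wilcoxon rank-sum")
}
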
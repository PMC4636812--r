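## Peak-to-feature and peak-to-gene annotation.

.FEATURE_LEVELS <- c("promoter-TSS", "5'UTR", "3'UTR", "exon", "intron",
                     "TTS", "intergenic")

.summit_gr <- function(peaks) {
  GRanges(seqnames(peaks), IRanges(mcols(peaks)$summit, width = 1L))
}

#' Annotate peaks to genomic feature classes
#'
#' Each peak is assigned, by its summit position, to exactly one category
#' with precedence promoter-TSS > 5'UTR > 3'UTR > exon > intron > TTS >
#' intergenic.  The promoter window follows the HOMER convention
#' (1 kb upstream to 100 bp downstream of the TSS, strand-aware); the TTS
#' window mirrors it at the 3' end.  The nearest gene (by absolute
#' summit-to-TSS distance) and the signed, strand-aware distance (negative
#' = upstream) are reported for every peak.
#'
#' @param peaks a [peak_set()] GRanges (with `summit` column).
#' @param genes a [gene_catalog()].
#' @param promoter_upstream,promoter_downstream promoter window around the
#'   TSS in bp (defaults 1000 / 100, both inclusive).
#' @param tts_upstream,tts_downstream TTS window around the 3' end in bp
#'   (defaults 100 / 1000).
#' @return data.frame: peak_id, category (factor with the seven levels),
#'   nearest_gene, distance_to_tss.
#' @export
annotate_features <- function(peaks, genes,
                              promoter_upstream = 1000L,
                              promoter_downstream = 100L,
                              tts_upstream = 100L,
                              tts_downstream = 1000L) {
  stopifnot(inherits(genes, "gene_catalog"))
  summit <- .summit_gr(peaks)
  n <- length(summit)
  if (length(genes$genes) == 0) {
    return(data.frame(peak_id = names(peaks),
                      category = factor(rep("intergenic", n),
                                        levels = .FEATURE_LEVELS),
                      nearest_gene = NA_character_,
                      distance_to_tss = NA_real_))
  }
  tss <- tss_points(genes)
  prom <- promoters(tss, upstream = promoter_upstream,
                    downstream = promoter_downstream + 1L)
  tts_pt <- resize(genes$genes, width = 1L, fix = "end")
  ttsw <- promoters(tts_pt, upstream = tts_upstream,
                    downstream = tts_downstream + 1L)
  flat <- function(grl) if (is.null(grl)) GRanges()
                        else BiocGenerics::unlist(grl, use.names = FALSE)
  in_prom <- overlapsAny(summit, prom, ignore.strand = TRUE)
  in_u5 <- overlapsAny(summit, flat(genes$utr5), ignore.strand = TRUE)
  in_u3 <- overlapsAny(summit, flat(genes$utr3), ignore.strand = TRUE)
  in_exon <- overlapsAny(summit, flat(genes$exons), ignore.strand = TRUE)
  in_gene <- overlapsAny(summit, genes$genes, ignore.strand = TRUE)
  in_tts <- overlapsAny(summit, ttsw, ignore.strand = TRUE)
  category <- rep("intergenic", n)
  category[in_tts] <- "TTS"
  category[in_gene & !in_exon] <- "intron"
  category[in_exon] <- "exon"
  category[in_u3] <- "3'UTR"
  category[in_u5] <- "5'UTR"
  category[in_prom] <- "promoter-TSS"
  ng <- GenomicRanges::nearest(summit, tss, ignore.strand = TRUE)
  d <- start(summit) - start(tss)[ng]
  flip <- as.character(strand(tss))[ng] == "-"
  d[flip] <- -d[flip]
  data.frame(peak_id = names(peaks) %||% paste0("peak_", seq_len(n)),
             category = factor(category, levels = .FEATURE_LEVELS),
             nearest_gene = mcols(tss)$gene_id[ng],
             distance_to_tss = d)
}

#' Category percentages of a feature annotation
#'
#' @param annotation result of [annotate_features()].
#' @return data.frame with category, count and percent (summing to 100).
#' @export
feature_percentages <- function(annotation) {
  tab <- table(annotation$category)
  data.frame(category = names(tab),
             count = as.integer(tab),
             percent = 100 * as.integer(tab) / nrow(annotation))
}

#' Assign peaks to genes by TSS proximity
#'
#' A gene is bound when at least one peak summit lies within `window` bp
#' (inclusive) of its TSS, up- or downstream.  A peak may bind several
#' genes (divergent promoters); the best peak per gene is the qualifying
#' peak with the highest tag density (ties: first by peak order).
#'
#' @param peaks a [peak_set()] GRanges.
#' @param genes a [gene_catalog()].
#' @param window half-window around each TSS in bp (default 1000).
#' @return data.frame: gene_id, bound, best_peak, tag_density,
#'   distance_to_tss.
#' @export
assign_peaks_to_genes <- function(peaks, genes, window = 1000L) {
  stopifnot(inherits(genes, "gene_catalog"), window > 0)
  tss <- tss_points(genes)
  summit <- .summit_gr(peaks)
  win <- resize(tss, width = 2L * as.integer(window) + 1L, fix = "center")
  hits <- findOverlaps(win, summit, ignore.strand = TRUE)
  out <- data.frame(gene_id = mcols(tss)$gene_id,
                    bound = FALSE,
                    best_peak = NA_character_,
                    tag_density = 0,
                    distance_to_tss = NA_real_)
  if (length(hits)) {
    td <- mcols(peaks)$tag_density
    byg <- split(subjectHits(hits), queryHits(hits))
    for (gi_chr in names(byg)) {
      gi <- as.integer(gi_chr)
      ps <- byg[[gi_chr]]
      best <- ps[which.max(td[ps])]
      out$bound[gi] <- TRUE
      out$best_peak[gi] <- names(peaks)[best]
      out$tag_density[gi] <- td[best]
      d <- start(summit)[best] - start(tss)[gi]
      if (as.character(strand(tss))[gi] == "-") d <- -d
      out$distance_to_tss[gi] <- d
    }
  }
  out
}

#' Tag density of the nearest peak to each TSS
#'
#' For every gene, the tag density of the *nearest* (not the strongest)
#' qualifying peak summit within the window; 0 when no peak qualifies.
#' Ties in distance resolve to the peak appearing first in `peaks`.
#'
#' @param genes a [gene_catalog()].
#' @param peaks a [peak_set()] GRanges.
#' @param window window size in bp (default 2000).
#' @param direction `"both"` (default, +/- window around the TSS) or
#'   `"downstream"` (0..window bp downstream, strand-aware).
#' @return Named numeric vector of tag densities, one per gene.
#' @export
nearest_peak_density <- function(genes, peaks, window = 2000L,
                                 direction = c("both", "downstream")) {
  direction <- match.arg(direction)
  stopifnot(inherits(genes, "gene_catalog"), window > 0)
  tss <- tss_points(genes)
  summit <- .summit_gr(peaks)
  win <- if (direction == "both")
    resize(tss, width = 2L * as.integer(window) + 1L, fix = "center")
  else
    promoters(tss, upstream = 0L, downstream = as.integer(window) + 1L)
  hits <- findOverlaps(win, summit, ignore.strand = TRUE)
  out <- setNames(numeric(length(tss)), mcols(tss)$gene_id)
  if (length(hits)) {
    td <- mcols(peaks)$tag_density
    q <- queryHits(hits); s <- subjectHits(hits)
    d <- abs(start(summit)[s] - start(tss)[q])
    ord <- order(q, d, s)
    first <- !duplicated(q[ord])
    out[q[ord][first]] <- td[s[ord][first]]
  }
  out
}
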
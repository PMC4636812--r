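## Readers and writers for every external format the pipeline touches.
## Coordinates are held internally as GRanges (1-based, closed); BED files
## are 0-based half-open and the conversion happens only here.

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns chromosome name and length (no header).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dat <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "numeric"))
  chrom_sizes(setNames(as.integer(dat$length), dat$chrom))
}

#' Validate a named vector of chromosome sizes
#'
#' @param sizes named numeric vector, one positive length per chromosome.
#' @export
chrom_sizes <- function(sizes) {
  if (length(sizes) == 0)
    return(structure(integer(0), names = character(0),
                     class = "chrom_sizes"))
  if (is.null(names(sizes)) || anyDuplicated(names(sizes)))
    .stopf("chromosome names must be present and unique")
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    .stopf("chromosome lengths must be positive")
  structure(as.integer(sizes), names = names(sizes), class = "chrom_sizes")
}

#' @export
write_chrom_sizes <- function(sizes, path) {
  write.table(data.frame(names(sizes), as.integer(sizes)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.set_seqlengths <- function(gr, sizes) {
  if (is.null(sizes)) return(gr)
  GenomeInfoDb::seqlevels(gr) <- names(sizes)
  seqlengths(gr) <- as.integer(sizes)
  gr
}

#' Read a BED3/BED6 file into a GRanges
#'
#' BED intervals are 0-based half-open; the returned GRanges is 1-based
#' closed.  Column 4 (name), 5 (score) and 6 (strand) are kept when present.
#'
#' @param path BED file with >= 3 whitespace-separated columns.
#' @param chrom_sizes optional [chrom_sizes()] vector; records on
#'   chromosomes absent from it are dropped with a warning
#'   (`on_unknown = "drop"`, the default) or raise an error.
#' @param stranded require a valid +/- strand on every record (read files).
#' @param on_unknown `"drop"` or `"error"`.
#' @return GRanges with optional `name` and `score` metadata columns.
#' @export
read_bed <- function(path, chrom_sizes = NULL, stranded = FALSE,
                     on_unknown = c("drop", "error")) {
  on_unknown <- match.arg(on_unknown)
  if (!file.exists(path)) .stopf("BED file not found: %s", path)
  raw <- tryCatch(
    read.table(path, header = FALSE, colClasses = "character",
               comment.char = "#"),
    error = function(e) .stopf("malformed BED file %s: %s", path,
                               conditionMessage(e)))
  if (ncol(raw) < 3) .stopf("BED file %s has fewer than 3 columns", path)
  s0 <- suppressWarnings(as.numeric(raw[[2]]))
  e0 <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(!is.finite(s0) | !is.finite(e0))
  if (length(bad))
    .stopf("malformed BED line %d in %s: non-numeric coordinates",
           bad[1], path)
  bad <- which(s0 >= e0 | s0 < 0)
  if (length(bad))
    .stopf("invalid BED line %d in %s: start (%s) must be < end (%s) and >= 0",
           bad[1], path, raw[[2]][bad[1]], raw[[3]][bad[1]])
  strand <- if (ncol(raw) >= 6) raw[[6]] else rep("*", nrow(raw))
  strand[!strand %in% c("+", "-")] <- "*"
  if (stranded && any(strand == "*"))
    .stopf("%s: read records must carry a +/- strand (line %d)", path,
           which(strand == "*")[1])
  keep <- rep(TRUE, nrow(raw))
  if (!is.null(chrom_sizes)) {
    unknown <- !(raw[[1]] %in% names(chrom_sizes))
    if (any(unknown)) {
      if (on_unknown == "error")
        .stopf("%s: %d records on chromosomes absent from chrom_sizes",
               path, sum(unknown))
      .warnf("%s: dropping %d records on unknown chromosomes", path,
             sum(unknown))
      keep <- !unknown
    }
  }
  gr <- GRanges(raw[[1]][keep], IRanges(s0[keep] + 1, e0[keep]),
                strand = strand[keep])
  if (ncol(raw) >= 4) mcols(gr)$name <- raw[[4]][keep]
  if (ncol(raw) >= 5) {
    sc <- suppressWarnings(as.numeric(raw[[5]][keep]))
    mcols(gr)$score <- ifelse(is.finite(sc), sc, 0)
  }
  if (!is.null(chrom_sizes)) {
    gr <- .set_seqlengths(gr, chrom_sizes[intersect(names(chrom_sizes),
                                                    unique(raw[[1]][keep]))])
    over <- end(gr) > seqlengths(gr)[as.character(seqnames(gr))]
    if (any(over)) .stopf("%s: %d records extend past the chromosome end",
                          path, sum(over))
  }
  gr
}

#' Write a GRanges as BED (0-based half-open)
#'
#' Emits BED6 when names, scores or strands are informative, BED3 otherwise.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  st <- as.character(strand(gr))
  if (!is.null(mcols(gr)$name) || !is.null(mcols(gr)$score) ||
      any(st != "*")) {
    df$name <- mcols(gr)$name %||% paste0("r", seq_along(gr))
    df$score <- mcols(gr)$score %||% rep(0, length(gr))
    df$strand <- ifelse(st %in% c("+", "-"), st, ".")
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read called peaks from BED
#'
#' The BED score column carries the peak tag density (the MACS14 "t"); the
#' summit defaults to the interval midpoint since MACS14 BED output records
#' no summit.
#'
#' @inheritParams read_bed
#' @return GRanges with `name`, `tag_density` and `summit` (1-based bp)
#'   metadata columns.
#' @export
read_peaks <- function(path, chrom_sizes = NULL) {
  gr <- read_bed(path, chrom_sizes = chrom_sizes)
  peak_set(gr)
}

#' Construct a peak set from a GRanges
#'
#' @param gr peak intervals; optional `score` column becomes `tag_density`,
#'   optional `summit` column (1-based bp within the interval) is validated.
#' @export
peak_set <- function(gr) {
  if (is.null(mcols(gr)$name)) mcols(gr)$name <- paste0("peak_", seq_along(gr))
  td <- mcols(gr)$tag_density %||% mcols(gr)$score %||% rep(0, length(gr))
  if (any(td < 0)) .stopf("tag densities must be >= 0")
  mcols(gr)$tag_density <- as.numeric(td)
  mcols(gr)$score <- NULL
  summit <- mcols(gr)$summit %||% (start(gr) + (width(gr) - 1L) %/% 2L)
  if (any(summit < start(gr) | summit >= end(gr) + 1L))
    .stopf("peak summits must lie within the peak interval")
  mcols(gr)$summit <- as.integer(summit)
  names(gr) <- mcols(gr)$name
  gr
}

## ---- gene annotation --------------------------------------------------

#' Gene catalog: gene bodies, strand-aware TSSs and exon structure
#'
#' @param genes GRanges of gene bodies with +/- strand and a `gene_id`
#'   metadata column (`gene_name` optional).
#' @param exons GRangesList of exons, named by gene id.
#' @param utr5,utr3 optional GRangesList of UTR intervals, named by gene id.
#' @return An object of class `gene_catalog` with the strand-aware TSS
#'   (5' end) precomputed per gene.
#' @export
gene_catalog <- function(genes, exons = NULL, utr5 = NULL, utr3 = NULL) {
  if (is.null(mcols(genes)$gene_id)) .stopf("genes need a gene_id column")
  if (anyDuplicated(mcols(genes)$gene_id)) .stopf("gene ids must be unique")
  st <- as.character(strand(genes))
  if (any(!st %in% c("+", "-"))) .stopf("genes must be stranded (+/-)")
  tss <- ifelse(st == "+", start(genes), end(genes))
  mcols(genes)$tss <- as.integer(tss)
  if (is.null(mcols(genes)$gene_name))
    mcols(genes)$gene_name <- mcols(genes)$gene_id
  names(genes) <- mcols(genes)$gene_id
  if (!is.null(exons)) {
    exons <- BiocGenerics::sort(exons)
    fl <- BiocGenerics::unlist(exons, use.names = FALSE)
    gid <- rep(names(exons), lengths(exons))
    keep <- gid %in% names(genes)
    fl <- fl[keep]; gid <- gid[keep]
    gm <- genes[gid]
    bad <- start(fl) < start(gm) | end(fl) > end(gm)
    if (any(bad))
      .stopf("exons of gene %s fall outside the gene body", gid[bad][1])
    if (length(fl) > 1) {
      same <- gid[-1] == gid[-length(gid)]
      ovl <- same & start(fl)[-1] <= end(fl)[-length(fl)]
      if (any(ovl))
        .stopf("exons of gene %s overlap after sorting", gid[-1][ovl][1])
    }
  }
  structure(list(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("gene_catalog: %d genes on %d chromosome(s)%s\n",
              length(x$genes),
              length(unique(as.character(seqnames(x$genes)))),
              if (is.null(x$exons)) "" else ", with exon models"))
  invisible(x)
}

#' Strand-aware TSS points of a gene catalog
#'
#' @return GRanges of width-1 TSS positions, named by gene id, strand kept.
#' @export
tss_points <- function(catalog) {
  g <- catalog$genes
  GRanges(seqnames(g), IRanges(mcols(g)$tss, width = 1L),
          strand = strand(g), gene_id = mcols(g)$gene_id)
}

#' Read gene models from GTF or BED12
#'
#' GTF parsing is delegated to rtracklayer; `gene` rows (or the span of each
#' gene's exons when absent) define gene bodies, `exon` rows the exon
#' structure, `five_prime_utr`/`three_prime_utr` rows the UTRs.  BED12 block
#' structure becomes the exon model.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @return A [gene_catalog()].
#' @export
read_gene_annotation <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff2?)$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    if (is.null(mcols(gr)$gene_id) || anyNA(mcols(gr)$gene_id))
      .stopf("GTF %s: records without a gene_id attribute", path)
    type <- as.character(mcols(gr)$type)
    gene_rows <- gr[type == "gene"]
    ex <- gr[type == "exon"]
    if (length(gene_rows) == 0) {
      spl <- S4Vectors::split(ex, mcols(ex)$gene_id)
      gene_rows <- BiocGenerics::unlist(range(spl))
      mcols(gene_rows)$gene_id <- names(gene_rows)
    }
    exl <- if (length(ex)) S4Vectors::split(granges(ex), mcols(ex)$gene_id)
           else NULL
    u5 <- gr[type %in% c("five_prime_utr", "5UTR")]
    u3 <- gr[type %in% c("three_prime_utr", "3UTR")]
    g <- granges(gene_rows)
    mcols(g)$gene_id <- mcols(gene_rows)$gene_id
    if (!is.null(mcols(gene_rows)$gene_name))
      mcols(g)$gene_name <- mcols(gene_rows)$gene_name
    gene_catalog(g,
                 exons = exl,
                 utr5 = if (length(u5))
                   S4Vectors::split(granges(u5), mcols(u5)$gene_id) else NULL,
                 utr3 = if (length(u3))
                   S4Vectors::split(granges(u3), mcols(u3)$gene_id) else NULL)
  } else {
    bed <- rtracklayer::import(path, format = "bed")
    if (is.null(mcols(bed)$name)) .stopf("BED12 %s lacks name column", path)
    g <- granges(bed)
    mcols(g)$gene_id <- mcols(bed)$name
    exl <- if (!is.null(mcols(bed)$blocks)) {
      bl <- rtracklayer::blocks(bed)
      names(bl) <- mcols(bed)$name
      bl
    } else NULL
    gene_catalog(g, exons = exl)
  }
}

## ---- expression -------------------------------------------------------

#' Read a gene-expression table (gene_id, fpkm)
#'
#' @param path TSV with header columns `gene_id` and `fpkm`.
#' @return data.frame with columns gene_id (character) and fpkm (numeric).
#' @export
read_expression_table <- function(path) {
  dat <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "numeric"))
  if (!identical(names(dat)[1:2], c("gene_id", "fpkm")))
    .stopf("%s: expected header columns gene_id and fpkm", path)
  if (anyDuplicated(dat$gene_id))
    .stopf("%s: duplicate gene id '%s'", path,
           dat$gene_id[anyDuplicated(dat$gene_id)])
  if (any(!is.finite(dat$fpkm)) || any(dat$fpkm < 0))
    .stopf("%s: FPKM values must be finite and >= 0", path)
  dat[, c("gene_id", "fpkm")]
}

#' @export
write_expression_table <- function(expression, path) {
  write.table(expression, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- wiggle -----------------------------------------------------------

#' Write a coverage track as fixedStep wiggle
#'
#' One fixedStep block per chromosome, 1-based start, step = span = bin
#' width.  The trailing partial bin (if any) is emitted with the full span,
#' as binned-track wigs conventionally are.
#'
#' @param track a [coverage_track()].
#' @param path output file.
#' @param digits decimal precision of the emitted values.
#' @export
write_wig <- function(track, path, digits = 6) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- track$bin_width
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (length(v) == 0) next
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       ch, w, w), con)
    txt <- formatC(v, format = "f", digits = digits, drop0trailing = TRUE)
    writeLines(txt, con)
  }
  invisible(path)
}

#' Read a fixedStep wiggle file into a coverage track
#'
#' @param path wiggle file (fixedStep blocks only).
#' @param chrom_sizes [chrom_sizes()] of the genome the track lives on.
#' @return A [coverage_track()] with `normalization = "unknown"` and
#'   `total_reads = NA` (the wig format records neither).
#' @export
read_wig <- function(path, chrom_sizes) {
  lines <- readLines(path)
  hdr <- grep("^fixedStep", lines)
  if (length(lines) && length(hdr) == 0)
    .stopf("%s: no fixedStep declaration found", path)
  vals <- list()
  bin_width <- NULL
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    h <- lines[hdr[i]]
    ch <- sub(".*chrom=(\\S+).*", "\\1", h)
    step <- as.integer(sub(".*step=(\\d+).*", "\\1", h))
    start <- as.integer(sub(".*start=(\\d+).*", "\\1", h))
    if (start != 1L)
      .stopf("%s: fixedStep block for %s does not start at 1", path, ch)
    if (is.null(bin_width)) bin_width <- step
    else if (step != bin_width)
      .stopf("%s: inconsistent step sizes", path)
    body <- lines[seq(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    vals[[ch]] <- as.numeric(body)
  }
  if (is.null(bin_width)) bin_width <- 25L
  for (ch in names(chrom_sizes)) {
    nb <- ceiling(chrom_sizes[[ch]] / bin_width)
    v <- vals[[ch]] %||% numeric(0)
    vals[[ch]] <- c(v, numeric(max(0, nb - length(v))))[seq_len(nb)]
  }
  coverage_track(vals[names(chrom_sizes)], chrom_sizes, bin_width,
                 total_reads = NA_real_, normalization = "unknown",
                 label = sub("\\.wig$", "", basename(path)))
}
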
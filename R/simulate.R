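## Synthetic genome, read and expression generator.  Every stage of the
## pipeline assumes a statistical structure (binding offsets downstream of
## TSSs, co-binding between factors, enhancer positivity, super-enhancer
## enrichment, expression coupled to promoter binding); the generator
## plants that structure with known parameters so each stage can be
## validated by parameter recovery.  Fully deterministic given the seed.

#' Specification of one simulated ChIP factor
#'
#' @param name factor name.
#' @param fraction_bound fraction of genes bound at the promoter.
#' @param offset_mean mean strand-aware 5'-position offset of bound-site
#'   reads downstream of the TSS, in bp (default 200).
#' @param offset_sd standard deviation of read 5' positions around the
#'   site (default 50 bp).
#' @param reads_per_site expected reads per bound site (default 50; the
#'   per-site expectation is drawn from a Gamma around this mean so sites
#'   differ in strength).
#' @param background_rate uniform background reads per kb of genome
#'   (default 20; with 200-bp extension this yields ~4x background
#'   coverage, i.e. ~10-fold enrichment at a default-strength site).
#' @param enhancer_fraction fraction of enhancers carrying a factor site
#'   at their midpoint (default 0.25).
#' @param se_fold uniform fold-enrichment of factor reads over background
#'   inside super-enhancer bodies (default 3; 1 = no enrichment).
#' @export
factor_spec <- function(name, fraction_bound = 0.6, offset_mean = 200,
                        offset_sd = 50, reads_per_site = 50,
                        background_rate = 20, enhancer_fraction = 0.25,
                        se_fold = 3) {
  if (fraction_bound < 0 || fraction_bound > 1 ||
      enhancer_fraction < 0 || enhancer_fraction > 1)
    .stopf("fractions must lie in [0, 1]")
  if (se_fold < 1) .stopf("se_fold must be >= 1")
  list(name = name, fraction_bound = fraction_bound,
       offset_mean = offset_mean, offset_sd = offset_sd,
       reads_per_site = reads_per_site, background_rate = background_rate,
       enhancer_fraction = enhancer_fraction, se_fold = se_fold)
}

#' Simulation configuration
#'
#' Defaults describe a small but realistic study condition: one 5-Mb
#' chromosome carrying 500 genes, 400 enhancers and 20 super-enhancers
#' (5-30 kb), one factor binding 60% of promoters with its read density
#' peaking 200 bp downstream of the TSS, ~10-fold enrichment over a
#' uniform background, and expression rank-coupled to promoter binding
#' strength.
#'
#' @param seed RNG seed governing every random choice.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param n_genes,min_tss_spacing gene count and minimal TSS spacing (bp).
#' @param gene_length min/max gene length (bp).
#' @param n_enhancers,enhancer_width enhancer count and width range (bp).
#' @param n_super_enhancers,se_length super-enhancer count and length
#'   range (bp).
#' @param read_length sequenced read length (bp, default 36).
#' @param factors list of [factor_spec()]s.
#' @param cobinding optional symmetric co-binding matrix with unit
#'   diagonal (dimnames = factor names); entry `[A, B]` is the planted
#'   fraction of the *first* factor's bound genes that are also bound by
#'   factor B.
#' @param expression_coupling target rank coupling between promoter
#'   binding strength of the first factor and FPKM (0..1).
#' @param expression_sdlog log-normal sd of FPKM values.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_sizes = c(chrS = 5e6),
                              n_genes = 500L, min_tss_spacing = 2000L,
                              gene_length = c(1000L, 6000L),
                              n_enhancers = 400L,
                              enhancer_width = c(800L, 2000L),
                              n_super_enhancers = 20L,
                              se_length = c(5000L, 30000L),
                              read_length = 36L,
                              factors = list(factor_spec("factorA")),
                              cobinding = NULL,
                              expression_coupling = 0.5,
                              expression_sdlog = 1.2) {
  fn <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(fn)) .stopf("factor names must be unique")
  names(factors) <- fn
  if (!is.null(cobinding)) {
    if (!isTRUE(all.equal(cobinding, t(cobinding))) ||
        any(diag(cobinding) != 1))
      .stopf("cobinding matrix must be symmetric with unit diagonal")
    if (is.null(dimnames(cobinding)) ||
        !all(rownames(cobinding) %in% fn))
      .stopf("cobinding dimnames must be factor names")
  }
  structure(list(seed = as.integer(seed),
                 chrom_sizes = chrom_sizes(chrom_sizes),
                 n_genes = as.integer(n_genes),
                 min_tss_spacing = as.integer(min_tss_spacing),
                 gene_length = as.integer(gene_length),
                 n_enhancers = as.integer(n_enhancers),
                 enhancer_width = as.integer(enhancer_width),
                 n_super_enhancers = as.integer(n_super_enhancers),
                 se_length = as.integer(se_length),
                 read_length = as.integer(read_length),
                 factors = factors, cobinding = cobinding,
                 expression_coupling = expression_coupling,
                 expression_sdlog = expression_sdlog),
            class = "sim_config")
}

# allocate counts across chromosomes proportionally to length
.alloc <- function(n, sizes) {
  p <- as.numeric(sizes) / sum(as.numeric(sizes))
  cnt <- floor(n * p)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(n * p - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  setNames(as.integer(cnt), names(sizes))
}

#' Simulate the genome annotation and its ground truth
#'
#' Places non-overlapping genes at near-regular TSS spacing, enhancers in
#' intergenic space, and super-enhancers in a reserved gene-free segment
#' at the right end of each chromosome.  Draws the per-gene bound flags
#' and binding strengths for every factor (honouring the planted
#' co-binding fractions against the first factor), the enhancer-positive
#' flags, and the per-super-enhancer enrichment.
#'
#' @param config a [simulation_config()].
#' @return Object of class `sim_annotation`: `genes` ([gene_catalog()]),
#'   `enhancers`, `super_enhancers` (GRanges), `chrom_sizes`, `truth`, and
#'   the `config`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_annotation_impl(config))
}

.simulate_annotation_impl <- function(config) {
  cs <- config$chrom_sizes
  g_per <- .alloc(config$n_genes, cs)
  e_per <- .alloc(config$n_enhancers, cs)
  s_per <- .alloc(config$n_super_enhancers, cs)
  gene_rows <- list(); enh_rows <- list(); se_rows <- list()
  margin <- 2000
  for (ch in names(cs)) {
    L <- as.numeric(cs[[ch]])
    n_se <- s_per[[ch]]
    se_len <- if (n_se > 0)
      round(runif(n_se, config$se_length[1], config$se_length[2])) else
      integer(0)
    se_gap <- 5000
    reserve <- sum(se_len) + se_gap * (n_se + 1)
    ng <- g_per[[ch]]
    region <- c(margin, L - reserve - margin)
    if (ng > 0) {
      spacing <- diff(region) / ng
      if (spacing < config$min_tss_spacing)
        .stopf("chromosome %s too small for %d genes at %d bp spacing",
               ch, ng, config$min_tss_spacing)
      tss <- round(region[1] + (seq_len(ng) - 0.5) * spacing +
                     runif(ng, -0.2, 0.2) * spacing)
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      # genes must stay inside their own TSS slot: with +/-0.2-spacing
      # jitter the guaranteed room on either side is 0.3 x spacing
      maxlen <- min(config$gene_length[2], floor(0.3 * spacing))
      len <- round(runif(ng, min(config$gene_length[1], maxlen), maxlen))
      gs <- ifelse(strand == "+", tss, tss - len + 1)
      ge <- ifelse(strand == "+", tss + len - 1, tss)
      gene_rows[[ch]] <- data.frame(chrom = ch, start = gs, end = ge,
                                    strand = strand, tss = tss)
    }
    # enhancers: sample positions in the gaps between gene bodies
    ne <- e_per[[ch]]
    if (ne > 0) {
      gb <- gene_rows[[ch]]
      occ <- IRanges(gb$start - 500L, gb$end + 500L)
      free <- IRanges::setdiff(IRanges(region[1], region[2]), occ)
      ew <- round(runif(ne, config$enhancer_width[1],
                        config$enhancer_width[2]))
      es <- integer(ne)
      for (i in seq_len(ne)) {
        cand <- free[width(free) >= ew[i] + 2L]
        if (length(cand) == 0)
          .stopf("chromosome %s: no intergenic space left for enhancer %d",
                 ch, i)
        j <- sample.int(length(cand), 1L,
                        prob = as.numeric(width(cand)))
        s <- start(cand[j]) +
          floor(runif(1, 0, width(cand[j]) - ew[i]))
        es[i] <- s
        free <- IRanges::setdiff(free, IRanges(s - 200L, s + ew[i] + 200L))
      }
      enh_rows[[ch]] <- data.frame(chrom = ch, start = es,
                                   end = es + ew - 1L)
    }
    if (n_se > 0) {
      pos <- L - reserve + se_gap
      ss <- integer(n_se)
      for (i in seq_len(n_se)) {
        ss[i] <- pos
        pos <- pos + se_len[i] + se_gap
      }
      se_rows[[ch]] <- data.frame(chrom = ch, start = ss,
                                  end = ss + se_len - 1L)
    }
  }
  gd <- do.call(rbind, gene_rows)
  gd$gene_id <- sprintf("g%04d", seq_len(nrow(gd)))
  genes_gr <- GRanges(gd$chrom, IRanges(gd$start, gd$end),
                      strand = gd$strand, gene_id = gd$gene_id)
  genes_gr <- .set_seqlengths(genes_gr, config$chrom_sizes)
  # simple exon model: 5' exon, 3' exon, intron between (single exon when
  # the gene is short); UTRs are the outer 100 bp of the terminal exons
  long <- (gd$end - gd$start + 1L) > 800L
  ex_id <- c(gd$gene_id[long], gd$gene_id[long], gd$gene_id[!long])
  ex_gr <- GRanges(c(gd$chrom[long], gd$chrom[long], gd$chrom[!long]),
                   IRanges(c(gd$start[long], gd$end[long] - 299L,
                             gd$start[!long]),
                           c(gd$start[long] + 299L, gd$end[long],
                             gd$end[!long])))
  exl <- S4Vectors::split(ex_gr, factor(ex_id, levels = gd$gene_id))
  plus <- gd$strand == "+"
  u5 <- S4Vectors::split(
    GRanges(gd$chrom, IRanges(ifelse(plus, gd$start, gd$end - 99L),
                              ifelse(plus, gd$start + 99L, gd$end))),
    factor(gd$gene_id, levels = gd$gene_id))
  u3 <- S4Vectors::split(
    GRanges(gd$chrom, IRanges(ifelse(plus, gd$end - 99L, gd$start),
                              ifelse(plus, gd$end, gd$start + 99L))),
    factor(gd$gene_id, levels = gd$gene_id))
  catalog <- gene_catalog(genes_gr, exons = exl, utr5 = u5, utr3 = u3)
  ed <- do.call(rbind, enh_rows)
  enh_gr <- if (!is.null(ed)) {
    g <- GRanges(ed$chrom, IRanges(ed$start, ed$end))
    names(g) <- sprintf("enh_%04d", seq_along(g))
    .set_seqlengths(g, config$chrom_sizes)
  } else GRanges()
  sd_ <- do.call(rbind, se_rows)
  se_gr <- if (!is.null(sd_)) {
    g <- GRanges(sd_$chrom, IRanges(sd_$start, sd_$end))
    names(g) <- sprintf("se_%03d", seq_along(g))
    .set_seqlengths(g, config$chrom_sizes)
  } else GRanges()
  truth <- .simulate_truth(config, gd, enh_gr, se_gr)
  structure(list(genes = catalog, enhancers = enh_gr,
                 super_enhancers = se_gr,
                 chrom_sizes = config$chrom_sizes,
                 truth = truth, config = config),
            class = "sim_annotation")
}

# bound flags, strengths, enhancer positivity; co-binding realized against
# the first factor as reference
.simulate_truth <- function(config, gd, enh_gr, se_gr) {
  ng <- nrow(gd); gid <- gd$gene_id
  fns <- names(config$factors)
  truth <- list(factors = list())
  ref_bound <- NULL
  for (fn in fns) {
    fs <- config$factors[[fn]]
    nb <- round(fs$fraction_bound * ng)
    cb <- if (!is.null(config$cobinding) && fn != fns[1] &&
              fns[1] %in% rownames(config$cobinding) &&
              fn %in% colnames(config$cobinding))
      config$cobinding[fns[1], fn] else NA_real_
    bound_ids <- if (!is.na(cb) && !is.null(ref_bound)) {
      n_shared <- min(round(cb * length(ref_bound)), nb, length(ref_bound))
      shared <- sample(ref_bound, n_shared)
      pool <- setdiff(gid, ref_bound)
      extra <- if (nb - n_shared > 0)
        sample(pool, min(nb - n_shared, length(pool))) else character(0)
      c(shared, extra)
    } else {
      sample(gid, nb)
    }
    bound <- setNames(gid %in% bound_ids, gid)
    strength <- setNames(numeric(ng), gid)
    strength[bound] <- rgamma(sum(bound), shape = 5,
                              scale = fs$reads_per_site / 5)
    enh_pos <- if (length(enh_gr))
      setNames(seq_along(enh_gr) %in%
                 sample(length(enh_gr),
                        round(fs$enhancer_fraction * length(enh_gr))),
               names(enh_gr))
    else logical(0)
    truth$factors[[fn]] <- list(bound = bound, strength = strength,
                                enhancer_positive = enh_pos,
                                offset = fs$offset_mean,
                                se_fold = fs$se_fold)
    if (fn == fns[1]) ref_bound <- bound_ids
  }
  truth$genes <- gd[, c("gene_id", "chrom", "tss", "strand")]
  truth
}

#' Simulate factor and input reads
#'
#' Bound-site reads have 5' positions drawn Normal(site + strand-aware
#' offset, sd) with random strand; enhancer-site reads centre on the
#' midpoint; super-enhancer enrichment adds uniform reads inside the
#' bodies at `(se_fold - 1)` times the background density; background
#' reads are uniform over the genome.  The input is background-only at
#' the factor background depth (matched sequencing depth).
#'
#' @param annotation a [simulate_annotation()] result.
#' @return Named list of stranded read GRanges, one per factor, plus
#'   `input`.
#' @export
simulate_reads <- function(annotation) {
  stopifnot(inherits(annotation, "sim_annotation"))
  config <- annotation$config
  with_seed(config$seed + 1L, .simulate_reads_impl(annotation))
}

.simulate_reads_impl <- function(annotation) {
  config <- annotation$config
  cs <- annotation$chrom_sizes
  rl <- config$read_length
  genome <- sum(as.numeric(cs))
  cum <- cumsum(c(0, as.numeric(cs)))
  chrom_of <- function(gpos) {
    i <- findInterval(gpos - 0.5, cum)
    list(chrom = names(cs)[i], pos = gpos - cum[i])
  }
  mk_reads <- function(chrom, p5) {
    st <- sample(c("+", "-"), length(p5), replace = TRUE)
    lim <- as.integer(cs[chrom])
    p5 <- pmin(pmax(as.integer(round(p5)), rl), lim - rl)
    s <- ifelse(st == "+", p5, p5 - rl + 1L)
    GRanges(chrom, IRanges(s, s + rl - 1L), strand = st)
  }
  out <- list()
  gtab <- annotation$truth$genes
  for (fn in names(config$factors)) {
    fs <- config$factors[[fn]]
    tr <- annotation$truth$factors[[fn]]
    parts <- list()
    # promoter sites
    bg_ids <- names(tr$bound)[tr$bound]
    if (length(bg_ids)) {
      gi <- match(bg_ids, gtab$gene_id)
      nreads <- rpois(length(gi), tr$strength[bg_ids])
      site <- gtab$tss[gi] +
        ifelse(gtab$strand[gi] == "+", 1, -1) * fs$offset_mean
      p5 <- rnorm(sum(nreads), rep(site, nreads), fs$offset_sd)
      parts$promoter <- mk_reads(rep(gtab$chrom[gi], nreads), p5)
    }
    # enhancer sites
    ep <- names(tr$enhancer_positive)[tr$enhancer_positive]
    if (length(ep)) {
      eg <- annotation$enhancers[ep]
      mid <- start(eg) + (width(eg) - 1L) %/% 2L
      nreads <- rpois(length(eg), fs$reads_per_site)
      p5 <- rnorm(sum(nreads), rep(mid, nreads), fs$offset_sd)
      parts$enhancer <- mk_reads(rep(as.character(seqnames(eg)), nreads),
                                 p5)
    }
    # super-enhancer body enrichment
    if (length(annotation$super_enhancers) && fs$se_fold > 1) {
      se <- annotation$super_enhancers
      extra <- rpois(length(se), (fs$se_fold - 1) *
                       fs$background_rate / 1000 * width(se))
      p5 <- runif(sum(extra), rep(start(se), extra), rep(end(se), extra))
      parts$se <- mk_reads(rep(as.character(seqnames(se)), extra), p5)
    }
    # uniform background
    nbg <- round(fs$background_rate / 1000 * genome)
    gpos <- runif(nbg, 0, genome)
    cp <- chrom_of(ceiling(gpos))
    parts$background <- mk_reads(cp$chrom, cp$pos)
    reads <- suppressWarnings(do.call(c, unname(parts)))
    out[[fn]] <- .set_seqlengths(BiocGenerics::sort(reads), cs)
  }
  # matched-depth input: background only
  fs1 <- config$factors[[1]]
  nbg <- round(fs1$background_rate / 1000 * genome)
  gpos <- runif(nbg, 0, genome)
  cp <- chrom_of(ceiling(gpos))
  out$input <- .set_seqlengths(BiocGenerics::sort(mk_reads(cp$chrom,
                                                           cp$pos)), cs)
  out
}

#' Simulate a gene-expression table coupled to promoter binding
#'
#' FPKM values are log-normal; their rank coupling to the first factor's
#' binding strength is planted through a Gaussian copula with correlation
#' `expression_coupling` (coupling 1 gives perfect rank agreement among
#' bound genes, coupling 0 independence).
#'
#' @param annotation a [simulate_annotation()] result.
#' @return data.frame with `gene_id` and `fpkm`.
#' @export
simulate_expression <- function(annotation) {
  stopifnot(inherits(annotation, "sim_annotation"))
  config <- annotation$config
  with_seed(config$seed + 2L, {
    strength <- annotation$truth$factors[[1]]$strength
    n <- length(strength)
    r <- rank(strength, ties.method = "first")
    zs <- qnorm(r / (n + 1))
    rho <- config$expression_coupling
    z <- rho * zs + sqrt(1 - rho^2) * rnorm(n)
    data.frame(gene_id = names(strength),
               fpkm = exp(1 + config$expression_sdlog * z))
  })
}

#' Run the full simulation
#'
#' @param config a [simulation_config()].
#' @return Object of class `chip_simulation`: `annotation`, `reads`
#'   (named list of stranded GRanges incl. `input`), `expression`,
#'   `truth`, `config`.
#' @export
simulate_chipseq <- function(config = simulation_config()) {
  ann <- simulate_annotation(config)
  reads <- simulate_reads(ann)
  expr <- simulate_expression(ann)
  structure(list(annotation = ann, reads = reads, expression = expr,
                 truth = ann$truth, config = config),
            class = "chip_simulation")
}

#' @export
print.chip_simulation <- function(x, ...) {
  a <- x$annotation
  cat(sprintf(
    "chip_simulation (seed %d): %d genes, %d enhancers, %d super-enhancers\n",
    x$config$seed, length(a$genes$genes), length(a$enhancers),
    length(a$super_enhancers)))
  for (fn in setdiff(names(x$reads), "input"))
    cat(sprintf("  %s: %d reads\n", fn, length(x$reads[[fn]])))
  cat(sprintf("  input: %d reads\n", length(x$reads$input)))
  invisible(x)
}

#' Write every simulated file to a directory
#'
#' Emits chrom_sizes.tsv, genes.gtf, enhancers.bed, super_enhancers.bed,
#' one `<factor>.reads.bed` per factor, input.reads.bed, expression.tsv
#' and truth.json.  Deterministic: the same simulation writes
#' byte-identical files.
#'
#' @param sim a [simulate_chipseq()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "chip_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- sim$annotation
  write_chrom_sizes(ann$chrom_sizes, file.path(dir, "chrom_sizes.tsv"))
  .write_gtf(ann$genes, file.path(dir, "genes.gtf"))
  if (length(ann$enhancers))
    write_bed(ann$enhancers, file.path(dir, "enhancers.bed"))
  if (length(ann$super_enhancers))
    write_bed(ann$super_enhancers, file.path(dir, "super_enhancers.bed"))
  for (fn in names(sim$reads)) {
    gr <- sim$reads[[fn]]
    mcols(gr)$name <- paste0(fn, "_r", seq_along(gr))
    mcols(gr)$score <- 0
    write_bed(gr, file.path(dir, paste0(fn, ".reads.bed")))
  }
  write_expression_table(sim$expression, file.path(dir, "expression.tsv"))
  tr <- sim$truth
  jsonlite::write_json(
    list(factors = lapply(tr$factors, function(f)
      list(bound_genes = names(f$bound)[f$bound],
           strength = as.list(round(f$strength[f$bound], 4)),
           positive_enhancers =
             names(f$enhancer_positive)[f$enhancer_positive],
           offset = f$offset, se_fold = f$se_fold))),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

# minimal GTF writer for simulated annotations
.write_gtf <- function(catalog, path) {
  g <- catalog$genes
  ids <- mcols(g)$gene_id
  chrom <- setNames(as.character(seqnames(g)), ids)
  st <- setNames(as.character(strand(g)), ids)
  rows <- function(type, id, s, e) sprintf(
    paste0("%s\tchipmeta_sim\t%s\t%d\t%d\t.\t%s\t.\t",
           'gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";'),
    chrom[id], type, s, e, st[id], id, id, id)
  parts <- list(rows("gene", ids, start(g), end(g)))
  ord <- integer(0)
  for (part in list(c("exon", "exons"), c("five_prime_utr", "utr5"),
                    c("three_prime_utr", "utr3"))) {
    grl <- catalog[[part[2]]]
    if (is.null(grl)) next
    fl <- BiocGenerics::unlist(grl, use.names = FALSE)
    gid <- rep(names(grl), lengths(grl))
    parts[[length(parts) + 1L]] <-
      rows(part[1], gid, start(fl), end(fl))
  }
  lines <- unlist(parts)
  # group lines by gene in catalog order, genes first within each group
  gene_of <- sub('.*gene_id "([^"]+)".*', "\\1", lines)
  lines <- lines[order(match(gene_of, ids))]
  writeLines(lines, path)
  invisible(path)
}
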
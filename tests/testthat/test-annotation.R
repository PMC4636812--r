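# hand-built two-gene catalog: gp on + at [2001,8000], gm on - at
# [12001,18000]; exons are the terminal 300 bp, UTRs the outer 100 bp
toy_catalog <- function() {
  g <- GRanges("chr1", IRanges(c(2001, 12001), c(8000, 18000)),
               strand = c("+", "-"), gene_id = c("gp", "gm"))
  ex <- S4Vectors::split(
    GRanges("chr1", IRanges(c(2001, 7701, 12001, 17701),
                            c(2300, 8000, 12300, 18000))),
    c("gp", "gp", "gm", "gm"))
  u5 <- S4Vectors::split(
    GRanges("chr1", IRanges(c(2001, 17901), c(2100, 18000))),
    c("gp", "gm"))
  u3 <- S4Vectors::split(
    GRanges("chr1", IRanges(c(7901, 12001), c(8000, 12100))),
    c("gp", "gm"))
  gene_catalog(g, exons = ex, utr5 = u5, utr3 = u3)
}

peaks_at <- function(summits, width = 200L) {
  gr <- GRanges("chr1", IRanges(summits - width %/% 2, width = width),
                summit = summits,
                tag_density = seq_along(summits))
  peak_set(gr)
}

test_that("summit categories follow the precedence order", {
  cat_ <- toy_catalog()
  # 50 bp downstream of the + TSS: promoter beats 5'UTR and exon
  ann <- annotate_features(peaks_at(c(2051)), cat_)
  expect_equal(as.character(ann$category), "promoter-TSS")
  # inside the intron, far from both TSSs
  ann2 <- annotate_features(peaks_at(c(5000)), cat_)
  expect_equal(as.character(ann2$category), "intron")
  expect_equal(ann2$nearest_gene, "gp")
  # 3' exon past the UTR, outside all windows: exon
  ann3 <- annotate_features(peaks_at(c(7750)), cat_)
  expect_equal(as.character(ann3$category), "exon")
  # 500 bp past the + gene end: TTS
  ann4 <- annotate_features(peaks_at(c(8500)), cat_)
  expect_equal(as.character(ann4$category), "TTS")
  # far from everything: intergenic, and no genes at all -> intergenic
  ann5 <- annotate_features(peaks_at(c(10500)), cat_)
  expect_equal(as.character(ann5$category), "intergenic")
  empty <- gene_catalog(GRanges("chr1", IRanges(1, 2),
                                strand = "+", gene_id = "x")[0])
  ann6 <- annotate_features(peaks_at(c(10500)), empty)
  expect_equal(as.character(ann6$category), "intergenic")
})

test_that("signed TSS distances are strand-aware", {
  cat_ <- toy_catalog()
  ann <- annotate_features(peaks_at(c(1901, 18100)), cat_)
  expect_equal(ann$distance_to_tss[1], -100)  # upstream of + TSS
  expect_equal(ann$distance_to_tss[2], -100)  # upstream of - TSS (higher coord)
})

test_that("feature percentages sum to 100", {
  cat_ <- toy_catalog()
  ann <- annotate_features(peaks_at(c(2051, 5000, 7750, 8500, 10500,
                                      15000, 17950)), cat_)
  pct <- feature_percentages(ann)
  expect_equal(sum(pct$percent), 100, tolerance = 0.1)
})

test_that("category counts are invariant under genome mirroring", {
  cat_ <- toy_catalog()
  summits <- c(2051, 5000, 7750, 8500, 10500, 15000, 17950, 1500)
  L <- 20000L
  mirror_catalog <- function(cat_) {
    mg <- function(gr) GRanges("chr1",
                               IRanges(L + 1L - end(gr), L + 1L - start(gr)),
                               strand = chartr("+-", "-+",
                                               as.character(strand(gr))))
    g <- mg(cat_$genes); mcols(g)$gene_id <- mcols(cat_$genes)$gene_id
    ml <- function(grl) {
      if (is.null(grl)) return(NULL)
      out <- S4Vectors::endoapply(grl, function(x)
        GRanges("chr1", IRanges(L + 1L - end(x), L + 1L - start(x))))
      out
    }
    gene_catalog(g, exons = ml(cat_$exons), utr5 = ml(cat_$utr5),
                 utr3 = ml(cat_$utr3))
  }
  ann <- annotate_features(peaks_at(summits), cat_)
  ann_m <- annotate_features(peaks_at(L + 1L - summits), mirror_catalog(cat_))
  expect_equal(table(ann$category), table(ann_m$category))
})

test_that("gene binding uses an inclusive +/- window around the TSS", {
  cat_ <- toy_catalog()
  # summit exactly at the TSS
  gb <- assign_peaks_to_genes(peaks_at(c(2001)), cat_, window = 1000)
  expect_true(gb$bound[gb$gene_id == "gp"])
  # summit at TSS + 1000: inclusive boundary
  gb2 <- assign_peaks_to_genes(peaks_at(c(3001)), cat_, window = 1000)
  expect_true(gb2$bound[gb2$gene_id == "gp"])
  # summit at TSS + 1001: outside
  gb3 <- assign_peaks_to_genes(peaks_at(c(3002)), cat_, window = 1000)
  expect_false(gb3$bound[gb3$gene_id == "gp"])
  # best peak is the strongest qualifying one
  gb4 <- assign_peaks_to_genes(peaks_at(c(2100, 2500)), cat_, window = 1000)
  expect_equal(gb4$tag_density[gb4$gene_id == "gp"], 2)
})

test_that("gene binding is monotone in the window size", {
  set.seed(41)
  cfg <- small_sim_config(seed = 41)
  ann <- simulate_annotation(cfg)
  summits <- sort(sample.int(7e5, 150)) + 1000L
  pk <- peak_set(GRanges("chrS", IRanges(summits - 100L, width = 201L),
                         summit = summits,
                         tag_density = seq_along(summits)))
  prev <- character(0)
  for (w in c(250, 1000, 4000)) {
    gb <- assign_peaks_to_genes(pk, ann$genes, window = w)
    bound <- gb$gene_id[gb$bound]
    expect_true(all(prev %in% bound))
    prev <- bound
  }
})

test_that("nearest peak density takes the nearest, not the strongest", {
  cat_ <- toy_catalog()
  pk <- peak_set(GRanges("chr1", IRanges(c(2051, 2851), width = 200),
                         summit = c(2101, 2901),
                         tag_density = c(50, 500)))
  d <- nearest_peak_density(cat_, pk, window = 2000)
  expect_equal(unname(d["gp"]), 50)   # +100 beats +900 despite lower density
  expect_equal(unname(d["gm"]), 0)    # nothing within the window
  # downstream-only mode ignores upstream peaks
  up <- peak_set(GRanges("chr1", IRanges(1801, width = 100),
                         summit = 1851, tag_density = 9))
  expect_equal(unname(nearest_peak_density(cat_, up, 2000,
                                           "downstream")["gp"]), 0)
  expect_equal(unname(nearest_peak_density(cat_, up, 2000, "both")["gp"]), 9)
})

test_that("nearest peak density matches an exhaustive scan", {
  set.seed(51)
  cfg <- small_sim_config(seed = 51)
  ann <- simulate_annotation(cfg)
  summits <- sort(sample.int(75e4, 200)) + 2000L
  pk <- peak_set(GRanges("chrS", IRanges(summits - 50, width = 101),
                         summit = summits,
                         tag_density = round(runif(200, 1, 100))))
  got <- nearest_peak_density(ann$genes, pk, window = 2000)
  tss <- tss_points(ann$genes)
  for (i in seq_along(tss)) {
    d <- abs(summits - start(tss)[i])
    expected <- if (min(d) <= 2000)
      mcols(pk)$tag_density[which.min(d)] else 0
    expect_equal(unname(got[mcols(tss)$gene_id[i]]), expected)
  }
})

test_that("planted promoter peaks give high bound-gene recall/precision", {
  cfg <- simulation_config(seed = 61, chrom_sizes = c(chrS = 3e6),
                           n_genes = 300L, n_enhancers = 0L,
                           n_super_enhancers = 0L,
                           factors = list(factor_spec(
                             "fA", fraction_bound = 0.7,
                             background_rate = 10,
                             enhancer_fraction = 0, se_fold = 1)))
  ann <- simulate_annotation(cfg)
  tr <- ann$truth$factors$fA
  bound_ids <- names(tr$bound)[tr$bound]
  # peaks at the planted sites (TSS + offset, strand-aware)
  gt <- ann$truth$genes
  gi <- match(bound_ids, gt$gene_id)
  site <- gt$tss[gi] + ifelse(gt$strand[gi] == "+", 1, -1) * 200L
  pk <- peak_set(GRanges("chrS", IRanges(site - 100L, width = 201L),
                         summit = site,
                         tag_density = tr$strength[bound_ids]))
  gb <- assign_peaks_to_genes(pk, ann$genes, window = 1000)
  called <- gb$gene_id[gb$bound]
  recall <- mean(bound_ids %in% called)
  precision <- mean(called %in% bound_ids)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})
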
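# track with a given value in a window around each enhancer midpoint
signal_track <- function(enh, level, sizes, bin = 25L, half = 500L,
                         base = 1) {
  nb <- ceiling(sizes[[1]] / bin)
  v <- rep(base, nb)
  mid <- start(enh) + (width(enh) - 1L) %/% 2L
  for (i in seq_along(enh)) {
    b0 <- max(0L, (mid[i] - half) %/% bin)
    b1 <- min(nb - 1L, (mid[i] + half) %/% bin)
    v[(b0:b1) + 1L] <- base + level[i]
  }
  coverage_track(setNames(list(v), names(sizes)), chrom_sizes(sizes),
                 bin, total_reads = 1e5, label = "k27ac")
}

test_that("enhancers are ranked into quartiles by midpoint signal", {
  sizes <- c(chr1 = 2e5)
  enh <- GRanges("chr1", IRanges(seq(10000, 150000, by = 20000),
                                 width = 1000))
  names(enh) <- paste0("e", seq_along(enh))  # 8 enhancers
  tr <- signal_track(enh, level = 8:1, sizes)
  rk <- rank_enhancers(enh, tr)
  q <- mcols(rk$gr)$quartile
  expect_equal(table(q)[["I"]], 2L)
  expect_equal(mcols(rk$gr)$id[q == "I"], c("e1", "e2"))
  expect_equal(as.character(unique(q)), c("I", "II", "III", "IV"))
  # quartile partition laws
  expect_setequal(mcols(rk$gr)$id, names(enh))
  expect_equal(anyDuplicated(mcols(rk$gr)$id), 0L)
  # all-equal signals: deterministic id tie-break
  rk2 <- rank_enhancers(enh, constant_track(1, sizes), window = 1000)
  expect_equal(mcols(rk2$gr)$id, sort(names(enh)))
  expect_error(rank_enhancers(enh[0], tr), "empty")
})

test_that("quartile profiles are ordered when ranked by the query track", {
  set.seed(91)
  sizes <- c(chr1 = 5e5)
  enh <- GRanges("chr1", IRanges(seq(20000, 470000, by = 15000),
                                 width = 1000))
  names(enh) <- paste0("e", seq_along(enh))
  lv <- seq(30, 1, length.out = length(enh))
  tr <- signal_track(enh, lv, sizes)
  rk <- rank_enhancers(enh, tr)
  profs <- quartile_midpoint_profiles(rk, tr, flank = 500, bin = 25)
  centre <- vapply(profs, function(p)
    mean(p$density[abs(p$offsets) < 100]), numeric(1))
  expect_true(all(diff(centre) < 0))  # I > II > III > IV
  # single-quartile run equals a plain average profile on those midpoints
  sub <- rk$gr[mcols(rk$gr)$quartile == "II"]
  refs <- midpoint_points(sub, ids = mcols(sub)$id)
  plain <- average_profile(extract_matrix(tr, refs, 500, 25))
  expect_equal(profs[["II"]]$density, plain$density)
})

test_that("classification recovers the planted factor-positive fraction", {
  cfg <- simulation_config(seed = 101, chrom_sizes = c(chrS = 2e7),
                           n_genes = 200L, n_enhancers = 2000L,
                           n_super_enhancers = 0L,
                           factors = list(factor_spec(
                             "fA", fraction_bound = 0.3,
                             background_rate = 20,
                             enhancer_fraction = 0.25, se_fold = 1)))
  sim <- simulate_chipseq(cfg)
  sizes <- sim$annotation$chrom_sizes
  tr <- bin_coverage(extend_reads(sim$reads$fA, 200, sizes), sizes, 25,
                     label = "fA")
  cls <- classify_positive_enhancers(sim$annotation$enhancers,
                                     list(fA = tr), "fA",
                                     k = 2, seed = 101)
  planted <- mean(sim$truth$factors$fA$enhancer_positive) * 100
  expect_lte(abs(cls$fraction - planted), 3)
  # partition law
  ids <- names(sim$annotation$enhancers)
  expect_setequal(c(cls$positive, cls$negative), ids)
  expect_length(intersect(cls$positive, cls$negative), 0)
})

test_that("an all-zero factor track yields no positive enhancers", {
  sizes <- c(chr1 = 2e5)
  enh <- GRanges("chr1", IRanges(seq(10000, 150000, by = 10000),
                                 width = 1000))
  names(enh) <- paste0("e", seq_along(enh))
  zero <- constant_track(0, sizes, label = "fA")
  noise <- signal_track(enh, runif(length(enh), 1, 2), sizes)
  noise$label <- "mark"
  cls <- classify_positive_enhancers(enh, list(fA = zero, mark = noise),
                                     "fA", k = 2, seed = 5)
  expect_equal(cls$fraction, 0)
  expect_length(cls$positive, 0)
})

test_that("scaled super-enhancer profiles are flat at ratio one", {
  set.seed(111)
  sizes <- c(chr1 = 3e5)
  v <- runif(ceiling(3e5 / 25), 0.5, 5)
  tr <- value_track(v)
  tr$chrom_sizes <- chrom_sizes(sizes)
  se <- GRanges("chr1", IRanges(c(20001, 120001), c(32000, 145000)))
  names(se) <- c("se1", "se2")
  prof <- scaled_superenhancer_profile(se, tr, tr)
  expect_equal(prof$body, rep(1, 80))
  expect_equal(prof$flank5, rep(1, 80))
  expect_equal(prof$flank3, rep(1, 80))
  # constant factor c over constant input d -> c/d everywhere
  pc <- scaled_superenhancer_profile(se, constant_track(6, sizes),
                                     constant_track(2, sizes))
  expect_equal(pc$body, rep(3, 80))
  expect_equal(pc$flank5, rep(3, 80))
  # a region shorter than the bin count is refused by name
  tiny <- GRanges("chr1", IRanges(1000, 1050))
  names(tiny) <- "runt"
  expect_error(scaled_superenhancer_profile(tiny, tr, tr), "runt")
})

test_that("body profiles are invariant under proportional stretching", {
  sizes1 <- c(chr1 = 1e5)
  sizes2 <- c(chr1 = 2e5)
  W <- 10000L
  grad <- seq(1, 5, length.out = W / 25)       # one value per 25 bp bin
  v1 <- rep(1, 4000); v1[(20000 / 25) + seq_along(grad)] <- grad
  v2 <- rep(1, 8000); v2[(40000 / 25) + seq_len(2 * length(grad))] <-
    rep(grad, each = 2)
  t1 <- value_track(v1); t1$chrom_sizes <- chrom_sizes(sizes1)
  t2 <- value_track(v2); t2$chrom_sizes <- chrom_sizes(sizes2)
  se1 <- GRanges("chr1", IRanges(20001, 20000 + W))
  se2 <- GRanges("chr1", IRanges(40001, 40000 + 2 * W))
  names(se1) <- names(se2) <- "se"
  i1 <- constant_track(1, sizes1); i2 <- constant_track(1, sizes2)
  p1 <- scaled_superenhancer_profile(se1, t1, i1)
  p2 <- scaled_superenhancer_profile(se2, t2, i2)
  expect_equal(p1$body, p2$body)
})

test_that("planted uniform body enrichment is recovered", {
  cfg <- simulation_config(seed = 121, chrom_sizes = c(chrS = 6e6),
                           n_genes = 50L, n_enhancers = 0L,
                           n_super_enhancers = 20L,
                           factors = list(factor_spec(
                             "fA", fraction_bound = 0,
                             background_rate = 20,
                             enhancer_fraction = 0, se_fold = 3)))
  sim <- simulate_chipseq(cfg)
  sizes <- sim$annotation$chrom_sizes
  tr <- bin_coverage(extend_reads(sim$reads$fA, 200, sizes), sizes, 25)
  inp <- bin_coverage(extend_reads(sim$reads$input, 200, sizes), sizes, 25)
  prof <- scaled_superenhancer_profile(sim$annotation$super_enhancers,
                                       tr, inp)
  expect_equal(mean(prof$body), 3, tolerance = 0.1)
  expect_equal(mean(c(prof$flank5, prof$flank3)), 1, tolerance = 0.1)
})
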
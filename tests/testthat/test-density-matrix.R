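test_that("constant tracks give constant rows regardless of anchor", {
  tr <- constant_track(3, c(chr1 = 10000L))
  refs <- reference_points(
    GRanges("chr1", IRanges(c(500, 5001, 7013), width = 1),
            strand = c("+", "-", "*")), "tss", ids = c("a", "b", "c"))
  dm <- extract_matrix(tr, refs, flank = 500, bin = 25)
  expect_equal(dim(dm$values), c(3L, 40L))
  expect_true(all(dm$values == 3))
  expect_equal(dm$offsets, -dm$offsets[rev(seq_along(dm$offsets))])
})

test_that("minus-strand anchors flip the offset axis", {
  # spike 200 bp downstream of each anchor
  v <- numeric(400)
  v[(5000 + 200) %/% 25 + 1] <- 9   # downstream of + anchor at 0-based 5000
  # mirror bin of [+200, +225) for the - anchor is [-225, -200) in genome
  # coordinates, i.e. [1775, 1800) for an anchor at 0-based 2000
  v[(2000 - 225) %/% 25 + 1] <- 9
  tr <- value_track(v)
  refs <- reference_points(
    GRanges("chr1", IRanges(c(5001, 2001), width = 1),
            strand = c("+", "-")), "tss", ids = c("p", "m"))
  dm <- extract_matrix(tr, refs, flank = 500, bin = 25)
  expect_equal(dm$values["p", ], dm$values["m", ])
  peak_col <- which(dm$values["p", ] > 0)
  expect_gt(dm$offsets[peak_col], 0)  # positive offsets mean downstream
})

test_that("matrix values equal a naive per-anchor slicing oracle", {
  set.seed(31)
  v <- runif(4000, 0, 20)
  tr <- value_track(v)
  n <- 50
  pos <- sample(2000:98000, n)
  st <- sample(c("+", "-"), n, TRUE)
  refs <- reference_points(GRanges("chr1", IRanges(pos, width = 1),
                                   strand = st), "tss",
                           ids = paste0("x", 1:n))
  dm <- extract_matrix(tr, refs, flank = 1000, bin = 25)
  # oracle: loop anchors and offsets, index the track bin holding the
  # sampled base
  offs <- seq(-1000 + 12.5, 1000 - 12.5, by = 25)
  for (i in seq_len(n)) {
    sgn <- if (st[i] == "-") -1 else 1
    expected <- vapply(offs, function(o) {
      base0 <- floor((pos[i] - 1) + 0.5 + sgn * o)
      v[base0 %/% 25 + 1]
    }, numeric(1))
    expect_equal(unname(dm$values[i, ]), expected)
  }
})

test_that("out-of-bounds windows are zero-padded and flagged", {
  tr <- constant_track(2, c(chr1 = 1000L))
  refs <- reference_points(GRanges("chr1", IRanges(c(10, 500), width = 1)),
                           "tss", ids = c("edge", "mid"))
  dm <- extract_matrix(tr, refs, flank = 500, bin = 25)
  expect_true(dm$oob[1])
  expect_false(dm$oob[2])
  expect_true(any(dm$values["edge", ] == 0))
  expect_true(all(dm$values["mid", ] == 2))
  bad <- reference_points(GRanges("chrZ", IRanges(5, width = 1)), "tss")
  expect_error(extract_matrix(tr, bad, 100, 25), "chrZ")
})

test_that("translation by a bin multiple leaves matrices unchanged", {
  set.seed(8)
  sizes <- chrom_sizes(c(chr1 = 60000L))
  reads <- reads_from_5p(sample.int(40000, 300, TRUE) + 5000L,
                         sample(c("+", "-"), 300, TRUE))
  shift <- 4000L
  shifted <- GRanges("chr1", IRanges(start(reads) + shift,
                                     end(reads) + shift),
                     strand = strand(reads))
  anchors <- c(9001L, 20001L)
  mk <- function(rd, anch) {
    tr <- bin_coverage(extend_reads(rd, 200, sizes), sizes, 25)
    refs <- reference_points(GRanges("chr1", IRanges(anch, width = 1)),
                             "tss", ids = c("a", "b"))
    extract_matrix(tr, refs, 1000, 25)$values
  }
  expect_equal(mk(reads, anchors), mk(shifted, anchors + shift))
})

test_that("average profiles are column means", {
  X <- rbind(c(0, 2), c(2, 0))
  dm <- fake_density_matrix(X, bin = 25)
  expect_equal(unname(average_profile(dm)$density), c(1, 1))
  single <- fake_density_matrix(X[1, , drop = FALSE])
  expect_equal(unname(average_profile(single)$density), c(0, 2))
  empty <- fake_density_matrix(X[0, , drop = FALSE])
  expect_error(average_profile(empty), "empty")
})

test_that("profile peak offset finds the smoothed maximum", {
  offs <- seq(-360, 360, by = 80)  # bin centres, includes +200 exactly
  d <- rep(1, length(offs))
  d[offs == 200] <- 10
  expect_equal(profile_peak_offset(fake_profile(offs, d),
                                   smoothing_window = 1), 200)
  # symmetric tie resolves downstream (toward 0 first, then positive)
  d2 <- rep(1, length(offs))
  d2[abs(offs) == 120] <- 10
  expect_equal(profile_peak_offset(fake_profile(offs, d2),
                                   smoothing_window = 1), 120)
  d3 <- rep(1, length(offs))
  d3[offs %in% c(-120, 280)] <- 10
  expect_equal(profile_peak_offset(fake_profile(offs, d3),
                                   smoothing_window = 1), -120)
  expect_error(profile_peak_offset(fake_profile(offs, rep(2, length(offs)))),
               "constant")
})

test_that("reversing anchor strands mirrors the average profile", {
  set.seed(13)
  v <- runif(2000, 0, 10)
  tr <- value_track(v)
  pos <- sample(5000:45000, 30)
  st <- sample(c("+", "-"), 30, TRUE)
  flip <- c("+" = "-", "-" = "+")[st]
  mk <- function(strands) {
    refs <- reference_points(GRanges("chr1", IRanges(pos, width = 1),
                                     strand = strands), "tss",
                             ids = paste0("x", seq_along(pos)))
    average_profile(extract_matrix(tr, refs, 500, 25))$density
  }
  expect_equal(unname(mk(st)), rev(unname(mk(flip))))
})

test_that("a planted signal offset is recovered from simulated reads", {
  cfg <- simulation_config(seed = 19, chrom_sizes = c(chrS = 3e6),
                           n_genes = 300L, n_enhancers = 0L,
                           n_super_enhancers = 0L,
                           factors = list(factor_spec(
                             "fA", fraction_bound = 1,
                             offset_mean = 200, offset_sd = 50,
                             reads_per_site = 50,
                             background_rate = 10,
                             enhancer_fraction = 0, se_fold = 1)))
  sim <- simulate_chipseq(cfg)
  sizes <- sim$annotation$chrom_sizes
  tr <- bin_coverage(extend_reads(sim$reads$fA, 200, sizes), sizes, 25)
  refs <- reference_points(tss_points(sim$annotation$genes), "tss")
  prof <- average_profile(extract_matrix(tr, refs, 1000, 25))
  expect_lte(abs(profile_peak_offset(prof) - 200), 25)
})
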
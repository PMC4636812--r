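## Config-driven orchestration: each recipe reproduces one figure-level
## analysis and writes numeric TSVs plus a manifest recording every
## parameter value actually used.

.RECIPES <- c("tss-heatmap", "tss-profile", "cooccupancy", "annotate",
              "expression", "enhancers", "superenhancer",
              "end-to-end-synthetic")

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.profile_df <- function(p) data.frame(offset = p$offsets, mean = p$density)

.load_tracks <- function(paths, sizes) {
  tr <- lapply(paths, read_wig, chrom_sizes = sizes)
  names(tr) <- names(paths) %||%
    vapply(paths, function(p) sub("\\.wig$", "", basename(p)), character(1))
  for (nm in names(tr)) tr[[nm]]$label <- nm
  tr
}

#' Run a named analysis recipe
#'
#' `config` is a list (or path to a YAML file) with fields `recipe`,
#' `inputs` (named file paths), optional `params` overriding module
#' defaults, optional `seed`, and `outdir`.  All referenced input files
#' are checked before any computation starts.  Outputs are numeric TSVs
#' plus `manifest.json` recording the recipe, the resolved parameter
#' values (every default and tie-break rule actually used), the seed and
#' the md5 of every written file.
#'
#' Recipes: `tss-profile` (average profiles around TSSs),
#' `tss-heatmap` (multi-track k-means at TSSs), `cooccupancy` (cluster-
#' and overlap-mode co-binding of two peak sets), `annotate` (feature
#' classes and gene binding), `expression` (quintiles, grouped densities,
#' bound-vs-all), `enhancers` (ranking, quartile profiles,
#' positive-enhancer classification), `superenhancer` (scaled body +
#' flank profile), and `end-to-end-synthetic` (simulate, then recover
#' every planted parameter).
#'
#' @param config list or YAML path.
#' @param outdir output directory (overrides `config$outdir`).
#' @return Invisibly, the manifest list.
#' @export
run_recipe <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  recipe <- config$recipe %||% .stopf("config$recipe is required")
  if (!recipe %in% .RECIPES)
    .stopf("unknown recipe '%s' (known: %s)", recipe,
           paste(.RECIPES, collapse = ", "))
  outdir <- outdir %||% config$outdir %||% .stopf("outdir is required")
  inputs <- config$inputs %||% list()
  ip <- unlist(inputs)
  missing <- if (length(ip)) ip[!file.exists(ip)] else character(0)
  if (length(missing))
    .stopf("missing input file(s): %s", paste(missing, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params %||% list()
  seed <- config$seed %||% 1L
  fn <- switch(recipe,
               "tss-profile" = .recipe_tss_profile,
               "tss-heatmap" = .recipe_tss_heatmap,
               "cooccupancy" = .recipe_cooccupancy,
               "annotate" = .recipe_annotate,
               "expression" = .recipe_expression,
               "enhancers" = .recipe_enhancers,
               "superenhancer" = .recipe_superenhancer,
               "end-to-end-synthetic" = .recipe_end_to_end)
  res <- fn(inputs, params, seed, outdir)
  manifest <- list(recipe = recipe,
                   package = "chipmeta",
                   version = as.character(utils::packageVersion("chipmeta")),
                   inputs = inputs,
                   params_used = res$params,
                   seed = seed,
                   outputs = lapply(res$files, function(f)
                     list(file = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.recipe_tss_profile <- function(inputs, params, seed, outdir) {
  p <- list(flank = params$flank %||% 1000L, bin = params$bin %||% 25L)
  sizes <- read_chrom_sizes(inputs$chrom_sizes)
  genes <- read_gene_annotation(inputs$genes)
  tracks <- .load_tracks(inputs$tracks, sizes)
  refs <- reference_points(tss_points(genes), "tss")
  files <- character(0)
  for (nm in names(tracks)) {
    prof <- average_profile(extract_matrix(tracks[[nm]], refs,
                                           p$flank, p$bin))
    files <- c(files, .write_tsv(.profile_df(prof),
                                 file.path(outdir,
                                           sprintf("profile_%s.tsv", nm))))
  }
  list(params = p, files = files)
}

.recipe_tss_heatmap <- function(inputs, params, seed, outdir) {
  p <- list(flank = params$flank %||% 1000L, bin = params$bin %||% 25L,
            k = params$k %||% 3L,
            row_normalization = params$row_normalization %||% "mean")
  sizes <- read_chrom_sizes(inputs$chrom_sizes)
  genes <- read_gene_annotation(inputs$genes)
  tracks <- .load_tracks(inputs$tracks, sizes)
  refs <- reference_points(tss_points(genes), "tss")
  mats <- lapply(tracks, extract_matrix, refs = refs, flank = p$flank,
                 bin = p$bin)
  asg <- kmeans_cluster(mats, k = p$k, seed = seed,
                        row_normalization = p$row_normalization)
  files <- .write_tsv(data.frame(anchor = asg$ids, cluster = asg$labels),
                      file.path(outdir, "clusters.tsv"))
  for (nm in names(asg$profiles)) {
    prof <- asg$profiles[[nm]]
    df <- data.frame(cluster = rep(seq_len(asg$k), each = ncol(prof)),
                     offset = rep(asg$offsets[[nm]], asg$k),
                     mean = as.vector(t(prof)))
    files <- c(files, .write_tsv(df,
      file.path(outdir, sprintf("cluster_profiles_%s.tsv", nm))))
  }
  list(params = p, files = files)
}

.recipe_cooccupancy <- function(inputs, params, seed, outdir) {
  p <- list(flank = params$flank %||% 1000L, bin = params$bin %||% 25L,
            k = params$k %||% 2L, rule = params$rule %||% 2,
            central_fraction = params$central_fraction %||% 0.2)
  sizes <- read_chrom_sizes(inputs$chrom_sizes)
  ref_peaks <- read_peaks(inputs$reference_peaks, sizes)
  query_peaks <- read_peaks(inputs$query_peaks, sizes)
  tracks <- .load_tracks(inputs$tracks, sizes)
  refs <- summit_points(ref_peaks)
  mats <- lapply(tracks, extract_matrix, refs = refs, flank = p$flank,
                 bin = p$bin)
  asg <- kmeans_cluster(mats, k = p$k, seed = seed)
  qt <- params$query_track %||% names(tracks)[length(tracks)]
  cl <- cooccupancy_fraction(ref_peaks, asg, query_track = qt,
                             rule = p$rule,
                             central_fraction = p$central_fraction)
  ov <- cooccupancy_fraction(ref_peaks, query_peaks)
  df <- data.frame(mode = c(cl$mode, ov$mode),
                   n_reference = c(cl$n_reference, ov$n_reference),
                   n_cobound = c(cl$n_cobound, ov$n_cobound),
                   fraction_pct = c(cl$fraction, ov$fraction))
  list(params = c(p, list(query_track = qt)),
       files = .write_tsv(df, file.path(outdir, "cooccupancy.tsv")))
}

.recipe_annotate <- function(inputs, params, seed, outdir) {
  p <- list(promoter_upstream = params$promoter_upstream %||% 1000L,
            promoter_downstream = params$promoter_downstream %||% 100L,
            gene_window = params$gene_window %||% 1000L)
  sizes <- if (!is.null(inputs$chrom_sizes))
    read_chrom_sizes(inputs$chrom_sizes) else NULL
  peaks <- read_peaks(inputs$peaks, sizes)
  genes <- read_gene_annotation(inputs$genes)
  ann <- annotate_features(peaks, genes,
                           promoter_upstream = p$promoter_upstream,
                           promoter_downstream = p$promoter_downstream)
  gb <- assign_peaks_to_genes(peaks, genes, window = p$gene_window)
  files <- c(.write_tsv(ann, file.path(outdir, "annotations.tsv")),
             .write_tsv(feature_percentages(ann),
                        file.path(outdir, "feature_percentages.tsv")),
             .write_tsv(gb, file.path(outdir, "gene_binding.tsv")))
  list(params = p, files = files)
}

.recipe_expression <- function(inputs, params, seed, outdir) {
  p <- list(window = params$window %||% 2000L,
            direction = params$direction %||% "both",
            gene_window = params$gene_window %||% 1000L,
            drop_zeros = params$drop_zeros %||% TRUE,
            pseudocount = params$pseudocount %||% 0.1)
  sizes <- if (!is.null(inputs$chrom_sizes))
    read_chrom_sizes(inputs$chrom_sizes) else NULL
  peaks <- read_peaks(inputs$peaks, sizes)
  genes <- read_gene_annotation(inputs$genes)
  expr <- read_expression_table(inputs$expression)
  groups <- rank_expression_quintiles(expr)
  dens <- nearest_peak_density(genes, peaks, window = p$window,
                               direction = p$direction)
  dens <- dens[intersect(names(dens), expr$gene_id)]
  gs <- group_density_summary(dens, groups, drop_zeros = p$drop_zeros)
  gb <- assign_peaks_to_genes(peaks, genes, window = p$gene_window)
  bound <- intersect(gb$gene_id[gb$bound], expr$gene_id)
  cmp <- compare_bound_vs_all(expr, bound, pseudocount = p$pseudocount)
  files <- c(.write_tsv(groups$table, file.path(outdir, "quintiles.tsv")),
             .write_tsv(gs, file.path(outdir, "group_density_summary.tsv")),
             .write_tsv(cbind(cmp$summary,
                              p_value = cmp$p_value, test = cmp$test),
                        file.path(outdir, "bound_vs_all.tsv")))
  list(params = p, files = files)
}

.recipe_enhancers <- function(inputs, params, seed, outdir) {
  p <- list(rank_window = params$rank_window %||% 1000L,
            flank = params$flank %||% 1000L, bin = params$bin %||% 25L,
            k = params$k %||% 2L)
  sizes <- read_chrom_sizes(inputs$chrom_sizes)
  enh <- read_bed(inputs$enhancers, sizes)
  tracks <- .load_tracks(inputs$tracks, sizes)
  rank_track <- tracks[[params$rank_track %||% names(tracks)[1]]]
  factor_name <- params$factor %||% names(tracks)[1]
  ranking <- rank_enhancers(enh, rank_track, window = p$rank_window)
  rk <- mcols(ranking$gr)
  files <- .write_tsv(
    data.frame(id = rk$id, chrom = as.character(seqnames(ranking$gr)),
               midpoint = rk$midpoint, signal = rk$signal,
               quartile = as.character(rk$quartile)),
    file.path(outdir, "enhancer_rank.tsv"))
  for (nm in names(tracks)) {
    profs <- quartile_midpoint_profiles(ranking, tracks[[nm]],
                                        flank = p$flank, bin = p$bin)
    df <- do.call(rbind, lapply(names(profs), function(q)
      cbind(quartile = q, .profile_df(profs[[q]]))))
    files <- c(files, .write_tsv(df,
      file.path(outdir, sprintf("quartile_profile_%s.tsv", nm))))
  }
  cls <- classify_positive_enhancers(enh, tracks, factor_name, k = p$k,
                                     seed = seed, flank = p$flank,
                                     bin = p$bin)
  files <- c(files, .write_tsv(
    data.frame(id = .region_ids(enh, "enh_"),
               positive = .region_ids(enh, "enh_") %in% cls$positive),
    file.path(outdir, "enhancer_classification.tsv")))
  list(params = c(p, list(rank_track = rank_track$label,
                          factor = factor_name,
                          positive_fraction_pct = cls$fraction)),
       files = files)
}

.recipe_superenhancer <- function(inputs, params, seed, outdir) {
  p <- list(body_bins = params$body_bins %||% 80L,
            flank = params$flank %||% 4000L,
            flank_bin = params$flank_bin %||% 50L,
            mode = params$mode %||% "average-then-ratio")
  sizes <- read_chrom_sizes(inputs$chrom_sizes)
  se <- read_bed(inputs$regions, sizes)
  tr <- .load_tracks(list(factor = inputs$track, input = inputs$input),
                     sizes)
  prof <- scaled_superenhancer_profile(se, tr$factor, tr$input,
                                       body_bins = p$body_bins,
                                       flank = p$flank,
                                       flank_bin = p$flank_bin,
                                       mode = p$mode)
  nf <- length(prof$flank5)
  df <- data.frame(
    section = c(rep("flank5", nf), rep("body", p$body_bins),
                rep("flank3", nf)),
    bin = c(seq_len(nf), seq_len(p$body_bins), seq_len(nf)),
    enrichment = c(prof$flank5, prof$body, prof$flank3))
  list(params = p,
       files = .write_tsv(df, file.path(outdir, "se_profile.tsv")))
}

.recipe_end_to_end <- function(inputs, params, seed, outdir) {
  p <- list(flank = params$flank %||% 1000L, bin = params$bin %||% 25L,
            fragment_length = params$fragment_length %||% 200L)
  cfg_args <- params[intersect(names(params),
                               names(formals(simulation_config)))]
  sim <- simulate_chipseq(do.call(simulation_config,
                                  c(list(seed = seed), cfg_args)))
  fixdir <- file.path(outdir, "fixtures")
  write_simulation(sim, fixdir)
  res <- recover_planted_parameters(sim, flank = p$flank, bin = p$bin,
                                    fragment_length = p$fragment_length)
  df <- data.frame(quantity = names(res), value = unlist(res))
  list(params = p,
       files = .write_tsv(df, file.path(outdir, "recovery.tsv")))
}

#' Recover the planted parameters from a simulation
#'
#' Runs the full pipeline on a [simulate_chipseq()] result: builds
#' extended-read coverage tracks, recovers the TSS offset from the
#' average profile at bound TSSs, the enhancer-positive fraction by
#' k-means classification, the super-enhancer body enrichment from the
#' scaled profile, and the density-expression rank correlation.
#'
#' @param sim a [simulate_chipseq()] result.
#' @param flank,bin density-matrix parameters.
#' @param fragment_length read extension length (default 200).
#' @return Named list of recovered quantities.
#' @export
recover_planted_parameters <- function(sim, flank = 1000L, bin = 25L,
                                       fragment_length = 200L) {
  ann <- sim$annotation
  sizes <- ann$chrom_sizes
  fn <- names(sim$config$factors)[1]
  track <- bin_coverage(extend_reads(sim$reads[[fn]], fragment_length,
                                     sizes), sizes, label = fn)
  input <- bin_coverage(extend_reads(sim$reads$input, fragment_length,
                                     sizes), sizes, label = "input")
  tr <- sim$truth$factors[[fn]]
  bound_ids <- names(tr$bound)[tr$bound]
  tss <- tss_points(ann$genes)
  refs <- reference_points(tss[mcols(tss)$gene_id %in% bound_ids], "tss")
  prof <- average_profile(extract_matrix(track, refs, flank, bin))
  offset <- profile_peak_offset(prof)
  enh_frac <- if (length(ann$enhancers) >= 8) {
    classify_positive_enhancers(ann$enhancers,
                                setNames(list(track), fn), fn,
                                k = 2L, seed = sim$config$seed,
                                flank = flank, bin = bin)$fraction
  } else NA_real_
  se_prof <- if (length(ann$super_enhancers))
    scaled_superenhancer_profile(ann$super_enhancers, track, input)
  else NULL
  dens <- setNames(tr$strength, names(tr$strength))
  expr <- sim$expression
  rho <- cor(dens[expr$gene_id], expr$fpkm, method = "spearman")
  list(tss_peak_offset_bp = offset,
       enhancer_positive_pct = enh_frac,
       se_body_enrichment = if (is.null(se_prof)) NA_real_
                            else mean(se_prof$body),
       se_flank_enrichment = if (is.null(se_prof)) NA_real_
                             else mean(c(se_prof$flank5, se_prof$flank3)),
       expression_density_spearman = rho)
}
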
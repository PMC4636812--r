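# chipmeta

Binned ChIP-seq coverage, metagene profiles and co-occupancy clustering.

`chipmeta` re-implements, as a tested and reusable R package, the
density-based analysis pipeline used to characterise genome-wide occupancy
of chromatin factors (histone acetyltransferase complexes, RNA polymerase
II, histone marks, pioneer factors) in chromatin immunoprecipitation
sequencing (ChIP-seq) experiments.  It is aimed at epigenomics analysts who
have aligned reads (BED), peak calls, a gene annotation and an expression
table, and want the classic occupancy summaries:

* **coverage tracks** — reads extended to the sonicated fragment length
  (default 200 bp) and accumulated in fixed-width bins (default 25 bp),
  with per-million, input-ratio and scalar normalisation;
* **density matrices and average profiles** — signal around stranded
  reference points (TSSs, peak summits, enhancer midpoints), with the
  offset of the profile maximum (e.g. "binding peaks ~200 bp downstream
  of the TSS") estimated from a smoothed average profile;
* **k-means co-occupancy clustering** — Lloyd's algorithm with k-means++
  seeding on row-normalised, column-concatenated multi-track matrices;
  deterministic under a seed; rule-based positive-cluster calling and
  co-bound-fraction estimates (cluster-membership and interval-overlap
  modes);
* **peak annotation** — feature classes (promoter-TSS, UTRs, exon,
  intron, TTS, intergenic) by summit position with HOMER-style precedence
  and windows; peak-to-gene assignment within ±1 kb of TSSs; nearest-peak
  tag density per TSS;
* **expression integration** — expression quintiles of equal size,
  notched-boxplot summaries of per-gene densities, bound-versus-all
  comparison with a Wilcoxon rank-sum test;
* **enhancer analysis** — enhancer quartiles (I–IV) ranked by an
  acetylation track around midpoints, per-quartile profiles,
  factor-positive enhancer classification, and length-scaled
  super-enhancer meta-profiles (80 body bins, 4-kb flanks in 50-bp bins,
  normalised to input);
* **a synthetic-data generator** — a small genome with genes, enhancers
  and super-enhancers, factor reads planted at configurable TSS offsets,
  co-binding fractions, enhancer positivity and super-enhancer
  enrichment, a matched-depth input, and expression rank-coupled to
  promoter binding strength — so the whole pipeline is validated by
  parameter recovery without any sequencing downloads.

The model underneath is deliberately simple and transparent.  A track is
a vector `c_b` of fragment counts per genomic bin `b` (a fragment counts
once in every bin it overlaps).  A density matrix `D[i, j]` samples the
track bin containing offset `o_j` from anchor `i` (minus-strand anchors
reverse the axis so positive offsets mean downstream).  The average
profile is the column mean of `D`; clustering runs on rows scaled by
`1 / (rowMean + 1)`.  A super-enhancer profile scales each region into 80
equal body bins and reports `mean_region(factor) / mean_region(input)`
per bin.

## Worked example

Simulate a study, build a track, and recover the planted structure:

```r
library(chipmeta)

sim   <- simulate_chipseq(simulation_config(seed = 1))
sizes <- sim$annotation$chrom_sizes
track <- bin_coverage(extend_reads(sim$reads$factorA, 200, sizes),
                      sizes, 25, label = "factorA")
input <- bin_coverage(extend_reads(sim$reads$input, 200, sizes),
                      sizes, 25, label = "input")

refs <- reference_points(tss_points(sim$annotation$genes), "tss")
prof <- average_profile(extract_matrix(track, refs, flank = 1000, bin = 25))
profile_peak_offset(prof)
#> [1] 187.5

cls <- classify_positive_enhancers(sim$annotation$enhancers,
                                   list(factorA = track), "factorA",
                                   k = 2, seed = 1)
cls$fraction
#> [1] 25

se <- scaled_superenhancer_profile(sim$annotation$super_enhancers,
                                   track, input)
se
#> scaled_meta_profile: 20 regions, 80 body bins + 2 x 80 flank bins (average-then-ratio)
#>   mean enrichment: flank5 1.044 | body 3.042 | flank3 1.023
```

The generator planted factor binding 200 bp downstream of each bound TSS
(recovered at 187.5 bp, the centre of the offset bin next to +200), made
25% of enhancers factor-positive (recovered exactly), and enriched
super-enhancer bodies 3-fold over background (recovered at 3.04 with flat
~1.0 flanks).

File-based workflows go through `run_recipe()`, which reads wig/BED/GTF
inputs, writes numeric TSVs and records every resolved parameter in a
`manifest.json`:

```r
run_recipe(list(recipe = "tss-profile",
                inputs = list(tracks = c(factorA = "factorA.wig"),
                              genes = "genes.gtf",
                              chrom_sizes = "chrom_sizes.tsv"),
                outdir = "out"))
```

## Layout

* `R/` — implementation (IO, tracks, matrices, clustering, annotation,
  expression, enhancers, simulator, recipes)
* `tests/testthat/` — unit, property and acceptance tests (fixtures are
  generated in code)
* `vignettes/chipmeta-methods.Rmd` — the methods vignette: model,
  parameters, defaults and their rationale, limitations
* `scripts/acceptance.R` — see above
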
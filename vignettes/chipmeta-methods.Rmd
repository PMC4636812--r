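---
title: "chipmeta: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chipmeta: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the computations it
implements: the models and their assumptions, every tunable parameter with
its unit, default and rationale, the numerical choices at the edges, what
the synthetic-data generator does and does not emulate, and the known
limitations.

## Coverage tracks

ChIP-seq reads mark only the ends of immunoprecipitated fragments, so each
read is first extended to the expected fragment length from its
strand-aware 5' end: a plus-strand read with 5' position $p$ becomes the
interval $[p, p+L)$, a minus-strand read $[p-L+1, p+1)$ (0-based half-open
terms), clipped at chromosome bounds.  The default $L = 200$ bp matches
standard sonication protocols.  Extended fragments are accumulated into
fixed-width bins (default 25 bp, a common browser-track resolution):
`bin_coverage()` counts a fragment once in every bin it overlaps by at
least one bp.  This *overlap-count* semantics matches how binned wiggle
tracks are usually built and displayed; the alternative of counting each
read once, in the bin holding its 5' end, is available as
`mode = "fiveprime"` for users who need strict count conservation
(`sum(bins) == n_reads`).

Normalisations (`normalize_track()`):

* **per-million** — `value * 1e6 / total_reads`, using the uniquely
  mapped read count the track was built from; makes tracks of different
  depth comparable.
* **input-ratio** — both ChIP and input are brought to per-million scale,
  then `(chip + c) / (input + c)` per bin.  The pseudocount `c` (default
  1 per-million unit) keeps bins with zero input coverage finite; any
  strictly positive value works, and 1 is small relative to typical
  promoter signals while preventing ratio blow-ups in empty bins.
* **scalar** — plain division, for putting one very deep track on a
  shared colour or axis scale (e.g. dividing a deep acetylation track by
  five before overlaying it with sparser factor tracks).

Internally all intervals are GRanges (1-based, closed), the Bioconductor
convention; BED input/output (0-based, half-open) is converted at the
readers and writers, and fixedStep wiggle output is 1-based as the format
requires.  Tracks record their normalisation state so that operations can
refuse meaningless combinations (e.g. per-million scaling of a ratio
track).

## Density matrices and profiles

`extract_matrix()` samples a track around stranded anchors (TSSs, peak
summits, enhancer midpoints).  Columns form a grid of `bin`-bp offset
windows covering `[-flank, +flank)` and are labelled by their bin centre,
so the grid is symmetric about zero.  Three conventions matter:

* **orientation** — minus-strand anchors reverse the offset axis, so
  positive offsets always mean downstream; enhancer midpoints are treated
  as unstranded (no flip), since enhancers have no intrinsic direction.
* **sampling** — each cell takes the value of the track bin containing
  the offset position, with no interpolation.  With `bin` equal to the
  track bin width and anchors near bin boundaries this is an exact slice;
  interpolation would blur the sub-bin offsets the profile-peak estimator
  is meant to localise.
* **edges** — windows running past a chromosome end are zero-padded and
  flagged (`oob`), keeping one row per anchor so matrices from different
  tracks stay row-aligned for clustering.  Dropping such anchors instead
  would silently desynchronise multi-track analyses.

`average_profile()` is the column mean.  `profile_peak_offset()` smooths
the profile with a centred moving average (default 3 bins — enough to
suppress single-bin noise without displacing a peak that spans several
bins; the window shrinks at the edges) and returns the bin-centre offset
of the maximum.  Ties resolve toward offset zero, and a tie between equal
and opposite offsets resolves downstream (positive); both rules are
arbitrary but deterministic, which is what reproducibility needs.  A
constant profile has no peak and raises an error rather than returning an
arbitrary offset.

## k-means co-occupancy clustering

`kmeans_cluster()` concatenates per-track matrices over shared anchors
column-wise and partitions rows with Lloyd's algorithm.  Choices:

* **row normalisation** — each row is divided by its mean plus a
  pseudocount (default 1), so clustering groups anchors by profile
  *shape* rather than amplitude; without it the deepest track dominates
  the partition.  Cluster mean profiles reported downstream are computed
  from the unnormalised values so they stay on the read-density scale.
* **initialisation** — k-means++ at a fixed seed; Lloyd's updates run to
  assignment convergence (or centroid shift below `tol = 1e-8`, max 100
  iterations).  Identical inputs and seed give bitwise-identical labels.
* **empty clusters** — an emptied centroid is re-seeded at the point
  farthest from its assigned centroid, the standard Lloyd fix, applied
  deterministically.
* **k** — supplied per analysis.  Promoter-state analyses typically use
  3–4 clusters (active, bivalent, enhancer-like, unbound); co-binding
  questions use k = 2.  The package hard-codes no k.

`call_positive_clusters()` turns a clustering into a binary call per
track: a cluster is positive when its mean central density (central
window: offsets within 20% of the flank) exceeds `rule` times (default
2-fold) the background plus a pseudocount (0.1).  The background is the
*lowest* central density among the other clusters.  Using the weakest
cluster as reference keeps calls correct when several clusters are
positive for the same track (e.g. a factor-only cluster and a
factor-plus-cofactor cluster); with k = 2 it coincides with the
across-cluster median.  `cooccupancy_fraction()` then reports the share
of anchors in positive clusters (cluster mode) or, independently, the
share of reference peaks overlapping query peaks by at least 1 bp
(overlap mode).  Cluster mode mirrors how co-occupancy is usually read
off heatmaps; overlap mode is the sharper-defined quantity, and both are
reported by the `cooccupancy` recipe.

## Peak annotation

Peaks enter as BED with the tag density in the score column; since MACS14
BED output records no summit, the summit defaults to the interval
midpoint.  `annotate_features()` classifies each peak by its *summit*
into exactly one category with precedence

promoter-TSS > 5'UTR > 3'UTR > exon > intron > TTS > intergenic,

the HOMER ordering, with HOMER's default promoter window (1 kb upstream
to 100 bp downstream of the TSS, strand-aware) and a mirrored TTS window
(100 bp upstream to 1 kb downstream of the 3' end).  Whole-peak overlap
would multiply-count broad peaks; the summit is the best single-point
proxy for the binding position.

`assign_peaks_to_genes()` calls a gene bound when a summit lies within
±`window` bp (default 1000, boundary inclusive) of its TSS; one peak may
bind two genes at divergent promoters, and the best peak per gene is the
qualifying one with the highest tag density.  `nearest_peak_density()`
returns the tag density of the *nearest* (not strongest) qualifying
summit within `window` (default 2000) of each TSS, 0 when none.  The
window direction is configurable (`"both"`, the default, or
`"downstream"`): descriptions of this analysis as "+2 kb" are ambiguous
between the two readings, so the choice is explicit and recorded in
recipe manifests.

## Expression integration

`rank_expression_quintiles()` sorts genes by FPKM (highest first, ties
broken by gene id for determinism) and splits them into five contiguous
groups whose sizes differ by at most one.  `group_density_summary()`
summarises per-gene densities per group as a notched boxplot: zero
densities are dropped first by default (a gene without a peak carries no
density information, only a bound/unbound flag), and the notch half-width
is the conventional `1.58 * IQR / sqrt(n)`.  `compare_bound_vs_all()`
compares `log2(FPKM + 0.1)` of bound genes against all genes with a
two-sided Wilcoxon rank-sum test; the 0.1 pseudocount keeps unexpressed
genes finite on the log scale while staying below meaningful expression.
The test and the notch formula are this package's choices — any
reasonable alternatives (t-test on logs, bootstrap notches) would serve;
the rank-sum test is robust to the heavy right tail of FPKM.  The
quintile ranking includes all genes in the expression table, expressed or
not; restricting to expressed genes is a caller-side filter.

## Enhancers and super-enhancers

`rank_enhancers()` scores each enhancer by the mean track signal within
±1 kb of its midpoint (window configurable; ±1 kb covers the nucleosomes
flanking a typical enhancer core) and assigns quartiles I (highest) to IV
by rank.  `classify_positive_enhancers()` clusters midpoint matrices of
the factor plus any co-factor tracks and takes the factor-positive
clusters as the positive enhancer set.

`scaled_superenhancer_profile()` handles regions of very different
lengths (5–30 kb and beyond) by scaling each body into 80 equal bins
(remainder bp distributed to the leftmost bins) and attaching fixed 4-kb
flanks in 50-bp bins.  Per meta-bin, the across-region mean factor
density is divided by the across-region mean input density
(*average-then-ratio*, the default); the alternative
*ratio-then-average* (mean of per-region ratios) weights every region
equally but is unstable when a single region has near-zero input in a
bin, so it is offered but not the default.  With identical factor and
input tracks every bin is exactly 1 by construction — a useful
self-check.  No pseudocount is added by default; callers with sparse
input coverage can supply one.

## The synthetic-data generator

`simulate_chipseq()` builds, deterministically under a seed, a small
genome whose defaults describe the study conditions the package is
validated under: one 5-Mb chromosome, 500 genes at near-regular TSS
spacing (gene lengths capped at 30% of the spacing so genes never
overlap), 400 enhancers placed in intergenic space, and 20
super-enhancers of 5–30 kb in a reserved gene-free segment.  One factor
binds 60% of promoters; bound-site read 5' positions are drawn
Normal(TSS + 200 bp strand-aware, sd 50 bp) with random strand, so the
extended-fragment coverage peaks at the planted offset.  Per-site
strengths are Gamma(shape 5) around 50 expected reads per site; the
uniform background of 20 reads/kb yields, after 200-bp extension, about
4x base coverage — roughly 10-fold enrichment at a default-strength site.
The input is background-only at the factor's background depth (matched
sequencing depth).  Co-binding between factors is planted by drawing the
second factor's bound set to contain the requested fraction of the first
factor's sites (pairwise constraints among three or more non-reference
factors are not jointly solved).  Expression is log-normal with rank
coupling to promoter binding strength planted through a Gaussian copula;
the realised Spearman correlation is close to, slightly below, the
nominal coupling (the copula maps Pearson rho to Spearman
(6/pi)*asin(rho/2), and ties among unbound genes attenuate it further).

What the generator does **not** emulate: mappability and duplicate-read
artefacts, GC bias, fragment-length variability, chromatin-state
heterogeneity between cells, broad-domain marks, peak-calling noise (the
planted sites play the role of called peaks), and multi-chromosome
genome structure beyond proportional allocation.  Passing the recovery
tests therefore demonstrates that the *computations* are correct on data
with the assumed statistical structure — not that the pipeline is robust
to every artefact of real sequencing data.

## Validation by parameter recovery

The test suite validates each stage against independent oracles
(per-base coverage counting, naive window slicing, exhaustive
nearest-neighbour scans, `stats::kmeans` on well-separated data,
round-trips through rtracklayer's parsers) and the pipeline end-to-end
by parameter recovery at these problem sizes: 2,000 planted sites for
offset recovery (within one 25-bp bin) and co-binding (60% planted,
recovered within ±5 pp), 2,000 enhancers for positivity (25% planted,
within ±3 pp), 20 super-enhancers for the 3x body enrichment, and 5,000
genes for the expression-coupling quintile analysis — the size at which
strictly monotone group medians are a reliable consequence of a 0.5 rank
coupling (at a quarter of that size the middle-quintile median gap is
comparable to its sampling noise).  `scripts/acceptance.R` re-runs these
recoveries from scratch at any seed.

## Limitations

* Tag densities are consumed from the peak caller, never recomputed; the
  package takes no position on whether they are pileup heights or tag
  counts.
* The seqMINER-style heatmap computation is re-implemented from its
  described behaviour (normalised densities for clustering, raw
  densities for display); exact numerical agreement with any particular
  seqMINER version is not claimed.
* Heatmap/figure rendering is a convenience (`plot()` methods), not a
  tested surface; the numeric TSVs written by `run_recipe()` are the
  contract.
* Published genome-scale counts (peak numbers, bound-gene totals) depend
  on ~50-million-read datasets and specific aligner/peak-caller
  versions; they are inputs to, not outputs of, this package.
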
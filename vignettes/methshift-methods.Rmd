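---
title: "Detecting iron-dependent epigenetic demethylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting iron-dependent epigenetic demethylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological question

During adipocyte differentiation (the 3T3-L1 model), removal of repressive
epigenetic marks — promoter and enhancer CpG methylation, and the histone
marks H3K9me2/me3 and H3K27me3 — accompanies the activation of adipogenic
genes. The demethylases acting on both DNA-adjacent histone marks (JMJD
family) and, indirectly, on 5mC are iron-dependent dioxygenases, so iron
chelation (deferoxamine, DFO) during the first days of differentiation is
predicted to leave these marks in place. `methshift` implements the
computational procedures needed to detect that iron dependence from
sequencing data: a per-CpG demethylation screen over promoter and enhancer
windows with a cross-condition contrast, temporal clustering of ChIP-seq
signal around transcription start sites, and aggregation profiles of
methylation and histone-signal change around differentially methylated
regions (DMRs), plus the small closed-form quantifications used for the
accompanying biochemical assays.

```{r setup}
library(methshift)
```

## The demethylation screen

Inputs are per-CpG whole-genome bisulfite sequencing tracks in bedGraph
form, one per condition and timepoint, carrying the methylation level in
percent and the methylated/unmethylated read counts (`counts6` dialect).
The screen proceeds in four steps:

1. **Coverage filter.** CpGs with read depth below 5 or above 1000 are
   omitted — the lower bound removes unreliable level estimates, the upper
   bound collapsed repeats and mapping artifacts. The bounds are closed:
   depths of exactly 5 and 1000 are kept. A CpG must pass in **both**
   timepoints to contribute (joint filtering), so every reported change is
   measured on adequately covered data at both ends.
2. **Delta.** For each surviving CpG, `delta = meth(later) - meth(base)`
   in percentage points.
3. **Window qualification.** Promoter windows are the 1 kb immediately
   upstream of each TSS, strand-aware and excluding the TSS base itself
   (on the minus strand the window starts one base 3' of the TSS in genome
   coordinates, mirroring the plus-strand definition; the window
   definitions are deliberately symmetric because inclusivity at the TSS
   base is a convention, not data). A CpG qualifies when `delta < -50`
   (strictly more than a 50-point drop; a drop of exactly 50 never
   qualifies, because the change is computed by plain subtraction of
   levels). We read "a 50% reduction" in percentage points for that
   reason; the relative-to-baseline reading is available via
   `screen_windows(..., relative = TRUE)`.
4. **Hit calling and contrast.** A gene is a hit when it has **three or
   more** qualifying CpGs, pooled across all of its TSS windows (a
   per-window mode exists). Running the screen under both conditions and
   partitioning the hit sets (`condition_contrast()`) yields the
   iron-dependent set: regions demethylated without DFO but not with it.

Enhancer screening reuses the same machinery over different windows:
peak sets from all timepoints are merged (bedtools-merge semantics,
book-ended intervals merged by default, configurable), each merged peak is
reduced to the ±500 bp around its center (floor midpoint for even widths,
matching common toolkits), and peaks already present before induction are
subtracted with `bedtools intersect -v` semantics (any 1-bp overlap
removes; book-ended contact does not) to give differentiation-specific
enhancers.

All coordinates are 0-based half-open throughout; chromosome names are
compared as exact strings; sorting is lexicographic in the chromosome and
numeric in the position, which is deterministic across platforms and
locales. Per-CpG records are treated independently — if an input collapses
the two strands of a CpG dyad into one record, that is transparent to the
screen, and tracks that do not are screened per strand.

## Temporal ChIP-seq clustering

ChIP-seq signal around TSSs (±5 kb; multiple TSS windows of one gene are
merged, and the total merged length recorded) is normalized in sequence:
counts per million within each sample, mean across replicates, division by
region length in kilobases, a coefficient-of-variation filter (rows with
`sd/mean < 0.2` on the linear scale carry no temporal information and are
dropped), `log2(x + 1)`, and per-row z-scores. Zero-variance rows are
dropped at transform time with a warning; the pseudocount of 1 keeps empty
regions finite and is negligible at typical CPM magnitudes.

Clustering is fuzzy c-means, written out in full in `fuzzy_cmeans()`:
alternating updates of centroids `v_k = sum u_ik^m x_i / sum u_ik^m` and
memberships `u_ik = 1 / sum_j (d_ik/d_ij)^(2/(m-1))` with Euclidean
distance, fuzzifier `m = 2` by default, random-membership initialization
from a seeded RNG, and convergence when the largest membership change
falls below `1e-6` (cap 300 iterations). A point coinciding with a
centroid takes membership 1 there (split equally over exact ties). The
objective `J = sum u^m d^2` is recorded every iteration and is
non-increasing by construction; the test suite asserts it on every run.
Because alternating optimization only finds local minima, `nstart` runs
the fit from several seeded initializations and keeps the lowest-objective
solution; the pipeline uses `nstart = 5`, which in our synthetic
experiments reliably avoids the occasional split-prototype optimum a
single start can land in. Hard labels are the row-wise argmax with ties
broken toward the lowest cluster index.

The number of clusters is a judgment call, not an output: `dmin_curve()`
fits a range of candidate counts and reports the mean minimum pairwise
centroid distance (Dmin). Dmin decays sharply once additional clusters
start splitting genuine groups; the user reads the curve and passes an
explicit cluster count (the emulated study design uses 7). The fuzzifier
is likewise an explicit knob: data-driven fuzzifier estimation heuristics
are out of scope, and `m = 2` is the conventional default.

## DMR-anchored aggregation

DMR detection itself (a statistical segmentation problem with dedicated
tools, e.g. metilene) is consumed as a BED input, not recomputed. Around
each DMR center (floor midpoint, consistent with the enhancer
construction) the package aggregates two kinds of change:

* **ChIP signal change**: binned coverage tracks (10-bp bins) are CPM
  normalized per track, subtracted (`later - Day 0`), and sampled in
  offset bins across ±3 kb of each anchor center; each offset bin reads
  the track bin containing its center, and the curve is the per-offset
  mean across anchors. Anchors whose window runs off a chromosome are
  skipped and counted; optionally, anchors sampling all-zero signal are
  skipped too (per-anchor, whole-window zero). Empty ChIP bins mean zero
  signal, so they enter the average as zeros.
* **Methylation change**: per-CpG deltas are pooled into offset bins
  across all anchors and averaged per bin. CpGs are sparse, so an offset
  bin containing no CpG is **missing** (`NA`), never zero — the two
  semantics differ deliberately and are both asserted in tests.

For ChIP the curve averages per offset across anchors; for methylation the
CpGs are pooled globally across anchors before averaging. Pooling is the
stable choice for sparse CpGs (a per-anchor mean of one or two CpGs is
noise); for dense binned signal the per-anchor average weights every
anchor equally. Duplicate anchors change both computations' weights
identically, so duplicating the anchor list leaves the ChIP curve
unchanged.

## Assay quantifications

The closed forms are implemented as pure functions with explicit
domain checks: HTRF `DF% = ((665/620)_+ / (665/620)_- - 1) * 100`;
lysosomal flux as inhibited-minus-vehicle level (negative values are
flagged as assay noise, never clipped); treatment deltas as post-minus-
pre; ChIP `%input = 100 * IP / (input / fraction)` with the input
dilution fraction a **required** argument (no hidden default, since it is
an experimental constant that varies between protocols);
bisulfite-clone summaries (per-CpG and overall percent methylated, which
coincide in mean for complete matrices — clone matrices are modelled as
complete, alignment QC being upstream); and Pearson colocalization over a
pixel mask, which errors on constant channels rather than returning NaN.

## The synthetic study and what it does (not) show

`simulate_dataset()` generates every input the pipeline consumes, with
planted ground truth, under one seed. Its defaults *are* the emulated
study conditions and are deliberately not tuned per run:

* **Genome and annotation**: two 1-Mb chromosomes, 200 genes on evenly
  spaced slots with ±2 kb TSS jitter, both strands, 20% of genes with a
  second TSS 1.5 kb downstream (so TSS ±5 kb windows overlap and exercise
  the merge path). Slot spacing guarantees promoter windows of different
  genes never overlap, so planted effects cannot leak between genes.
* **Methylomes**: CpGs genome-wide at ~150-bp mean spacing plus
  CpG-island-like promoter density (60-bp spacing); baseline methylation
  per site from Beta(8, 2) (mean 80%, the high-methylation regime the
  screen starts from); per-track Gaussian level noise of 3 points; read
  depth negative-binomial with mean 30 (merged-replicate WGBS scale) and
  deliberate sub-5 and over-1000 depth outliers to exercise the filter;
  methylated-read counts binomially sampled given level and depth, which
  adds the granularity real levels have. Twenty planted genes lose 60
  points across their upstream windows at Day 8 in the DFO(−) condition
  only.
* **Peaks**: 60 baseline peaks (present from Day 0) and 40 induced-only
  peaks (Day 2 onward) on disjoint slots ≥1 kb apart, so merging never
  fuses distinct peaks and the manifest is recoverable exactly.
* **ChIP counts**: every gene follows one of 7 temporal prototypes across
  (Day 0, Day 2 DFO−, Day 2 DFO+). The prototypes are 7 equally spaced
  points on the circle that row-z-scored 3-vectors live on, i.e. 7
  maximally distinct temporal shapes; log2 amplitude 2 (4-fold swings)
  with log2 noise 0.4 (≈0.2 on the z-scale), duplicate samples, counts
  scaled by region length.
* **Binned tracks and DMRs**: 40 DMR anchors; the Day 2 DFO(−) track
  loses signal around each anchor center with exponential decay (depth 4
  on a baseline of mean 5, length scale 400 bp — concentrated loss
  decaying into the flanks), on a shared per-bin baseline so the
  Day-0-subtracted profile isolates the planted dip.

The generator shares the strand-aware window code with the screen
(one definition of "upstream"), and coverage is sampled independently per
CpG — adequate for testing the depth filter, but it does not reproduce
the positional autocorrelation, GC/repeat structure, bisulfite conversion
error, batch effects, or the unbalanced DMR sizes of real data. Passing
tests therefore demonstrate that the *procedures* are implemented
correctly and recover planted truth under realistic noise; they do not
certify performance on real methylomes, where coverage and effect sizes
are confounded in ways the simulation does not model.

Problem sizes were chosen so the full synthetic study (two 1-Mb
chromosomes, ~17k CpGs per track, 200 genes, 200k track bins) runs the
complete pipeline in a few seconds, which keeps property-based testing
over many random instances practical.

## End-to-end pipeline

`run_pipeline(data_dir, out_dir, pipeline_config(...))` chains the
stages — promoter screens and contrast, enhancer construction and screen,
ChIP clustering, DMR aggregation — writing per-stage TSVs, a
`summary.json` with the funnel counts (CpGs read, passing coverage,
qualifying, hits per condition, contrast sizes, cluster sizes), a
`pipeline.log`, and the resolved configuration (`config_used.yaml`) for
provenance. Configuration defaults equal the analysis parameters above;
a YAML file of overrides can be supplied, and identical inputs plus
configuration yield byte-identical outputs. Stages never mutate their
inputs.

## Known limitations

* The screen reports hit regions and qualifying CpGs; it performs no
  statistical test of methylation differences (that is the role of
  dedicated DMR callers upstream).
* Read-level processing (alignment, methylation calling, peak calling,
  read counting into regions) is out of scope; the package starts from
  bedGraph/BED/count-table artifacts.
* Enhancer windows are unstranded by design; promoter windows are
  strand-aware.
* `level4` (count-free) bedGraphs are readable but rejected by
  coverage-dependent screens with a clear error, since depth is integral
  to the screen's definition.
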
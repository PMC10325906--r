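# methshift

Screens and quantification for **iron-dependent epigenetic demethylation**
during adipocyte differentiation.

Adipogenic gene activation in 3T3-L1 cells is accompanied by loss of
repressive epigenetic marks — promoter/enhancer CpG methylation and the
histone marks H3K9me2/me3 and H3K27me3. The demethylases responsible are
iron-dependent dioxygenases, so iron chelation (deferoxamine, DFO) during
early differentiation should leave these marks in place. `methshift`
provides the computational pipeline to detect that iron dependence from
whole-genome bisulfite sequencing (WGBS) and ChIP-seq artifacts, for
epigenomics analysts working with per-CpG bedGraph tracks, BED peak/DMR
sets and region count tables.

## What it computes

* **Promoter/enhancer demethylation screen** — for CpGs with read depth
  in [5, 1000] at *both* timepoints, the change
  Δ = meth(Day 8) − meth(Day 0) in percentage points; a region
  (1 kb-upstream promoter window per TSS, or ±500 bp of a merged peak
  center) is a hit when it holds ≥ 3 CpGs with Δ < −50. Contrasting the
  DFO(−) and DFO(+) hit sets yields the iron-dependent demethylated
  regions (the Venn partition).
* **Interval algebra** — strand-aware upstream windows, bedtools-style
  merge and `intersect -v` subtraction (differentiation-specific peaks),
  peak-center windows, merged TSS ±5 kb regions with recorded lengths.
* **Temporal ChIP clustering** — CPM → replicate mean → per-kb length
  normalization → CV ≥ 0.2 filter → log2 → row z-scores, then fuzzy
  c-means (written from scratch: memberships
  u<sub>ik</sub> = 1/Σ<sub>j</sub>(d<sub>ik</sub>/d<sub>ij</sub>)<sup>2/(m−1)</sup>,
  centroids v<sub>k</sub> = Σu<sub>ik</sub><sup>m</sup>x<sub>i</sub>/Σu<sub>ik</sub><sup>m</sup>)
  with the minimum-centroid-distance **Dmin** diagnostic for choosing the
  cluster count.
* **DMR-anchored aggregation** — Day-0-subtracted CPM ChIP signal and
  per-CpG methylation change, averaged in 10-bp offset bins across
  ±3 kb of DMR centers.
* **Assay arithmetic** — HTRF DF%, lysosomal flux
  (bafilomycin − vehicle), treatment deltas, ChIP %input,
  bisulfite-clone percent methylation, masked Pearson colocalization.
* **Synthetic study generator** — seeded, with planted ground truth
  (demethylated promoters, induced-only peaks, 7 ChIP prototypes,
  DMR-localized signal loss), so the whole pipeline is testable offline.

See `vignettes/methshift-methods.Rmd` for the models, parameter
definitions and design choices.

## Worked example

```r
library(methshift)

dir <- file.path(tempdir(), "demo")
sim <- simulate_dataset(sim_config(seed = 1), dir)      # writes inputs + truth.json
s   <- run_pipeline(dir, file.path(dir, "out"))         # full analysis
str(s[c("tss_hits", "contrast", "enhancers_diffspec")])
#> List of 3
#>  $ tss_hits          :List of 2
#>   ..$ DFO-: int 20
#>   ..$ DFO+: int 0
#>  $ contrast          :List of 3
#>   ..$ DFO-_only: int 20
#>   ..$ DFO+_only: int 0
#>   ..$ shared   : int 0
#>  $ enhancers_diffspec: int 40
```

The 20 `DFO-` promoter hits are exactly the 20 genes the generator
planted with a 60-point Day-8 methylation drop in the untreated condition
(and none are found under iron chelation — the `DFO-_only` set is the
iron-dependent one); all 40 induced-only peaks are recovered as
differentiation-specific enhancers. The per-stage funnel is logged:

```text
DFO-: 17141/17141 CpGs read
DFO-: 15130 CpGs pass coverage in both timepoints
DFO-: 20 hit regions (>= 3 CpGs dropping > 50 points)
...
clustering: 7 clusters, Dmin = 1.1665, converged
aggregation: 40 DMR anchors, ChIP profile minimum -3.947 at offset -5
```

`out/` holds the hit tables (`tss_hits_*.tsv` with qualifying CpG
positions and deltas), the contrast, enhancer BEDs, cluster memberships/
centroids/labels, the DMR profiles, `summary.json`, and the resolved
configuration for provenance. The ChIP profile minimum of −3.947 CPM at
offset −5 bp is the planted DMR-centered histone-signal loss surfacing in
the aggregation curve (dead center, within half a bin).

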
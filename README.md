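# cistrometry

Integrative cistrome analysis for pioneer-factor studies.

Demonstrating that a transcription factor acts as a *pioneer factor* for
the estrogen receptor (ERα) — engaging closed chromatin ahead of hormone
stimulation and licensing a specific transcriptional response — rests on a
chain of genomic computations rather than any single assay. `cistrometry`
implements that chain as reusable, tested R stages:

* **Interval algebra** on BED cistromes under the ≥1-bp overlap rule
  (`read_bed`, `intersect_members`, `subtract_members`, `basepair_overlap`),
  member-level by design: the objects of interest are sets of binding
  sites, e.g. FoxA1-independent ERα sites.
* **Motif screening** of peak sequences against TRANSFAC matrices with
  log2-odds scoring (pseudocount 1, both strands, N-neutral) and a
  matrix-adaptive threshold from the exact background score distribution
  (`parse_transfac`, `screen_cistrome`, `pwm_threshold`).
* **Genome-structure-corrected overlap significance**: a GSC-style
  block-translocation null for the base-pair overlap statistic
  S(obs) vs S(null), with region/sub-region fractions R = 0.2, S = 0.4
  and p = (1 + #{S_null ≥ S_obs})/(n + 1) (`gsc_test`,
  `bonferroni_adjust`).
* **Three-way Venn partitioning** of cistromes into the 7 exclusive site
  classes, counted per reference factor (`venn_partition`).
* **TSS-window enrichment** ("radar" statistic): for each site class, the
  proportion of responsive genes with a class site within ±20 kb of the
  TSS over the same proportion among null genes, with Fisher exact p
  (`genes_with_site`, `enrichment_ratio`, `radar_table`).
* **Differential expression** in a 2×2 siRNA × estrogen design:
  median-reference normalization, detection filtering, per-gene t-tests
  and four-class ANOVA at raw p < 0.01, and the knockdown-**dependent
  fraction** of responsive genes (`median_reference_normalize`,
  `two_class_ttest`, `four_class_anova`, `dependent_genes`).
* **Accessibility aggregation**: WIG tracks binned at fixed width,
  averaged around site centers per class (`read_wig`,
  `aggregate_profile`, `fraction_in_peaks`).
* **Expression-stratified outcome**: top/bottom-decile strata, Fisher
  exact metastasis-free comparisons at fixed follow-ups, Kaplan-Meier
  curves, and gene-signature association at p < 0.01 and OR > 2
  (`stratify`, `fisher_outcome`, `km_estimate`, `signature_association`).
* A **synthetic-data module** that generates every input with planted
  ground truth (`synthetic_design`, `gen_genome`, `gen_cistromes`,
  `plant_motifs`, `gen_expression`, `gen_track`, `gen_cohort`), and an
  end-to-end driver (`pipeline_config`, `run_pipeline`).

See `vignettes/cistrometry-methods.Rmd` for the models, parameter
conventions and design rationale.

## Worked example

```r
library(cistrometry)

report <- run_pipeline(pipeline_config(synthetic_design(seed = 1)))
print(report)
```

```
== cistrometry run report ==
seed 1, package 0.1.0

Motif screen: ERa 50.4% with hit; ERa minus FoxA1 52.1% (Fisher p = 0.699)
ERa/PBX1 member overlap: 50.9% of ERa sites; GSC p <= 0.004975 (z = 231.6)

Venn classes (counts per reference factor):
               ERa FoxA1 PBX1
ERa            120    NA   NA
FoxA1           NA   200   NA
PBX1            NA    NA  250
ERa+FoxA1      150   150   NA
ERa+PBX1       120    NA  120
FoxA1+PBX1      NA    80   80
ERa+FoxA1+PBX1 160   160  160

<responsive_genes> 125 responsive (up), 92 dependent (73.6% by attenuation; 83.2% by significance loss)

Openness peak heights: FoxA1+PBX1=3.49, PBX1=2.51, FoxA1=1.52
Outcome (year 5): OR = 43.50, p = 2.59e-06; signature association OR = 394.3, p = 7.47e-102

Qualitative checks:
  dependent_enriched_at_pbx1_classes       PASS
  openness_greatest_at_shared              PASS
  poor_outcome_in_high_expressers          PASS
```

Reading the output: the synthetic design planted the motif in 85% of
PBX1-class sites, made ~51% of ERα sites PBX1-shared, abolished the
estrogen response of 71% of responsive genes under knockdown, ordered
chromatin openness shared > PBX1-unique > FoxA1-unique, and gave
top-decile expressers a 0.5 vs 0.1 yearly event probability — and each
stage recovers its planted quantity: the block-resampling test calls the
cistrome overlap maximally significant, the dependent fraction lands near
71% (attenuation criterion; the significance-loss figure is reported
alongside and is visibly biased upward), the radar table shows the
dependent genes enriched only at PBX1-unique and PBX1+ERα classes, and
the high-expression stratum has far worse metastasis-free outcome.

Each stage is equally usable on its own files — `read_bed()`,
`read_genome_fasta()`, `read_wig()`, `read_expression_study()`,
`read_cohort()` accept the plain-text formats written by
`run_pipeline(..., out_dir = )`.

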
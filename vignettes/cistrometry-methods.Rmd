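---
title: "Methods: integrative cistrome analysis with cistrometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative cistrome analysis with cistrometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

A pioneer transcription factor engages compacted chromatin and renders it
accessible to other regulators. Establishing that a candidate factor (here
PBX1, alongside the canonical pioneer FoxA1) plays that role for the
estrogen receptor ERα in breast cancer cells requires an *integrative*
argument stitched from several independent genomic measurements:

1. the factor's recognition motif is over-represented in the ERα cistrome;
2. the binding-site sets (cistromes) of ERα, FoxA1 and the candidate
   overlap far more than genome structure alone explains;
3. the classes of shared and unique sites associate differentially with
   estrogen-responsive genes, and knockdown of the candidate abolishes the
   response of a specific gene subset;
4. chromatin at the candidate's sites is measurably open (FAIRE signal);
5. the candidate's expression stratifies patient outcome.

`cistrometry` implements each link of that chain as a reusable, tested
stage, plus a synthetic-data module that generates every input with
planted ground truth, so the whole chain can be validated end to end
without any external data.

# Interval algebra

All cistromes are `interval_set`s in BED convention (0-based, half-open).
Two intervals overlap iff they share at least one base pair
(`max(starts) < min(ends)`); abutting half-open intervals do not overlap.
Set operations are *member-level*: `subtract_members(a, b)` removes whole
intervals of `a` that touch `b`, because the quantity of interest is a set
of binding *sites* (e.g. "FoxA1-independent ERα sites"), not sequence
fragments. A base-pair-truncating mode (`mode = "bp"`) exists for coverage
arithmetic. Before base-pair computations sets are merged internally
(book-ended runs collapse); member operations act on the original members
after `canonicalize()` (sort + exact-duplicate removal). Strand is ignored
throughout.

# Motif screening

TRANSFAC count matrices are scored as log2-odds in bits with pseudocount 1
per cell and a uniform background by default:
$s(w) = \sum_i \log_2 \frac{p_i(w_i)}{b(w_i)}$,
where $p$ are the pseudocount-smoothed column frequencies. `N` bases
contribute exactly 0, so repeat-masked sequence neither creates nor
destroys hits. Both strands are scanned (the reverse strand via the
reverse-complemented matrix) and a peak is a hit if any window reaches the
threshold.

The default threshold is *matrix-adaptive*: the smallest score whose tail
probability under the background model is at most $10^{-4}$ per window,
computed by exact dynamic programming over the discretized score
distribution (1/1000 bit resolution). This makes the default reproducible
and transferable between matrices, unlike a fixed absolute score. Absolute
screen fractions still depend on this choice, so cross-cistrome
*comparisons* (Fisher exact test on hit counts, `compare_screen_fractions`)
are the stable statistic, and planted-truth tests treat fractions with a
binomial tolerance.

The package ships `pbx1_like_synthetic.transfac`, a synthetic
TALE-homeodomain-style matrix (consensus TGATTGAT) constructed for this
package; commercial TRANSFAC matrices are not redistributable, and only
the consensus and information content matter to the synthetic study.

# Overlap significance: GSC-style block resampling

A naive binomial test of cistrome overlap is wildly anticonservative
because binding sites cluster along the genome. `gsc_test()` therefore
resamples at the *block* level: each chromosome is tiled — with a random
phase per iteration — by blocks of length
$S \times R \times L_{chrom}$ (defaults $R = 0.2$, $S = 0.4$, the
conventional region/sub-region fractions for cistrome comparisons); the
second set's intervals are cut at block boundaries and each block is
translocated as a unit to a uniformly random position on its chromosome.
Clustering at scales below the block length survives under the null, which
is the property the correction exists for. The statistic is the marginal
base-pair overlap, and the add-one estimator
$p = (1 + \#\{S_{null} \ge S_{obs}\})/(n + 1)$ keeps $p \ge 1/(n+1)$.
One-sided enrichment is the default (overlap enrichment is the hypothesis);
two-sided is available. The original genome-structure-correction software's
internal segmentation heuristics are not published in reproducible detail,
so this implementation is documented as *GSC-style*: same purpose, same
parameters, fully specified algorithm. Calibration (uniform p under
independence) and power (planted base-pair sharing) are verified by
simulation in the test suite. Bonferroni adjustment over a declared family
of comparisons is provided (`bonferroni_adjust`, e.g. m = 12).

# Venn classes and the choice of reference

Peak overlap is not transitive, so "the" count of a three-way Venn class is
ill-defined: each factor sees the class through its own members.
`venn_partition()` assigns every member of every factor the subset of
factors it overlaps, and summaries quote counts from a stated *reference*
factor (configurable; the partition property — each reference's classes
are disjoint and exhaustive — holds for every reference). The synthetic
generator places multi-factor loci as literally identical intervals, so
recovery of designed counts must be exact, which the tests assert.

# TSS-window enrichment (the radar statistic)

A gene is "associated" with a site class if at least one class site
overlaps the half-open window `[tss - w, tss + w)` (default w = 20 kb,
symmetric, strand-independent). The radar statistic for a class is the
*ratio of proportions*: the fraction of responsive genes with a site over
the same fraction in the null list (all annotated genes not responsive).
The literal count ratio would scale with list sizes and could not hover
around 1 for unequal lists, so proportions are the default and raw counts
sit behind a flag. Each class is evaluated independently (a gene near two
classes counts toward both), and significance is the minimal-assumption
Fisher exact test on the 2×2 table. Classes are anchored to the reference
factor's members when the reference belongs to the class.

# Differential expression and the dependent fraction

The expression stage mirrors a classic two-color-era array workflow:
log2 intensities, detection filtering (drop genes detected in fewer than a
configurable number of samples; default 1), then median-reference
normalization — subtract from each array the median of its gene-by-gene
difference to the per-gene median (reference) array, after which each
array's median difference to that reference is zero (exactly, up to one
double rounding). The reference used is stored on the result; a second
pass only moves arrays by the noise-level residual, which the tests bound.

Per-gene testing uses the pooled (equal-variance) two-sample t-test by
default. At n = 3 per cell the pooled test's level is exact under the
equal-variance Gaussian model the generator (and, plausibly, normalized
array data) follows, whereas the Welch test is measurably conservative
(type-I ≈ 0.005 at nominal 0.01), which would break the calibration
properties this package promises; Welch remains available
(`var_equal = FALSE`). Raw p < 0.01 defines responsiveness — no multiple
testing correction by default, for fidelity to the emulated workflow; a
BH-FDR mode exists. A four-class one-way ANOVA across the 2×2 design cells
is provided alongside.

**Dependence criterion.** A responsive gene is knockdown-dependent when
its estrogen response disappears under the knockdown. Operationalizing
this as "no longer significant in the knockdown arm" is structurally
biased upward whenever per-arm power is below 1 (the closed-form power at
effect 2.0, σ = 0.5, n = 3/cell, α = 0.01 is 0.63): every responsive gene
the knockdown arm merely fails to re-detect is miscalled dependent — the
classic fallacy that the difference between significant and
non-significant is itself significant. The default criterion is therefore
*fold-change attenuation*: the knockdown-arm effect is less than 50% of
the control-arm effect (signed ratio, so sign flips count). On planted
data this recovers the designed dependent fraction within a few points,
while the significance-loss rule overshoots by ~10 points; both numbers
are always reported (`fraction_by_method`), and the significance-loss mode
can be selected. "Estrogen-induced" genes are the up-regulated responsive
genes by default (`direction = "both"` keeps both signs).

# Accessibility signal

Tracks are fixed-bin vectors (default 10 bp) read from fixedStep or
variableStep WIG with per-bp-weighted binning; unspecified positions are
zero. `aggregate_profile()` averages the track around floor-midpoint site
centers over ±flank (default 2 kb); sites whose window leaves the
chromosome are dropped, not zero-padded (padding would deflate means), and
counted. The profile is linear in the track and mirrors under coordinate
reflection — both are asserted as invariants. `fraction_in_peaks()` gives
the per-class fraction of sites inside called accessibility peaks.

# Outcome analysis

The cohort model is deliberately simple, matching how fixed-follow-up
outcome tables are published: per sample, an expression value and a binary
metastasis-free status at years 1/3/5 (with `unknown` handled per year by
complete-case analysis, dropped counts reported). `stratify()` takes the
top and bottom `floor(n·f)` expressers (default f = 0.10; 0.25 reproduces
quartile splits), breaking ties by stable input order with a warning.
`fisher_outcome()` tests the 2×2 stratum × event table two-sided; odds
ratios are ad/bc with the Haldane 0.5 correction for display only — never
inside the exact p. Kaplan-Meier curves (`km_estimate`, delegating to
`survival::survfit`) serve the time-to-event view; with no censoring the
product-limit estimate equals the empirical survival function exactly.
`signature_association()` applies the p < 0.01 and OR > 2 filter to 2×2
overlap tables of gene signatures against a universe.

# The synthetic-data module

Every generator is deterministic given the design seed (each derives its
own stream, so stages can be re-run independently) and returns its planted
truth alongside the data. Defaults are the emulated study's conditions:

| parameter | default | meaning |
|---|---|---|
| `peak_width` | 200 bp | binding-site width |
| `venn_counts` | 120/200/250/150/120/80/160 | loci per Venn class; ~51% of ERa sites shared with PBX1 |
| `motif_plant_prob` | 0.85 at PBX1 classes, 0.15 elsewhere | consensus planting probability |
| `effect_size`, `noise_sd` | 2.0, 0.5 log2 units | estrogen response vs noise |
| `n_samples_per_cell` | 3 | replicates per design cell |
| `dependent_fraction` | 0.71 | planted knockdown-dependent share |
| `openness_amplitudes` | shared 3 > PBX1-unique 2 > FoxA1-unique 1 | accessibility bump heights |
| `event_prob_high/low` | 0.5 / 0.1 per year | outcome model |
| `chrom_lengths` | 12 + 9 + 7 Mb | synthetic genome |

The genome size is chosen so that the spacing between planted loci
(~26 kb) exceeds the ±20 kb TSS window; on a denser genome every gene has
every class nearby and the radar statistic saturates at 1 — site density
relative to the assignment window, not absolute genome size, is what the
generator must respect. Site density remains within a factor ~3 of the
real genome-wide density the study reports. Motifs are planted as the
consensus (unambiguous hits); a PWM-sampled mode would additionally
exercise threshold sensitivity but makes planted truth probabilistic, so
consensus is the default. The class→gene linkage for expression
(`dep_link_classes`, `resp_link_classes`, `link_prob`) is an explicit,
serialized device to create testable enrichment — it is not a biological
model. `gen_enrichment_layout()` offers exactly calibrated with-site rates
on a sparse coordinate-only domain for quantitative recovery tests.
The cohort generator draws one exponential event time per sample (rate
`-log(1-p)`), from which both the fixed-year statuses and the censored
Kaplan-Meier columns derive, keeping them mutually consistent.

**What the generator does not emulate:** read-level noise, peak-calling
artifacts, probe effects and batch structure, correlated genes,
non-Gaussian heavy-tailed expression noise, nucleosome-scale accessibility
texture, or covariate-confounded cohorts. Passing tests therefore
demonstrate correctness of the computations and recoverability of planted
structure — not robustness to every pathology of real data.

# Numerical choices and degenerate inputs

* PWM score discretization 1/1000 bit in the threshold DP; thresholds are
  the smallest discretized score meeting the target tail probability.
* GSC p never 0 (add-one); empty input sets short-circuit to a flagged
  degenerate result with p = 1; blocks longer than a chromosome error.
* t/F statistics with zero within-class variance: p = 1 when means agree
  (a constant gene is not responsive), p = 0 on exact separation.
* Odds ratios: Haldane 0.5 only when a cell is zero, display only.
* Expression-tie stratification is deterministic (stable order) and warns.
* All Monte-Carlo tolerances in tests are derived from binomial/closed-form
  error bounds at the simulated sizes, not tuned constants.

# Problem sizes used in the validation suite

The test suite runs the interval/motif oracles at n ≤ 100 intervals and
100 peaks × 50 kb; GSC calibration with 200 replicates × 99 null samples
on a 1 Mb domain and power with 100 × 199; expression recovery at
10,000 genes × 12 arrays (3 studies); the radar recovery at 200 + 2,000
genes × 50 seeds; and the end-to-end pipeline at the full default design
(28 Mb genome, 1,080 loci, 2,000 genes, 300 patients) twice to assert
byte-level determinism. These sizes keep the whole suite in a few minutes
on one core while leaving every tolerance binomially justified.

# Known limitations

* The block-translocation null is one member of the GSC family, not a
  byte-level reimplementation of the original software; published
  overlap p-values are matched in kind, not bit-for-bit.
* Absolute motif-screen fractions depend on the threshold convention; only
  planted-truth designs and cross-cistrome comparisons are quantitative.
* Venn counts depend on the declared reference factor; there is no single
  "true" three-way count for non-transitive overlap graphs.
* The outcome module implements stratified fixed-horizon comparisons and
  Kaplan-Meier curves; Cox regression and log-rank testing are out of
  scope, as is meta-analytic pooling beyond per-study tables (a simple
  count-summation pooling across cohorts can be performed by concatenating
  cohort tables, but is flagged as interpretation).
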
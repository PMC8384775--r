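---
title: "Methods: connectivity mapping, enrichment and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity mapping, enrichment and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigconnect)
```

This vignette is the package's own account of its methods: what each stage
computes, which conventions were chosen where the field leaves room, what
the synthetic generator does and does not emulate, and what a green test
does and does not establish.

## 1. Data model

The root object is an `ExpressionMatrix`: raw non-negative integer counts,
probes × samples, with probe annotation (probe → gene symbol, panel ∈
{ST, WT}) and sample metadata (chemical, concentration in µM, batch,
replicate, panel, vehicle flag). Counts stay raw until a stage explicitly
normalizes; all QC statistics are computed on raw counts with no
pre-filtering. Treatments are identified by hyphen-joined tokens
(`chemical-<conc>uM-duration-species-cell-study`, e.g.
`valproic-acid-400.00uM-24h-rn-hep-e-mtab-797`); the parser splits from
the right of the concentration token so chemical names containing hyphens
and digits (`wy-14643`) survive.

## 2. QC statistics

* Read depth = column sums; zero fraction = per-sample fraction of probes
  with zero count; consistent zero fraction = probes zero in *every*
  sample.
* Technical replicate correlations: Pearson r of raw counts for the three
  unordered pairs of a within-batch triplicate. Biological replicate
  correlations: replicate-index-matched pairs across the two batches. All
  probes are included (the raw-count convention); no normalization is
  applied before correlation.
* Variance stabilization for PCA is a documented stand-in: size factors by
  median-of-ratios (reference = per-probe geometric mean across samples;
  each sample's factor is the **linear-domain median** of its count ratios
  over probes with positive geometric mean), then `log2(count/sf + 1)`.
  This preserves the rank and gross variance structure PCA needs but is
  *not* a fitted mean–dispersion transform; a model-based VST will differ,
  especially at low counts. The linear-domain median is used because it is
  the convention this package documents; log-domain implementations differ
  when the probe count is even (the median then averages two ratios, and
  averaging in log space yields their geometric mean instead).

## 3. Differential expression stand-in

The DEG caller deliberately replaces a negative-binomial GLM with a
per-gene ordinary linear model on `log2(count/sf + 0.5)`: a treatment
indicator plus, in `batch_mode = "corrected"`, an additive batch factor
(no interaction — the simplest model consistent with "batch correction").
Two-sided t-test on the treatment coefficient, Benjamini–Hochberg across
genes, DEG ⇔ adjusted p < α (default 0.05). Consequences to keep in mind:

* no dispersion shrinkage, so power at n = 3 per group is below a
  moderated NB test; the null calibration (BH-significant count = 0 in
  ≥95% of null runs) is what the package actually guarantees;
* the interface consumes and emits a plain TSV schema
  (`gene, l2fc, stat, p, adj_p, is_deg`), so externally computed
  NB-GLM results can be dropped into every downstream stage.

L2FC profiles are computed independently of the test:
`log2((mean_trt + c)/(mean_ctl + c))` with pseudocount `c = 0.5` by
default (kept positive so zero means stay finite); for reference data
already on the log2 scale the profile is the difference of group means.
Reference profiles from intensity platforms are consumed as precomputed
log2 values — normalization of raw arrays is an input contract, not
reimplemented. Multi-probe genes collapse by `mean` by default (`max_abs`
available); the choice is a convention, not an inference.

## 4. Signatures and connectivity scores

A query signature is rank-based: the `nq` largest and `nq` smallest L2FC
values, ties at a boundary broken by ascending gene symbol so results are
identical across platforms. "Down" genes are the most negative by rank,
not by sign; a skewed profile can place a positive gene in the down set
(logged when it happens). Reference profiles are restricted the same way
to `nr` per direction, clamped (with a log) to half the universe when a
small synthetic profile cannot supply `2·nr` genes. Default grids are
nq = 100…1000 by 100 and nr = 1000…6000 by 1000.

Conventions behind the five scores:

* **sji** — mean of the two direction-matched Jaccard indices minus the
  two cross-direction ones, divided by two: bounded in [−1, 1], with
  J(∅,∅) ≡ 0. Signed-Jaccard variants in the literature differ in
  normalization; this one is chosen for its clean bounds and is flagged
  prominently here.
* **weighted-KS ES** — the running sum increments by |value|^p (normalized
  over set members, p = 1 for connectivity and enrichment, p = 0 for the
  classic KS statistic) at set members and decrements by `1/(N − N_hit)`
  at non-members; ES is the extremum of the running sum, the positive
  extremum winning exact magnitude ties. If every member weight is zero at
  p = 1, equal weights are used. The implementation evaluates the sum only
  at hit boundaries (O(k) after position lookup); the test suite pins it
  to a position-by-position brute-force oracle at 1e-12 on a thousand
  random instances.
* **gtes** — bidirectional composition
  `[ES(q_up|r) − ES(q_down|r)] + [ES(r_up|q) − ES(r_down|q)]` with p = 1,
  range [−4, 4]. The bidirectional form is adopted because published
  score magnitudes exceed 2, which excludes the common unidirectional
  `ES_up − ES_down` (range [−2, 2]); the exact upstream formula is not
  restated in the motivating literature, so the composition is isolated in
  one function for easy substitution. Sets are intersected with the
  opposing ranking first; an empty intersection contributes 0.
* **xc / xcp / xcs** — cosine, Pearson, Spearman on the signature genes,
  with the reference vector masked to 0 outside its extremes (and for
  genes absent from the reference universe). Masking to zero rather than
  dropping keeps the vectors aligned; dropping is not offered because it
  changes the score's meaning silently. Fewer than 3 signature genes
  surviving masking, a zero-norm vector, or zero variance ⇒ the score is
  undefined (NA); undefined scores always rank after defined ones, so a
  treatment with no usable signal can never be a top hit.

Ranking is deterministic: primary score descending, NA last, ties broken
by reference id.

## 5. Retrieval benchmarking

The correct hit is the highest-ranked reference whose chemical matches the
query's (names compared lowercase with punctuation stripped, so `WY14643`
matches `wy-14643`). A chemical absent from the database, or present with
only undefined scores, yields a missing rank — logged distinctly — which
stays in the Fr denominator and never the numerator. Per chemical, ranks
aggregate over that chemical's query treatments by minimum (the "best
rank" convention). The grid evaluator is exhaustive over
(nq, nr, algorithm); the best-rank table picks, per algorithm, the cell
maximizing the selection metric with ties resolved toward the shortest nq
then the shortest nr, and reports per-chemical best ranks with their
median and mean (missing ranks excluded from those two summaries).

## 6. Gene set enrichment

`run_gsea` consumes one ranking per treatment (by default the DE
stand-in's t statistic; any named statistic works) and a GMT collection.
The null model is gene-label permutation: `n_perm` size-matched random
sets drawn from the ranking universe, shared across sets of equal size.
NES = ES / mean(|null ES| of the same sign);
p = (1 + #{same-sign nulls with |null| ≥ |ES|}) / (1 + #same-sign nulls),
so the attainable floor is 1/(1 + #same-sign nulls) — close to, but not
exactly, 1/(n_perm + 1); FDR is BH across scored sets. Phenotype
permutation is not offered because the pipeline has no replicate-level
labels at enrichment time. Sets are restricted to the expressed universe
first; sets below 15 or above 500 genes are scored but flagged rather than
dropped — out-of-range sets are reported with a caution, matching how such
results are interpreted in practice, and the empty ones are skipped.
With a fixed seed the whole run is bit-reproducible.

Cross-panel concordance reports the Pearson r of NES over sets scored in
both runs plus the overlap of the two top-5 lists (descending NES,
name-tiebroken).

## 7. Clustering and cluster differences

Columns (treatments) cluster by Euclidean distance with the ward.D2
criterion — Ward linkage applied to *unsquared* distance input, pinned
explicitly because the ward.D/ward.D2 discrepancy is a classic source of
irreproducibility. Missing NES values are refused, not imputed. Cut
labels are renumbered by first appearance in column order so the partition
is stable under column permutation. Cluster "A" vs "B" identification is
automated from tagged gene sets (highest mean NES over metabolism-tagged
sets ⇒ A; over injury-tagged sets ⇒ B), replacing by-inspection labeling.
The per-set cluster difference test is Welch's t (unequal sizes and
variances expected; Mann–Whitney behind a flag), BH across sets;
discriminating sets must exceed |ΔNES| > 2.5 *and* FDR < 5×10⁻⁴, both
strict inequalities, and are returned in descending Δ order.
Nearest-neighbor pairing checks, for each treatment, whether its ST
column's nearest neighbor (self excluded) is its own WT column.

## 8. The synthetic study: what it emulates, and what it does not

The generator reproduces the statistical structure the analysis assumes,
with defaults chosen once:

* **Design** — 14 chemicals × 2 concentrations (nominal 2 and 10 µM,
  effect scaling 1:5) + vehicle, triplicate wells × two batches; a ~20k
  gene whole panel with a 12% surrogate panel; a reference database with
  the same chemicals at three concentrations (effect scaling 1:5:25,
  mirroring a 3-dose reference resource) plus 20 decoys, half of which
  share one mechanism program with a real chemical.
* **Counts** — NB(mean = baseline × 2^(β·conc) × batch × libsize,
  per-gene dispersion) with 2% extra dropout. Baseline lognormal
  (meanlog = log 1.5, sdlog = 2.4) was calibrated once so per-panel mean
  zero fractions land on the reported operating points (~38% WT, ~17.5%
  ST) inside the 15–40% band; individual samples spread wider because
  treatment effects and library sizes vary. Surrogate library sizes are
  scaled so total ST depth is one fifth of WT, spread over the smaller,
  expression-weighted panel — which is exactly why the surrogate's zero
  fraction is much lower.
* **Mechanisms** — 8 disjoint 100-gene programs, half tagged
  "metabolism", half "injury". Chemicals follow three archetypes
  (A: metabolism up / injury down; B: the reverse; C: weak positive on
  both), giving the clustering stage its three planted classes. Two
  design choices reconcile archetype structure with retrievability, and
  they were the genuinely open part of this design: each chemical loads
  every tagged program **except one per side** (the left-out pair unique
  per chemical), and every (gene, chemical) program effect carries
  multiplicative lognormal jitter while background genes receive dense,
  weak, chemical-specific effects (sd 0.15 log2 units). Without these,
  same-archetype chemicals would share their top-gene *membership*
  exactly and set-based scores (sji) could not separate them even with
  noise-free references; with them, sign-coherent archetypes remain for
  NES clustering while every chemical keeps a unique gene-level
  fingerprint. The dense background also keeps reference rankings free of
  ties, which real profiles never have.
* **Reference platform** — independent of the count noise: true effect
  vectors plus Gaussian noise (default sd 0.5), on a universe missing 5%
  of genes, exercising the gene-intersection code paths. Noise draws use
  common random numbers across noise levels under a fixed seed, so
  degradation studies move smoothly.
* **Gene sets** — program cores with 10% membership jitter (imperfect
  curation), two pooled tag sets, deliberately tiny sets to exercise size
  flags, and off-program decoy sets.

Not emulated: probe-level chemistry and isoform structure (probes map 1:1
to genes; the isoform-aggregation path is tested on hand-built fixtures),
time-course designs, dose–response viability curves, and correlated
gene–gene noise. A green test on this generator establishes that the
*pipeline* recovers planted structure under its stated assumptions — not
that any particular laboratory platform meets them.

## 9. Acceptance criteria and scaling

The acceptance suite is property-based; where a criterion names a runtime
budget the simulation is scaled down rather than the claim weakened:
noiseless self-retrieval runs on an 8,000-gene universe (so the nr = 3000
cell needs no clamping) with the full 14 chemicals, 102 reference
profiles, all five algorithms and the reduced nq ∈ {100, 300} ×
nr ∈ {1000, 3000} grid; the extreme-noise uniformity check uses one
matching reference per chemical (middle concentration) so the correct
rank is uniform on {1..20} under the null, tested by a randomized-PIT
Kolmogorov–Smirnov test over 200 replicates; archetype recovery runs in
the strong-effect regime (loadings 2–4 log2 units) on a 3,000-gene
universe. The planted-DEG recovery case uses dispersion 0.01 at mean 200 —
"low dispersion" made concrete, since at n = 3 vs 3 an unmoderated t-test
at dispersion 0.05 sits exactly on the BH boundary and the criterion is
about recovery, not about that boundary.

## 10. Known limitations

* The DE stand-in's t statistics are meaningless on rows the linear model
  fits exactly (zero residual); such rows only arise in degenerate
  constructed data.
* NES normalization by the same-sign null mean is undefined when no null
  of that sign appears; the set is then reported with NES 0 and p 1
  rather than invented.
* `gtes` implements one defensible composition of four enrichment scores;
  alternative published compositions exist and would change magnitudes
  (not self-retrieval at noise 0).
* The generator's archetype C ("intermediate") is weakly positive on both
  tag groups; other intermediate phenotypes (e.g. mixed signs) would
  stress the A/B identification differently.
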
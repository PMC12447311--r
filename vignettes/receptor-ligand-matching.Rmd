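---
title: "Receptor-ligand matching from deep label-free proteomics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-ligand matching from deep label-free proteomics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlmatch)
```

## The problem

Neurons induced from human iPSCs by forced NGN2 expression differentiate
fast but mature poorly under the conventional medium, which supplements
only BDNF and NT3. Receptor-ligand matching (RLM) turns deep label-free
proteomics of the differentiated cells into a medium-design tool: inventory
the surface receptors the cells actually express, find the receptors
strongly enriched in the differentiated state relative to the source iPSCs,
and supplement the medium with the ligands those receptors respond to.

`rlmatch` implements the computational arm of that strategy as four stages,
each a package function with a thin driver script under `analysis/`:

1. **Quantify** — total-intensity normalization of replicate iBAQ tables
   and per-protein differential statistics across batches
   (`normalize_ibaq()`, `differential()`).
2. **Annotate** — cross-reference the quantified proteome with
   UniProt-style annotations to inventory membrane proteins, growth-factor
   receptors and the neurotrophic subset (`filter_membrane()`,
   `classify_receptors()`).
3. **Select** — apply the enrichment rule (default: at least 10-fold
   higher in induced neurons, quantifiable there) to the neurotrophic
   inventory (`select_enriched_receptors()`).
4. **Recommend** — join candidates to a curated receptor→ligand
   knowledgebase and rank the supplementation recommendations
   (`match_ligands()`, `compare_supplement_sets()`).

## Data model and normalization

A `QuantMatrix` is a protein × sample matrix of iBAQ intensities with
sample metadata (condition × batch; each batch contributes one sample per
condition). Intensities are non-negative and **exact zeros are the
non-detection sentinel**: empty cells, `NA` and 0 in input tables all map
to it, because "undetected" and "too low for quantification" are one
category downstream.

Normalization is per-sample total-intensity scaling (relative iBAQ): each
column is divided by its sum, so columns sum to 1 and any global
multiplicative per-sample factor — including the multiplicative batch
effects the generator plants — cancels exactly. The property is testable
(conservation to 1e-12; scale invariance of every downstream record) and
is the standard reading of "normalized iBAQ".

## Differential statistics

For every protein quantifiable in at least one condition we report
condition means of normalized intensity, the iN/hiPSC ratio, and a
p-value from a two-sample test on `log10(intensity + floor)` across
batches.

**Floor.** The floor is a global pseudo-intensity, by default half the
smallest positive normalized intensity
(`floor_factor = 0.5`, `floor_quantile = 0`). It is added inside the log
transform and applied to *both* condition means before the ratio is
formed. Flooring both sides (rather than only the denominator) is
deliberate: it keeps every fold change finite — one-sided detections give
large finite ratios instead of infinities, so the volcano stays plottable
— and it makes the estimator antisymmetric: swapping the condition labels
exactly negates every log2 ratio. Ratios for proteins detected on one
side only are therefore *floor-limited*, not estimates of a true fold
change; their detection class says so.

**Test.** The default test is the pooled two-sample (Student) *t* on the
floored log10 intensities. With three batches per condition this choice
matters: under the equal-variance log-normal model the pooled *t* is
exact, whereas the Welch test's Satterthwaite approximation is
conservative at *n* = 3 per group (its true size is about 0.035 at
nominal 0.05, which we verified by simulation on iid normal data), and a
rank test is degenerate (its smallest achievable two-sided p is 0.1 at
3 vs 3). Welch (`test = "welch"`) and Wilcoxon (`test = "wilcoxon"`)
remain available for larger or heteroscedastic designs. Degenerate inputs
are handled explicitly: if both groups have zero variance the p-value is
1 when the means agree and 0 otherwise (the latter unreachable with
continuous noise); with fewer than two batches per condition every
p-value is the sentinel 1 and a warning is raised.

**No multiplicity correction by default** — the volcano reports raw
p-values, and the selection rule is fold-based, not p-based.
Benjamini-Hochberg is available via `adjust = "BH"` and is recorded in
the run report.

**Detection.** A protein is quantifiable in a condition iff it is nonzero
in at least `min_batches` (default 2, a majority of the three-batch
design) distinct batches of that condition; the four detection classes
(both / A-only / B-only / neither) drive which records exist and which
receptors are selectable.

## Annotation funnel

Membrane status is derived from declarative rules
(`inst/extdata/annotation_rules.tsv`): the UniProt keyword `Membrane` or a
subcellular location matching "Cell membrane"/"Plasma membrane". Receptor
classes come from those rules OR'ed with a packaged curated list of 29
growth-factor receptors, 15 of them neurotrophic (TRK/p75, GDNF-family
and CNTF-family receptors plus MET and IGF1R) — the class boundary is a
versioned, explicit artifact rather than an implicit keyword query, and
the annotation `source_version` is recorded in the run report because
every funnel count depends on it. Class nesting (neurotrophic ⇒
growth-factor receptor ⇒ membrane) is definitional, so implied flags are
propagated upward at read time and violations are a hard constructor
error.

## Selection and ligand matching

The selection rule is the printed one: ratio ≥ `fold_threshold`
(default 10) in the derived state, and — by default — quantifiable there.
No p-value gate is applied: p is reported, not filtered on. Candidates are
ordered by descending log2 ratio with ties broken by ascending p then
accession, so output order is deterministic under input permutation.

The packaged knowledgebase pairs each neurotrophic receptor with its
ligand; the five supplementation pairs are TRKB–BDNF, CNTFR–CNTF,
GFRA1–GDNF, GFRA2–NRTN and GFRA3–PSPN. Two curation notes: the GFRA3–PSPN
pairing follows the study design this package emulates (the canonical
high-affinity GFRA3 ligand is artemin, recorded in the KB notes), and
`ligand_available` marks the supplementable panel, so the commercial
availability gate (`require_ligand_available`, default off for
transparency) reproduces the five-ligand supplement set while the full
candidate table stays visible. The empirical demotion of PSPN in
follow-up wet-lab work is not a computable rule; the recommender reports
the full set and `compare_supplement_sets()` expresses set-level
comparisons such as RLM versus the conventional {BDNF, NT3}.

## The synthetic-data generator

The generator stands in for the deposited study data and defines the
conditions every test runs under. Protein *i* in sample *s* has

  log10 I_is = base + offset_i ± ½·log10(fold_i) + b_s + ε_is

with `offset_i ~ N(0, base_log10_sd)` (between-protein dynamic range),
the planted condition effect applied symmetrically in log space so total
abundance stays balanced, `b_s ~ N(0, batch_sd)` a multiplicative
per-sample batch factor and `ε_is ~ N(0, noise_sd)` residual noise. Each
cell is then censored by a Bernoulli draw from a logistic detection curve
`p = plogis(detection_slope · (log10 I − detection_midpoint))` —
missingness is left-censored and missing-not-at-random by construction.

Defaults mirror the study composition: 11,025 proteins, 3,934 membrane
(35.7%), 29 growth-factor receptors, 15 neurotrophic, 3 batches per
condition. Ten neurotrophic receptors are planted enriched in the induced
state at 16–64-fold (the five supplementable ones at the high end, since
deep proteomics finds them nearly iN-exclusive), FGFR1 is planted 8-fold
toward the pluripotent state, pluripotency/neuronal marker panels at
20-fold in their home state, and NTRK3 (TRKC) is generated about six
logistic units below the detection midpoint, so it is censored in both
states — the "undetected or too low for quantification" case. The
remaining numeric defaults (base 6 ± 1.2 log10 units of dynamic range,
batch and residual sd 0.15, detection midpoint 3.5 with slope 1.2, i.e.
roughly 2% of proteins heavily censored) are fixed, realistic choices for
deep label-free data and are not revisited per analysis.

Two structural choices make fixtures stable. The random stream has a
documented draw order — batch factors first, then per protein in index
order: offset, noise, detection uniforms, always drawn — so a fixed seed
gives byte-identical output and appending proteins never perturbs earlier
rows. And because the emulated receptor inventory is of receptors the
study *quantified*, receptor baseline abundances are clamped (not
redrawn) to stay above the detection region; the clamp is a no-op when
censoring is disabled.

What the generator does **not** emulate: peptide-level evidence and its
inference noise, correlated protein modules, ratio compression,
interference, or annotation errors. Passing tests therefore demonstrate
the correctness and calibration of the pipeline's statistics under its
own model, not the accuracy of any biological claim on real data; on real
tables the funnel counts depend on the annotation snapshot used.

## Numerical and design choices

- **Null calibration** is assessed with censoring disabled (detection
  probability 1): near the detection boundary the floor-imputed *t*
  statistic is discretely distributed, so the calibration check isolates
  the test itself, which under the generating model is exactly *t*
  distributed. Batch effects need not be disabled — normalization cancels
  them.
- **Problem sizes.** The study-scale analyses run at the full 11,025 ×
  6 matrix (seconds). Property tests use 300–5,000-protein simulations;
  the null-calibration check uses 5,000 proteins × 6 samples, the p-value
  oracle check 1,000 proteins, and the monotonicity properties 100
  randomized fixtures — sizes chosen to make binomial bounds and
  counterexample search meaningful at interactive runtimes.
- **Determinism.** All writers emit fixed column order, fixed row order
  (rank, then accession), 15-significant-digit numbers and binary-mode
  line endings, so reports are byte-stable and round-trip to better than
  1e-12 relative.
- **Duplicate accessions** in input tables are merged by summing (the
  protein-group reading) with a warning; accession is the primary key
  throughout, gene symbols are display-only.

## Known limitations

- Fold changes for one-sided detections are floor-limited lower bounds.
- The funnel counts on real exports inherit whatever membrane/receptor
  definition the annotation snapshot encodes; the rule file and curated
  list make that definition explicit but not universal.
- The pooled *t* assumes equal variances on the log scale; use
  `test = "welch"` when that is implausible and batches are ≥ 5.
- Ligand recommendation is an inventory-level heuristic: it knows nothing
  of receptor signaling competence, co-receptor requirements (RET is in
  the KB only through its GFRA partners) or dosage.
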
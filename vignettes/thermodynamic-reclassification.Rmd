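---
title: "Thermodynamic reclassification of CDKL5 missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic reclassification of CDKL5 missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdkl5ddg)
```

## The problem

CDKL5 deficiency disorder is a developmental and epileptic encephalopathy
caused by variants in the X-linked *CDKL5* kinase gene. Hundreds of
missense variants are reported in clinical databases, but most carry
ambiguous germline classifications ("uncertain significance",
"conflicting"), which blocks both genetic counselling and mechanism-guided
therapeutic design. The premise of this package is that pathogenicity in
CDKL5 is strongly linked to two thermodynamic quantities: the change in
folding free energy of the kinase upon substitution
(ddG\_folding, kcal/mol) and the change in binding free energy of the
kinase to its phosphorylation substrates (ddG\_binding, kcal/mol). Both
quantities can be predicted computationally by several independent tools,
and aggregated across tools they separate strictly annotated benign from
pathogenic variants cleanly enough to call the ambiguous ones.

## The statistics and the classifier

Per variant, the package computes two sign-blind aggregate statistics:

* **ddG\_Fmax** — the maximum of |ddG\_folding| across prediction methods
  (by default the five structure-based predictors: I-Mutant2.0, mCSM,
  INPS, DDMut, DDGun; the method subset is an argument so sequence-based
  runs are possible).
* **ddG\_Bmax** — for each modelled CDKL5–substrate complex (AMPH1,
  GATAD2A, SOX9, ZNF219), the mean of |ddG\_binding| over the methods
  that scored it; then the maximum of those complex averages.

Absolute values are essential: the binding predictors disagree on sign
convention (iSEE and SAAMBE-3D report dG\_mutant − dG\_wildtype, mCSM-PPI
and DDMutPPI the opposite), and |·| makes the aggregation invariant to any
per-method convention flip. `canonicalize_sign()` exists for *signed*
class summaries and reporting only; the aggregation itself never needs it.
This invariance is enforced by property tests.

The classifier is a one-dimensional midpoint rule. From the strictly
annotated variants only (original category exactly "benign" or
"pathogenic" — 4 and 9 kinase-domain variants, respectively), take the
largest benign and smallest pathogenic value of the statistic and place
the cutoff halfway between them:

* folding: (0.68 + 0.86) / 2 = **0.77 kcal/mol**
* binding: (0.82 + 0.95) / 2 = **0.885 kcal/mol**, displayed as 0.88.

Every variant with the statistic above the midpoint is called pathogenic;
at or below it, benign.

```{r thresholds}
model <- derive_threshold(
  c(a = 0.09, b = 0.68, c = 0.86, d = 3.42),
  c(a = "benign", b = "benign", c = "pathogenic", d = "pathogenic")
)
model
```

### Numerical choices

* **Boundary rule.** A value exactly at the midpoint is called *benign*.
  This is the conservative direction (fewer pathogenic calls) and is
  unobservable on realistic data, where the cutoff sits in a gap between
  the class supports.
* **Display rounding.** Thresholds are displayed truncated toward zero at
  two decimals (0.885 prints as 0.88); classification always uses the
  full-precision midpoint.
* **Non-separable training data** (largest benign ≥ smallest pathogenic)
  is a hard error: the model is flagged `separable = FALSE` and
  `classify()` refuses to run. We deliberately do not fall back to an
  ROC-optimal cut; a midpoint is only meaningful when the classes are
  disjoint on the training set.
* **Missing statistics** propagate as `unclassified` calls in
  `reclassify_variants()`, never as silently dropped rows; single-value
  helpers (`ddg_fmax()`, `ddg_bmax()`) treat an all-missing variant as an
  error.
* **Ties** in the contributing method/complex annotation break by name
  order; ties in AUROC scores use the standard mid-rank treatment.

## Curation model

Curation consumes heterogeneous delimited exports (a ClinVar-like table, a
population-panel-like table, a literature list), each with `variant`,
`consequence` and `classification` columns, and produces the non-redundant
analysis table:

1. keep rows whose consequence contains the `missense_variant` term
   (compound annotations such as `missense_variant|intron_variant` are
   retained by default);
2. deduplicate within each source and union across sources keyed on the
   protein-level change (ref, pos, alt) — nucleotide identity is out of
   scope because reclassification operates at protein level;
3. on category disagreement between sources, the ClinVar-sourced category
   wins (ClinVar is the clinical authority), otherwise first-seen; every
   disagreement is logged, none is fatal;
4. validate each record against the reference protein sequence and discard
   wild-type mismatches into an inspectable report;
5. annotate protein regions with 1-based inclusive intervals. Residue 302
   is *inside* the kinase domain (the curated kinase-domain lists include
   L302F).

Allele frequency is a pass-through column: absent values stay absent and
are never imputed. The eight germline categories are harmonized by an
explicit, punctuation-tolerant mapping; the several spellings of the
conflicting category collapse to one value.

## Motif scanning

CDKL5 phosphorylates substrates at the consensus motif RPX[S/T][A/G/P/S]
with the phosphoacceptor at the fourth slot and a roughly 85:15
serine:threonine preference. `scan_consensus()` reports *every* window
satisfying the position classes, including overlapping ones — which
window is the biologically relevant phosphosite is left to the consumer.
Display windows put the phosphoacceptor in lowercase; published windows
vary in printed length (12–15 residues), so the package standardizes on a
flank of 7 with silent truncation at the termini and treats the printed
windows as display substrings: comparisons against the published table
test the motif 5-mer, not the window length. The scanner is validated
against a brute-force oracle that tests every 5-mer of random sequences.

## What the synthetic-data generator emulates

The generator (`generator_config()` and the `generate_*()` functions)
stands in for every external input:

* **Variant tables** with exactly the published category tallies
  (kinase domain: 4, 1, 12, 30, 10, 22, 24, 9 summing to 112; full
  length: 20, 10, 15, 43, 13, 22, 24, 9 summing to 156), positions placed
  inside/outside residues 1–302 accordingly, and wild-type residues
  consistent with a generated reference sequence.
* **ddG tables** drawn as Normal(class mean, 0.5 kcal/mol) per method (and
  complex) on each method's native sign convention. The class means are
  the published per-method summaries; where a method's means were not
  published (DDMut and DDGun among the structure-based folding tools),
  the defaults are package-chosen values consistent with the published
  qualitative description (DDMut tracks mCSM/I-Mutant2.0; DDGun is
  neutral for benign variants). The 0.5 kcal/mol dispersion is a package
  choice — per-variant dispersions are not derivable from the published
  summaries — and is configurable.
* **Separable mode** rescales each variant's values so the per-variant
  statistics form disjoint class supports around a planted cutoff (0.77
  for folding, 0.885 for binding) with a 0.18 kcal/mol gap, mirroring the
  observed 0.68 → 0.86 training gap. One strictly annotated variant per
  class is pinned to the support edge so the derived midpoint reproduces
  the planted cutoff exactly.
* **Sequences** with motifs planted at recorded positions at the 85:15
  S/T ratio, over backgrounds rejected until motif-free, re-drawn until
  the scanner finds exactly the planted sites (recall and precision 1 by
  construction).
* **Source exports** with planted cross-source overlaps (four), a
  within-source duplicate, non-missense consequence rows, and exactly two
  reference mismatches, so curation reproduces the published arithmetic
  120 + 8 + 30 = 158 merged, 156 kept.

Mutant residues are drawn uniformly from the 19 alternatives — no
substitution-matrix weighting, because the analysis never uses one. A
single root seed drives independent per-stage substreams, so any stage can
be regenerated in isolation and a fixed seed yields byte-identical output.

What the generator does **not** emulate: inter-method correlation (real
predictors are correlated; generated methods are independent, which likely
understates the variance of the max statistics), position-dependent effect
sizes, allele-frequency structure, and every 3D-structural aspect of the
original workflow (homology modelling, docking, predictor internals are
consumed only as tabular values). Passing tests therefore demonstrate the
*bookkeeping and statistical machinery* on data with the assumed
structure, not predictive validity on real variants.

## Predictor evaluation

Third-party pathogenicity calls are scored two ways:

* **Binary-grouped accuracy**: categories collapse into a benign group
  (benign, benign/likely benign, likely benign) versus everything else; a
  "benign" prediction is correct only inside the benign group, a
  "pathogenic" prediction correct only outside it. This rule favours
  predictors that force ambiguous categories into pathogenic, and the
  published per-tool accuracies are not reproducible from published
  counts alone, so they are report-only comparisons here, never test
  assertions.
* **Label-flip-invariant metrics** for a continuous statistic:
  `auroc_sym = max(AUROC, 1 − AUROC)` and `mcc_sym = |MCC|` are the
  minimal symmetrizations that make the named metrics invariant under a
  global label complement; they are implementation-defined and flagged as
  such. Balanced accuracy is computed at the midpoint operating point
  (the classifier has exactly one), with the higher-scoring class
  predicted on the high side, which makes it flip-invariant too.

## Mechanism partition

Pathogenic variants split into folding-dominant
(ddG\_Fmax > ddG\_Bmax — candidates for stability-enhancing drugs) and
binding-dominant (ddG\_Fmax ≤ ddG\_Bmax — candidates for
binding-restoring drugs); boundary equality goes to binding-dominant. On
the published kinase-domain lists this yields 86 and 17 variants. The
folding and binding reclassifications produce different pathogenic sets
(98 versus 80 in the published run); which combination fed the published
partition of 103 is not stated, so `partition_mechanism()` takes whatever
pathogenic set the caller supplies — by convention the folding-call set —
and the published lists ship as a dataset for bookkeeping checks.

## Problem sizes and test design

The test suite regenerates all fixtures in code: category-tally tables at
their natural sizes (112 and 156 variants), mean-recovery checks at 500
variants per class with a 3-standard-error tolerance, scanner/oracle
equivalence on 200 random sequences up to length 200, and planted-motif
recovery on a few hundred sites. These sizes put every statistical check
well inside its tolerance while keeping the whole suite around a minute on
one CPU. The acceptance script re-derives the published thresholds,
curation arithmetic, tallies, mechanism counts and motif-scan results from
package code at the same sizes.

## Known limitations

* The two variants that failed reference validation in the original
  curation are not identified in the published account; the discard
  report makes the equivalent synthetic step inspectable, but no real
  ground truth exists.
* Whether the published tallies used primary or review-status-filtered
  ClinVar categories is unstated; the harmonization here treats the
  printed tallies as authoritative.
* The package does not implement ACMG/AMP criterion combination; calls
  carry a free-text computational-evidence tag only.
* Nothing here runs a ddG predictor, builds a structure, or queries a
  live database: predictions enter as tables, sequences as FASTA.
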
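---
title: "IHC/FISH-based subclassification of glioblastoma: methods and design"
author: "gbmsub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IHC/FISH-based subclassification of glioblastoma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmsub)
```

# Background and model

Transcriptional profiling of glioblastoma (GBM) consistently distinguishes
a Proneural (PN) and a Mesenchymal (MES) signature, with a Classical (CLAS)
signature driven by EGFR alterations also widely reported. Array-based
subtyping is costly and averages over the cellular heterogeneity of a
tumor, so this package implements an alternative that uses only standard
pathology laboratory readouts: semi-quantitative immunohistochemistry (IHC)
on tissue-microarray (TMA) cores and a dual-probe EGFR/CEP7 FISH assay.

The workflow has five stages, each exposed as ordinary functions over a
`GBMCohort` container (a `SummarizedExperiment` with markers as rows,
tumors as columns, and the marker registry in `rowData`):

1. per-core scoring and per-tumor aggregation (`aggregateMarker`,
   `aggregateCohort`, `callEgfrFish`, `proliferationIndex`);
2. unsupervised biclustering of the standardized score matrix
   (`standardizeMatrix`, `pruneMarkers`, `clusterCohort`);
3. the PN/MES index (`pnmesIndex`, `indexDistributionReport`);
4. the ordered three-step subclass assignment (`assignSubclass`,
   `summarizeAssignments`, `orderSensitivity`);
5. the 9-gene qRT-PCR metagene (`deltaCt`, `metageneScores`).

# Scoring schemes and aggregation

Six scoring schemes cover the 24-marker panel (23 proteins + EGFR FISH);
the registry (`defaultMarkerRegistry()`) records each marker's scheme,
pre-designated subclass, and whether it reflects a genetic abnormality.

| scheme | levels | aggregation |
|---|---|---|
| binary_alteration | 0, 1 | single consensus call |
| quartile_0to3 | 0–3 (positive-cell quartiles) | mean of cores |
| triad_0to2 | 0 negative / 1 mixed / 2 positive | mean of cores |
| quad_intensity_0to3 | 0–3 (intensity/extent) | mean of cores |
| basal_1to2 | 1 basal / 2 diffuse intense | mean of cores |
| proliferation_fraction | [0, 1] | mean of per-core fractions |

Each tumor contributes 4 TMA cores. Alteration markers (IDH1 R132H, EGFR,
EGFRvIII) are expected to be consistent across cores and receive a single
consensus call. Observed cohorts were perfectly consistent, so no
disagreement rule is published; our rule is majority vote, with exact ties
resolved **toward the altered state**, and every disagreement is flagged
`INCONSISTENT_CONSENSUS` — alteration detection errs on the side of
sensitivity but never silently. Missing cores are tolerated (mean over
available cores, `LOW_CORE_COUNT` under 2 cores); TMA punch loss is common
and no published handling rule exists.

FISH calls pool signal counts over all cores (tumor ratio = total EGFR /
total CEP7, positive iff ≥ 2, boundary inclusive). Pooling rather than
averaging per-core ratios is robust to low-count cores and matches the
tumor-level phrasing of the adopted criterion; the per-core alternative is
not published in enough detail to prefer it.

# Biclustering

## Standardization

Before clustering, every non-genetic marker is min–max scaled **by its
scheme's theoretical range**, not the observed range: scheme-based scaling
is data-independent, so the same tumor gets the same standardized profile
in any cohort. Markers reflecting genetic abnormalities (IDH1 R132H, EGFR,
EGFRvIII, EGFR FISH) pass through as 0/1.

## Similarity and linkage

Similarity is Kendall's tau-b. The tie-corrected variant is a deliberate
choice: semi-quantitative scores are heavily tied, and the uncorrected
tau-a shrinks toward zero under ties. Tau-b is undefined when either
vector is constant (its denominator vanishes); such items must be pruned
first (filter 1 below guarantees this for markers), and `averageLinkage()`
refuses to guess, aborting with the offending pairs.

Dissimilarity is d = (1 − τ)/2, mapping τ = 1 to 0 and τ = −1 to 1; the
transform used by the original analysis software is undocumented, so we fix
this one. Trees are unweighted average linkage (UPGMA) with deterministic
tie-breaking (lexicographically smallest pair of original item indices) and
a reproducible leaf order (tighter subtree first, ties by smallest label).
The implementation uses Lance–Williams updates and is tested against a
brute-force agglomerator that recomputes every inter-cluster mean from the
original matrix, and against `stats::hclust`. Because the reference
software's exact tau variant and transform are unknown, published trees can
only be matched structurally, never bit-for-bit.

## Marker pruning

Markers without discriminating power are removed in three recorded,
sequential filters (`pruneMarkers()`):

1. **differential staining** — minor-category frequency below
   `minMinorFreq` (default 0.02). The default must sit *below* the ~5%
   cohort prevalence of IDH1 R132H (a real, retained marker) while catching
   effectively constant stains (the DLL3 case, which additionally ships
   registry-excluded).
2. **designation concordance** — the marker dendrogram is cut into
   `markerK` groups (default 4, roughly one per subclass signature); a
   marker whose co-members never share its designated subclass is removed
   (the published FN1/NES/p53/PDGFR-α removals are of this kind).
3. **high-expression group** — tumors are clustered into `tumorK`
   preliminary groups (default 3); a marker is removed when no group's mean
   exceeds the outside mean by `margin` (default 0.1). Filters 2–3 iterate
   to a fixed point, mirroring repeated clustering attempts (the published
   second pass removed NF1 and STAT3 this way).

Genetic markers are exempt from filters 2 and 3: in the published final
panel all four are retained and IDH1 R132H stands as the *only*
PN-designated marker — a singleton that any concordance rule would
otherwise discard — and every published pruning casualty is an expression
marker. They remain subject to filter 1, since a constant marker breaks the
similarity computation.

## Cut and labels

The tumor tree is cut at `k = 3` by default (the three reported expression
patterns; the published choice was made by reading the heatmap, so `k` is a
parameter). Each cluster is labelled with the subclass whose designated
markers are most enriched (mean standardized score inside minus outside),
if that enrichment exceeds `threshold` (default 0.25, i.e. a quarter of the
standardized range — the published labelling was done by eye, so this too
is a parameter).

# The PN/MES index

The five index markers recode linearly from their scheme ranges onto the
stated target ranges, applied to per-core means so fractional scores recode
continuously:

* IDH1 R132H (0/1 consensus) → {0, 1.5}; p53 (0–2 triad) → ×0.75;
* PTEN, VIM (0–2 triads) → ×0.5; YKL40 (1–2 basal) → −1.

Only the target ranges (0–1.5 for PN, 0–1 for MES) and the "maximum total
score of 3" constraint are published; the recoding legend itself is in a
figure that is not machine-readable, and the linear map is the simplest
rule consistent with both facts. Exhaustive enumeration over the scheme
values confirms max PN total = max MES total = 3. The index is PN total −
MES total ∈ [−3, 3]; classification is strict (PN iff > 1, MES iff < −1),
verified at the boundaries ±1 ± ε. One published count (3 PN + 75 MES + 44
unassigned = 122 of 123) does not conserve the cohort size; our report
enforces conservation and therefore cannot reproduce that arithmetic.

# Three-step assignment

`assignSubclass()` evaluates, strictly in order: (1) IDH1 R132H positive →
PN; (2) EGFR IHC score 1 ("diffuse high expression") → CLAS; (3) at least
two of PTEN/VIM/YKL40 "high" → MES; otherwise UNCLASSIFIED. Design
choices:

* **"High EGFR expression" is the binary IHC score only.** Amplification
  and EGFRvIII are reported as aligned flags but do not enter the decision:
  the published scheme names EGFR expression alone, and 43 of 49 amplified
  tumors were IHC-positive anyway. Whether amplification without
  overexpression should rescue a CLAS call is left open by the source and
  by us.
* **MES "high" = recoded score ≥ 0.75** (config-overridable, boundary
  inclusive): a core majority at the top scoring category.
* **Percentages round half away from zero.** The published validation
  "Other" rate (31%) is inconsistent with its own count (14/44 → 32%); we
  report the computed value.

The order is load-bearing: PN features are mutually exclusive with the
others, but MES markers co-occur in CLAS tumors, so evaluating MES before
CLAS flips exactly the EGFR-high tumors with ≥ 2 high MES markers —
`orderSensitivity()` verifies this set identity.

# qRT-PCR metagene

ΔCt = replicate-mean gene Ct − replicate-mean RPS27 Ct, per sample. Group
fold ratios use ΔΔCt exponentiation at assumed 100% efficiency (the
published computation is unstated), with the two-group comparison delegated
to the Wilcoxon rank-sum test. The metagene averages the *inverse* ΔCt
over the 4 PN genes and over the 4 MES genes, Z-corrects each signature
mean across samples, and subtracts PN from MES. "Inverse" is genuinely
ambiguous; we implement **negation** (monotone in log2 expression,
continuous through ΔCt = 0) with `inverse = "reciprocal"` as a switch.
Whether the Z-correction was per gene or per signature mean is also
unstated; we Z-score the signature means, with `zMode = "per_gene"` as the
alternative. Both variants preserve sample ordering on the synthetic test
bed.

# Synthetic data

## Generator

`generateCohort()` draws each tumor's subclass from configurable
proportions (default 0.05/0.42/0.15/0.38 PN/CLAS/MES/other, the training
assignment rates), then per-core scores from per-subclass categorical
emission distributions, with 4 cores per tumor. Consensus markers are
drawn once per tumor; `core_noise` (default 0.05) independently bumps each
core by one category, which is the sole source of inconsistent consensus
calls and fractional means. Defining markers are emitted
deterministically at their characteristic category (IDH1 for PN, EGFR for
CLAS, VIM + YKL40 for MES) and secondary markers carry roughly 80% mass on
the characteristic category, so noise-free cohorts are perfectly separable
— a documented idealization chosen for recovery testing, not a claim about
real cohorts. PN tumors structurally emit no EGFR features and no high-MES
combinations (mutual exclusivity); CLAS tumors emit high MES markers with
appreciable probability, because MES co-expression in CLAS tumors is
common. Every tumor draws from its own seeded substream, so cohorts are
reproducible and stable under subsetting. `generateQpcr()` analogously
emits triplicate Ct values with a programmed group separation (default 2
cycles) and replicate noise (default sd 0.2).

What the generator does *not* emulate: staining-batch effects, observer
disagreement, intratumoral heterogeneity beyond one-category core noise,
correlated marker noise, or tumors with genuinely mixed dominant
signatures. Passing recovery tests therefore demonstrates correctness of
the pipeline's logic under the stated statistical structure, not expected
performance on real cohorts.

## Deterministic fixtures

Two fixtures rebuild the published cohorts from their printed marginals.
The joint feature distribution is underdetermined by the marginals; each
fixture adopts the unique configuration consistent with the printed
per-subclass assignment counts, specifically:

* **Validation (44 tumors):** 2 IDH1-positive (no other features), 21
  EGFR-high (1 EGFRvIII-positive), 16 tumors with ≥ 2 high MES markers of
  which 9 overlap the EGFR-high set and none the IDH1 set — leaving 7 MES
  calls and 14 unclassified.
* **Training (123 tumors):** blocks of 52 CLAS / 6 PN / 18 MES / 47
  feature-poor. All 52 CLAS-block tumors are EGFR-high: the published
  cohort marginal is 51/123, but cluster-level assignment counts
  (52 CLAS calls) require 52, and the fixture serves the assignment
  arithmetic. The 24 EGFRvIII-positive tumors nest inside the 43 amplified
  (published overlap: 23 of 24; the joint table is unpublished).
  Feature-poor tumors carry mild GFAP/MET staining so that no tumor
  profile is constant over the retained marker panel (tau-b would be
  undefined) — they attach to the MES-labelled cluster at k = 3, as some
  cluster must absorb them.

# Problem sizes and numerical choices

The test suite checks tau-b exhaustively against an all-pairs oracle for
every pair of vectors over a 3-letter alphabet up to length 4, plus
randomized coverage at lengths 5–8; average linkage against the
brute-force agglomerator on 1000 random instances of up to 8 items;
recovery and property suites use cohorts of 30–1000 tumors and 50–100
seeds — sizes chosen so each suite is a complete, fast check of the
property concerned. Z-columns are verified to mean 0 / sd 1 within 1e-9;
tau and linkage agreement within 1e-12. Ties in linkage are broken
deterministically as described; equal-height leaf ordering falls back to
lexicographic labels.

# Known limitations

* Published dendrograms cannot be reproduced bit-for-bit (unknown tau
  variant and similarity transform in the original software).
* The recoding legend, the FISH per-core convention, the metagene
  "inverse" and the Z-correction axis are each underdetermined by the
  source; every choice is documented above and config-exposed where
  reasonable.
* Neural and Proliferative subclasses are out of scope (not detected as
  distinct classes in the source analysis), as are survival analysis and
  any image-level processing.
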
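---
title: "Decision-tree diagnosis of Parkinsonian syndromes from DAT SPECT and MIBG indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree diagnosis of Parkinsonian syndromes from DAT SPECT and MIBG indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkcart)
```

## The diagnostic problem

Differentiating Parkinson's disease (PD) from dementia with Lewy bodies
(DLB), progressive supranuclear palsy (PSP), multiple system atrophy (MSA)
and non-Parkinsonian presentations (NPS) is difficult clinically, but two
nuclear-medicine studies probe complementary systems: dopamine-transporter
(DAT) SPECT images striatal presynaptic dopaminergic integrity, and cardiac
^123^I-MIBG scintigraphy images postganglionic sympathetic innervation.
`parkcart` implements a complete, testable version of a strategy that
reduces each patient to six quantitative indices and classifies them with a
binary decision tree.

The six indices, and their defining formulas as implemented:

* **SBR** (striatal binding ratio): `(S - O) / O`, the background-subtracted
  whole-striatum VOI mean `S` over the occipital reference VOI mean `O`,
  computed per side; the *smaller* side is reported. Note some tools report
  the raw ratio `S / O`; this convention is that ratio minus one.
* **PCR** (putamen-to-caudate ratio): putamen VOI mean over caudate VOI
  mean per side, smaller side reported.
* **AI** (asymmetry index): `|SBR_L - SBR_R| / mean(SBR_L, SBR_R)`, a
  fraction (not percent).
* **H/M (Early)**, **H/M (Delay)**: heart-ROI count density over
  mediastinal-ROI count density on the early (~15 min) and delayed (~3 h)
  planar images.
* **WR** (washout rate, percent):
  `100 * ((He - Me) - (Hd - Md)/k) / (He - Me)`, where `k` is the physical
  decay coefficient between the two acquisitions. The source description
  leaves the value of `k` unstated; the package computes it from the
  acquisition schedule and isotope half-life,
  `k = 2^(-(t_d - t_e)/T_half) = 2^(-2.75/13.2232) ≈ 0.866` for the
  15-min/3-h ^123^I schedule, and every entry point accepts an override.

Per-side SBR uses the voxel-weighted union mean of the caudate and putamen
VOIs (whole-striatum convention); whether the original VOI software instead
averages sub-region SBRs is not documented, so the union mean is the
package's documented choice.

## Synthetic cohorts

No per-patient data accompany the source cohort, so the package ships a
seeded generator whose defaults encode the published marginal summary of
the 216-patient cohort: five groups (NPS 80, PD 90, DLB 21, PSP 16, MSA 9)
with per-group mean and SD for each of the six indices. Each index is drawn
from a normal distribution truncated to physiologically plausible bounds
(H/M in [0.5, 6], WR in [-30, 100] %, SBR in [-0.5, 8], PCR in [0.05, 2.5],
AI in [0, 1.5]); the published group means sit well inside these bounds, so
truncation only removes implausible tails, and `truncated_normal_mean()`
gives the exact mean the sample marginals converge to. Sampling is
inverse-CDF on copula uniforms, making cohorts bit-reproducible under a
seed. The SDs are treated as pure between-patient variation (the summary
does not separate measurement replication).

Because only marginal moments are published, indices are independent by
default: the generator refuses to invent a covariance structure, though a
Gaussian copula with a user-supplied correlation matrix is available for
sensitivity analyses. This is the single most important limitation to keep
in mind when reading test results. Real DAT and MIBG indices are strongly
dependent within patients, and that dependence is exactly what made the
putamen-to-caudate ratio the dominant first split in the source cohort.
On independent marginals the SBR alone separates NPS (mean 2.13) from
every PS group (means 1.01–1.24), so trees fitted to default synthetic
cohorts split on SBR first and give it the bulk of the Gini importance.
Passing tests on these cohorts therefore validate the *machinery*
(growth, pruning, selection, metrics), not the claim that marginal-only
simulation reproduces the published tree shape, importance profile or
per-class performance — it demonstrably does not, and the test suite
records that honestly rather than tuning the generator toward the
published numbers.

Image-level fixtures follow the same philosophy. `generate_spect_phantom()`
builds a 64³ volume (4.4 mm voxels) with ellipsoidal caudate/putamen
compartments, a cuboid occipital slab and a jointly generated VOI label
map; `generate_planar_pair()` builds 128×128 early/delayed chest images
with circular cardiac and rectangular mediastinal ROIs. Configured uptakes
are exact voxel values, so the implied indices are known analytically and
noise-free quantification must round-trip them to ≤ 1e-9 relative error.
Noise is additive Gaussian clipped at zero (Poisson available behind a
flag). These phantoms deliberately omit attenuation, scatter, collimator
blur, reconstruction and template registration: they exercise VOI/ROI
arithmetic, not SPECT physics.

## The CART engine

Tree derivation is implemented from scratch and checked against exhaustive
enumeration:

* **Growth.** Gini impurity `1 - sum(p^2)`; candidate thresholds at
  midpoints between consecutive distinct sorted values; routing is
  "value ≤ threshold goes left". Splits maximize the weighted impurity
  decrease; scores are computed as `SS_L/n_L + SS_R/n_R` (sums of squared
  class counts over child sizes), a form whose comparisons are exact for
  integer counts, so tie-breaking — first by the fixed feature order
  H/M(Early), H/M(Delay), WR, SBR, PCR, AI, then by the smallest
  threshold, then by class-label order for leaf majorities — is fully
  deterministic and reproducible by an independent implementation.
  Defaults `minsplit = 20`, `minbucket = 7`, `max_depth = 30` are the
  conventional recursive-partitioning controls (the source names none);
  all are configurable.
* **Pruning.** Weakest-link cost-complexity pruning on misclassification
  counts. Link strengths `g(t) = (R(t) - R(T_t)) / (|leaves| - 1)` are kept
  as exact integer ratios and compared by cross-multiplication; all nodes
  achieving the minimum collapse simultaneously, which makes the reported
  alphas strictly increasing. The alpha = 0 entry is the smallest subtree
  attaining the full tree's resubstitution error (zero-gain links are
  collapsed first). Alphas and errors are reported relative to the
  root-stump error, so the stump has relative error 1.
* **Cross-validation.** Stratified, seeded k-fold (default 10). Each fold
  is grown and pruned with the same controls; the subtree evaluated at
  each master-path position is the fold subtree optimal at the geometric
  mean of adjacent master alphas. `xerror` is the pooled held-out
  misclassification count on the root-error scale; `xstd` is its binomial
  standard error `sqrt(E(n-E)/n) / R_root` — the exact estimator behind
  the published software's standard error is undocumented, so the package
  states and tests this one.
* **Min-1SE selection.** The smallest subtree (largest alpha) whose
  `xerror` does not exceed `min(xerror) + xstd` at the minimum.
* **Importance.** Per feature, the sum over its split nodes of the node's
  weighted Gini decrease times the fraction of training rows reaching the
  node, normalized to sum to one; a stump yields an all-zero, flagged
  table.

Class priors are the empirical frequencies and misclassification costs are
uniform. Surrogate splits and missing-value handling are out of scope.

## The published fixed tree

`published_tree()` encodes the reported four-cutoff classifier: PCR 0.81 at
the root, then WR 44.55 on the PCR-high side (NPS vs DLB) and H/M(Delay)
2.26 / SBR 0.91 on the PCR-low side (PD vs PSP). Cutoffs are compared
verbatim at two decimals with the "≤ goes left" convention, so a value
exactly at a cutoff takes the low branch. MSA is never an output label.
The published figure's terminal-node graphics are not machine-readable, so
one leaf is a documented reconstruction: the residual leaf (PCR ≤ 0.81,
H/M(Delay) > 2.26, SBR > 0.91) is assigned PD, which is the only
assignment consistent with the published prediction totals (the PD column
denominator 109 is the largest, and PSP sensitivity of 8/16 requires
PSP cases with SBR > 0.91 to fall in a non-PSP leaf). The whole topology
can be replaced from a JSON file for readers who reconstruct it
differently.

## Evaluation

`diagnostic_metrics()` computes one-vs-rest TP/FP/FN/TN per class and the
five standard percentages; zero-denominator metrics are `NA` (undefined),
never 0, and classes the classifier cannot emit are flagged rather than
dropped. Display rounding is half-away-from-zero to one decimal; full
precision is kept internally. Group differences use the Kruskal-Wallis
test (via `stats::kruskal.test`) with, as post hoc, Dunn's rank-based
z-tests over all 10 unordered group pairs, Bonferroni-multiplied and
capped at 1; pairwise Wilcoxon rank-sum tests are available behind a flag
because the source names only "post hoc analysis with Bonferroni
correction" and either reading is defensible.

## Orchestration and reproducibility

`run_pipeline()` is the package's end-to-end entry point (simulate →
classify or fit → evaluate → report) and writes every artifact — cohort
CSV, tree JSON/DOT, pruning-path and importance tables, metrics CSV,
statistics JSON and a manifest with the resolved configuration — to an
output directory; runs with identical manifests are byte-identical. A
single run seed is fanned out into fixed per-stage child seeds so stages
are independently reproducible, and every generator restores the caller's
RNG state. A YAML configuration file can stand in for arguments. The
pipeline is exposed as R functions rather than a shell binary: the
package's users drive it from R scripts, as with any analysis package.

## Problem sizes used by the test suite

The suite validates the engine with: 100 random small instances (n ≤ 60,
≤ 4 features, deliberately discretized values to force ties) compared
split-for-split and alpha-for-alpha against brute-force enumeration of
splits and of all pruned subtrees; 25 seeded default cohorts (216 rows,
10-fold CV) for the importance-profile measurement; 200 null simulations
(5 × 50 rows) for the omnibus test's size; and 100 seeded cohorts for the
post hoc separation rates. These sizes give stable Monte-Carlo estimates
for the properties asserted while keeping the default run quick; they are
the package's chosen study conditions, stated here so results are
interpretable.

## Known limitations

* Independent-marginal cohorts cannot reproduce conditional structure:
  fitted-tree topology, importance profiles and per-class performance on
  synthetic cohorts must not be read as reproductions of the published
  clinical results.
* Phantoms are arithmetic fixtures, not physical simulations.
* The residual leaf of the fixed tree is a reconstruction (overridable),
  not a verbatim published fact.
* Regression trees, surrogate splits, random forests and ROC analysis are
  out of scope.
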
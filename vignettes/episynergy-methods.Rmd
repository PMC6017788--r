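---
title: "Methods: from case-control epistasis to drug-combination candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from case-control epistasis to drug-combination candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episynergy)
```

## Overview

`episynergy` turns case-control genotypes into ranked drug-combination
candidates. The chain is: SNP quality control, exhaustive pairwise
interaction testing, SNP-to-gene mapping, construction of druggable target
pairs and predicted drug pairs, enrichment testing against a combination
database, filtration by a gene co-opening network, and — for experimental
follow-up — Chou–Talalay combination-index analysis of dose-response data.
This vignette records the models, the tunable parameters, the numerical
choices, and the limits of what the synthetic generators demonstrate.

## Quality control

Four SNP-level filters are applied in fixed order, each removal attributed
to the first filter failed:

| filter       | statistic                               | default  |
|--------------|-----------------------------------------|----------|
| missingness  | missing calls / samples                 | `< 0.1`  |
| MAF          | folded minor-allele frequency           | `> 0.05` |
| HWE          | exact conditional test p                | `> 0.001`|
| LD           | pairwise dosage r², windowed greedy     | `< 0.8`  |

Decisions that were genuinely open:

* **HWE on controls only** (configurable to all samples). Deviation from
  Hardy–Weinberg among cases can be a disease signal; testing controls
  avoids discarding it. The exact test enumerates heterozygote counts
  conditional on allele counts, in log space, summing outcomes no more
  probable than the observed one.
* **LD pruning** is greedy and windowed (window 50 SNPs, step 5), keeping
  the earlier SNP in map order of any pair with r² at or above threshold.
  Full all-pairs pruning is available by setting the window to the panel
  size. r² is the squared Pearson correlation of dosages
  (composite LD): phase-free and well defined under missingness.

## Interaction tests

Both tests operate on the 2×3×3 phenotype × genotype contingency cube, the
sufficient statistic for a pair, and are fitted by iteratively reweighted
least squares on the grouped (cell-level) data to a relative
log-likelihood tolerance of 1e-13 (at most 200 iterations; grouped fits
converge in well under ten).

* `genotype_lrt4`: deviance of `phenotype ~ factor(gA) + factor(gB)`
  against the saturated 3×3 model, referred to χ² with 4 df. Structurally
  empty cells reduce the degrees of freedom one-for-one
  (`collapse_df`, the default); alternatively `require_n` flags pairs
  with any cell below a minimum count. Negative deviances beyond −1e-8
  are treated as numerical failure, smaller ones clamped to zero.
* `dosage_interaction1`: Wald χ²₁ for the product term in
  `logit P(case) = β0 + β1 gA + β2 gB + β3 gA gB`. Collinear columns are
  dropped by QR pivoting; if the product column itself is collinear, or
  coefficients diverge (|β| > 30, a separation heuristic), the pair is
  flagged with `p = NaN` rather than silently dropped.

The scan is exhaustive over all C(m, 2) pairs with no screening
heuristics, so results are exactly reproducible and order-independent.
Following common practice in pairwise interaction scans, significance is a
fixed threshold (`alpha = 1e-5` by default) rather than a formal
multiple-testing correction; Bonferroni can be imposed by setting
`alpha = 0.05 / choose(m, 2)`.

## From SNP pairs to drug combinations

* **SNP-to-gene**: a SNP maps to every gene whose interval, extended by
  `flankBp` on both sides, contains it. The default flank of 20 kb is a
  deliberate, reported assumption — proximity rules in the literature vary
  — and overlapping genes all receive the SNP.
* **Gene pairs** are the cross product of the two SNPs' gene sets,
  same-gene pairs discarded, duplicates merged keeping the minimum p and
  counting supporting SNP pairs. All unordered pairs in the package are
  canonical (lexicographically smaller member first), which makes every
  downstream set independent of input row order.
* **Target pairs** keep gene pairs whose both members have at least one
  drug. **Predicted combinations** are all cross-set drug pairs with the
  two drugs distinct; a drug targeting both genes may pair with partners
  of either gene but never with itself.
* **Database matching** uses subset semantics — a predicted pair matches a
  record containing both drugs among its components, even if the record
  has more than two — because multi-component records genuinely contain
  the predicted pair. Exact-two matching is available by flag. Disease
  labels are compared after normalization (case-fold, whitespace
  collapse) plus an optional user synonym table; no terminology service
  is consulted.

## Enrichment and the permutation null

The hypergeometric upper tail `P(X ≥ k)` is summed in log space from exact
`lchoose` terms, preserving relative precision down to ~1e-300. The
background `(K, N)` is always an explicit argument: the analyses this
package supports use different backgrounds (whole database vs. an
upstream matched set), and inferring one silently would invite mistakes.

The permutation null asks whether the number of distinct "success" drugs
(e.g. clinically active for the disease) hitting the observed target pairs
exceeds what random target pairing produces. Each of B (default 10,000)
permutations draws the same number of distinct unordered gene pairs
uniformly from the druggable-gene universe; a drug hits a drawn pair when
it targets at least one member. Uniform pair resampling was chosen as the
cleanest reading of "random target combinations"; the empirical p uses
the add-one estimator `(1 + #{perm ≥ obs})/(1 + B)`, so it is never zero
and with B = 10,000 a maximal observed statistic reports `1/10001 < 1e-4`.

## Network filtration

Filtration retains exactly the target pairs whose gene pair is an edge of
the co-opening network — strict membership, no path-distance relaxation,
and genes absent from the network remove their pairs. This is the
interpretation under which filtration is a sharp precision filter; the
coverage of input genes by the network is reported so an aggressive
removal is visible. The network is consumed as an edge list; building it
from chromatin accessibility data is upstream of this package.

## Median-effect and combination-index analysis

Single agents and fixed-ratio mixtures are fitted by ordinary least
squares on the linearized median-effect equation
`log10(fa/fu) = m log10(D) − m log10(Dm)`. Points with `fa` outside the
open unit interval carry no information about the line and are excluded
(with a logged count) rather than clipped, which would bias the slope.
The combination index at effect level `fa` is the mutually exclusive form
`CI = d1/Dx1 + d2/Dx2` (the classic two-term index); the non-exclusive
variant adds `(d1 d2)/(Dx1 Dx2)` and is optional. CI is reported at
`fa = 0.5` by default — the median effect, where `Dx = Dm` exactly — and
over a grid via `ciCurve()`. Classification is strict: CI < 1
synergistic, CI = 1 additive (an optional tolerance widens the additive
band), CI > 1 antagonistic. Note that some published tables invert this
convention in footnotes; this package follows the standard
Chou–Talalay reading (CI < 1 = synergism) throughout.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their scenario (including the seed).

**Genotypes** (`simulateGenotypes`). A prospective population is simulated
— per-SNP Hardy–Weinberg genotypes at MAFs uniform in `mafRange`, disease
from `logit P(case) = α + Σ β_main g + Σ β_int g_i g_j` — and cases and
controls are then sampled retrospectively until the requested counts are
reached, with α calibrated by bisection on a pilot population so the
prevalence matches the target case fraction. The retrospective route was
chosen over the shortcut of sampling genotypes given status because it
keeps the logistic model exactly correct for the tests under study. Main
effects default to zero so planted signal is unambiguously epistatic.
There is no effect-size information for real epistatic pairs in this
disease; the planted `β_int = ln 3` used in tests is the implementer's
choice of a moderate, detectable interaction at n = 2000.

**Drug universe** (`simulateDrugUniverse`). Genes are tiled without
overlap on synthetic chromosomes; each drug targets ≥ 1 gene (count ~ 1 +
geometric(0.3)); combinations are random drug pairs; a disease-gene subset
is drawn; network edges appear with probability `networkEdgeProb`,
multiplied by `diseasePairEdgeBoost` between disease genes. Two planted
correlations carry the signal the pipeline is designed to detect: the
network is denser among disease genes, and disease-indicated
("active") combinations are sampled preferentially (weight 20 : 1) from
combinations whose both drugs target disease genes. The second is a
deliberate design choice: with indications assigned independently of
targets, network filtration could not enrich for active combinations even
in expectation, and the directional property the package tests would be
vacuous. Default sizes (150 genes, 80 drugs, 400 combinations, 15%
active) are desk-scale stand-ins chosen so matched sets after filtration
are populated enough for ratios to be meaningful.

**Dose-response** (`simulateDoseResponse`). Single agents follow the
median-effect model exactly; the mixture follows a median-effect curve
with slope the mean of the component slopes and `Dm` solved in closed
form so the CI at `fa = 0.5` equals `targetCi`. The mean-slope rule is a
smooth arbitrary choice — any generative mixture curve consistent with the
target CI would do, since CI is computed from fitted curves — and is
recorded here so it is not mistaken for a pharmacological claim.

**What passing tests show.** The generators have no linkage
disequilibrium structure, no population stratification, no genotyping
batch effects, and drug-target and indication tables without curation
noise. Tests on them validate the statistical machinery — calibration,
power against planted effects, bookkeeping exactness — not performance on
real cohorts, where LD, stratification and annotation error all matter.

## Problem sizes and runtime choices

The test suite exercises the scans at 200 SNPs × 2000 samples (19,900
pairs) for type-I calibration, 50 SNPs × 2000 samples across 20 seeds for
power, 20 replicate universes for the filtration trend, and 200 replicate
dose-response fits for parameter recovery; these sizes give stable Monte
Carlo estimates (3-SE bands on binomial fractions) while keeping a full
run in the low minutes on one CPU. The exhaustive scan is O(m²) in SNPs
with a small per-pair cost via the contingency-cube route; genome-scale
panels (~5×10⁵ SNPs) are out of scope for this implementation, which
targets method development and desk-scale reanalysis.

## Known limitations

* Interaction tests carry no covariates; stratification must be handled
  upstream.
* The χ² reference for the 4-df LRT needs adequately filled cells; at very
  low MAF or small n, use `require_n` or the 1-df dosage test.
* Disease-label matching is lexical (plus synonym table); free-text
  indication vocabularies need curation before use.
* Exact reproduction of published combination-index values requires the
  underlying dose-response measurements; this package reproduces the
  mathematics and classification rule, and validates them on generative
  data where the true CI is known by construction.
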
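---
title: "Detecting miRNA-mRNA paired variations: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting miRNA-mRNA paired variations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpv)
```

## The statistical model

An MMPV (miRNA-mRNA paired variation) is a validated targeting pair
whose regulatory pattern — the Pearson correlation between the miRNA and
mRNA expression rows — differs between the two statuses of a binary
biopathological feature. The detection procedure for one feature is:

1. **Per-stratum correlation.** For each pair, split the samples by
   status and compute the pairwise-complete Pearson correlation in each
   stratum. Pairwise-complete handling maximises the usable sample count:
   a sample is excluded for a pair and stratum only when either member is
   missing there. Significance is the exact test under bivariate
   normality, `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of
   freedom, two-sided; `r = ±1` is assigned `p = 0` as the degenerate
   limit. q-values are Benjamini-Hochberg adjusted **per feature per
   stratum** across all retained pairs: each stratum's correlations form
   one family of simultaneous tests, so its FDR is controlled within
   that family rather than pooled across strata.

2. **Removal of doubly insignificant pairs.** A pair with
   `q1 >= alpha` and `q2 >= alpha` carries no reliable regulatory signal
   in either status and is classified `none` before the change rules are
   consulted.

3. **Classification.** Opposite algebraic signs of `r1` and `r2` give a
   *sign-change* pair. Equal nonzero signs with the between-stratum ratio
   `r1/r2 >= fold` or `<= 1/fold` give a *fold-change* pair. The ratio is
   taken between the two condition correlations: no healthy-population
   expression data exist in the intended workflow, so a ratio "to the
   normal" is not computable, and the condition-to-condition ratio is the
   declared reading (this is the one genuinely interpretive step in the
   pipeline and is worth restating in any report built on it).
   An exact zero correlation is a measure-zero event that still needs a
   total decision rule: one zero against a nonzero partner counts as an
   infinite ratio (fold change), two zeros give `none`, and pattern
   encoding writes a zero as `U` with a logged tie warning.

4. **Pattern encoding.** `H_S1_S2`, where `H` is the healthy-population
   sign from the pair list (`U` positive, `D` negative) and `S1`, `S2`
   are the per-status signs with `*` appended when that stratum's
   `q < alpha`. The registry fixes which status is first: `status1`
   always occupies the middle token, so swapping the registry order swaps
   the second and third tokens (and the stratum statistics) while leaving
   the class unchanged — a property the test suite asserts.

## Differential expression and DE-MMPVs

The DE stage uses a SAM-type moderated statistic,
`d = (mean1 - mean2) / (s + s0)`, with `s` the unpaired pooled standard
error of the mean difference and `s0` an exchangeability constant that
keeps near-constant rows from dominating. `s0` defaults to the median of
the per-row standard errors (falling back to the smallest positive one);
this is a deliberate simplification of the original quantile-searching
machinery that keeps the statistic self-contained and fully
reproducible. Significance is a permutation null: status labels are
permuted uniformly at random `n_perm` times (default 200), `d` is
recomputed with the *same* `s0` as observed, and
`p = (1 + #{|d_b| >= |d_obs|}) / (n_perm + 1)`, so p-values are floored
at `1/(n_perm + 1)` and never exactly zero. q-values are
Benjamini-Hochberg over the rows of the matrix; the original
pi0-calibrated q-value estimator is intentionally not reimplemented. A
DE-MMPV is an MMPV whose miRNA and mRNA both reach `q < alpha`.

The direction letter is `U` when `mean(status1) > mean(status2)` under
the registry's status order. Published tables of this analysis type are
not internally consistent about which status anchors the direction, so
the convention here is the package's own and is stated in the output
column documentation rather than inferred from any external table.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | FDR level for both the correlation and DE stages (dimensionless) |
| `fold` | 2.0 | correlation-ratio threshold; must exceed 1 |
| `n_perm` | 200 | label permutations for the DE null |
| `p_threshold` | 1e-3 | raw hypergeometric threshold for term enrichment |
| `min_n` | 3 | minimum pairwise-complete samples per stratum (smallest n with a correlation p-value) |
| `collapse` | `max_variance` | duplicate-probe rule on read; the most variable probe preserves correlation signal, `mean` is offered as the conservative alternative |

Enrichment uses the union of mRNAs in the supplied pair list as the
background, mirrors the raw `P < 1e-3` reporting threshold with no
multiple-testing correction, and emits a BH column `q_info` for
information only. The term map is taken flat: no ontology-graph
propagation. The network stage reads the "compare against the network"
instruction as a one-sample, one-tailed t-test of the mapped genes'
degrees against the network-wide mean degree treated as a fixed
population constant; genes absent from the network are excluded as
missing, not scored as isolated. Degrees follow the distinct-neighbour
convention with a self-loop adding 1.

## What the generator emulates — and what it does not

`simulate_dataset()` draws each pair's expression from a bivariate
normal per stratum with exact population correlation, a common standard
deviation, and a between-status mean shift split symmetrically
(`±delta/2`), on the log scale where array intensities are
approximately Gaussian and where the Pearson correlation is the natural
parameter to control. Seeding is hierarchical: a master seed spawns a
deterministic substream per pair, so extending a design never perturbs
existing draws. Ground-truth labels apply the same classification rule
to the population correlations with significance ignored — the shared
code path guarantees the truth table and the detector cannot drift
apart.

The generator deliberately omits probe effects, batch structure, heavy
tails, outliers, and shared-miRNA pleiotropy beyond what a user encodes
by hand. Passing the recovery tests therefore demonstrates that the
decision rules behave as designed under their own model; it does not
certify performance on array data with batch artefacts or non-Gaussian
noise.

The benchmark design used for operating characteristics is 100
sign-change pairs (`rho = +0.7 / -0.7`), 100 fold-change pairs
(`0.6 / 0.2`, population ratio 3), and 1,000 null pairs at 60 samples
per stratum. Null pairs use `rho = 0` in both strata — no regulatory
coupling, the natural null for a non-functional pair and one under
which the doubly-insignificant filter does most of the work. At these
settings sign-change sensitivity is essentially 1, fold-change
sensitivity sits near 0.7 (the ratio statistic is noisy when the weaker
correlation is near its sampling error), and null contamination among
reported MMPVs stays well under 15%. The problem sizes here and in the
test suite (hundreds of rows, dozens of samples, 200 permutations) were
chosen as the smallest designs at which these proportions are stable
across seeds.

## Numerical and degenerate-input choices

- Correlations are clamped to `[-1, 1]` against floating-point
  overshoot before the t-transform.
- Constant vectors have no defined correlation: such pairs are dropped
  with a warning and a `degenerate_pairs` counter, never silently.
  Unresolvable ids and under-sized strata are likewise dropped and
  counted (`unresolved_pairs`, `small_n_pairs`).
- Hypergeometric tails are computed through the distribution function
  in log-stable form, and are exact: the test suite checks them against
  explicit combinatorial summation for every instance with `N <= 25`.
- The permutation stage sorts samples within each stratum before
  drawing labels, so results are invariant to the column order of the
  input matrix.
- Identifier matching is exact and case-sensitive, after a read-time
  normalisation that trims whitespace and unifies the
  `hsa-mir`/`HSA-MIR`/`has-mir` prefix variants of miRNA names — public
  pair lists mix these spellings.

## Ambiguities resolved by this package

Two steps of the published analysis style admit more than one reading,
and the package exposes both rather than asserting one: the shared-gene
filter for two features (`two_feature_genes()` has an `exclude_others`
switch covering the inclusive and exclusive readings of "also present in
other features"), and the overlap unit (`overlap_counts()` counts pair
identity by default with an mRNA-level mode behind `level = "mrna"`).
The survival feature can legitimately return zero MMPVs; the reporting
schema keeps its row with zero counts rather than dropping the feature.

## Known limitations

- The fold-change ratio is condition-to-condition, not
  condition-to-healthy (see above); results are not comparable to a
  hypothetical analysis with healthy-population expression.
- BH on permutation p-values is coarser than a pi0-aware q-value
  estimator; with small `n_perm` the floor `1/(n_perm + 1)` limits how
  small q can get, so `n_perm` must comfortably exceed
  `m / (alpha * rank)` for the signals expected.
- PPI degree comparisons inherit the ascertainment biases of curated
  interaction databases; no bias correction is attempted.
- Spearman or robust correlation alternatives are out of scope for the
  canonical path.
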
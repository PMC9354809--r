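---
title: "Enterotyping methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enterotyping methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enterotyper)
```

## The enterotyping model

Enterotyping treats a cohort of microbial communities as a mixture of a
small number of discrete composition classes. The procedure implemented
here is the one standard in the field:

1. Genus-level counts are converted to relative abundances, and every
   pair of samples is compared by the **square root of the
   Jensen–Shannon divergence**,
   $d(p, q) = \sqrt{H\!\left(\tfrac{p+q}{2}\right) -
   \tfrac{H(p) + H(q)}{2}}$, with $H$ the Shannon entropy in nats.
   JSD itself violates the triangle inequality; its square root is a
   proper metric, which matters because the downstream clustering,
   ordination and silhouette computations all assume metric behaviour.
   Zero proportions are replaced by a pseudocount before the logarithms.
2. **PAM** (k-medoids, BUILD initialization plus SWAP refinement, via the
   `cluster` package) partitions the distance matrix for each candidate
   $k$ in `2..k_max`. PAM involves no randomness, so partitions are
   reproducible without a seed.
3. The cluster count is the **argmax of the Calinski–Harabasz index**,
   with ties resolved toward the smaller $k$. Mean silhouette width and
   prediction strength are computed for every $k$ and reported as
   cross-validation, but they never override the CH choice: selection and
   validation are kept distinct so that the selection rule is a single,
   auditable criterion.
4. Each cluster is named after its **driver genus**, the genus with the
   highest within-cluster mean relative abundance; exact ties are broken
   lexicographically and flagged.
5. Samples whose read totals fall below an amplification threshold form a
   **low-biomass class**: they are excluded from the distance matrix
   (their compositions are mostly noise) but appended to the fitted
   labels as one extra class, so membership cross-tabulations span the
   full cohort.

### Calinski–Harabasz on a distance matrix

CH is classically defined on Euclidean coordinates, not dissimilarities.
We therefore embed the distance matrix by principal coordinates, keep the
axes with positive eigenvalues, and compute
$\mathrm{CH} = \frac{SSB/(k-1)}{SSW/(n-k)}$ from centroid sums of squares
in that embedding — the distance-native analogue used by the established
enterotyping tooling. A partition with zero within-cluster scatter
(coincident points) reports `Inf`, which the argmax handles naturally.

### Prediction strength

Prediction strength follows the Tibshirani–Walther scheme: a random
50/50 split, PAM on each half, test-half samples assigned to the nearest
training medoid, and the score is the minimum over test clusters of the
fraction of within-cluster test pairs co-assigned by the training
medoids, averaged over `n_splits` splits (default 20). It is the only
seeded step of the fit. Values above roughly 0.8–0.9 support a cluster
count; in the bundled simulations the CH-chosen $k$ also maximizes
prediction strength.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `pseudocount` (JSD) | `1e-6` | small relative to any observed fraction at typical depths (~1/depth² scale effects are negligible); keeps `log 0` finite without distorting abundant taxa |
| `k_max` | 10 | generous upper bound for cohort enterotyping, where reported class counts are 2–6; capped at `n/2` so prediction strength stays defined |
| `low_biomass_threshold` | 0 (off) | read total below which a sample is non-amplifiable; cohort-specific — 1,000 reads in the bundled neonatal preset |
| `min_fraction` (rare-taxon filter) | `5e-5` | removes taxa under 0.005% of all reads (mostly singleton OTUs); strictly-less-than, ties retained |
| rarefaction depth | `"min"` | subsample without replacement to the smallest retained sample total; under-depth samples are excluded and reported rather than erroring, because simulated cohorts contain amplification failures |
| `n_perm` | 999 | conventional permutation count; add-one p-values have floor 1/1000 |
| DA prevalence filter | abundance ≥ 0.001 in ≥ 1% of samples | the abundance unit is genuinely ambiguous in common usage (reads, percent, proportion); we adopt relative abundance 0.1% and expose both cuts |

Alpha diversity uses the bias-corrected Chao1,
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$, which stays defined when no doubletons
occur (the classic $S_{obs} + F_1^2/(2F_2)$ form is available by flag),
and Shannon entropy in nats (base exposed). "UniFrac" is implemented as
**unweighted** UniFrac — the incidence-based fraction of branch length
unique to either sample — the phylogeny-only variant; a weighted variant
is out of scope. Bray–Curtis, Shannon and PAM/silhouette are delegated to
`vegan` and `cluster`; UniFrac to `picante`; sqrt-JSD, CH-in-embedding,
prediction strength, PERMANOVA, Mantel and the CLR stage are implemented
in this package.

## Inference conventions

* **Permutation tests** (PERMANOVA pseudo-F with the
  $SST = \sum d^2/n$ decomposition; Mantel on off-diagonal entries,
  Spearman, one-sided greater) report
  $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{perm})$. Both
  accept `n_perm = "exact"`, which enumerates all permutations and
  divides by the total including the identity — this is what the
  brute-force oracle tests compare against at $n \le 6$.
* **Contingency tests** follow a fixed compatibility profile: Pearson
  chi-squared with Yates continuity correction (floored at zero) for 2×2
  tables, plain Pearson for larger tables, Fisher's exact test where an
  exact test is requested (with a seeded Monte-Carlo fallback for large
  sparse tables). Complete-case analysis throughout: rows missing the
  tested variable are dropped per test, never imputed. This profile
  reproduces, to the printed three decimals, all fifteen categorical
  rows of the bundled covariate-by-enterotype tables
  (`preterm_covariate_screen()`).
* **Summary-statistic t-test**: pooled-variance Student by default
  (Welch by flag), so published mean/SD/n rows are directly checkable.
  Note that published summary rows are themselves rounded, so p-values
  recomputed from them can differ from originals in the third decimal.
* **Differential abundance** is a deliberately simplified compositional
  stage: per Monte-Carlo instance, per-sample compositions are drawn from
  Dirichlet(counts + 0.5), CLR-transformed and rank-tested per taxon;
  p-values are averaged over instances and BH-adjusted. It preserves the
  CLR + Wilcoxon skeleton of the established compositional DA tools but
  is not claimed to reproduce any package's output; the
  concordance-intersection rule (`concordant_da()`: significant in both
  lists with matching sign) is the operation of interest.
* The cross-timepoint alpha comparison uses the **unpaired** Wilcoxon
  rank-sum test even though samples are paired, matching common reporting
  practice for these cohorts; a paired analysis would be a trivial
  extension but is intentionally not the default.

## The synthetic cohort generator

Real neonatal cohorts show strong single-genus dominance, highly variable
library sizes, amplification failures, and (in childhood) a
Bacteroides/Prevotella split. The generator emulates exactly these
features: each sample draws a mixture component, a composition from a
per-component Dirichlet base with the component's driver taxon multiplied
by `driver_boost`, a lognormal library size (per-component mean, so one
component can be a low-biomass group), and multinomial counts.
`simulate_paired()` couples two such cohorts through an association
parameter: with probability `association` a sample's second-timepoint
component is a fixed mapping of its first; `association = 0` gives
independence, the null of no enterotype carry-over.

Two presets encode the study conditions the package is validated
against: `config_neonatal()` (159 samples, six components in proportions
69:18:25:18:11:18, five strongly boosted drivers, one low-biomass
component below a 1,000-read threshold) and `config_childhood()`
(159 samples, Bacteroides- and Prevotella-driven components 128:31, the
Bacteroides base elevated inside the Prevotella component so it stays
second-ranked). Dominance levels are not published quantities; the boost
values are simulation knobs chosen once to produce the qualitative
dominance structure, not estimates.

What the generator does **not** emulate: taxonomic misassignment,
sequence-level errors, within-subject autocorrelation beyond the single
association parameter, and realistic phylogenetic signal (trees are
random with exponential branch lengths). Passing recovery tests on these
simulations therefore shows the procedure is correct and well-calibrated
on data with the assumed structure — not that real cohorts satisfy that
structure.

## Numerical and design choices

* PCoA drops negative-eigenvalue axes and reports their magnitudes; no
  Cailliez/Lingoes correction is applied. Axis signs are fixed by making
  each axis's largest-magnitude coordinate positive.
* Rare-taxon filtering precedes rarefaction (the two do not commute; the
  order is fixed and tested).
* All seeded stages derive their streams from one global seed by fixed
  offsets, so any stage reproduces in isolation and end-to-end reports
  are byte-identical across runs.
* Asymptotic p-values that underflow to 0 (e.g. a perfect rank
  correlation) are floored at the smallest positive double so the
  $(0, 1]$ invariant holds.
* Reference-class comparisons take the reference cluster as a parameter
  rather than hard-coding a particular enterotype.
* Cross-timepoint statistics use the intersection of samples analyzable
  at both timepoints, since amplification failures differ by timepoint.

## Validation scale

The test suite validates recovery on cohorts of 90–159 samples at depths
near $10^4$, type-I calibration of PERMANOVA, Mantel and the CLR stage
over 500 null replicates at 199 permutations each, metric properties on
1,000 random triples, and exhaustive-enumeration equivalence of all
permutation tests at $n \le 6$. These sizes were chosen as the smallest
at which the checks are statistically meaningful.

## Limitations

* Cluster-count selection is sensitive to sample size and separation;
  with weak structure the CH argmax can be unstable even when silhouette
  and prediction strength flag the instability. The fit reports all three
  so users can see disagreement.
* Only one-factor (marginal) PERMANOVA is provided; sequential/partial
  designs and mixed-effects models for clustered cohorts are out of
  scope.
* The DA stage is an emulation for pipeline completeness, not a
  replacement for dedicated compositional DA packages.
* Supervised assignment of new samples to fitted enterotypes is
  intentionally not provided.
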
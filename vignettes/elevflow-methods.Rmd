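---
title: "Inferring gene flow along elevational gradients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene flow along elevational gradients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(elevflow)
```

# Overview

`elevflow` implements a pipeline for asking how much gene flow connects
populations arrayed along a steep elevational gradient, and in which
direction it runs. The motivating system is a community of montane
grasshoppers sampled at three to five sites between roughly 1,600 and
3,500 m, genotyped at thousands of biallelic SNPs, with long-term weekly
abundance surveys and published population trait means. The pipeline has
five analytical layers:

1. **Genotype import and filtering** — VCF to a complete dosage matrix.
2. **Diversity and differentiation statistics** — Nei–Chesser estimators of
   H~O~, H~S~, H~T~, F~IS~, F~ST~ and Jost's D.
3. **Demographic simulation and ABC** — a structured-coalescent simulator
   for five spatial gene-flow topologies, with approximate Bayesian
   computation for model choice, cross-validation, goodness of fit and
   parameter estimation.
4. **AFS composite likelihood** — folded site-frequency-spectrum fitting
   with parametric bootstrap, an independent estimator of the same
   parameters.
5. **Ecology** — Mantel tests of trait–predictor association and Pianka
   phenological overlap from weekly survey counts.

Synthetic-data generators reproduce the *shape* of the study inputs
(sampling layouts, elevation-shifted seasons, linear trait clines), so the
entire pipeline is testable with no external data.

# Genotype filtering and imputation

Genotypes are alternate-allele dosages (0/1/2, `NA` missing). Two filters
mirror a standard post-calling pipeline:

* `filter_maf()` removes loci whose *overall* (pooled, unweighted by
  population) minor-allele frequency is strictly below 2%; the boundary
  value is kept.
* `impute_missing()` replaces each missing call with the genotype of
  maximal within-population Hardy–Weinberg probability, provided that
  probability reaches 70%; loci where any call cannot be imputed that
  confidently are dropped, so downstream code always sees a complete
  matrix. This is a deliberate simplification of haplotype-model
  imputation: the analyses downstream need only a complete matrix, and the
  Hardy–Weinberg posterior is a transparent, testable rule with the same
  confidence cut-off. Loci for which a population has no called genotype at
  all are unresolvable and dropped.

# Diversity statistics

Per locus, with `r` populations, diploid sample sizes `n_k`, allele
frequencies `p_k`, observed heterozygosities `h_k`, harmonic-mean sample
size `ñ` and `Ho = mean(h_k)`, the package fixes the Nei & Chesser (1983)
unbiased estimators:

```
Hs = ñ/(ñ−1) · [1 − mean_k(p_k² + q_k²) − Ho/(2ñ)]
Ht = 1 − (p̄² + q̄²) + Hs/(rñ) − Ho/(2rñ),  p̄ = mean_k(p_k)
```

Multilocus statistics average the components across loci *first* and then
form ratios (F~ST~ = (H̄~T~ − H̄~S~)/H̄~T~, F~IS~ = 1 − H̄~O~/H̄~S~, Jost's
D = (r/(r−1))(H̄~T~ − H̄~S~)/(1 − H̄~S~)); pairwise F~ST~ recomputes the
components with `r = 2` for each pair. Two consequences worth knowing:

* Per-population expected heterozygosity is reported both as plain `2pq`
  (`He`) and as the unbiased within-population gene diversity (`Hs`); they
  are different columns on purpose.
* The unbiased estimators correct for sampling noise, so a pair of
  *literally identical samples* has a slightly **negative** F~ST~ estimate,
  not zero; the tests assert exactly that.

`linearize_fst()` applies Latter's transform `f/(1−f)`, the conventional
genetic-distance scale for isolation-by-distance regressions.

# The gene-flow models

Demes are ordered low → high elevation. The scalar migration rate `m` is a
*per-edge forward rate*: the proportion of a recipient deme replaced per
generation by migrants from one donor, matching the migration-matrix
semantics of standard coalescent simulators. The five topologies are

| label | forward gene flow |
|-------|-------------------|
| `dn`  | each deme → its adjacent lower deme |
| `up`  | each deme → its adjacent higher deme |
| `ss`  | both adjacent neighbours (stepping stone) |
| `am`  | every other deme (island) |
| `sk`  | island **plus** an extra unidirectional rate `m` from every deme into the top deme (source–sink; the top deme is the sink) |

Directional models use adjacent-deme chains rather than all-pairs downhill
edges — the minimal reading of "unidirectional gene flow downslope"; the
matrix builder is a single function so the alternative is a one-line
change. Backward (lineage) rates are the forward edges reversed without
N~e~ reweighting. A model is accepted only if some deme is reachable by
lineages from every other deme; note this is weaker than full mutual
reachability — the directional chains are valid because all lineages can
reach the terminal deme, where they coalesce.

## The coalescent SNP simulator

Each candidate locus is an independent structured-coalescent genealogy:
within deme *i*, every lineage pair coalesces at rate 1/(2N~e,i~)
(generations); each lineage migrates per the backward matrix; waiting
times are exponential. The event loop is written in C++ and runs on its
own xoshiro256++ generator seeded from R's RNG, so `set.seed()` governs
everything while the loop stays fast (a 20,000-dataset reference table
builds in minutes).

**SNP conditioning.** The study design this emulates simulates short
independent sequences and draws SNPs from those that segregate. In the
low-mutation-rate limit that is *length-weighted* sampling: a genealogy
carries a SNP with probability proportional to its total branch length.
The simulator therefore builds a pool of genealogies (default one per
requested SNP; `pool_factor` enlarges it) and places each SNP's mutation
uniformly at random on the *pool's* total branch length. Uniform placement
per tree — the seemingly obvious alternative — yields the E[L~i~/L]
spectrum instead and visibly distorts rare-allele classes; with
length-weighting the single-deme folded spectrum matches the classical
conditioned form ∝ 1/i + 1/(2n−i), which the tests assert. Because the
pool is finite, two SNPs can share a genealogy (as two SNPs on one
simulated sequence would); the study-scale analogue had a vastly larger
pool, and `pool_factor` lets users buy more independence at linear cost.

A closed form used in the tests: for the island model with `d` demes,
per-edge rate `m` and equal sizes N~e~, total immigration per lineage is
`(d−1)m`, mean within-deme coalescence time is `2 Ne d` and the
between-deme excess is `(d−1)/(2(d−1)m)`, so the expected Nei pairwise
G~ST~ is `1/(1 + 8 Ne m d)`. This was cross-checked against an independent
coalescent simulator during development; the test band is ±30% over 20
replicates of 200 loci.

## Summary statistics

`dataset_sumstats()` returns a fixed-order vector: pooled expected
heterozygosity; pooled segregating-site count; per-population segregating
sites; per-population mean pairwise haplotype differences (unbiased);
between-population mean pairwise differences for every pair; pairwise
F~ST~ for every pair. The within-population differences are part of the
standard output of the summary-statistic program the design emulates and
carry the directional diversity signal that separates `dn` from `up`.
Under SNP conditioning the pooled segregating-site count is constant by
construction; it is retained for interface stability and automatically
dropped from ABC distances by the zero-MAD rule.

# ABC

All ABC operations standardize statistics by the reference table's
per-statistic median and MAD, drop zero-MAD statistics with a warning, and
use Euclidean distance. Acceptance keeps the `ceiling(tol · rows)` nearest
rows; boundary ties are broken by table order after a seeded shuffle.

* `abc_reject()` — model probability = share of each model among accepted
  rows.
* `regression_model_probs()` — a multinomial logistic (soft-max)
  classifier fitted to the accepted rows with Epanechnikov distance
  weights (via `nnet::multinom`), evaluated at the observed statistics.
  The logistic special case is the default because it is deterministic and
  mirrors the reference implementation's estimator family; models absent
  from the accepted set are reported with probability 0 and flagged.
* `cross_validate()` — leave-one-out over held-out table rows; the held
  out row is excluded from its own acceptance set.
* `goodness_of_fit()` — gfit-style: the observed statistic is the median
  standardized distance to the accepted set; the null distribution comes
  from pseudo-observed table rows; `p = (1 + #{null ≥ obs})/(n_rep + 1)`
  so p is never 0.
* `estimate_parameters()` — rejection at `tol = 0.05` followed by
  weighted local-linear regression adjustment (N~e~ on the log scale, `m`
  linear), weighted 2.5/50/97.5% quantiles, clamped to the prior support.
  A degenerate design falls back to the unadjusted sample with a warning.

## What the scaled-down cross-validation can and cannot show

The acceptance-scale study design uses 5,000 simulations per model at 200
conditioned SNPs. At that SNP count the summary statistics are noisy
enough that the four topologies overlap substantially in statistic space:
both rejection and soft-max cross-validation plateau at roughly 70–75%
mean correct assignment (the values `scripts/acceptance.R` recomputes),
and a global multinomial classifier trained on the full table does no
better, indicating an information ceiling rather than an estimation
artefact. Within that ceiling the stepping-stone model is the most
confused class, mostly with the island model — the two topologies differ
only through the non-adjacent edges. Empirically the assignment rate
climbs steeply with SNP count (five-fold more SNPs adds roughly ten
points at fixed table size); at the study scale of 4,000–9,500 SNPs per
dataset and millions of simulations, rates in the mid-90s for rejection
are consistent with that trend, but they are not reproducible at desk
scale — a genuine limit of the scaled conditions, documented here rather
than papered over.

# AFS composite likelihood

`minor_afs()` folds each population's spectrum at its own sample size
(classes 0…n~k~ minor-allele copies; class 0 = monomorphic within that
population, informative about shared polymorphism). `expected_afs()`
estimates class probabilities by Monte Carlo from the simulator with
add-one smoothing, so no class has probability zero. `composite_ll()` is
`Σ obs·log(exp)` across classes and populations — a composite likelihood
treating loci and populations as independent.

`fit_afs()` maximizes by cyclic coordinate search on `(m, log Ne)` with
**common random numbers**: every candidate evaluation reuses one fixed
simulation sub-seed, making the Monte-Carlo surface deterministic so a 1-D
`optimize()` per coordinate behaves; cycles stop at a 0.001 relative
parameter change, and the best of several seeded restarts is returned.

**Identifiability.** Conditioned SNP spectra are invariant to rescaling
time, so they constrain products like 4N~e~m, not `m` and N~e~
separately. `fit_afs(fixed = list(m = ...))` pins one rate; the recovery
test fixes `m` at truth and recovers a shared N~e~ within a factor of 3 in
at least 8 of 10 replicates (500 loci, 10 diploids per deme).
`parametric_bootstrap()` refits simulated datasets at the point estimate
and returns 2.5–97.5 percentile intervals; interval width shrinks as the
observed locus count grows.

# Mantel tests and distances

`build_distances()` produces population distance matrices: geography
(Euclidean on locally projected coordinates — longitude scaled by
cos(mean latitude), in km; over a ~35 km extent any sensible projection is
affinely equivalent, and Mantel r is scale-invariant), elevation (|Δm|),
environment and phenotype (Euclidean on z-scored variables — z-scoring
prevents unit-dominated distances since the sources do not state a
scaling), and genetic (linearized pairwise F~ST~ passed through).

`mantel_test()` correlates lower-triangle vectors (Pearson) and permutes
rows+columns of the second matrix jointly, sampling `n_perm` permutations
with replacement; `p = (1 + #{r_perm ≥ r_obs})/(n_perm + 1)`, one-sided
upper tail (matching the convention under which strongly negative
correlations report large p). The permutation loop is in-package so the
+1 sampling convention holds at any population count; `vegan::mantel`,
which enumerates exhaustively for few populations, is used as an
independent cross-check in development. `trait_association_suite()` runs
one test per trait category × predictor and reports `NA` for categories
with complete data in fewer than three populations.

# Phenology

`pianka_overlap()` is the normalized dot product of two weekly abundance
proportion vectors. `percentile_dates()` uses the first-crossing (step)
convention — the day of the first survey at which the cumulative adult
proportion reaches the percentile — rather than interpolation, matching
the literal "day the percentile adult was surveyed". Weekly proportions
are aligned on the union of surveyed weeks; a week one site was surveyed
with zero adults counts as zero, an unsurveyed week is absent. Sites with
zero adults in a season are skipped with a warning. Only adults are
scored.

# Synthetic data

`species_config()` returns the four study sampling layouts (deme
elevations, 8–23 diploids per deme, 4,087–9,454 SNPs, candidate model
sets; the source–sink model only for the five-deme widespread species).
`gen_survey_data()` draws weekly Poisson counts around a Gaussian seasonal
curve whose peak shifts later by `delay_per_100m` days per 100 m (default
3 d/100 m, season SD 14 d, peak 100 adults — a realistic montane insect
season); the survey grid automatically spans ±3 SD around every site's
peak, as a field program would. `gen_trait_clines()` makes population
trait means linear in elevation with optional Gaussian noise. What these
generators do **not** emulate: linkage, GBS missingness structure,
overdispersed counts, detection failure — so green tests here demonstrate
correct statistical machinery, not robustness to those real-data
features.

# Numerical and scale choices

* Reference tables default to thousands of rows per model (the acceptance
  design uses 5,000/model at 200 SNPs; the study-scale analogue was 2
  million/model); AFS fits default to a few restarts with ~10³ simulated
  loci per likelihood evaluation. All scale knobs are exposed as
  arguments.
* The event loop re-sums total rates each event from exact per-deme terms,
  so floating-point drift can never select an impossible event; a
  configurable event cap catches migration structures that cannot reach a
  common ancestor.
* Integer seeds for the C++ generator are drawn from R's RNG below 2^53;
  every simulation result is reproducible from `set.seed()`.

# Known limitations

* No recombination/linkage, selection, population-size change through
  time, or divergence times — the models are equilibrium migration
  matrices.
* The AFS module uses per-population marginal folded spectra (not the
  full joint multidimensional spectrum), a composite-likelihood
  simplification chosen because the full joint spectrum over 4–5
  populations is extremely sparse at desk scale.
* ABC model-choice accuracy at 200 SNPs is information-limited (see
  above); conclusions about the full-scale design's accuracy are
  extrapolations.
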
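# elevflow

Demographic inference and phenotype association for populations along
elevational gradients.

## The problem

Codistributed species on a steep mountain gradient differ in dispersal
ability, and that should leave fingerprints in their genomes: less
dispersive (short-winged) insects are expected to show stronger genetic
differentiation among elevation sites, lower gene flow, and more scope for
local adaptation of growth, reproductive and physiological traits. Testing
this requires several kinds of machinery in one place:

* **Diversity and differentiation statistics** for biallelic SNPs —
  observed/expected heterozygosity, Nei–Chesser within- and
  total-population gene diversity (H<sub>S</sub>, H<sub>T</sub>),
  F<sub>IS</sub>, F<sub>ST</sub> (overall and pairwise, with Latter's
  linearization f/(1−f)) and Jost's D<sub>est</sub> =
  (r/(r−1))·(H<sub>T</sub>−H<sub>S</sub>)/(1−H<sub>S</sub>).
* **Competing spatial gene-flow models** fitted by approximate Bayesian
  computation (ABC): unidirectional downslope (`dn`), unidirectional
  upslope (`up`), bidirectional stepping stone (`ss`), island (`am`), and
  source–sink (`sk`, an island model whose every deme additionally feeds
  the top-elevation deme). Datasets are simulated under a structured
  coalescent with migration (one length-weighted conditioned SNP per
  genealogy, priors m ~ U(0.001, 0.05), N<sub>e</sub> ~
  log-uniform(200, 10000)), compared through summary statistics, and
  classified by rejection or a distance-weighted soft-max
  (regression/neural) method; leave-one-out cross-validation,
  goodness-of-fit and local-linear parameter estimation complete the ABC
  toolkit.
* **Folded site-frequency-spectrum composite likelihood** as an
  independent parameter estimator, with parametric bootstrap intervals.
* **Mantel permutation tests** relating phenotypic distance to
  geographic, elevational, environmental and genetic (linearized
  F<sub>ST</sub>) distance.
* **Phenological overlap** — Pianka's index O =
  Σp<sub>jw</sub>p<sub>kw</sub> / √(Σp<sub>jw</sub>²·Σp<sub>kw</sub>²) on
  weekly adult-count proportions, plus 15th/85th-percentile adult dates —
  an ecological ceiling on gene flow between sites.

All inputs can be generated synthetically (genotypes from the coalescent
simulator, surveys with elevation-shifted seasons, linear trait clines),
so the full pipeline runs and is tested without any external data.

## Worked example

Simulate a three-site species layout under stepping-stone gene flow
(m = 0.004, N<sub>e</sub> = 1500), compute its statistics, and ask the ABC
engine which topology generated it:

```r
library(elevflow)
set.seed(1)

cfg <- species_config("C. pellucida", n_snps = 300)
truth <- demographic_model("ss", c(1500, 1500, 1500), m = 0.004,
                           elevations = cfg$elevations)
sim <- simulate_dataset(truth, cfg$samples, cfg$n_snps)

overall_stats(locus_stats(sim$genotypes, sim$popmap))
#> Multilocus statistics over 300 loci, 3 populations
#>     MAF      Ho      Hs      Ht     Fis     Fst    Dest
#>  0.1350  0.1929  0.1912  0.1941 -0.0091  0.0153  0.0055
#> Per population:
#>  population     Ho     He     Hs     Fis
#>          P1 0.1919 0.1865 0.1906 -0.0066
#>          P2 0.1906 0.1866 0.1912  0.0029
#>          P3 0.1962 0.1872 0.1917 -0.0236

pairwise_fst(sim$genotypes, sim$popmap)
#> Pairwise Fst:
#>        P1     P2     P3
#> P1 0.0000 0.0093 0.0187
#> P2 0.0093 0.0000 0.0065
#> P3 0.0187 0.0065 0.0000
```

Differentiation is low (F<sub>ST</sub> ≈ 0.015) and increases with the
number of steps between demes — the stepping-stone signature. Model
choice against a small reference table (300 simulations per model; use
thousands for real analyses):

```r
tab <- build_reference_table(c("dn", "up", "ss", "am"), n_per_model = 300,
                             samples = cfg$samples, n_snps = cfg$n_snps,
                             elevations = cfg$elevations)
obs <- dataset_sumstats(sim$genotypes, sim$popmap)

abc_reject(obs, tab, tol = 0.02)
#> ABC model posterior (rejection, tol = 0.02)
#>     dn     up     ss     am
#> 0.1667 0.0833 0.6250 0.1250

regression_model_probs(obs, tab, tol = 0.02)
#> ABC model posterior (mnlogistic, tol = 0.02)
#> dn up ss am
#>  0  0  1  0
```

Both methods recover the generating stepping-stone model. Phenology from
a synthetic survey with a 5 d / 100 m seasonal delay:

```r
st <- gen_survey_data(cfg$elevations, delay_per_100m = 5)
overlap_pipeline(st)$overlap
#>     species year site_a site_b    overlap elev_sep
#> 1 synthetic 2010  S2195  S2591 0.58765998      396
#> 2 synthetic 2010  S2591  S3048 0.43224256      457
#> 3 synthetic 2010  S2195  S3048 0.08690743      853
```

Pianka overlap falls from 0.59 to 0.09 as elevational separation grows —
the phenological ceiling on gene flow between distant sites.

## Documentation

`vignettes/elevflow-methods.Rmd` describes the models, estimators,
conditioning scheme, numerical choices and known limitations in detail.
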
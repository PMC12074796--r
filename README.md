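# reefstab

Temporal stability of reef-fish community biomass, partitioned into its
species-level and compensatory components, and linked to environmental
variability, human pressure and the functional composition of the
community through a piecewise structural equation model.

## Who this is for

Quantitative community ecologists working with long-term, size-structured
visual-census data (reef-fish transect surveys and similar), who need a
tested, reproducible path from raw block-level counts to a
biodiversity–stability analysis — including the unglamorous parts:
length–weight conversion, detection-limit zero replacement, gap
interpolation, and a site filter — plus a synthetic data generator with
known ground truth so every stage can be validated without any field data.

## The quantities at the core

For a species × year biomass matrix with species means *m<sub>i</sub>*,
standard deviations *sd<sub>i</sub>*, covariance matrix *v<sub>ij</sub>*
and annual totals with mean *m<sub>c</sub>* and sd *sd<sub>c</sub>*:

- community stability **S<sub>c</sub> = m<sub>c</sub> / sd<sub>c</sub>**
  (inverse CV of total biomass);
- average species stability **1/CV<sub>sp</sub> = m<sub>c</sub> / Σ
  sd<sub>i</sub>** (reciprocal biomass-weighted mean species CV);
- synchrony **φ = Σ v<sub>ij</sub> / (Σ sd<sub>i</sub>)²** ∈ [0, 1],
  asynchrony 1 − φ;
- the exact partition **log S<sub>c</sub> = log(1/CV<sub>sp</sub>) − ½ log φ**.

Functional composition enters through four facets: community-weighted
trait means, trait diversity **FD₁** (functional Hill number of order 1
with distance threshold τ = mean pairwise trait distance), trait
redundancy **FR₁ = 1 − FD₁/TD₁**, and richness-residualized counts of
functionally distinct species. A piecewise SEM (per-response OLS on
z-scored variables, all-subsets AICc covariate selection, d-separation
goodness of fit via Fisher's **C = −2 Σ log p**) quantifies direct and
trait-mediated effects, and `accumulate_effects()` multiplies and sums
path segments into direct/indirect/total effect tables.

## Worked example

```r
library(reefstab)

traits <- generate_species_pool(120, seed = 1)
sites  <- generate_sites(40, seed = 2)
sim    <- simulate_surveys(traits, sites, sim_config(), seed = 3)

pl  <- reef_pipeline(sim$surveys, traits, sites)
decompose_stability(pl$matrices[["site001"]]$biomass)
#> Community biomass stability partition (14 years, 27 species)
#>   community stability   S_c      = 6.438
#>   avg species stability 1/CV_sp  = 2.096
#>   synchrony             phi      = 0.106
#>   asynchrony            1 - phi  = 0.894
#>   log S_c = log(1/CV_sp) - 0.5 log(phi): 1.862 = 0.7399 + 1.122
```

Site `site001`'s total biomass is 6.4 times its own interannual standard
deviation; only a modest part of that comes from individual species being
stable (1/CV_sp ≈ 2.1), the rest from compensatory dynamics (φ ≈ 0.11,
i.e. species fluctuate nearly independently, and −½ log φ contributes the
larger share of log S_c).

```r
fit <- fit_path_model(default_path_spec(), pl$data, selection = TRUE)
fit
#> Piecewise path model: 6 local models, n = 40 sites
#> Fisher's C = 11.327, df = 24, p = 0.986 (12 independence claims)

head(subset(accumulate_effects(fit), outcome == "community_stability"), 3)
#>       driver             outcome direct indirect  total
#> 7   mean_sst community_stability      0    0.019  0.019
#> 8 sst_change community_stability      0   -0.083 -0.083
#> 9    gravity community_stability      0   -0.289 -0.289
```

The non-significant Fisher's C (p = 0.99) says no independence claim of
the fitted structure is contradicted by these synthetic data. The effect
table reads: human gravity lowers community stability by −0.29 standard
deviations per standard deviation of gravity, entirely through indirect
paths (here via destabilized species biomass) — which is exactly the
effect the generator was configured to embed (`sim$truth`).

## Layout

- `R/synthetic-data.R`, `R/path-sim.R` — generator (species pools, site
  gradients, survey simulation, truth ledger, structural simulator)
- `R/data-prep.R` — aggregation, biomass, zero replacement,
  interpolation, site filter, degradation sensitivity
- `R/stability.R` — the stability partition
- `R/functional-diversity.R` — CWM, TD₁/FD₁/FR₁, distinctiveness
- `R/environment.R` — abiotic predictor summaries
- `R/path-model.R` — spec, selection, piecewise fit, Fisher's C, effects
- `vignettes/reefstab-methods.Rmd` — full methods account and design
  rationale
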
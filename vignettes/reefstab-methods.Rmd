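---
title: "Methods: partitioning reef-fish biomass stability and its functional drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning reef-fish biomass stability and its functional drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefstab)
```

## The question

Shallow-reef fish communities are monitored by divers who count
individuals per species and size class along transect lines. Over a decade
or more, the total biomass of such a community fluctuates; how *stable*
that total is, and why, is the quantity of interest here. `reefstab`
implements the complete chain from raw block-level counts to a piecewise
structural equation model (SEM) that separates the direct effects of
environmental variability and human pressure on stability from the
indirect effects that operate through the functional composition of the
community.

## From counts to annual biomass

A survey record is a count of individuals of one species in one size class
(total-length bin, cm) on one side ("block") of a 50 m transect. The data
preparation follows fixed rules:

1. **Block aggregation** (`aggregate_blocks()`): counts are summed over
   the two blocks of each transect.
2. **Length-weight conversion** (`biomass_from_counts()`): a fish of
   length $L$ weighs $w = a L^b$ grams, with species-specific $(a, b)$ and
   $b \approx 3$. The length entering the formula is the size-class
   midpoint — the within-class convention has to be fixed somewhere, and
   the midpoint is the standard choice. Per-species annual biomass is the
   sum over size classes within a transect, averaged over **all**
   transects surveyed that year (a transect where the species was not
   seen contributes zero).
3. **Zero replacement** (`impute_zero_records()`): a zero for a species
   otherwise observed at a site is read as "present but below detection",
   and replaced by half the minimum positive biomass of that species at
   that site across surveyed years. The rule is applied to the
   transect-averaged biomass series, which is the interpretation that
   composes cleanly with the preceding averaging step; applying it to raw
   counts instead is possible by reordering the pipeline calls, since each
   step is exposed separately.
4. **Gap interpolation** (`interpolate_missing_years()`): not every site
   is surveyed every year. Interior gaps are filled by linear
   interpolation of each species' biomass; years before the first or
   after the last survey are held constant at the nearest surveyed value.
   Every cell carries a provenance flag (`observed`, `zero_imputed`,
   `interpolated`, `edge_extrapolated`).
5. **Site filter** (`filter_sites()`): only sites surveyed in at least 7
   of the 14 window years (2008–2021, closed) are analysed.

Steps 3–4 are idempotent and never alter positive observed cells; the
test suite asserts both properties on random matrices.

## The stability partition

For a species $\times$ year biomass matrix with species means $m_i$,
standard deviations $sd_i$, covariance matrix $v_{ij}$ and annual totals
with mean $m_c$ and standard deviation $sd_c$:

* community stability $S_c = m_c / sd_c$ (inverse CV of the totals);
* average species stability $1/\mathrm{CV}_{sp} = m_c / \sum_i sd_i$, the
  reciprocal of the biomass-weighted mean species CV;
* synchrony $\varphi = \sum_{ij} v_{ij} / (\sum_i sd_i)^2 \in [0, 1]$,
  with asynchrony $1 - \varphi$ capturing compensatory dynamics.

These satisfy the exact identity
$$\log S_c = \log(1/\mathrm{CV}_{sp}) - \tfrac12 \log \varphi,$$
which `decompose_stability()` asserts at $10^{-10}$ on every call. A
caveat worth recording: the *literal* biomass-weighted sum of species-level
inverse CVs, $\sum_i (m_i/m_c)(m_i/sd_i)$, which appears in parts of the
literature, does **not** satisfy this identity in general; it is available
via `average_species_stability(form = "printed")` for comparison, but the
partition-consistent form is the default everywhere. Sample ($n-1$)
variances are used throughout, natural logs everywhere, and both
stability components are log-transformed before modelling (they are
ratio-scale and right-skewed). Correlation-based synchrony estimators are
deliberately not offered: they are unreliable on 14-point series.

Degenerate inputs are signalled, not crashed on: constant totals give an
infinite-stability warning, an all-constant community gives an undefined
synchrony (`NaN`), and the log partition refuses both.

## Four facets of functional diversity

Species are described by maximum length (cm), growth coefficient
(year$^{-1}$), trophic level (2–4.6) and maximum depth (m).

* **CWMs** (`cwm()`): trait means weighted by mean relative biomass over
  the gap-filled window, on raw trait scales.
* **Trait diversity** $FD_1$ (`hill_functional()`): the functional Hill
  number of order 1 under a distance threshold $\tau$,
  $FD_1 = \exp(-\sum_i p_i \log \sum_j [1 - \min(d_{ij},\tau)/\tau] p_j)$.
  Distances are Euclidean in trait space after log-transforming maximum
  length and maximum depth (they span orders of magnitude) and z-scoring
  all four traits over the species pool — the scaling is not dictated by
  the Euclidean-distance choice itself, but without it the distance would
  be dominated by whichever trait has the largest unit, so standardization
  is the default (disable with `standardize = FALSE`). $\tau$ is the mean
  off-diagonal distance.
* **Trait redundancy** $FR_1 = 1 - FD_1/TD_1$ (`trait_redundancy()`),
  with $TD_1$ the exponential Shannon entropy of the weights.
* **Trait distinctiveness** $D_i$ (`distinctiveness()`): the mean
  functional distance from species $i$ to the other species in scope
  (global pool or one community). The mean over $S-1$ neighbours is used
  rather than the raw sum, because the sum grows mechanically with
  richness; the raw sum is available (`normalize = FALSE`). All four
  traits enter by default for internal consistency with $FD_1$; a
  three-trait convention (length, trophic level, depth) is available via
  `trait_cols`. The per-site variable entering the path model is the
  count of globally most-distinct species (top 25%, ties at the threshold
  included) residualized on richness (`n_distinct_residual()`), again to
  remove the mechanical richness dependence.

Invariants asserted in tests: $1 \le FD_1 \le TD_1 \le S$, relabelling
invariance, weak monotonicity of $FD_1$ in the distances, and exact
agreement (to $10^{-12}$) with independent literal-summation
implementations.

## Abiotic predictors

`abiotic_summary()` reduces each site to: temporal mean SST (the
biogeographic gradient), the OLS slope of SST on year (warming trend,
degC/yr), interannual CVs of SST and chlorophyll a, the human gravity
index (population density over travel time; a fishing-pressure proxy),
mean site depth, and the number of surveyed years (a control for how much
of the series is gap-filled). Mean chlorophyll and its trend are computed
but excluded by default because they track SST too closely to enter the
same regressions.

## The piecewise path model

The hypothesized structure (`default_path_spec()`): every abiotic driver
may affect every facet; drivers and facets may affect the two stability
components; community stability is the sink determined by its two
components. Estimation is piecewise: one OLS regression per endogenous
variable on z-scored variables, so coefficients are standardized and
comparable across paths.

* **Covariate selection** (`select_covariates()`): all subsets of each
  response's candidates are ranked by AICc and the best model's
  predictors are kept (option: union of predictors within $\Delta$AICc of
  the best). Facets selected for neither stability component are dropped
  before the final fit — they cannot mediate anything. Selection is
  exhaustive rather than stepwise; with at most ~14 candidates this is
  $2^{14}$ linear solves from precomputed cross-products, which is cheap.
* **Correlated errors**: the residuals of the two components are allowed
  to correlate (they are computed from the same matrices), and the
  residual Pearson correlation is reported.
* **Goodness of fit** (`fishers_c()`): the d-separation basis set — every
  non-adjacent pair conditioned on the parents of both, skipping
  exogenous-exogenous pairs, declared correlated-error pairs and excluded
  pairs — is tested by the p-value of the omitted variable, and combined
  as $C = -2\sum\log p \sim \chi^2_{2k}$. Facet–facet pairs are excluded
  by default: the facets are all computed from the same community data,
  so their mutual correlations are acknowledged rather than treated as
  testable independence claims. The deterministic sink is excluded from
  the basis set entirely — conditioning on both of its parents leaves no
  residual variation to test. A saturated structure returns
  $C = 0, p = 1$ with a notice.
* **The sink**: community stability is regressed on the two components;
  the standardized coefficients serve as the weights that combine
  component effects into community-stability effects in
  `accumulate_effects()`. With asynchrony expressed as $1-\varphi$ (the
  scale used in modelling) rather than $-\tfrac12\log\varphi$ (the scale
  on which the partition is exact), this regression is near- but not
  exactly deterministic; its $r^2$ is reported rather than hard-coded to 1.
* **Effect accumulation** (`accumulate_effects()`): total effects are the
  matrix geometric series $B + B^2 + \dots$ of the standardized edge
  matrix, which terminates for a DAG and equals exhaustive
  path-product-and-sum enumeration (asserted to $10^{-12}$ on random
  sparse DAGs); direct effects are the direct edges, indirect the
  difference.

## What the synthetic generator emulates — and what it does not

The generator is first-class, tested code; its defaults are the study
conditions, fixed once:

* 215 sites, 655-species pool; mean SST uniform on 13.9–25.4 degC;
  per-site SST trends $\mathcal N(0.1, 0.2)$ degC/yr; survey gap
  probability 0.36 with a 7-year floor, giving a mean of about 9 surveyed
  years of 14; 1–6 transects per site (the field protocol varies, so this
  is configurable rather than asserted); site depth lognormal around
  6.5 m; lognormal gravity.
* Species traits are drawn with realistic correlation structure (length
  positively correlated with trophic level, negatively with growth rate);
  length-weight exponents near 3.
* Occurrence: site richness scales as
  $\exp(0.4 \cdot z(\text{mean SST}))$ around a baseline of 40, and
  species are drawn preferentially near their thermal optimum. Optima are
  warm-skewed (tropical pools are richer) and negatively correlated with
  trophic level, so cold-water communities have a higher mean trophic
  level.
* Dynamics: per species-site lognormal AR(1) biomass
  ($\rho = 0.3$), with the standard deviation of log biomass responding
  to standardized gravity in proportion to the species' trophic score
  (+0.35: human pressure destabilizes high-trophic species) and to the
  standardized warming trend in proportion to one minus the trophic score
  (+0.35: warming destabilizes low-trophic species). Effect magnitudes
  sit in the 0.2–0.5 band — recoverable at a few hundred sites without
  being trivial — and every nonzero effect is recorded in a
  `truth_ledger()`.
* Observation: expected counts are spread over geometric length bins
  around 0.65 $\times$ maximum length and observed as Poisson draws per
  block, which produces genuine zero-detection years for sparse species.
  In the noise-free mode (`observation = "none"`) each trajectory is
  quantized to whole individuals in a single representative size class,
  and that quantized series *is* the recorded latent truth — this is what
  makes the exact round-trip test (`data_prep` output equals latent
  biomass) well-posed with integer abundances.

Not emulated: spatial autocorrelation between sites, mechanistic food-web
or habitat structure, species' thermal-affinity dynamics, and any direct
dependence of species-level variance on mean SST. Consequently a passing
test suite demonstrates that the *methods* are correct and recover known
structure; it does not certify any empirical claim about real reefs.

### Two levels of ground truth

Community-level simulation cannot guarantee *standardized linear* effect
sizes for emergent quantities (a facet computed from simulated communities
has no preordained regression coefficient on gravity). Parameter-recovery
and type-I-error experiments therefore use `simulate_path_data()`, which
draws site-level variables directly from a linear-Gaussian DAG with known
standardized coefficients (`default_path_truth()`, magnitudes 0.2–0.5,
signs matching the community generator's rules): exogenous variables are
standard normal and each endogenous variable has unit marginal variance,
so population standardized coefficients equal the declared ones exactly.
The community-level generator is tested for what it can guarantee —
effect *signs* recovered by regression on its latent biomass, null
configurations showing no effects, and exact reconstruction in the
noise-free mode. A full-pipeline null cannot have an exactly nominal
Fisher's C rejection rate, because facets and stability components derived
from the same matrices are mutually dependent even with all driver
effects zero; the nominal-rate check (rejection rate in [0.03, 0.07] at
$\alpha = 0.05$ over 500 replicates) is therefore run at the structural
level, where the claim is exact.

## Problem sizes and numerical choices

The test suite runs the partition identity on 1,000 random matrices
(tolerance $10^{-10}$), the Hill-number oracles on 500 random communities
($10^{-12}$), parameter recovery on 100 replicates of 500 sites
(requiring every effect's sign in $\ge 90\%$ and 95%-interval coverage in
$\ge 90\%$ of replicates), the null rejection rate on 500 replicates of
200 sites, the degradation trend on 20 seeds $\times$ 8 drop levels over
25 fully surveyed sites, and effect accumulation on 100 random DAGs.
The acceptance script re-runs the full pipeline at survey scale (215
sites, 655 species). Ties at the distinctiveness quantile are all
included (deterministic and order-independent); z-scoring uses the sample
standard deviation; a trait constant over the pool contributes a zero
axis rather than `NaN`s.

## Known limitations

* The basis-set exclusion list is a modelling decision; users who want
  facet–facet independence claims tested can pass their own
  `exclude_pairs`.
* Best-subset AICc selection, like any selection, admits spurious
  predictors at the usual information-criterion rate; the `delta` option
  trades this against power. p-values reported after selection are
  conditional on the selected structure.
* The interpolation rules (linear interior, constant edges) damp
  variance, biasing stability upward for sparsely surveyed sites — that
  is precisely why the number of surveyed years is carried as a control
  variable and why `degrade_and_correlate()` quantifies the distortion.
* `hill_functional()` accepts general Hill orders, but the pipeline fixes
  $q = 1$ and $\tau$ = mean distance; no dendrogram-based FD or
  categorical-trait distances are provided.
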
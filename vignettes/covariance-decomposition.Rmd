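---
title: "Hierarchical covariance decomposition of telomere length, infection, immunity and survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical covariance decomposition of telomere length, infection, immunity and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Longitudinal studies of wild vertebrates ask whether leucocyte relative
telomere length (RLTL) reflects physiological costs of parasite infection or
of mounting an immune response, and whether it mediates links between
infection, immunity and fitness. With repeated August captures of known
individuals one can measure, per individual and year: RLTL (a qPCR T/S
ratio), strongyle faecal egg count (FEC, eggs per gram from a McMaster
slide), plasma anti-nematode IgG level (IgG-Tc, a blank-corrected ELISA OD
ratio) and overwinter survival.

A raw correlation between, say, RLTL and FEC confounds three very different
processes. `telovar` decomposes trait covariances into hierarchical levels:

* **among-individual** — consistent differences between individuals
  (genetics, early environment, frailty);
* **among-year** — population-wide annual environment;
* **within-individual (residual)** — year-to-year deviations of an
  individual from its own mean.

A causal physiological link is expected to leave covariance at every level;
covariance confined to the within-individual level points to short-term,
state-dependent processes instead.

## The model

For trait $k$ of individual $i$ in year $t$, a latent value is built
additively:

$$\ell_{itk} = \mathbf{x}_{itk}^\top\boldsymbol\beta_k + u_{ik} + v_{tk}
  + (\text{assay batch effects})_k + e_{itk},$$

with $\mathbf{u}_i \sim \mathcal N(\mathbf 0, \Sigma_{\text{ind}})$,
$\mathbf{v}_t \sim \mathcal N(\mathbf 0, \Sigma_{\text{yr}})$ and
$\mathbf{e}_{it} \sim \mathcal N(\mathbf 0, \Sigma_{\text{res}})$, each an
unstructured $K \times K$ covariance matrix shared across traits.
Observation families:

* RLTL, IgG-Tc: Gaussian, observed directly ($y = \ell$);
* FEC: Poisson with log link around the latent value
  (Poisson-lognormal) — the residual-level latent variance *is* the
  overdispersion, honouring a negative-binomial-like marginal while keeping
  all covariances on a Gaussian latent scale;
* survival: Bernoulli through a logit (default) or probit link, with the
  residual latent variance fixed at exactly 1 — the standard identifiability
  constraint for binary traits, imposed by a conditional inverse-Wishart
  draw rather than post-hoc rescaling.

qPCR plate and row-within-plate enter the RLTL equation, and ELISA plate the
IgG-Tc equation, as scalar random intercepts ("assay" variances).

Fixed effects default to: age for RLTL; age, age² and sex for FEC; age and
sex for IgG-Tc; age (plus the lamb/adult factor in whole-population models)
for survival. Interactions are checked for marginality. Before fitting,
`prepare_model_traits()` z-scores RLTL, IgG-Tc and age and converts FEC back
to slide counts (rounded, divided by 100); correlations and repeatabilities
are invariant to this scaling, and the returned scaling constants allow
back-transforming fixed effects.

## Sampler

`fit_multivariate_glmm()` runs a purpose-built block Gibbs sampler
(RcppArmadillo):

1. conjugate joint GLS draw of all fixed effects across traits;
2. conjugate multivariate-normal draws of individual and year effects,
   grouped by replicate count;
3. **parameter expansion** for each random level: effects are stored as a
   working covariance $\Psi$ and redundant per-trait multipliers
   $\boldsymbol\alpha$, with $\Sigma = \mathrm{diag}(\boldsymbol\alpha)\,
   \Psi\,\mathrm{diag}(\boldsymbol\alpha)$. The working prior is
   inverse-Wishart with scale $I$ and the multipliers have
   $\mathcal N(0, 1000)$ priors (prior mean 0, variance 1, covariance 1000
   in the usual parameter-expanded phrasing). This keeps mixing healthy when
   variance components approach zero;
4. conjugate inverse-Wishart draw of the residual covariance; when a binary
   trait is present the draw is from the conditional inverse-Wishart with
   that diagonal element fixed at 1, via the Wishart block factorisation
   (the free block and the regression block are independent of the fixed
   Schur complement, which is pinned);
5. slice-sampling (stepping-out) updates of the latent values of count and
   binary traits, each against its Gaussian conditional prior given the
   other traits' residuals;
6. a non-centered Metropolis sweep on the residual entries that involve
   latent (count or binary) traits: each proposal perturbs one covariance
   entry and applies the matching linear transform to the latent residuals,
   so the Gaussian terms cancel and acceptance is decided by the observation
   likelihood. Without this move the correlation between two latent traits
   has almost no restoring force under plain data augmentation — it random
   walks and sticks near the singular boundary; with it, mixing of those
   correlations is near-white and the chain tracks the marginal information
   (verified against a direct Gauss–Hermite maximum-likelihood oracle on a
   bivariate count/binary model).

The residual prior defaults to inverse-Wishart with scale $I$ and degrees
of freedom $K + 1$ (configurable through `prior_spec()`), calibrated by
prior-predictive simulation on the *correlation* scale. Two facts drive the
choice. First, df $K + 1$ makes each free correlation marginally uniform.
Second — and specific to models with a binary trait — fixing the binary
residual variance at 1 makes the implied conditional prior on correlations
with that trait pile up at $\pm 1$ whenever the scale is small relative to
1 (the conditional regression coefficients acquire prior variance
proportional to 1/scale); a scale comparable to the fixed variance keeps
that implied prior flat. Near-zero scales additionally let a chain with
several latent (count and binary) traits fall onto a quasi-absorbing
boundary ridge where two traits' latent residuals become deterministic
copies of each other; a draw whose residual correlation matrix has an
eigenvalue below `residual_eigen_floor` (default 0.2) is rejected as a
safety net. The parameter-expanded working prior uses df $K + 1$ for the
same uniform-correlation reason. Fixed effects have $\mathcal N(0, 10^8)$
priors. A
single integer seed makes a chain bit-reproducible on one platform. The
production chain default is 495,000 iterations with 95,000 warm-up and
thinning 400 (1000 stored draws); all examples and tests scale this down.

Point estimates are posterior **modes** (Gaussian-kernel density with
Silverman bandwidth on a fine grid), uncertainty is the 95% **highest
posterior density** interval (shortest contiguous window of sorted draws),
significance is strict exclusion of zero, and every stored chain is screened
for lag-1 autocorrelation below 0.1 (`autocorrelation_check()`).

## Derived quantities

All derived quantities are computed **per stored draw** and then summarised,
so posterior uncertainty propagates exactly:

* `tv_correlations()`: $r = \sigma_{jk} / (\sigma_j \sigma_k)$ per level;
* `tv_repeatability()`: among-individual variance over the sum of
  among-individual, among-year and residual variances. Assay batch variances
  are **excluded** from the denominator by default — they are measurement
  noise external to the phenotype — with `include_assay = TRUE` as the
  alternative;
* `tv_survival_gradients()`: per level,
  $\boldsymbol\beta = \Sigma_{pp}^{-1}\boldsymbol\sigma_{ps}$ — the partial
  regression of survival on the other traits within that level, i.e. each
  trait's association with survival after accounting for trait-trait
  covariance. Draws with a singular predictor sub-matrix are skipped and
  counted, never silently regularised.

## Assay-level trait computation

* `compute_rltl()` implements the calibrator-normalised T/S ratio
  $E_{TEL}^{\Delta Cq_{TEL}} / E_{B2M}^{\Delta Cq_{B2M}}$, excluding samples
  whose triplicate coefficient of variation exceeds 5% on either amplicon or
  whose plate efficiency leaves a configurable window (default 1.6–2.2; the
  upstream efficiency rule is not quantified, so the window is this
  package's explicit choice).
* `od_ratio()` is the blank-corrected OD ratio; `filter_elisa_duplicates()`
  removes duplicate pairs with COV above 0.2 (we read "0.2 OD units" as the
  dimensionless COV with threshold 0.2); `check_plate_pair()` fails a
  duplicate plate pair whose OD correlation falls below 0.8.
* Threshold comparisons are strict as printed; boundary values pass.
* `fec_from_count()` multiplies McMaster slide counts by 100.

## The synthetic-data generator

`simulate_population()` draws the full data-generating process with known
truth: staggered cohort entry (lambs at age 0, or a standing adult panel),
annual survival through the same latent machinery — so trait–survival
covariances are *induced* by the configured matrices, never hard-coded —
capture as a single Bernoulli per alive-year, assay plates assigned across
years, and per-trait MCAR missingness (the analyses are complete-case, so
MCAR keeps subset construction clean). With `capture_prob = 0` the generator
degenerates to a first-captures-only cross-section rather than an empty
dataset.

Default conditions emulate the study system: 1366 individuals over 19
cohorts, capture probability 0.55, per-trait missingness of 0.15–0.20
(different assays have different coverage), total latent SDs 0.15 (RLTL),
1.0 (log FEC) and 0.18 (IgG-Tc), among-individual variance shares 0.254 /
0.375 / 0.595, among-year shares 0.05 / 0.10 / 0.05, survival latent
variances 0.5 (individual) and 0.3 (year) with residual 1, and the published
point estimates as level correlations (within-individual RLTL–FEC 0.190,
among-individual RLTL–survival 0.318, within-individual FEC–survival
−0.461, within-individual IgG-Tc–survival 0.181). Values the source analysis
does not print — year shares, survival latent variances, assay SDs, capture
and demographic rates — were chosen once as field-realistic and are stated
here rather than revisited. Egg counts default to a Poisson draw around the
exponentiated latent value (`fec_dispersion = Inf`), so the generator
coincides with the fitted Poisson-lognormal family; a finite
negative-binomial size adds extra count noise for robustness checks.

Two presets pin the study scales. `sim_config_adult_trivariate()` follows
the full 19-year design (572 adults entering at ages 3–7 across the first 15
years, capture 0.79, giving roughly the published 1348 adult observations);
the number of year levels matters because year-level variances are estimated
from as many effective replicates as there are years.
`sim_config_population_quadrivariate()` is a deliberately scaled-down
population (700 lamb-entry individuals across 9 cohorts of a 12-year window,
capture 0.72, roughly 1500 observations). The shorter window is a design
choice, not a shortcut: at half the real sample size, a window long enough
for near-complete lifespans lets selective disappearance be absorbed by the
age fixed effects (an age–frailty confound) and the among-individual
survival variance becomes unidentifiable; keeping the window shorter than
the lifespan horizon preserves the censoring balance of the full study and
keeps the among-individual survival components estimable. Entry and capture
rates were set by design arithmetic to reproduce the target sample sizes.

What the generator deliberately does **not** emulate: spatial structure,
maternal and genetic effects, density dependence, age- or sex-biased
trapping, and non-random missingness. Passing recovery tests therefore shows
the estimator is consistent for this data-generating process at field sample
sizes — not that real data meet these assumptions.

## Numerical choices and degenerate inputs

* Covariance draws are validated symmetric positive definite; initial values
  are $0.1\,I$ (residual $I$), fixed effects start at trait-wise OLS on the
  initialised latent scale.
* A constant stored chain has undefined autocorrelation: treated as passing,
  with a warning.
* Zero variance in a trait to be z-scored, degenerate ELISA plates
  (positive ≤ blank), efficiencies ≤ 1, negative egg counts, and empty
  complete-case subsets all raise explicit errors.
* Unused factor levels are dropped; sex is a two-level factor with female as
  reference (an arbitrary, documented contrast).
* Chain lengths in the tests and in `scripts/acceptance.R` (50,000
  iterations for the trivariate fit, 80,000 for the quadrivariate fit, 1000+
  stored draws) are this package's validation-scale choice: long enough that
  the lag-1 autocorrelation screen passes for the reported quantities while
  keeping a full run in minutes.

## Known limitations

* Binary survival carries little information per observation: at ~1400
  observations the posterior for survival covariances is wide, and
  level attribution (individual vs residual) is weakly identified at ~2
  samples per individual. Recovery tolerances for survival correlations are
  correspondingly loose.
* **Informative panel attrition.** Like the analyses it implements, the model
  treats records as exchangeable given the latent effects, but in a
  mortality-driven panel membership itself depends on the survival trait:
  individuals leave the data at their first death. A paired simulation
  experiment (the generator's diagnostic `attrition = FALSE` switch) shows
  the consequences at the reduced validation scale: with attrition disabled
  all quadrivariate parameters are recovered, while with attrition enabled
  the among-individual survival variance is strongly shrunk and the residual
  egg-count–survival correlation magnitude is inflated (posterior modes near
  −0.6 to −0.7 when the generating value is −0.461). Quadrivariate
  survival-covariance estimates from this model class should therefore be
  read as conditional on non-informative panel membership, an assumption
  wild-population mortality data violate by construction.
* One chain per fit; convergence screening is the lag-1 autocorrelation rule
  plus trace plots (`autoplot(fit)`), not multi-chain diagnostics.
* No imputation: every model is complete-case, with filter counts logged.
* The survival fixed-effect structure (intercept, age, age-class) is a
  configurable default, as is the repeatability denominator.
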
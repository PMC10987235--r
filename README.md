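# telovar

Hierarchical covariance decomposition of leucocyte telomere length, helminth
infection, antibody immunity and overwinter survival in longitudinal
individual-based field studies.

## The problem

In wild populations, telomere length is often proposed as a biomarker of the
physiological costs of infection and immune investment, and as a mediator of
trade-offs with fitness. Testing this needs more than a raw correlation:
repeated measurements of the same individuals across years let the covariance
between traits be split into **among-individual**, **among-year** and
**within-individual (residual)** components, each with a different biological
reading. `telovar` implements that decomposition end to end for four traits
measured at annual captures of wild sheep-like systems:

* **RLTL** — relative leucocyte telomere length, the qPCR ratio
  `E_TEL^(Cq_TEL[cal] − Cq_TEL[sample]) / E_B2M^(Cq_B2M[cal] − Cq_B2M[sample])`
  with triplicate-COV (5%) and efficiency-window QC;
* **FEC** — strongyle faecal egg count (McMaster slide count × 100 eggs/g);
* **IgG-Tc** — anti-nematode plasma IgG as the blank-corrected ELISA OD ratio
  `(sample − blank) / (positive − blank)`, with duplicate-COV (0.2) and
  plate-pair correlation (0.8) QC;
* **survival** — binary overwinter survival.

The core model is a multivariate generalized linear mixed model: per trait
*k*, individual *i*, year *t*,

    l_itk = x_itk' beta_k + u_ik + v_tk + (assay effects) + e_itk,
    u_i ~ N(0, Sigma_ind),  v_t ~ N(0, Sigma_yr),  e_it ~ N(0, Sigma_res),

with unstructured K×K covariance matrices shared across traits, Gaussian
observation for RLTL and IgG-Tc, a log-link latent-Gaussian (Poisson-
lognormal) family for FEC and a logit latent value with residual variance
fixed at 1 for survival. Fitting is by a purpose-built parameter-expanded
block Gibbs sampler (RcppArmadillo) with slice-sampled latent values; point
estimates are posterior modes with 95% highest-posterior-density intervals.
From the fitted covariance matrices the package derives, per stored draw:
level-specific correlations `cov/(sd·sd)`, repeatabilities
`V_ind/(V_ind+V_yr+V_res)`, and partial regression coefficients of survival
on the other traits `beta = Sigma_pp^-1 sigma_ps`.

A synthetic-data generator (`simulate_population()`) draws the whole process
with known ground truth — staggered cohorts, latent-scale survival coupling,
assay plates, missingness — so every stage is testable without any field
data; raw-plate simulators invert the qPCR and ELISA formulas for round-trip
tests of the assay layer.

## Worked example

```r
library(telovar)

# simulate an adult panel at the published study scale (572 adults, ~1350
# complete records over 19 years) with known truth: repeatabilities
# 0.254/0.375/0.595 and a residual RLTL-FEC correlation of 0.190
cfg <- sim_config_adult_trivariate(seed = 1)
sim <- simulate_population(cfg)

adults <- subset_records(sim$records, "adults3")   # age >= 3, complete cases
prep   <- prepare_model_traits(adults)             # z-score RLTL/IgG/age, FEC -> counts

spec <- model_spec(c("rltl", "fec", "igg_tc"),
                   iterations = 50000, warmup = 10000, thin = 40, seed = 8)
fit <- fit_multivariate_glmm(prep, spec)

tv_repeatability(fit)
#> # A tibble: 3 × 6
#>   trait  estimate conf.low conf.high significant lag1_autocorr
#>   <chr>     <dbl>    <dbl>     <dbl> <lgl>               <dbl>
#> 1 rltl      0.300    0.211     0.357 TRUE              -0.0194
#> 2 fec       0.423    0.334     0.507 TRUE              -0.0346
#> 3 igg_tc    0.592    0.526     0.644 TRUE               0.0530

dplyr::filter(tv_correlations(fit), level == "residual")
#> # A tibble: 3 × 8
#>   level    trait_1 trait_2 estimate conf.low conf.high significant lag1_autocorr
#>   <chr>    <chr>   <chr>      <dbl>    <dbl>     <dbl> <lgl>               <dbl>
#> 1 residual rltl    fec      0.170     0.0666    0.249  TRUE               0.0157
#> 2 residual rltl    igg_tc  -0.00430  -0.0716    0.0735 FALSE             -0.0155
#> 3 residual fec     igg_tc   0.0300   -0.0536    0.128  FALSE             -0.0151
```

The repeatability modes track the generating variance shares (0.254, 0.375,
0.595), the residual telomere–egg-count correlation recovers its generating
value 0.190 with an HPD excluding zero, and the two correlations generated at
zero are correctly non-significant. `autoplot()` on any derived table gives a
forest plot; `tidy(fit)` / `glance(fit)` return the full posterior summary
and chain health (`autocorrelation_check`).

For survival, `analysis_plan("population_quadrivariate")` + `run_plan()`
drive the same pipeline on the whole population and add
`tv_survival_gradients()`, the per-level multiple regression of survival on
RLTL, FEC and IgG-Tc.

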
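TV_TRAITS <- c("rltl", "fec", "igg_tc", "survival")

#' Build level-specific covariance matrices from variance shares
#'
#' Convenience constructor for the among-individual, among-year and residual
#' covariance matrices of the four modelled traits (relative telomere length,
#' faecal egg count on the latent log scale, antibody OD ratio, and survival
#' on the latent link scale). Gaussian-trait components are parameterised by a
#' total latent SD, the among-individual share (the trait's repeatability when
#' assay variance is excluded) and the among-year share; survival components
#' are absolute latent variances with the residual fixed at 1 (the standard
#' identifiability constraint for a binary trait). Cross-trait covariances are
#' supplied as named correlations per level, e.g. `c("rltl:fec" = 0.19)`.
#'
#' @param repeatability Named among-individual variance shares for the
#'   Gaussian-scale traits.
#' @param year_share Named among-year variance shares.
#' @param total_sd Named total latent SDs (individual + year + residual).
#' @param survival Named latent variances for survival at the individual and
#'   year levels (residual always 1).
#' @param cor_individual,cor_year,cor_residual Named correlation vectors;
#'   names are `"traitA:traitB"` pairs.
#' @return A list with elements `individual`, `year`, `residual`: symmetric
#'   4x4 covariance matrices with dimnames over the traits.
#' @export
sigma_matrices <- function(repeatability = c(rltl = 0.254, fec = 0.375, igg_tc = 0.595),
                           year_share = c(rltl = 0.05, fec = 0.10, igg_tc = 0.05),
                           total_sd = c(rltl = 0.15, fec = 1.0, igg_tc = 0.18),
                           survival = c(individual = 0.5, year = 0.3),
                           cor_individual = c("rltl:survival" = 0.318),
                           cor_year = numeric(),
                           cor_residual = c("rltl:fec" = 0.190,
                                            "fec:survival" = -0.461,
                                            "igg_tc:survival" = 0.181)) {
  gtr <- c("rltl", "fec", "igg_tc")
  if (any(repeatability[gtr] + year_share[gtr] >= 1)) {
    abort("Repeatability plus year share must be below 1 for every trait.")
  }
  v <- list(
    individual = c(repeatability[gtr] * total_sd[gtr]^2,
                   survival = unname(survival["individual"])),
    year = c(year_share[gtr] * total_sd[gtr]^2,
             survival = unname(survival["year"])),
    residual = c((1 - repeatability[gtr] - year_share[gtr]) * total_sd[gtr]^2,
                 survival = 1)
  )
  cors <- list(individual = cor_individual, year = cor_year,
               residual = cor_residual)
  purrr::map2(v, cors, function(vars, rho) {
    vars <- setNames(as.numeric(vars), TV_TRAITS)
    m <- diag(vars)
    dimnames(m) <- list(TV_TRAITS, TV_TRAITS)
    for (nm in names(rho)) {
      pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (length(pair) != 2 || !all(pair %in% TV_TRAITS)) {
        abort(paste0("Unknown trait pair in correlation name: `", nm, "`."))
      }
      m[pair[1], pair[2]] <- m[pair[2], pair[1]] <-
        rho[[nm]] * sqrt(vars[pair[1]] * vars[pair[2]])
    }
    assert_psd(m, nm = "level covariance matrix")
    m
  })
}

assert_psd <- function(m, nm = "covariance matrix", tol = 1e-8) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    abort(paste0("The ", nm, " must be symmetric."))
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    abort(paste0("The ", nm, " is not positive semi-definite."))
  }
  invisible(m)
}

default_fixed_effects <- function() {
  list(
    rltl = c(intercept = 1.0, age = -0.006),
    fec = c(intercept = 2.2, adult = -0.8, age = -0.05, age2 = 0.001,
            sex_m = 0.3),
    igg_tc = c(intercept = 0.55, adult = 0.12, age = 0.01, sex_m = -0.04),
    survival = c(intercept = 0.3, adult = 1.2, age = -0.08)
  )
}

#' Simulation configuration for a longitudinal wild-population study
#'
#' Defines the ground truth for [simulate_population()]: demography (cohort
#' entry, annual overwinter survival, capture probability), per-trait fixed
#' effects, correlated random effects at the individual, year and residual
#' levels, assay batch effects and per-trait missingness. Defaults emulate a
#' two-decade individual-based sheep study: ~19 annual cohorts, roughly half
#' the population trapped each August, Gaussian telomere-length and antibody
#' traits, an overdispersed egg count and binary overwinter survival.
#'
#' @param n_individuals Number of individuals ever entering the study.
#' @param n_years Number of study years (annual cohorts).
#' @param capture_prob Probability an alive individual is trapped in a year.
#' @param max_age Age at which any survivor dies (years).
#' @param sex_ratio Probability an individual is female.
#' @param entry_ages Integer vector of possible ages at entry; the default
#'   `0` enters everyone as a lamb. Supplying e.g. `3:7` simulates a standing
#'   adult panel.
#' @param entry_year_max Last year in which new individuals may enter.
#' @param fixed_effects Per-trait named coefficient vectors with names among
#'   `intercept`, `age`, `age2`, `sex_m`, `adult`.
#' @param sigma_individual,sigma_year,sigma_residual Symmetric 4x4 covariance
#'   matrices over `rltl`, `fec`, `igg_tc`, `survival` (see
#'   [sigma_matrices()]). The survival residual variance should be 1 for a
#'   logit/probit latent scale.
#' @param assay_sds Named SDs for `qpcr_plate`, `qpcr_row`, `elisa_plate`
#'   batch effects.
#' @param fec_dispersion Negative-binomial size for the egg-count draw around
#'   its lognormal latent mean; `Inf` (default) gives a Poisson draw so all
#'   overdispersion lives on the latent scale.
#' @param survival_link `"logit"` (default) or `"probit"`.
#' @param missingness Named per-trait missing probabilities (MCAR).
#' @param attrition If `TRUE` (default) an individual disappears after its
#'   first survival = 0 draw, as in a real mortality-driven panel. `FALSE`
#'   keeps individuals under observation to `max_age` regardless of the
#'   recorded survival trait — a diagnostic mode that breaks the link between
#'   the survival outcome and panel membership.
#' @param qpcr_plate_size,qpcr_rows,elisa_plate_size Batch geometry.
#' @param qpcr_triplicate_sd,elisa_duplicate_sd Replicate noise (Cq cycles /
#'   OD units) used by the raw-plate simulators.
#' @param seed Integer seed controlling all randomness.
#' @return A validated list of class `tv_sim_config`.
#' @export
sim_config <- function(n_individuals = 1366,
                       n_years = 19,
                       capture_prob = 0.55,
                       max_age = 10,
                       sex_ratio = 0.5,
                       entry_ages = 0L,
                       entry_year_max = n_years,
                       fixed_effects = default_fixed_effects(),
                       sigma_individual = NULL,
                       sigma_year = NULL,
                       sigma_residual = NULL,
                       assay_sds = c(qpcr_plate = 0.03, qpcr_row = 0.02,
                                     elisa_plate = 0.04),
                       fec_dispersion = Inf,
                       survival_link = c("logit", "probit"),
                       missingness = c(rltl = 0.15, fec = 0.20,
                                       igg_tc = 0.15, survival = 0),
                       qpcr_plate_size = 30,
                       qpcr_rows = 8,
                       elisa_plate_size = 40,
                       qpcr_triplicate_sd = 0.05,
                       elisa_duplicate_sd = 0.01,
                       attrition = TRUE,
                       seed = 1L) {
  sig <- sigma_matrices()
  if (is.null(sigma_individual)) sigma_individual <- sig$individual
  if (is.null(sigma_year)) sigma_year <- sig$year
  if (is.null(sigma_residual)) sigma_residual <- sig$residual
  survival_link <- match.arg(survival_link)

  stopifnot(n_individuals >= 1, n_years >= 1, max_age >= 1)
  probs <- c(capture_prob, sex_ratio, missingness)
  if (any(probs < 0 | probs > 1)) {
    abort("Probabilities must lie in [0, 1].")
  }
  if (fec_dispersion <= 0) abort("`fec_dispersion` must be positive.")
  for (m in list(sigma_individual, sigma_year, sigma_residual)) {
    if (!identical(dim(m), c(4L, 4L))) {
      abort("Sigma matrices must be 4x4 over rltl, fec, igg_tc, survival.")
    }
    assert_psd(m)
  }
  miss <- setNames(rep(0, 4), TV_TRAITS)
  miss[names(missingness)] <- missingness

  structure(list(
    n_individuals = as.integer(n_individuals), n_years = as.integer(n_years),
    capture_prob = capture_prob, max_age = as.integer(max_age),
    sex_ratio = sex_ratio, entry_ages = as.integer(entry_ages),
    entry_year_max = as.integer(min(entry_year_max, n_years)),
    fixed_effects = fixed_effects,
    sigma_individual = unname(sigma_individual),
    sigma_year = unname(sigma_year),
    sigma_residual = unname(sigma_residual),
    assay_sds = assay_sds, fec_dispersion = fec_dispersion,
    survival_link = survival_link, missingness = miss,
    qpcr_plate_size = qpcr_plate_size, qpcr_rows = qpcr_rows,
    elisa_plate_size = elisa_plate_size,
    qpcr_triplicate_sd = qpcr_triplicate_sd,
    elisa_duplicate_sd = elisa_duplicate_sd,
    attrition = isTRUE(attrition),
    seed = as.integer(seed)
  ), class = "tv_sim_config")
}

#' Preset: adult trivariate study conditions
#'
#' A configuration matching the scale of the adult (age >= 3) trivariate
#' analysis: a standing panel of 572 adults sampled over 19 study years
#' (entering in the first 15), entry ages 3-7, no missingness, and level covariance
#' matrices whose among-individual shares equal the adult repeatability
#' estimates (0.254, 0.375, 0.595) with a residual-level telomere-egg-count
#' correlation of 0.190 and all other cross-trait covariances zero.
#'
#' @param seed Integer seed.
#' @param capture_prob Annual capture probability (chosen so the realized
#'   sample size matches the study scale).
#' @param ... Overrides passed on to [sim_config()].
#' @return A `tv_sim_config`.
#' @export
sim_config_adult_trivariate <- function(seed = 1L, capture_prob = 0.79, ...) {
  sig <- sigma_matrices(cor_individual = numeric(),
                        cor_residual = c("rltl:fec" = 0.190))
  sim_config(n_individuals = 572, n_years = 19, capture_prob = capture_prob,
             entry_ages = 3:7, entry_year_max = 15,
             sigma_individual = sig$individual, sigma_year = sig$year,
             sigma_residual = sig$residual,
             missingness = c(rltl = 0, fec = 0, igg_tc = 0, survival = 0),
             seed = seed, ...)
}

#' Preset: whole-population quadrivariate study conditions
#'
#' A reduced-scale population (700 individuals entering as lambs over 9
#' cohorts, followed for 12 years) for the four-trait model of telomere
#' length, egg count, antibody level and overwinter survival. Survival
#' covariances are set at the whole-population point estimates: among-
#' individual telomere-survival latent correlation 0.318 and residual
#' egg-count-survival latent correlation -0.461; all other cross-trait
#' covariances are zero.
#'
#' @inheritParams sim_config_adult_trivariate
#' @return A `tv_sim_config`.
#' @export
sim_config_population_quadrivariate <- function(seed = 1L, capture_prob = 0.72, ...) {
  sig <- sigma_matrices(cor_individual = c("rltl:survival" = 0.318),
                        cor_residual = c("fec:survival" = -0.461))
  sim_config(n_individuals = 700, n_years = 12, capture_prob = capture_prob,
             entry_ages = 0L, entry_year_max = 9,
             sigma_individual = sig$individual, sigma_year = sig$year,
             sigma_residual = sig$residual,
             missingness = c(rltl = 0, fec = 0, igg_tc = 0, survival = 0),
             seed = seed, ...)
}
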
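#' Prior settings for the Gibbs sampler
#'
#' Variance components at the individual and year levels (and the assay batch
#' variances) carry parameter-expanded priors: a working inverse-Wishart with
#' scale `px_variance * I` and the redundant multipliers given independent
#' Gaussian priors with mean `px_mean` and variance `px_alpha_variance`. The
#' residual covariance matrix carries an inverse-Wishart prior with scale
#' `residual_scale * I` and degrees of freedom `K + residual_df_add` (K =
#' number of traits). The defaults (scale 1, df K + 1) are calibrated on the
#' prior-predictive correlation scale: df K + 1 makes each free correlation
#' marginally uniform, and a scale comparable to the fixed binary residual
#' variance (1) keeps the implied prior on binary-trait correlations flat as
#' well — with a near-zero scale that implied prior piles up at +/-1 (the
#' conditional regression coefficients get prior variance proportional to
#' 1/scale), which both biases weakly-identified correlations outward and
#' lets chains with several latent traits collapse onto a singular boundary
#' ridge. Binary-trait residual variances are fixed at 1 and not sampled.
#' Fixed effects have independent N(0, `beta_variance`) priors.
#'
#' @param px_variance Working inverse-Wishart scale (default 1).
#' @param px_mean Prior mean of the redundant multipliers (default 0).
#' @param px_alpha_variance Prior variance of the redundant multipliers
#'   (default 1000).
#' @param residual_scale,residual_df_add Residual inverse-Wishart scale factor
#'   and degrees-of-freedom increment over the trait count (defaults 1 and 1).
#' @param residual_eigen_floor Truncation of the residual prior: draws whose
#'   residual correlation matrix has an eigenvalue below this floor are
#'   rejected (default 0.2). Latent (count/binary) trait pairs can otherwise
#'   fall into a quasi-absorbing singular state where their residuals become
#'   deterministic copies of each other.
#' @param beta_variance Fixed-effect prior variance (default 1e8).
#' @return A list of class `tv_prior`.
#' @export
prior_spec <- function(px_variance = 1, px_mean = 0, px_alpha_variance = 1000,
                       residual_scale = 1, residual_df_add = 1,
                       residual_eigen_floor = 0.2,
                       beta_variance = 1e8) {
  structure(list(px_variance = px_variance, px_mean = px_mean,
                 px_alpha_variance = px_alpha_variance,
                 residual_scale = residual_scale,
                 residual_df_add = residual_df_add,
                 residual_eigen_floor = residual_eigen_floor,
                 beta_variance = beta_variance),
            class = "tv_prior")
}

default_family <- function(trait) {
  switch(trait,
         rltl = "gaussian", igg_tc = "gaussian",
         fec = "count", survival = "binary-logit",
         "gaussian")
}

default_fixed_terms <- function(trait, age_class = FALSE) {
  base <- switch(trait,
    rltl = ~age,
    fec = ~ age + I(age^2) + sex,
    igg_tc = ~ age + sex,
    survival = ~age,
    ~1
  )
  if (age_class) stats::update.formula(base, ~ . + age_class) else base
}

check_marginality <- function(f, trait) {
  tt <- stats::terms(f)
  labs <- attr(tt, "term.labels")
  ords <- attr(tt, "order")
  for (i in which(ords > 1)) {
    parts <- strsplit(labs[i], ":", fixed = TRUE)[[1]]
    if (!all(parts %in% labs)) {
      abort(paste0("Fixed effects for `", trait, "` violate marginality: `",
                   labs[i], "` requires main effects ",
                   paste(setdiff(parts, labs), collapse = ", "), "."))
    }
  }
  invisible(f)
}

#' Specify a univariate or multivariate mixed model
#'
#' Defines the response traits, their observation families, per-trait fixed
#' effects, the shared random levels whose covariance matrices are
#' unstructured, trait-specific assay batch effects and the chain settings.
#' Relative telomere length and antibody level are Gaussian; the faecal egg
#' count uses a log-link latent Gaussian (Poisson-lognormal, so the residual
#' level carries the overdispersion); survival is binary through a logit
#' (default) or probit latent value whose residual variance is fixed at 1.
#'
#' @param traits Ordered character vector among `rltl`, `fec`, `igg_tc`,
#'   `survival` (each at most once).
#' @param fixed Named list of one-sided formulas, one per trait; defaults to
#'   the standard structure (telomere length: age; egg count: age + age^2 +
#'   sex; antibody: age + sex; survival: age) with `age_class` added when
#'   `age_class = TRUE`. Interactions must obey marginality.
#' @param families Optional named overrides among `gaussian`, `count`,
#'   `binary-logit`, `binary-probit`.
#' @param random_levels Subset of `c("individual", "year")`.
#' @param assay_effects Named list mapping a trait to batch-label columns,
#'   default qPCR plate and row for telomere length and ELISA plate for the
#'   antibody trait.
#' @param age_class Add the lamb/adult factor to every trait's fixed effects
#'   (used for whole-population models).
#' @param iterations,warmup,thin Chain settings. Defaults match a long
#'   production run (495000 / 95000 / 400, storing 1000 draws); scale these
#'   down for exploratory fits.
#' @param seed Integer seed controlling the whole chain.
#' @param priors A [prior_spec()].
#' @return A list of class `tv_model_spec`.
#' @export
model_spec <- function(traits,
                       fixed = NULL,
                       families = NULL,
                       random_levels = c("individual", "year"),
                       assay_effects = list(rltl = c("qpcr_plate", "qpcr_row"),
                                            igg_tc = "elisa_plate"),
                       age_class = FALSE,
                       iterations = 495000, warmup = 95000, thin = 400,
                       seed = 1L,
                       priors = prior_spec()) {
  if (anyDuplicated(traits)) abort("Each trait may be listed at most once.")
  fam <- vapply(traits, default_family, character(1))
  if (!is.null(families)) fam[names(families)] <- unlist(families)
  ok <- c("gaussian", "count", "binary-logit", "binary-probit")
  if (!all(fam %in% ok)) abort("Unknown family; use gaussian, count, binary-logit or binary-probit.")
  if (is.null(fixed)) fixed <- list()
  for (tr in traits) {
    if (is.null(fixed[[tr]])) fixed[[tr]] <- default_fixed_terms(tr, age_class)
    check_marginality(fixed[[tr]], tr)
  }
  random_levels <- match.arg(random_levels, c("individual", "year"),
                             several.ok = TRUE)
  if (((iterations - warmup) %% thin) != 0) {
    warn("(iterations - warmup) is not a multiple of thin; the trailing partial interval is dropped.")
  }
  structure(list(
    traits = traits, families = fam, fixed = fixed[traits],
    random_levels = random_levels,
    assay_effects = assay_effects[intersect(names(assay_effects), traits)],
    mcmc = list(iterations = as.integer(iterations),
                warmup = as.integer(warmup), thin = as.integer(thin),
                seed = as.integer(seed)),
    priors = priors
  ), class = "tv_model_spec")
}
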
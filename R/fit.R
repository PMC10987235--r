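fam_code <- function(f) {
  c("gaussian" = 0L, "count" = 1L, "binary-logit" = 2L,
    "binary-probit" = 3L)[[f]]
}

init_latent_scale <- function(y, fam) {
  switch(as.character(fam),
         "0" = y,
         "1" = log(y + 0.5),
         ifelse(y > 0.5, 1, -1))
}

# shared engine behind the univariate and multivariate fitting fronts
fit_engine <- function(records, spec) {
  records <- as_tibble(records)
  traits <- spec$traits
  K <- length(traits)

  vars_needed <- unique(c(
    traits,
    unlist(lapply(spec$fixed, all.vars)),
    if ("individual" %in% spec$random_levels) "individual_id",
    if ("year" %in% spec$random_levels) "year",
    unlist(spec$assay_effects)
  ))
  missing_cols <- setdiff(vars_needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("Records lack columns required by the model: ",
                 paste(missing_cols, collapse = ", ")))
  }
  dat <- records[stats::complete.cases(records[vars_needed]), , drop = FALSE]
  n <- nrow(dat)
  if (n == 0) abort("No complete cases for the requested traits and terms.")
  if ("sex" %in% names(dat) && is.character(dat$sex)) dat$sex <- factor(dat$sex)
  if ("age_class" %in% names(dat) && is.character(dat$age_class)) {
    dat$age_class <- factor(dat$age_class, levels = c("lamb", "adult"))
    dat$age_class <- droplevels(dat$age_class)
  }

  fams <- vapply(spec$families[traits], fam_code, integer(1))
  Y <- matrix(0, n, K)
  for (k in seq_len(K)) {
    y <- dat[[traits[k]]]
    if (fams[k] == 1L) {
      if (any(y < 0) || max(abs(y - round(y))) > 1e-8) {
        abort(paste0("Count trait `", traits[k],
                     "` must hold non-negative integers; run prepare_model_traits() first."))
      }
      y <- round(y)
    }
    if (fams[k] >= 2L && !all(y %in% c(0, 1))) {
      abort(paste0("Binary trait `", traits[k], "` must be 0/1."))
    }
    if (fams[k] == 0L && stats::sd(y) == 0) {
      abort(paste0("Trait `", traits[k], "` has zero variance."))
    }
    Y[, k] <- y
  }

  Xlist <- lapply(seq_len(K), function(k) {
    X <- stats::model.matrix(spec$fixed[[traits[k]]], data = dat)
    colnames(X) <- paste0(traits[k], ":", colnames(X))
    X
  })
  beta_init <- unlist(lapply(seq_len(K), function(k) {
    z <- init_latent_scale(Y[, k], fams[k])
    stats::lm.fit(Xlist[[k]], z)$coefficients
  }))
  beta_init[!is.finite(beta_init)] <- 0

  id_idx <- if ("individual" %in% spec$random_levels) {
    as.integer(factor(dat$individual_id)) - 1L
  } else integer(0)
  year_idx <- if ("year" %in% spec$random_levels) {
    as.integer(factor(dat$year)) - 1L
  } else integer(0)

  assays <- list()
  assay_names <- character(0)
  for (tr in names(spec$assay_effects)) {
    for (col in spec$assay_effects[[tr]]) {
      assays[[length(assays) + 1L]] <- list(
        trait = match(tr, traits) - 1L,
        idx = as.integer(factor(dat[[col]])) - 1L
      )
      assay_names <- c(assay_names, paste0(tr, ":", col))
    }
  }

  pr <- spec$priors
  prior <- list(V_R = diag(pr$residual_scale, K),
                nu_R = K + pr$residual_df_add,
                px_V = diag(pr$px_variance, K),
                px_nu = K + 1,
                alpha_variance = pr$px_alpha_variance,
                beta_variance = pr$beta_variance)

  control <- list(update_sigma_ind = TRUE, update_sigma_year = TRUE,
                  update_sigma_res = TRUE,
                  eigen_floor = pr$residual_eigen_floor,
                  mh_sweep = TRUE,
                  sigma_ind_init = diag(0.1, K),
                  sigma_year_init = diag(0.1, K),
                  sigma_res_init = diag(1, K),
                  beta_init = beta_init)
  extra <- attr(spec, "engine_control")
  if (!is.null(extra)) control <- modifyList(control, extra)

  mc <- spec$mcmc
  set.seed(mc$seed)
  raw <- .gibbs_glmm_cpp(Y, fams, Xlist, id_idx, year_idx, assays, prior,
                         mc$iterations, mc$warmup, mc$thin, control)

  S <- raw$n_stored
  beta <- raw$beta[seq_len(S), , drop = FALSE]
  colnames(beta) <- unlist(lapply(Xlist, colnames))
  dimnames_kk <- list(traits, traits, NULL)
  shape <- function(a) {
    a <- a[, , seq_len(S), drop = FALSE]
    dimnames(a) <- dimnames_kk
    a
  }
  draws <- list(
    beta = beta,
    sigma_individual = if ("individual" %in% spec$random_levels) shape(raw$sigma_ind),
    sigma_year = if ("year" %in% spec$random_levels) shape(raw$sigma_year),
    sigma_residual = shape(raw$sigma_res),
    assay_var = if (length(assays)) {
      m <- raw$assay_var[seq_len(S), seq_along(assays), drop = FALSE]
      colnames(m) <- assay_names
      m
    }
  )
  structure(list(
    draws = draws, spec = spec, traits = traits,
    n_obs = n,
    n_individuals = if (length(id_idx)) dplyr::n_distinct(id_idx) else NA_integer_,
    n_years = if (length(year_idx)) dplyr::n_distinct(year_idx) else NA_integer_,
    n_stored = S,
    data = dat
  ), class = "tv_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a univariate Gaussian mixed model by Gibbs sampling
#'
#' Bayesian linear mixed model with crossed random intercepts (year and assay
#' batches, plus individual identity for repeat-measures models), used for
#' the lamb analyses of telomere length against egg count and antibody level
#' and for the adult sex-interaction models.
#'
#' @param records Capture-record tibble (already subset; complete cases are
#'   taken over every model term).
#' @param spec A [model_spec()] with a single Gaussian trait.
#' @return A `tv_fit`: stored draws of every fixed effect, variance component
#'   and assay variance, with [tidy()], [glance()] and [autoplot()] methods.
#' @export
fit_univariate_lmm <- function(records, spec) {
  if (length(spec$traits) != 1 || spec$families[[1]] != "gaussian") {
    abort("fit_univariate_lmm() expects a spec with exactly one Gaussian trait.")
  }
  fit_engine(records, spec)
}

#' Fit a multivariate GLMM with level-specific covariance matrices
#'
#' The central model: an ordered set of traits (Gaussian telomere length and
#' antibody level, log-link latent-Gaussian egg count, latent-scale binary
#' survival) sharing unstructured covariance matrices at the individual, year
#' and residual levels, fitted by block Gibbs sampling with parameter-expanded
#' priors; non-Gaussian latent values are updated by slice sampling, and
#' binary residual variances are fixed at 1 through a conditional
#' inverse-Wishart draw.
#'
#' @inheritParams fit_univariate_lmm
#' @param spec A [model_spec()] with two or more traits.
#' @return A `tv_fit`.
#' @export
fit_multivariate_glmm <- function(records, spec) {
  if (length(spec$traits) < 2) {
    abort("fit_multivariate_glmm() expects at least two traits.")
  }
  fit_engine(records, spec)
}

#' @export
print.tv_fit <- function(x, ...) {
  cat("<tv_fit> ", paste(x$traits, collapse = " + "), "\n",
      "  ", x$n_obs, " observations",
      if (!is.na(x$n_individuals)) paste0(" from ", x$n_individuals, " individuals"),
      "; ", x$n_stored, " stored draws\n", sep = "")
  invisible(x)
}
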
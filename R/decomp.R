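#' Correlation from a covariance matrix element
#'
#' `cov(i, j) / (sd(i) * sd(j))`, applied per draw when `m` is a stack of
#' covariance-matrix draws (a K x K x S array) and once when `m` is a single
#' matrix.
#'
#' @param m A K x K covariance matrix or a K x K x S array of draws.
#' @param i,j Trait indices or names.
#' @return A scalar, or a vector of per-draw correlations.
#' @export
correlation_from_cov <- function(m, i, j) {
  one <- function(mm) {
    if (mm[i, i] <= 0 || mm[j, j] <= 0) {
      abort("Correlation undefined: zero variance on the diagonal.")
    }
    mm[i, j] / sqrt(mm[i, i] * mm[j, j])
  }
  if (length(dim(m)) == 3) {
    apply(m, 3, one)
  } else {
    one(m)
  }
}

#' Repeatability from variance-component draws
#'
#' Among-individual variance divided by the sum of the among-individual,
#' among-year and residual variances; assay batch variances are excluded from
#' the denominator by default (treated as measurement noise external to the
#' phenotype) and can be added via `v_assay`.
#'
#' @param v_individual,v_year,v_residual Numeric vectors of per-draw
#'   variances.
#' @param v_assay Optional per-draw total assay variance to include in the
#'   denominator (default 0).
#' @return Per-draw repeatabilities.
#' @export
repeatability <- function(v_individual, v_year, v_residual, v_assay = 0) {
  if (any(c(v_individual, v_year, v_residual, v_assay) < 0)) {
    abort("Variance draws must be non-negative.")
  }
  v_individual / (v_individual + v_year + v_residual + v_assay)
}

#' Partial regression coefficients of survival on the other traits
#'
#' For each stored covariance-matrix draw at one hierarchical level, solves
#' the multiple-regression normal equations within that level:
#' `beta = Sigma_pp^{-1} sigma_ps`, where `Sigma_pp` is the predictors'
#' sub-matrix and `sigma_ps` the predictor-survival covariance vector. The
#' coefficients measure each predictor's association with survival after
#' accounting for the covariance among the predictors at that level. Draws
#' with a computationally singular predictor sub-matrix are skipped; the
#' skipped count is attached as attribute `"n_skipped"`.
#'
#' @param m A K x K covariance matrix or K x K x S array of draws.
#' @param predictors Indices or names of the predictor traits.
#' @param survival Index or name of the survival trait.
#' @return A matrix of per-draw coefficients (S x length(predictors)), or a
#'   single named vector for a single matrix.
#' @export
partial_regression_on_survival <- function(m, predictors, survival) {
  one <- function(mm) {
    spp <- mm[predictors, predictors, drop = FALSE]
    sps <- mm[predictors, survival]
    out <- tryCatch(solve(spp, sps), error = function(e) NULL)
    if (is.null(out) || any(!is.finite(out))) return(NULL)
    out
  }
  if (length(dim(m)) == 3) {
    res <- apply(m, 3, one, simplify = FALSE)
    skipped <- sum(vapply(res, is.null, logical(1)))
    res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
    colnames(res) <- if (is.character(predictors)) predictors else
      rownames(m[, , 1])[predictors]
    attr(res, "n_skipped") <- skipped
    res
  } else {
    out <- one(m)
    if (is.null(out)) abort("Singular predictor covariance sub-matrix.")
    setNames(as.numeric(out),
             if (is.character(predictors)) predictors else rownames(m)[predictors])
  }
}

fit_level_array <- function(fit, level) {
  a <- switch(level,
              individual = fit$draws$sigma_individual,
              year = fit$draws$sigma_year,
              residual = fit$draws$sigma_residual)
  if (is.null(a)) abort(paste0("The fit has no `", level, "` level."))
  a
}

#' Posterior level-specific trait correlations from a fit
#'
#' Computes every pairwise correlation at each requested hierarchical level,
#' per stored draw, and summarizes each by its posterior mode and 95% highest
#' posterior density interval.
#'
#' @param fit A `tv_fit` from [fit_multivariate_glmm()].
#' @param levels Hierarchical levels to decompose.
#' @param mass Credible mass (default 0.95).
#' @return A tibble: `level`, `trait_1`, `trait_2`, `estimate` (posterior
#'   mode), `conf.low`, `conf.high`, `significant`, `lag1_autocorr`; class
#'   `tv_derived`.
#' @export
tv_correlations <- function(fit, levels = c("individual", "year", "residual"),
                            mass = 0.95) {
  levels <- intersect(levels, c(fit$spec$random_levels, "residual"))
  traits <- fit$traits
  pairs <- utils::combn(traits, 2, simplify = FALSE)
  out <- purrr::map_dfr(levels, function(lv) {
    a <- fit_level_array(fit, lv)
    purrr::map_dfr(pairs, function(pp) {
      r <- correlation_from_cov(a, pp[1], pp[2])
      dplyr::bind_cols(
        tibble(level = lv, trait_1 = pp[1], trait_2 = pp[2]),
        summarise_draw_vector(r, mass)
      )
    })
  })
  structure(out, class = c("tv_derived", class(out)),
            quantity = "correlation")
}

#' Posterior repeatabilities from a fit
#'
#' Among-individual variance share per trait, computed per draw from the
#' level covariance draws; assay variances are excluded from the denominator
#' unless `include_assay = TRUE`.
#'
#' @inheritParams tv_correlations
#' @param include_assay Add the trait's assay batch variances to the
#'   denominator.
#' @return A tibble with one row per trait (class `tv_derived`).
#' @export
tv_repeatability <- function(fit, include_assay = FALSE, mass = 0.95) {
  if (!"individual" %in% fit$spec$random_levels) {
    abort("Repeatability needs an individual random level in the fit.")
  }
  si <- fit$draws$sigma_individual
  sy <- fit$draws$sigma_year
  sr <- fit$draws$sigma_residual
  out <- purrr::map_dfr(fit$traits, function(tr) {
    v_assay <- 0
    if (include_assay && !is.null(fit$draws$assay_var)) {
      cols <- grep(paste0("^", tr, ":"), colnames(fit$draws$assay_var))
      if (length(cols)) {
        v_assay <- rowSums(fit$draws$assay_var[, cols, drop = FALSE])
      }
    }
    r <- repeatability(si[tr, tr, ],
                       if (is.null(sy)) 0 else sy[tr, tr, ],
                       sr[tr, tr, ], v_assay)
    dplyr::bind_cols(tibble(trait = tr), summarise_draw_vector(r, mass))
  })
  structure(out, class = c("tv_derived", class(out)),
            quantity = "repeatability")
}

#' Posterior partial regressions of survival on the other traits, per level
#'
#' Applies [partial_regression_on_survival()] to each level's covariance
#' draws and summarizes the per-draw coefficients.
#'
#' @inheritParams tv_correlations
#' @return A tibble: `level`, `predictor`, summaries (class `tv_derived`).
#' @export
tv_survival_gradients <- function(fit,
                                  levels = c("individual", "year", "residual"),
                                  mass = 0.95) {
  if (!"survival" %in% fit$traits) {
    abort("The fit does not include a survival trait.")
  }
  levels <- intersect(levels, c(fit$spec$random_levels, "residual"))
  preds <- setdiff(fit$traits, "survival")
  out <- purrr::map_dfr(levels, function(lv) {
    a <- fit_level_array(fit, lv)
    bmat <- partial_regression_on_survival(a, preds, "survival")
    res <- purrr::map_dfr(preds, function(p) {
      dplyr::bind_cols(tibble(level = lv, predictor = p),
                       summarise_draw_vector(bmat[, p], mass))
    })
    res$n_skipped_draws <- attr(bmat, "n_skipped")
    res
  })
  structure(out, class = c("tv_derived", class(out)),
            quantity = "survival gradient")
}
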
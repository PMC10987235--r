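#' Tidy a fitted mixed model
#'
#' One row per stored parameter: every fixed-effect coefficient, every element
#' of each level's covariance matrix, and every assay variance, each
#' summarized by its posterior mode, 95% highest posterior density interval,
#' strict zero-exclusion significance flag and lag-1 autocorrelation of the
#' stored chain.
#'
#' @param x A `tv_fit`.
#' @param mass Credible mass (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `component`, `term`, `estimate`, `conf.low`,
#'   `conf.high`, `significant`, `lag1_autocorr`.
#' @export
tidy.tv_fit <- function(x, mass = 0.95, ...) {
  rows <- list()
  b <- x$draws$beta
  rows$fixed <- purrr::map_dfr(colnames(b), function(nm) {
    dplyr::bind_cols(tibble(component = "fixed", term = nm),
                     summarise_draw_vector(b[, nm], mass))
  })
  for (lv in c("individual", "year", "residual")) {
    a <- switch(lv, individual = x$draws$sigma_individual,
                year = x$draws$sigma_year, residual = x$draws$sigma_residual)
    if (is.null(a)) next
    K <- length(x$traits)
    idx <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
    rows[[lv]] <- purrr::map_dfr(seq_len(nrow(idx)), function(q) {
      i <- idx[q, 1]; j <- idx[q, 2]
      nm <- if (i == j) paste0("var(", x$traits[i], ")") else
        paste0("cov(", x$traits[i], ",", x$traits[j], ")")
      dplyr::bind_cols(tibble(component = lv, term = nm),
                       summarise_draw_vector(a[i, j, ], mass))
    })
  }
  if (!is.null(x$draws$assay_var)) {
    av <- x$draws$assay_var
    rows$assay <- purrr::map_dfr(colnames(av), function(nm) {
      dplyr::bind_cols(tibble(component = "assay", term = paste0("var(", nm, ")")),
                       summarise_draw_vector(av[, nm], mass))
    })
  }
  dplyr::bind_rows(rows)
}

#' One-line summary of a fitted mixed model
#'
#' @param x A `tv_fit`.
#' @param ... Unused.
#' @return A one-row tibble: trait set, observation and individual counts,
#'   chain settings, stored draw count, and whether every stored chain passes
#'   the lag-1 autocorrelation screen (< 0.1).
#' @export
glance.tv_fit <- function(x, ...) {
  all_draws <- cbind(x$draws$beta,
                     matrix(aperm(x$draws$sigma_residual, c(3, 1, 2)),
                            nrow = x$n_stored))
  ac <- suppressWarnings(autocorrelation_check(all_draws))
  tibble(
    traits = paste(x$traits, collapse = "+"),
    n_obs = x$n_obs, n_individuals = x$n_individuals,
    n_years = x$n_years, n_stored = x$n_stored,
    iterations = x$spec$mcmc$iterations, warmup = x$spec$mcmc$warmup,
    thin = x$spec$mcmc$thin,
    max_lag1_autocorr = ac$max_abs, autocorr_pass = ac$pass
  )
}
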
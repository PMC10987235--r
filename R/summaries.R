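#' Posterior mode via kernel density estimation
#'
#' The point estimate used throughout: the maximiser of a Gaussian-kernel
#' density estimate with Silverman's rule-of-thumb bandwidth, evaluated on a
#' fine grid over the range of the draws.
#'
#' @param draws Numeric vector of at least 100 MCMC draws.
#' @param n_grid Grid resolution (default 2048).
#' @return The estimated mode (scalar).
#' @export
posterior_mode <- function(draws, n_grid = 2048) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100) {
    abort("posterior_mode() needs at least 100 draws.")
  }
  if (stats::sd(draws) == 0) return(draws[1])
  d <- stats::density(draws, bw = "nrd0", n = n_grid)
  d$x[which.max(d$y)]
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws.
#'
#' @param draws Numeric vector of at least 100 draws.
#' @param mass Posterior mass to cover, in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  if (mass <= 0 || mass >= 1) abort("`mass` must lie strictly in (0, 1).")
  draws <- sort(draws[is.finite(draws)])
  n <- length(draws)
  if (n < 100) abort("hpd_interval() needs at least 100 draws.")
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = draws[1], upper = draws[n]))
  widths <- draws[m:n] - draws[1:(n - m + 1)]
  i <- which.min(widths)
  c(lower = draws[i], upper = draws[i + m - 1])
}

#' Lag-1 autocorrelation screen for stored chains
#'
#' Computes the lag-1 autocorrelation of each stored (thinned) chain and
#' passes when every absolute value is below the threshold. A constant chain
#' has undefined autocorrelation and is treated as passing, with a warning.
#'
#' @param draws Numeric vector, matrix or data frame of stored draws
#'   (columns = parameters).
#' @param threshold Default 0.1.
#' @return A list with `pass` (logical), `max_abs` and per-parameter `lag1`.
#' @export
autocorrelation_check <- function(draws, threshold = 0.1) {
  m <- as.matrix(draws)
  lag1 <- apply(m, 2, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  })
  if (anyNA(lag1)) {
    warn("Constant chain(s): autocorrelation undefined, treated as passing.")
  }
  finite <- lag1[!is.na(lag1)]
  max_abs <- if (length(finite)) max(abs(finite)) else 0
  list(pass = max_abs < threshold, max_abs = max_abs, lag1 = lag1)
}

summarise_draw_vector <- function(draws, mass = 0.95) {
  hpd <- hpd_interval(draws, mass)
  ac <- suppressWarnings(autocorrelation_check(draws))
  tibble(
    estimate = posterior_mode(draws),
    conf.low = hpd[["lower"]], conf.high = hpd[["upper"]],
    significant = hpd[["lower"]] > 0 | hpd[["upper"]] < 0,
    lag1_autocorr = unname(ac$lag1)
  )
}

#' Flag derived quantities whose credible interval excludes zero
#'
#' @param summaries A tibble with `conf.low` and `conf.high` columns (as
#'   produced by [tidy()] on a fit or by the derived-quantity functions).
#' @return The input with a logical `significant` column (strict exclusion:
#'   an interval touching 0 is not significant).
#' @export
significance_flags <- function(summaries) {
  dplyr::mutate(summaries,
                significant = .data$conf.low > 0 | .data$conf.high < 0)
}
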
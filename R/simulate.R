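fixed_effect_value <- function(coefs, age, sex_m, adult) {
  g <- function(nm) if (nm %in% names(coefs)) coefs[[nm]] else 0
  g("intercept") + g("age") * age + g("age2") * age^2 +
    g("sex_m") * sex_m + g("adult") * adult
}

rmvn_chol <- function(n, sigma) {
  # eigen-based PSD square root: exact for singular matrices (zero variances,
  # boundary correlations) and keeps the draw count per record fixed so the
  # RNG stream stays auditable
  k <- ncol(sigma)
  e <- eigen(sigma, symmetric = TRUE)
  r <- sqrt(pmax(e$values, 0)) * t(e$vectors)
  matrix(rnorm(n * k), n, k) %*% r
}

#' Simulate a longitudinal capture-record dataset with known ground truth
#'
#' Generates one row per individual x capture year. Each trait is built
#' additively on its latent scale as fixed effects + individual effect + year
#' effect (+ assay batch effects for the measured traits) + residual, with the
#' level-specific effects drawn from the configured covariance matrices so
#' that trait-survival covariances are induced rather than hard-coded.
#' Relative telomere length and antibody level are observed Gaussian traits;
#' the faecal egg count is a count draw around the exponentiated latent value,
#' multiplied by 100 to mimic McMaster slide granularity; overwinter survival
#' is a Bernoulli draw through the configured link, and an individual
#' disappears after its first survival = 0 year (survival is evaluated every
#' alive year whether or not the individual was captured).
#'
#' @param config A [sim_config()] object.
#' @return A list of class `tv_simulation` with elements
#'   \describe{
#'     \item{records}{tibble: `individual_id`, `year`, `age`, `sex`,
#'       `age_class`, `rltl`, `fec`, `igg_tc`, `survival`, `qpcr_plate`,
#'       `qpcr_row`, `elisa_plate`.}
#'     \item{truth}{the realized config plus the drawn individual, year,
#'       assay-batch effects and per-record latent values.}
#'   }
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "tv_sim_config")) {
    abort("`config` must be created by sim_config().")
  }
  set.seed(config$seed)
  K <- 4L
  n_id <- config$n_individuals
  u <- rmvn_chol(n_id, config$sigma_individual)
  v <- rmvn_chol(config$n_years, config$sigma_year)
  colnames(u) <- colnames(v) <- TV_TRAITS

  entry_year <- sample(seq_len(config$entry_year_max), n_id, replace = TRUE)
  entry_age <- sample(config$entry_ages, n_id, replace = TRUE)
  sex <- ifelse(runif(n_id) < config$sex_ratio, "F", "M")
  link <- if (config$survival_link == "logit") stats::plogis else stats::pnorm

  rows <- vector("list", n_id)
  latents <- vector("list", n_id)
  for (i in seq_len(n_id)) {
    recs <- list(); lats <- list()
    for (yr in seq(entry_year[i], config$n_years)) {
      age <- entry_age[i] + (yr - entry_year[i])
      if (age > config$max_age) break
      e <- drop(rmvn_chol(1L, config$sigma_residual))
      lat <- vapply(TV_TRAITS, function(tr) {
        fixed_effect_value(config$fixed_effects[[tr]], age,
                           sex_m = sex[i] == "M", adult = age > 0) +
          u[i, tr] + v[yr, tr] + e[match(tr, TV_TRAITS)]
      }, numeric(1))
      surv <- rbinom(1L, 1L, link(lat[["survival"]]))
      count <- if (is.finite(config$fec_dispersion)) {
        rnbinom(1L, mu = exp(lat[["fec"]]), size = config$fec_dispersion)
      } else {
        rpois(1L, exp(lat[["fec"]]))
      }
      # capture_prob = 0 degenerates to a first-captures-only cross-section
      captured <- if (config$capture_prob == 0) yr == entry_year[i] else
        runif(1) < config$capture_prob
      if (captured) {
        recs[[length(recs) + 1L]] <- tibble(
          individual_id = sprintf("id%04d", i), year = yr, age = age,
          sex = sex[i], age_class = if (age == 0) "lamb" else "adult",
          rltl = lat[["rltl"]], fec = count * 100,
          igg_tc = lat[["igg_tc"]], survival = surv
        )
        lats[[length(lats) + 1L]] <- lat
      }
      if (surv == 0L && config$attrition) break
    }
    rows[[i]] <- if (length(recs)) dplyr::bind_rows(recs) else NULL
    latents[[i]] <- if (length(lats)) do.call(rbind, lats) else NULL
  }
  records <- dplyr::bind_rows(rows)
  latent <- do.call(rbind, latents)
  if (nrow(records) == 0) {
    abort("Simulation produced no capture records; check capture_prob/n_years.")
  }

  # assay batch assignment after the fact: plates mix years and ages
  n <- nrow(records)
  n_qplate <- max(1L, ceiling(n / config$qpcr_plate_size))
  n_eplate <- max(1L, ceiling(n / config$elisa_plate_size))
  qplate <- sample(rep_len(seq_len(n_qplate), n))
  qrow <- sample.int(config$qpcr_rows, n, replace = TRUE)
  eplate <- sample(rep_len(seq_len(n_eplate), n))
  qplate_eff <- rnorm(n_qplate, 0, config$assay_sds[["qpcr_plate"]])
  # rows are nested within plates: one effect per plate x row combination
  qrow_levels <- paste0("p", rep(seq_len(n_qplate), each = config$qpcr_rows),
                        "r", rep(seq_len(config$qpcr_rows), n_qplate))
  qrow_eff <- setNames(rnorm(length(qrow_levels), 0,
                             config$assay_sds[["qpcr_row"]]), qrow_levels)
  eplate_eff <- rnorm(n_eplate, 0, config$assay_sds[["elisa_plate"]])

  records <- records |>
    dplyr::mutate(
      qpcr_plate = sprintf("qp%03d", qplate),
      qpcr_row = paste0("p", qplate, "r", qrow),
      elisa_plate = sprintf("ep%03d", eplate),
      rltl = .data$rltl + qplate_eff[qplate] + unname(qrow_eff[.data$qpcr_row]),
      igg_tc = .data$igg_tc + eplate_eff[eplate]
    )

  for (tr in TV_TRAITS) {
    p <- config$missingness[[tr]]
    if (p > 0) records[[tr]][runif(n) < p] <- NA
  }
  records <- dplyr::arrange(records, .data$individual_id, .data$year)

  truth <- list(
    config = config,
    individual_effects = u, year_effects = v,
    qpcr_plate_effects = qplate_eff, qpcr_row_effects = qrow_eff,
    elisa_plate_effects = eplate_eff,
    latent = latent, entry_year = entry_year, entry_age = entry_age
  )
  structure(list(records = records, truth = truth), class = "tv_simulation")
}

#' @export
print.tv_simulation <- function(x, ...) {
  cat("<tv_simulation>: ", nrow(x$records), " records from ",
      dplyr::n_distinct(x$records$individual_id), " individuals over ",
      x$truth$config$n_years, " years\n", sep = "")
  invisible(x)
}
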
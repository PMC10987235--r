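#' Select an analysis subset of capture records
#'
#' Applies the age-window selector, then keeps complete cases for the
#' requested traits. Row counts per filtering reason are attached as attribute
#' `"counts"` so that kept + dropped always equals the input row count.
#'
#' @param records Capture-record tibble.
#' @param selector One of `"lambs"` (age 0), `"adults3"` (age >= 3),
#'   `"adults1"` (age >= 1), `"population"` (lambs plus adults >= 1, keeping
#'   the age-class factor).
#' @param traits Columns whose complete cases are required.
#' @return The filtered tibble with attribute `counts = list(input,
#'   dropped_age, dropped_incomplete, kept)`.
#' @export
subset_records <- function(records,
                           selector = c("lambs", "adults3", "adults1",
                                        "population"),
                           traits = c("rltl", "fec", "igg_tc")) {
  selector <- match.arg(selector)
  records <- as_tibble(records)
  if (!"age" %in% names(records)) abort("Records must carry `age`.")
  n_in <- nrow(records)
  keep_age <- switch(selector,
                     lambs = records$age == 0,
                     adults3 = records$age >= 3,
                     adults1 = records$age >= 1,
                     population = records$age == 0 | records$age >= 1)
  sub <- records[keep_age, , drop = FALSE]
  n_age <- nrow(sub)
  traits <- intersect(traits, names(sub))
  cc <- stats::complete.cases(sub[traits])
  out <- sub[cc, , drop = FALSE]
  if (nrow(out) == 0) {
    abort(paste0("Selector `", selector,
                 "` leaves no complete-case records for traits ",
                 paste(traits, collapse = ", "), "."))
  }
  attr(out, "counts") <- list(input = n_in, dropped_age = n_in - n_age,
                              dropped_incomplete = n_age - nrow(out),
                              kept = nrow(out))
  out
}

#' Sampling-intensity bookkeeping of a longitudinal dataset
#'
#' Summarizes how often individuals were sampled: total observations,
#' individuals, mean samples per individual, counts of individuals sampled
#' once / twice / thrice / four-or-more times, and the percentage sampled
#' more than once.
#'
#' @param records Capture-record tibble with `individual_id`, or a numeric
#'   vector of per-individual sample counts.
#' @return A one-row tibble: `n_obs`, `n_individuals`, `mean_samples`,
#'   `sampled_once`, `sampled_twice`, `sampled_thrice`, `sampled_4plus`,
#'   `pct_resampled`.
#' @export
resampling_profile <- function(records) {
  counts <- if (is.data.frame(records)) {
    as.integer(table(records$individual_id))
  } else {
    as.integer(records)
  }
  tibble(
    n_obs = sum(counts),
    n_individuals = length(counts),
    mean_samples = sum(counts) / length(counts),
    sampled_once = sum(counts == 1),
    sampled_twice = sum(counts == 2),
    sampled_thrice = sum(counts == 3),
    sampled_4plus = sum(counts >= 4),
    pct_resampled = 100 * mean(counts > 1)
  )
}

PLAN_MENU <- list(
  lamb_fec = list(selector = "lambs", traits = "rltl",
                  covariates = "fec", sex_interaction = FALSE),
  lamb_igg = list(selector = "lambs", traits = "rltl",
                  covariates = "igg_tc", sex_interaction = FALSE),
  lamb_combined = list(selector = "lambs", traits = "rltl",
                       covariates = c("fec", "igg_tc"),
                       sex_interaction = FALSE),
  lamb_sex_fec = list(selector = "lambs", traits = "rltl",
                      covariates = "fec", sex_interaction = TRUE),
  lamb_sex_igg = list(selector = "lambs", traits = "rltl",
                      covariates = "igg_tc", sex_interaction = TRUE),
  adult_sex_fec = list(selector = "adults3", traits = "rltl",
                       covariates = "fec", sex_interaction = TRUE),
  adult_sex_igg = list(selector = "adults3", traits = "rltl",
                       covariates = "igg_tc", sex_interaction = TRUE),
  adult_trivariate = list(selector = "adults3",
                          traits = c("rltl", "fec", "igg_tc")),
  adult_trivariate_all = list(selector = "adults1",
                              traits = c("rltl", "fec", "igg_tc")),
  adult_trivariate_no_age = list(selector = "adults3",
                                 traits = c("rltl", "fec", "igg_tc"),
                                 drop_age = TRUE),
  population_quadrivariate = list(selector = "population",
                                  traits = c("rltl", "fec", "igg_tc",
                                             "survival"))
)

#' Define an end-to-end analysis plan
#'
#' Pairs a dataset selector with a model from the analysis menu: the lamb
#' univariate models (egg count, antibody, combined, sex interactions), the
#' adult sex-interaction models, the adult trivariate model (age >= 3, all
#' adults, or the no-age-fixed-effect variant) and the whole-population
#' quadrivariate model including survival.
#'
#' @param model Menu entry: `lamb_fec`, `lamb_igg`, `lamb_combined`,
#'   `lamb_sex_fec`, `lamb_sex_igg`, `adult_sex_fec`, `adult_sex_igg`,
#'   `adult_trivariate`, `adult_trivariate_all`, `adult_trivariate_no_age`
#'   or `population_quadrivariate`.
#' @param iterations,warmup,thin,seed Chain settings forwarded to
#'   [model_spec()].
#' @return A list of class `tv_plan`.
#' @export
analysis_plan <- function(model = names(PLAN_MENU),
                          iterations = 50000, warmup = 10000, thin = 40,
                          seed = 1L) {
  model <- match.arg(model)
  entry <- PLAN_MENU[[model]]
  structure(c(list(model = model,
                   mcmc = list(iterations = iterations, warmup = warmup,
                               thin = thin, seed = seed)),
              entry),
            class = "tv_plan")
}

plan_to_spec <- function(plan, population = identical(plan$selector, "population")) {
  multivariate <- length(plan$traits) > 1
  if (multivariate) {
    fixed <- NULL
    if (isTRUE(plan$drop_age)) {
      fixed <- list(rltl = ~1, fec = ~sex, igg_tc = ~sex, survival = ~1)
    }
    model_spec(plan$traits, fixed = fixed, age_class = population,
               iterations = plan$mcmc$iterations, warmup = plan$mcmc$warmup,
               thin = plan$mcmc$thin, seed = plan$mcmc$seed)
  } else {
    lamb <- identical(plan$selector, "lambs")
    rhs <- c(plan$covariates, "sex",
             if (plan$sex_interaction) paste0("sex:", plan$covariates),
             if (!lamb) "age")
    f <- stats::reformulate(rhs, intercept = TRUE)
    model_spec("rltl", fixed = list(rltl = f),
               random_levels = if (lamb) "year" else c("individual", "year"),
               iterations = plan$mcmc$iterations, warmup = plan$mcmc$warmup,
               thin = plan$mcmc$thin, seed = plan$mcmc$seed)
  }
}

#' Run a full analysis plan on a set of capture records
#'
#' Stages: subset selection, trait preparation (standardization and egg-count
#' rescaling), model fitting, covariance decomposition (for multivariate
#' plans) and summary collection. Deterministic under the plan's seed.
#'
#' @param records Capture-record tibble (e.g. from [simulate_population()]).
#' @param plan An [analysis_plan()].
#' @param outdir Optional directory; when given, the resolved plan, filter
#'   counts, parameter summaries and derived quantities are written there as
#'   JSON/CSV.
#' @return A list of class `tv_report`: `plan`, `counts`, `fit`, `summary`
#'   (tidy fit), and for multivariate plans `correlations`, `repeatability`
#'   and (when survival is modelled) `survival_gradients`.
#' @export
run_plan <- function(records, plan, outdir = NULL) {
  if (!inherits(plan, "tv_plan")) abort("`plan` must come from analysis_plan().")
  need <- unique(c(plan$traits, plan$covariates))
  sub <- subset_records(records, plan$selector, traits = need)
  counts <- attr(sub, "counts")
  # lamb subsets have constant age; it is neither scaled nor modelled there
  scale_traits <- c("rltl", "igg_tc",
                    if (!identical(plan$selector, "lambs")) "age")
  prep <- prepare_model_traits(sub, scale_traits = scale_traits)
  spec <- plan_to_spec(plan)
  fit <- if (length(plan$traits) > 1) {
    fit_multivariate_glmm(prep, spec)
  } else {
    fit_univariate_lmm(prep, spec)
  }
  out <- list(plan = plan, counts = counts, scaling = attr(prep, "scaling"),
              fit = fit, summary = tidy(fit))
  if (length(plan$traits) > 1) {
    out$correlations <- tv_correlations(fit)
    out$repeatability <- tv_repeatability(fit)
    if ("survival" %in% plan$traits) {
      out$survival_gradients <- tv_survival_gradients(fit)
    }
  }
  class(out) <- "tv_report"
  if (!is.null(outdir)) write_report(out, outdir)
  out
}

#' @export
print.tv_report <- function(x, ...) {
  cat("<tv_report> plan:", x$plan$model, "\n")
  cat("  kept", x$counts$kept, "of", x$counts$input, "records (",
      x$counts$dropped_age, "outside age window,",
      x$counts$dropped_incomplete, "incomplete )\n")
  print(head(x$summary, 10))
  invisible(x)
}
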
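# sampler correctness against independent oracles

test_that("chains are bit-reproducible under a seed and order-invariant in distribution", {
  sim <- simulate_population(tiny_config(seed = 2))
  prep <- prepare_model_traits(subset_records(sim$records, "adults1"))
  spec <- model_spec(c("rltl", "igg_tc"), iterations = 1200, warmup = 200,
                     thin = 5, seed = 31)
  f1 <- fit_multivariate_glmm(prep, spec)
  f2 <- fit_multivariate_glmm(prep, spec)
  expect_identical(f1$draws, f2$draws)
})

test_that("with variances fixed at truth the Gibbs fixed effects match the GLS solution", {
  set.seed(20)
  n <- 600; n_yr <- 15
  yr <- sample(n_yr, n, TRUE)
  v <- rnorm(n_yr, 0, sqrt(0.3))
  x <- rnorm(n)
  y <- 1.5 + 0.8 * x + v[yr] + rnorm(n, 0, sqrt(0.6))
  d <- tibble::tibble(rltl = y, x = x, year = yr, individual_id = 1:n, age = 1)
  spec <- model_spec("rltl", fixed = list(rltl = ~x), random_levels = "year",
                     assay_effects = list(),
                     iterations = 6000, warmup = 1000, thin = 5, seed = 4)
  attr(spec, "engine_control") <- list(
    update_sigma_year = FALSE, update_sigma_res = FALSE,
    sigma_year_init = matrix(0.3), sigma_res_init = matrix(0.6))
  fit <- fit_univariate_lmm(d, spec)
  # closed-form GLS with the same (known) covariance structure
  Z <- outer(yr, seq_len(n_yr), `==`) * 1
  V <- 0.3 * Z %*% t(Z) + diag(0.6, n)
  X <- cbind(1, x)
  Vi <- solve(V)
  gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  post <- colMeans(fit$draws$beta)
  post_sd <- apply(fit$draws$beta, 2, sd)
  expect_lt(abs(post[1] - gls[1]), 3 * post_sd[1] / sqrt(10))
  expect_lt(abs(post[2] - gls[2]), 3 * post_sd[2] / sqrt(10))
})

test_that("a null slope is covered by the 95% HPD in most replicate simulations", {
  covered <- vapply(1:20, function(rep) {
    set.seed(100 + rep)
    n <- 800
    yr <- sample(10, n, TRUE)
    d <- tibble::tibble(rltl = 1 + rnorm(10, 0, 0.1)[yr] + rnorm(n, 0, 0.3),
                        x = rnorm(n), year = yr, individual_id = 1:n, age = 0)
    spec <- model_spec("rltl", fixed = list(rltl = ~x),
                       random_levels = "year", assay_effects = list(),
                       iterations = 2500, warmup = 500, thin = 2,
                       seed = rep)
    fit <- fit_univariate_lmm(d, spec)
    h <- hpd_interval(fit$draws$beta[, "rltl:x"])
    h["lower"] <= 0 && h["upper"] >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("a strong slope with residual-only noise is recovered within posterior uncertainty", {
  set.seed(21)
  n <- 2000
  x <- rnorm(n)
  d <- tibble::tibble(rltl = 2 - 0.7 * x + rnorm(n, 0, 0.4), x = x,
                      year = sample(8, n, TRUE), individual_id = 1:n, age = 0)
  spec <- model_spec("rltl", fixed = list(rltl = ~x), random_levels = "year",
                     assay_effects = list(),
                     iterations = 4000, warmup = 1000, thin = 3, seed = 6)
  fit <- fit_univariate_lmm(d, spec)
  b <- fit$draws$beta[, "rltl:x"]
  expect_lt(abs(mean(b) - (-0.7)), 3 * sd(b))
})

test_that("Gaussian bivariate variance components agree with a REML oracle when covariances are zero", {
  skip_if_not_installed("lme4")
  set.seed(22)
  n_id <- 250; reps <- 4; n <- n_id * reps
  id <- rep(seq_len(n_id), each = reps)
  yr <- sample(12, n, TRUE)
  mk <- function(vi, vy, vr) {
    rnorm(n_id, 0, sqrt(vi))[id] + rnorm(12, 0, sqrt(vy))[yr] +
      rnorm(n, 0, sqrt(vr))
  }
  d <- tibble::tibble(individual_id = id, year = yr, age = 1,
                      rltl = 1 + mk(0.5, 0.1, 1.0),
                      igg_tc = -0.3 + mk(0.3, 0.2, 0.7))
  spec <- model_spec(c("rltl", "igg_tc"),
                     fixed = list(rltl = ~1, igg_tc = ~1),
                     assay_effects = list(),
                     iterations = 8000, warmup = 2000, thin = 6, seed = 8)
  fit <- fit_multivariate_glmm(d, spec)
  for (tr in c("rltl", "igg_tc")) {
    ml <- lme4::lmer(d[[tr]] ~ 1 + (1 | individual_id) + (1 | year), data = d,
                     REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(ml))
    reml <- setNames(vc$vcov, vc$grp)
    vi <- fit$draws$sigma_individual[tr, tr, ]
    vr <- fit$draws$sigma_residual[tr, tr, ]
    expect_lt(abs(posterior_mode(vi) - reml[["individual_id"]]),
              max(0.1, 3 * sd(vi)))
    expect_lt(abs(posterior_mode(vr) - reml[["Residual"]]),
              max(0.1, 3 * sd(vr)))
  }
  # truly-zero covariances: HPDs cover zero at every level
  for (lv in c("sigma_individual", "sigma_year", "sigma_residual")) {
    h <- hpd_interval(fit$draws[[lv]]["rltl", "igg_tc", ])
    expect_lt(h[["lower"]], 0)
    expect_gt(h[["upper"]], 0)
  }
})

test_that("stored covariance draws are symmetric positive definite with correlations in [-1, 1]", {
  sim <- simulate_population(tiny_config(seed = 5))
  prep <- prepare_model_traits(subset_records(sim$records, "adults1"))
  spec <- model_spec(c("rltl", "fec", "igg_tc"), iterations = 1500,
                     warmup = 300, thin = 4, seed = 12)
  fit <- fit_multivariate_glmm(prep, spec)
  for (lv in c("sigma_individual", "sigma_year", "sigma_residual")) {
    a <- fit$draws[[lv]]
    for (s in seq_len(dim(a)[3])) {
      m <- a[, , s]
      expect_equal(m, t(m), tolerance = 1e-10)
      expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
  co <- tv_correlations(fit)
  expect_true(all(co$estimate >= -1 & co$estimate <= 1))
})

test_that("the count family is overdispersed relative to Poisson in its posterior predictive", {
  set.seed(30)
  n <- 1500
  e <- rnorm(n, 0, 1)              # large latent overdispersion
  d <- tibble::tibble(fec = rpois(n, exp(1.6 + e)), year = sample(8, n, TRUE),
                      individual_id = 1:n, age = 1)
  spec <- model_spec("fec", fixed = list(fec = ~1), families = list(fec = "count"),
                     random_levels = "year", assay_effects = list(),
                     iterations = 5000, warmup = 1000, thin = 4, seed = 2)
  fit <- telovar:::fit_engine(d, spec)
  # posterior predictive: Poisson-lognormal with the posterior residual variance
  mu <- fit$draws$beta[, "fec:(Intercept)"]
  v <- fit$draws$sigma_residual["fec", "fec", ]
  set.seed(31)
  yrep <- rpois(length(mu) * 20, exp(rep(mu, 20) + rnorm(length(mu) * 20, 0, sqrt(rep(v, 20)))))
  expect_gt(var(yrep) / mean(yrep), 1)
  expect_gt(posterior_mode(v), 0.5)
})

test_that("the constrained residual draw keeps the binary variance at 1 and matches a quadrature oracle", {
  S <- matrix(c(8, 3, 3, 6), 2); nu <- 10
  set.seed(40)
  draws <- replicate(20000, telovar:::.riwish_fixed_cpp(S, nu, 0L, 1L, matrix(1)))
  expect_true(all(abs(draws[2, 2, ] - 1) < 1e-12))
  # 2-d quadrature over the conditional density of (s11, s12) given s22 = 1
  logf <- function(s11, s12) {
    det <- s11 - s12^2
    if (det <= 0 || s11 <= 0) return(-Inf)
    Si <- solve(matrix(c(s11, s12, s12, 1), 2))
    -(nu + 3) / 2 * log(det) - 0.5 * sum(S * Si)
  }
  g1 <- seq(0.01, 15, length.out = 300)
  g2 <- seq(-3, 3, length.out = 300)
  z <- outer(g1, g2, Vectorize(function(a, b) exp(logf(a, b))))
  m11 <- sum(outer(g1, g2, function(a, b) a) * z) / sum(z)
  m12 <- sum(outer(g1, g2, function(a, b) b) * z) / sum(z)
  expect_equal(mean(draws[1, 1, ]), m11, tolerance = 0.02)
  expect_equal(mean(draws[1, 2, ]), m12, tolerance = 0.02)
})

test_that("binary and count residual correlations are recovered on latent scales", {
  set.seed(41)
  n <- 2500
  Sr <- matrix(c(1, -0.45, -0.45, 1), 2)
  e <- MASS::mvrnorm(n, c(0, 0), Sr)
  d <- tibble::tibble(individual_id = 1:n, year = rep(1:10, n / 10), age = 1,
                      rltl = 0.5 + e[, 1],
                      survival = rbinom(n, 1, plogis(0.4 + e[, 2])))
  spec <- model_spec(c("rltl", "survival"),
                     fixed = list(rltl = ~1, survival = ~1),
                     random_levels = "year", assay_effects = list(),
                     iterations = 12000, warmup = 2000, thin = 10, seed = 3)
  fit <- fit_multivariate_glmm(d, spec)
  r <- correlation_from_cov(fit$draws$sigma_residual, "rltl", "survival")
  h <- hpd_interval(r)
  expect_lt(abs(posterior_mode(r) - (-0.45)), 0.12)
  expect_true(all(abs(fit$draws$sigma_residual["survival", "survival", ] - 1) < 1e-10))
})

test_that("model specification rejects marginality violations and bad inputs", {
  expect_error(model_spec("rltl", fixed = list(rltl = ~ sex:fec)),
               "marginality")
  expect_error(model_spec(c("rltl", "rltl")), "at most once")
  sim <- simulate_population(tiny_config(seed = 6))
  spec <- model_spec("rltl", fixed = list(rltl = ~nonexistent),
                     iterations = 500, warmup = 100, thin = 2)
  expect_error(fit_univariate_lmm(sim$records, spec), "lack columns")
})
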
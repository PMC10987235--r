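test_that("simulation is deterministic under a seed", {
  s1 <- simulate_population(tiny_config(seed = 7))
  s2 <- simulate_population(tiny_config(seed = 7))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$individual_effects, s2$truth$individual_effects)
  s3 <- simulate_population(tiny_config(seed = 8))
  expect_false(identical(s1$records, s2$records) &&
                 identical(s1$records$rltl, s3$records$rltl))
})

test_that("capture records satisfy their structural invariants", {
  sim <- simulate_population(tiny_config(seed = 3))
  r <- sim$records
  expect_true(all(r$age >= 0))
  expect_true(all((r$age_class == "lamb") == (r$age == 0)))
  expect_lte(max(table(r$individual_id, r$year)), 1)
  # survival = 0 occurs at most once per individual, and only in its last record
  by_id <- split(r, r$individual_id)
  for (d in by_id) {
    deaths <- which(d$survival == 0)
    expect_lte(length(deaths), 1)
    if (length(deaths)) expect_identical(deaths, nrow(d))
  }
  expect_true(all(r$fec %% 100 == 0, na.rm = TRUE))
})

test_that("zero covariance and zero assay noise give exact fixed-effect Gaussians", {
  z <- matrix(0, 4, 4)
  cfg <- sim_config(n_individuals = 50, n_years = 3, capture_prob = 1,
                    sigma_individual = z, sigma_year = z, sigma_residual = z,
                    assay_sds = c(qpcr_plate = 0, qpcr_row = 0, elisa_plate = 0),
                    missingness = c(rltl = 0, fec = 0, igg_tc = 0, survival = 0),
                    seed = 4)
  sim <- simulate_population(cfg)
  fe <- cfg$fixed_effects
  pred_rltl <- fe$rltl[["intercept"]] + fe$rltl[["age"]] * sim$records$age
  expect_equal(sim$records$rltl, pred_rltl, tolerance = 1e-10)
  pred_igg <- fe$igg_tc[["intercept"]] + fe$igg_tc[["age"]] * sim$records$age +
    (sim$records$sex == "M") * fe$igg_tc[["sex_m"]] +
    (sim$records$age > 0) * fe$igg_tc[["adult"]]
  expect_equal(sim$records$igg_tc, pred_igg, tolerance = 1e-10)
})

test_that("empirical among-individual covariance converges to the configured matrix", {
  sig <- sigma_matrices(cor_individual = c("rltl:survival" = 0.318),
                        total_sd = c(rltl = 1, fec = 1, igg_tc = 1))
  sig$individual[1, 1] <- 0.25
  cfg <- sim_config(n_individuals = 5000, n_years = 2, capture_prob = 0.3,
                    sigma_individual = sig$individual, seed = 11)
  sim <- simulate_population(cfg)
  u <- sim$truth$individual_effects
  expect_lt(abs(var(u[, "rltl"]) - 0.25), 0.02)
  emp <- cov(u)
  expect_lt(max(abs(emp - sig$individual)), 0.06)
})

test_that("finite dispersion makes egg counts overdispersed and survival is monotone in its intercept", {
  cfg1 <- tiny_config(seed = 5, fec_dispersion = 1.5)
  fec <- simulate_population(cfg1)$records$fec / 100
  expect_gt(var(fec), mean(fec))

  surv_rate <- function(b0) {
    fe <- default_fixed_effects()
    fe$survival[["intercept"]] <- b0
    cfg <- sim_config(n_individuals = 600, n_years = 4, capture_prob = 1,
                      fixed_effects = fe, seed = 42,
                      missingness = c(rltl = 0, fec = 0, igg_tc = 0, survival = 0))
    mean(simulate_population(cfg)$records$survival)
  }
  rates <- vapply(c(-2, 0, 2), surv_rate, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("degenerate capture and validation paths behave as documented", {
  cfg <- tiny_config(seed = 9, capture_prob = 0)
  sim <- simulate_population(cfg)
  expect_lte(max(table(sim$records$individual_id)), 1)  # first captures only
  bad <- matrix(c(1, 2, 0, 0, 2, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1), 4)
  expect_error(sim_config(sigma_individual = bad), "positive semi-definite|symmetric")
  expect_error(sim_config(capture_prob = 1.4), "\\[0, 1\\]")
})

test_that("qPCR plate simulation round-trips through compute_rltl", {
  cfg <- tiny_config(seed = 13, qpcr_triplicate_sd = 0)
  sim <- simulate_population(cfg)
  plates <- simulate_qpcr_plates(sim$records, cfg)
  out <- compute_rltl(plates$samples)
  expect_false(any(out$excluded))
  expect_equal(out$rltl, out$target_rltl, tolerance = 1e-9)
  # unit-ratio targets sit exactly on the calibrator for both amplicons
  rec1 <- sim$records[1, ]
  rec1$rltl <- 1
  one <- simulate_qpcr_plates(rec1, cfg)$samples
  expect_equal(one$cq_tel_1, one$cq_tel_cal, tolerance = 1e-9)
  expect_equal(one$cq_b2m_1, one$cq_b2m_cal, tolerance = 1e-9)
  # plate layout: 8 calibrator wells and 2 NTC placeholders per plate
  per_plate <- dplyr::count(plates$wells, plate, role)
  expect_true(all(per_plate$n[per_plate$role == "calibrator"] == 16))  # 8 x 2 amplicons
  expect_true(all(per_plate$n[per_plate$role == "NTC"] == 2))
})

test_that("ELISA plate simulation round-trips through od_ratio and the QC gates", {
  cfg <- tiny_config(seed = 14, elisa_duplicate_sd = 0)
  sim <- simulate_population(cfg)
  plates <- simulate_elisa_plates(sim$records, cfg)
  kept <- filter_elisa_duplicates(plates)
  expect_identical(nrow(kept), nrow(plates))
  recovered <- od_ratio(kept$mean_od, kept$blank_od, kept$positive_od)
  expect_equal(recovered, kept$target_igg, tolerance = 1e-9)
  gate <- check_plate_pair(plates$od_1, plates$od_2)
  expect_true(gate$pass)
  expect_equal(gate$correlation, 1, tolerance = 1e-12)
  # a constructed duplicate pair with COV 0.25 is removed by the 0.2 filter
  bad <- tibble::tibble(od_1 = 0.5 - 0.25 * 0.5 / sqrt(2),
                        od_2 = 0.5 + 0.25 * 0.5 / sqrt(2))
  expect_identical(nrow(filter_elisa_duplicates(bad)), 0L)
})
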
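test_that("coefficient of variation matches hand-computed values and guards", {
  expect_identical(coefficient_of_variation(c(1, 1, 1)), 0)
  expect_equal(coefficient_of_variation(c(10, 10, 11.5)), 0.0824786,
               tolerance = 1e-6)
  expect_equal(coefficient_of_variation(c(0.55, 0.45)), 0.1414214,
               tolerance = 1e-6)
  expect_error(coefficient_of_variation(c(0.5, -0.5)), "mean 0")
  expect_error(coefficient_of_variation(1), "at least two")
})

test_that("relative telomere length follows the calibrator-normalised formula", {
  # sample Cqs equal to calibrator Cqs -> both exponents zero
  expect_equal(compute_rltl(qpcr_row(0, 0, 1.9, 1.7))$rltl, 1.0)
  # one-cycle telomere advantage at efficiency 2 doubles the ratio
  expect_equal(compute_rltl(qpcr_row(1, 0, 2, 2))$rltl, 2.0)
  # closed-form evaluation
  expect_equal(compute_rltl(qpcr_row(0.5, -0.25, 1.9, 1.85))$rltl,
               1.9^0.5 / 1.85^(-0.25), tolerance = 1e-12)
  expect_equal(compute_rltl(qpcr_row(0.5, -0.25, 1.9, 1.85))$rltl,
               1.60756, tolerance = 1e-4)
  expect_error(compute_rltl(qpcr_row(eff_tel = 0.9)), "exceed 1")
})

test_that("triplicate COV and efficiency exclusions flag samples", {
  spread <- triplicate_with_cov(0.08, m = 24) - 24
  bad_cov <- compute_rltl(qpcr_row(spread_tel = spread))
  expect_true(bad_cov$excluded)
  expect_match(bad_cov$exclusion_reason, "COV")
  bad_eff <- compute_rltl(qpcr_row(eff_tel = 2.35))
  expect_true(bad_eff$excluded)
  expect_match(bad_eff$exclusion_reason, "efficiency")
  # boundary COV exactly at the threshold passes (strict rule)
  at <- triplicate_with_cov(0.05, m = 24) - 24
  expect_false(compute_rltl(qpcr_row(spread_tel = at))$excluded)
})

test_that("RLTL is invariant to a joint shift of sample and calibrator Cqs", {
  base <- qpcr_row(0.7, -0.3, 1.92, 1.88)
  shifted <- base
  for (cl in c(paste0("cq_tel_", 1:3), "cq_tel_cal")) {
    shifted[[cl]] <- shifted[[cl]] + 1.8
  }
  expect_equal(compute_rltl(base)$rltl, compute_rltl(shifted)$rltl,
               tolerance = 1e-12)
})

test_that("OD ratio matches its definition and rejects degenerate plates", {
  expect_equal(od_ratio(1.05, 0.05, 1.05), 1.0)
  expect_equal(od_ratio(0.05, 0.05, 1.05), 0.0)
  expect_equal(od_ratio(0.55, 0.05, 1.05), 0.5)
  expect_error(od_ratio(0.5, 0.6, 0.55), "Degenerate")
  # common multiplicative gain on all three ODs cancels
  g <- 2.7
  expect_equal(od_ratio(g * 0.55, g * 0.05, g * 1.05),
               od_ratio(0.55, 0.05, 1.05), tolerance = 1e-12)
})

test_that("ELISA duplicate filter removes inconsistent pairs and keeps means", {
  plate <- tibble::tibble(sample_id = c("a", "b", "c"),
                          od_1 = c(0.5, 0.2, 0.5), od_2 = c(0.5, 0.8, 0.6))
  kept <- filter_elisa_duplicates(plate)
  expect_setequal(kept$sample_id, c("a", "c"))   # (0.2, 0.8) has COV 0.849
  expect_equal(kept$mean_od[kept$sample_id == "a"], 0.5)
  expect_equal(kept$mean_od[kept$sample_id == "c"], 0.55)
  expect_equal(kept$duplicate_cov[kept$sample_id == "c"], 0.1285649,
               tolerance = 1e-6)
})

test_that("plate-pair gate uses Pearson correlation with a 0.8 cutoff", {
  x <- c(0.2, 0.4, 0.6, 0.8)
  expect_true(check_plate_pair(x, x)$pass)
  neg <- check_plate_pair(x, -x)
  expect_false(neg$pass)
  expect_equal(neg$correlation, -1)
  res <- check_plate_pair(x, c(0.25, 0.35, 0.65, 0.75))
  expect_equal(res$correlation, 0.97619, tolerance = 1e-5)
  expect_true(res$pass)
  expect_error(check_plate_pair(c(1, 2), c(1, 2)), "At least 3")
})

test_that("faecal egg counts are slide counts times 100", {
  expect_identical(fec_from_count(c(0L, 7L, 23L)), c(0, 700, 2300))
  expect_true(all(fec_from_count(0:50) %% 100 == 0))
  expect_error(fec_from_count(-1), "negative")
})

test_that("trait preparation standardizes and rescales as specified", {
  d <- tibble::tibble(rltl = c(0.8, 1.0, 1.3, 1.1), igg_tc = c(0.2, 0.5, 0.4, 0.9),
                      age = c(3, 4, 5, 6), fec = c(700, 0, 1300, 200))
  prep <- prepare_model_traits(d)
  for (cl in c("rltl", "igg_tc", "age")) {
    expect_lt(abs(mean(prep[[cl]])), 1e-10)
    expect_lt(abs(stats::sd(prep[[cl]]) - 1), 1e-10)
  }
  expect_identical(prep$fec, c(7, 0, 13, 2))
  expect_true(all(prep$fec == round(prep$fec)))
  sc <- attr(prep, "scaling")
  expect_setequal(sc$trait, c("rltl", "igg_tc", "age"))
  d$rltl <- 1
  expect_error(prepare_model_traits(d), "zero variance")
})
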
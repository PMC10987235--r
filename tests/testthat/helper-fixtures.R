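# small simulation configs shared across tests

tiny_config <- function(seed = 1L, capture_prob = 0.7, ...) {
  sim_config(n_individuals = 120, n_years = 6, capture_prob = capture_prob,
             missingness = c(rltl = 0, fec = 0, igg_tc = 0, survival = 0),
             seed = seed, ...)
}

# one-row qPCR sample set with explicit calibrator deltas
qpcr_row <- function(d_tel = 0, d_b2m = 0, eff_tel = 2, eff_b2m = 2,
                     cq_tel_cal = 24, cq_b2m_cal = 22,
                     spread_tel = c(0, 0, 0), spread_b2m = c(0, 0, 0)) {
  tibble::tibble(
    sample_id = "s1", qpcr_plate = "p1", qpcr_row = "r1",
    cq_tel_1 = cq_tel_cal - d_tel + spread_tel[1],
    cq_tel_2 = cq_tel_cal - d_tel + spread_tel[2],
    cq_tel_3 = cq_tel_cal - d_tel + spread_tel[3],
    cq_b2m_1 = cq_b2m_cal - d_b2m + spread_b2m[1],
    cq_b2m_2 = cq_b2m_cal - d_b2m + spread_b2m[2],
    cq_b2m_3 = cq_b2m_cal - d_b2m + spread_b2m[3],
    eff_tel = eff_tel, eff_b2m = eff_b2m,
    cq_tel_cal = cq_tel_cal, cq_b2m_cal = cq_b2m_cal
  )
}

# triplicate values with an exact target coefficient of variation around mean m
triplicate_with_cov <- function(target_cov, m = 10) {
  base <- c(-1, 0, 1)                     # sd = 1, mean 0
  x <- m + base * (target_cov * m / stats::sd(base))
  stopifnot(abs(coefficient_of_variation(x) - target_cov) < 1e-12)
  x
}
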
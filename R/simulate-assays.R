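#' Simulate raw qPCR plates consistent with target telomere-length values
#'
#' Inverts the calibrator-normalised T/S formula: for each record with a
#' positive target `rltl`, triplicate telomere-amplicon Cq values are placed
#' at `cq_tel_cal - log(rltl)/log(eff_tel)` and reference-amplicon triplicates
#' at the calibrator Cq, then replicate noise of SD
#' `config$qpcr_triplicate_sd` cycles is added. Each plate carries 8
#' calibrator wells per amplicon and 2 non-template control placeholders, and
#' the per-plate calibrator summaries consumed by [compute_rltl()] are the
#' means over those calibrator wells, so with zero noise
#' `compute_rltl(simulate_qpcr_plates(...))` reproduces the inputs exactly.
#'
#' @param records Capture-record tibble with `rltl` and `qpcr_plate`,
#'   `qpcr_row` columns.
#' @param config A [sim_config()] (supplies replicate noise SD and seed).
#' @return A list with `samples` (one row per sample, the [compute_rltl()]
#'   input layout) and `wells` (one row per well: plate, row, sample id,
#'   amplicon, Cq, efficiency, role in {sample, calibrator, NTC}).
#' @export
simulate_qpcr_plates <- function(records, config) {
  set.seed(config$seed + 101L)
  recs <- dplyr::filter(records, !is.na(.data$rltl) & .data$rltl > 0)
  plates <- unique(recs$qpcr_plate)
  eff <- tibble(
    qpcr_plate = plates,
    eff_tel = pmin(pmax(rnorm(length(plates), 1.90, 0.02), 1.7), 2.1),
    eff_b2m = pmin(pmax(rnorm(length(plates), 1.85, 0.02), 1.7), 2.1),
    cal_tel_center = 24, cal_b2m_center = 22
  )
  noise <- config$qpcr_triplicate_sd

  cal_wells <- eff |>
    dplyr::reframe(
      well = seq_len(8L),
      cq_tel = .data$cal_tel_center + rnorm(8L, 0, noise),
      cq_b2m = .data$cal_b2m_center + rnorm(8L, 0, noise),
      .by = "qpcr_plate"
    )
  cal_means <- cal_wells |>
    dplyr::summarise(cq_tel_cal = mean(.data$cq_tel),
                     cq_b2m_cal = mean(.data$cq_b2m), .by = "qpcr_plate")

  samples <- recs |>
    dplyr::select(sample_id = "individual_id", year = "year",
                  "qpcr_plate", "qpcr_row", "rltl") |>
    dplyr::mutate(sample_id = paste0(.data$sample_id, "_", .data$year)) |>
    dplyr::left_join(eff, by = "qpcr_plate") |>
    dplyr::left_join(cal_means, by = "qpcr_plate")
  mu_tel <- samples$cq_tel_cal - log(samples$rltl) / log(samples$eff_tel)
  mu_b2m <- samples$cq_b2m_cal
  n <- nrow(samples)
  for (j in 1:3) {
    samples[[paste0("cq_tel_", j)]] <- mu_tel + rnorm(n, 0, noise)
    samples[[paste0("cq_b2m_", j)]] <- mu_b2m + rnorm(n, 0, noise)
  }
  samples <- dplyr::select(samples, "sample_id", "qpcr_plate", "qpcr_row",
                           dplyr::starts_with("cq_tel_"),
                           dplyr::starts_with("cq_b2m_"),
                           "eff_tel", "eff_b2m", "cq_tel_cal", "cq_b2m_cal",
                           target_rltl = "rltl")

  wells <- dplyr::bind_rows(
    samples |>
      tidyr::pivot_longer(dplyr::matches("^cq_(tel|b2m)_[123]$"),
                          names_to = c("amplicon", "replicate"),
                          names_pattern = "cq_(tel|b2m)_([123])",
                          values_to = "cq") |>
      dplyr::transmute(plate = .data$qpcr_plate, row = .data$qpcr_row,
                       sample_id = .data$sample_id, amplicon = .data$amplicon,
                       cq = .data$cq,
                       efficiency = ifelse(.data$amplicon == "tel",
                                           .data$eff_tel, .data$eff_b2m),
                       role = "sample"),
    cal_wells |>
      tidyr::pivot_longer(c("cq_tel", "cq_b2m"), names_to = "amplicon",
                          names_prefix = "cq_", values_to = "cq") |>
      dplyr::transmute(plate = .data$qpcr_plate, row = NA_character_,
                       sample_id = paste0("cal", .data$well),
                       amplicon = .data$amplicon, cq = .data$cq,
                       efficiency = NA_real_, role = "calibrator"),
    tidyr::expand_grid(plate = plates, sample_id = c("ntc1", "ntc2")) |>
      dplyr::mutate(row = NA_character_, amplicon = NA_character_,
                    cq = NA_real_, efficiency = NA_real_, role = "NTC")
  )
  list(samples = samples, wells = wells)
}

#' Simulate duplicate ELISA plates consistent with target antibody values
#'
#' Inverts the blank-corrected OD ratio: each record's target `igg_tc` is
#' mapped to `blank + igg_tc * (positive - blank)` and measured twice (the
#' duplicate plate run) with independent noise of SD
#' `config$elisa_duplicate_sd` OD units. Blank and positive-control wells are
#' carried per plate, so with zero noise [od_ratio()] of the duplicate mean
#' recovers `igg_tc` exactly.
#'
#' @inheritParams simulate_qpcr_plates
#' @return A tibble with one row per sample: `sample_id`, `elisa_plate`,
#'   `od_1`, `od_2`, `blank_od`, `positive_od`, `target_igg`.
#' @export
simulate_elisa_plates <- function(records, config) {
  set.seed(config$seed + 202L)
  recs <- dplyr::filter(records, !is.na(.data$igg_tc))
  plates <- unique(recs$elisa_plate)
  ctrl <- tibble(elisa_plate = plates,
                 blank_od = 0.05 + rnorm(length(plates), 0, 0.002),
                 positive_od = 1.05 + rnorm(length(plates), 0, 0.01))
  noise <- config$elisa_duplicate_sd
  recs |>
    dplyr::transmute(
      sample_id = paste0(.data$individual_id, "_", .data$year),
      elisa_plate = .data$elisa_plate, target_igg = .data$igg_tc
    ) |>
    dplyr::left_join(ctrl, by = "elisa_plate") |>
    dplyr::mutate(
      true_od = .data$blank_od +
        .data$target_igg * (.data$positive_od - .data$blank_od),
      od_1 = .data$true_od + rnorm(dplyr::n(), 0, noise),
      od_2 = .data$true_od + rnorm(dplyr::n(), 0, noise)
    ) |>
    dplyr::select("sample_id", "elisa_plate", "od_1", "od_2",
                  "blank_od", "positive_od", "target_igg")
}
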
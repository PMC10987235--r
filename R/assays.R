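#' Coefficient of variation of replicate measurements
#'
#' Sample standard deviation divided by the mean, the replicate-consistency
#' statistic used to screen qPCR triplicates and ELISA duplicates.
#'
#' @param values Numeric vector of at least two finite replicate measurements.
#' @return A single dimensionless ratio.
#' @examples
#' coefficient_of_variation(c(10, 10, 11.5))
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values) || any(!is.finite(values))) {
    abort("`values` must contain at least two finite measurements.")
  }
  m <- mean(values)
  if (m == 0) {
    abort("Coefficient of variation is undefined for replicates with mean 0.")
  }
  stats::sd(values) / m
}

#' Relative telomere length from triplicate qPCR measurements
#'
#' Computes the plate-calibrated T/S ratio
#' \deqn{RLTL = E_{TEL}^{(Cq_{TEL}[cal] - Cq_{TEL}[sample])} /
#'       E_{B2M}^{(Cq_{B2M}[cal] - Cq_{B2M}[sample])}}
#' where the sample Cq for each amplicon is the mean of its triplicate and the
#' efficiencies are per-plate means for the amplicon group. Samples whose
#' triplicate coefficient of variation exceeds `cov_threshold` on either
#' amplicon, or whose plate efficiency falls outside `efficiency_window`, are
#' excluded (RLTL returned as `NA` with the reason recorded).
#'
#' @param samples A data frame with one row per sample carrying columns
#'   `cq_tel_1..3`, `cq_b2m_1..3`, `eff_tel`, `eff_b2m`, `cq_tel_cal`,
#'   `cq_b2m_cal` (as produced by [simulate_qpcr_plates()]).
#' @param cov_threshold Triplicate COV above which a sample is excluded
#'   (strict inequality; default 0.05).
#' @param efficiency_window Length-2 numeric; amplification efficiencies
#'   outside this closed interval exclude the sample. Default `c(1.6, 2.2)`.
#' @return The input tibble with added columns `rltl`, `excluded` (logical)
#'   and `exclusion_reason`.
#' @export
compute_rltl <- function(samples, cov_threshold = 0.05,
                         efficiency_window = c(1.6, 2.2)) {
  samples <- as_tibble(samples)
  need <- c(paste0("cq_tel_", 1:3), paste0("cq_b2m_", 1:3),
            "eff_tel", "eff_b2m", "cq_tel_cal", "cq_b2m_cal")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    abort(paste0("`samples` lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(samples$eff_tel <= 1 | samples$eff_b2m <= 1)) {
    abort("Amplification efficiencies must exceed 1 (per-cycle fold change).")
  }
  cq_tel <- as.matrix(samples[paste0("cq_tel_", 1:3)])
  cq_b2m <- as.matrix(samples[paste0("cq_b2m_", 1:3)])
  if (any(cq_tel <= 0) || any(cq_b2m <= 0)) {
    abort("Cq values must be positive.")
  }
  cov_tel <- apply(cq_tel, 1, coefficient_of_variation)
  cov_b2m <- apply(cq_b2m, 1, coefficient_of_variation)
  eff_ok <- samples$eff_tel >= efficiency_window[1] &
    samples$eff_tel <= efficiency_window[2] &
    samples$eff_b2m >= efficiency_window[1] &
    samples$eff_b2m <= efficiency_window[2]
  cov_ok <- cov_tel <= cov_threshold & cov_b2m <= cov_threshold
  reason <- dplyr::case_when(
    !cov_ok & !eff_ok ~ "triplicate COV and efficiency",
    !cov_ok ~ "triplicate COV",
    !eff_ok ~ "efficiency",
    TRUE ~ NA_character_
  )
  rltl <- samples$eff_tel^(samples$cq_tel_cal - rowMeans(cq_tel)) /
    samples$eff_b2m^(samples$cq_b2m_cal - rowMeans(cq_b2m))
  rltl[!(cov_ok & eff_ok)] <- NA_real_
  dplyr::mutate(samples,
                rltl = rltl,
                excluded = !(cov_ok & eff_ok),
                exclusion_reason = reason)
}

#' Blank-corrected optical density ratio
#'
#' `(sample OD - blank OD) / (positive control OD - blank OD)`, the
#' plate-normalised antibody measure used for parasite-specific IgG.
#'
#' @param sample_od,blank_od,positive_od Numeric vectors (recycled).
#' @return Dimensionless ratio(s).
#' @examples
#' od_ratio(0.55, 0.05, 1.05)
#' @export
od_ratio <- function(sample_od, blank_od, positive_od) {
  if (any(positive_od <= blank_od)) {
    abort("Degenerate plate: positive-control OD must exceed blank OD.")
  }
  (sample_od - blank_od) / (positive_od - blank_od)
}

#' Screen ELISA duplicates by replicate consistency
#'
#' Removes samples whose duplicate ODs have a coefficient of variation above
#' `cov_threshold` (strict); survivors carry the duplicate mean OD.
#'
#' @param plate A data frame with columns `od_1` and `od_2` (one row per
#'   sample), e.g. one element of [simulate_elisa_plates()] output.
#' @param cov_threshold Default 0.2.
#' @return The kept rows with added columns `duplicate_cov` and `mean_od`.
#' @export
filter_elisa_duplicates <- function(plate, cov_threshold = 0.2) {
  plate <- as_tibble(plate)
  if (!all(c("od_1", "od_2") %in% names(plate))) {
    abort("`plate` must carry duplicate OD columns `od_1` and `od_2`.")
  }
  covs <- purrr::map2_dbl(plate$od_1, plate$od_2,
                          ~ coefficient_of_variation(c(.x, .y)))
  plate |>
    dplyr::mutate(duplicate_cov = covs,
                  mean_od = (.data$od_1 + .data$od_2) / 2) |>
    dplyr::filter(.data$duplicate_cov <= cov_threshold)
}

#' Cross-plate consistency gate for duplicate ELISA plates
#'
#' Pearson correlation of ODs across the shared samples of a duplicate plate
#' pair; the pair fails (and would be rerun) when the correlation is below
#' `threshold`.
#'
#' @param od_a,od_b Numeric OD vectors for the same samples on the two plates.
#' @param threshold Default 0.8 (fail strictly below).
#' @return A one-row tibble with `correlation`, `n_shared` and `pass`.
#' @export
check_plate_pair <- function(od_a, od_b, threshold = 0.8) {
  if (length(od_a) != length(od_b)) {
    abort("Duplicate plates must share the same sample set.")
  }
  keep <- is.finite(od_a) & is.finite(od_b)
  if (sum(keep) < 3) {
    abort("At least 3 shared samples are required to assess a plate pair.")
  }
  r <- stats::cor(od_a[keep], od_b[keep])
  tibble(correlation = r, n_shared = sum(keep), pass = r >= threshold)
}

#' Faecal egg count from a McMaster slide count
#'
#' Eggs counted on the slide multiplied by 100, giving eggs per gram.
#'
#' @param egg_count Non-negative integer count(s).
#' @return Eggs per gram (always a multiple of 100).
#' @export
fec_from_count <- function(egg_count) {
  if (any(egg_count < 0)) abort("Slide egg counts cannot be negative.")
  if (any(egg_count != round(egg_count))) abort("Slide egg counts must be whole numbers.")
  egg_count * 100
}

#' Transform capture records to the modelling scale
#'
#' Standardizes relative telomere length, antibody OD ratio and age to mean 0
#' and SD 1 over the supplied (already subset) records, and converts faecal
#' egg counts back to slide-count units (rounded to the nearest whole number
#' then divided by 100). The scaling constants are attached so fixed-effect
#' estimates can be back-transformed.
#'
#' @param records A capture-record tibble with columns `rltl`, `igg_tc`,
#'   `age`, `fec` (others passed through).
#' @param scale_traits Character vector of columns to z-score.
#' @return The transformed tibble; attribute `"scaling"` is a tibble of the
#'   means and SDs used.
#' @export
prepare_model_traits <- function(records,
                                 scale_traits = c("rltl", "igg_tc", "age")) {
  records <- as_tibble(records)
  scale_traits <- intersect(scale_traits, names(records))
  scaling <- purrr::map_dfr(scale_traits, function(tr) {
    x <- records[[tr]]
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      abort(paste0("Column `", tr, "` has zero variance; cannot standardize."))
    }
    tibble(trait = tr, center = mean(x, na.rm = TRUE), scale = s)
  })
  for (i in seq_len(nrow(scaling))) {
    tr <- scaling$trait[i]
    records[[tr]] <- (records[[tr]] - scaling$center[i]) / scaling$scale[i]
  }
  if ("fec" %in% names(records)) {
    records$fec <- round(records$fec) / 100
  }
  attr(records, "scaling") <- scaling
  records
}
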
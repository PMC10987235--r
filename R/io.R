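#' Write a simulated dataset to plain-text files
#'
#' Records go to `records.csv` (documented header, one row per individual x
#' year), the ground truth (config echo, seed, level effect draws) to
#' `truth.json`.
#'
#' @param sim A `tv_simulation` from [simulate_population()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  truth$latent <- NULL  # bulky; regenerate from config + seed when needed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(dir)
}

#' Read capture records written by [write_simulation()]
#'
#' @param path Path to a `records.csv`.
#' @return A capture-record tibble.
#' @export
read_records <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Assay quality-control report
#'
#' Counts samples excluded per rule across the qPCR and ELISA processing
#' steps, optionally written as JSON.
#'
#' @param qpcr Output of [compute_rltl()] (or `NULL`).
#' @param elisa Raw ELISA duplicates tibble (before filtering, or `NULL`).
#' @param path Optional JSON output path.
#' @param cov_threshold ELISA duplicate COV threshold (default 0.2).
#' @return A list of exclusion counts.
#' @export
qc_report <- function(qpcr = NULL, elisa = NULL, path = NULL,
                      cov_threshold = 0.2) {
  rep <- list()
  if (!is.null(qpcr)) {
    rep$qpcr <- list(
      n_samples = nrow(qpcr),
      excluded_total = sum(qpcr$excluded),
      excluded_by_reason = as.list(table(qpcr$exclusion_reason))
    )
  }
  if (!is.null(elisa)) {
    kept <- filter_elisa_duplicates(elisa, cov_threshold)
    rep$elisa <- list(n_samples = nrow(elisa),
                      excluded_duplicate_cov = nrow(elisa) - nrow(kept))
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  }
  rep
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    plan = report$plan$model,
    mcmc = report$plan$mcmc,
    counts = report$counts,
    package_version = as.character(utils::packageVersion("telovar"))
  )
  jsonlite::write_json(meta, file.path(outdir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$summary, file.path(outdir, "summary.csv"),
                   row.names = FALSE)
  for (nm in c("correlations", "repeatability", "survival_gradients")) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(as_tibble(report[[nm]]),
                       file.path(outdir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(outdir)
}
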
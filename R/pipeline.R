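# End-to-end orchestration: simulate, single-timepoint analysis,
# longitudinal analysis. TSV (tab-separated, header, UTF-8, '.' decimal) is
# the interchange dialect; every run can write a provenance record.

#' Read / write pipeline TSV tables
#'
#' Thin wrappers fixing the interchange dialect: tab-separated, header row,
#' UTF-8, '.' decimal, no quoting or row names.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv_table()` returns a data.frame; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             fileEncoding = "UTF-8")
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

write_provenance <- function(dir, config, extra = list()) {
  rec <- c(list(timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
                package = "chtrace",
                version = as.character(packageVersion("chtrace")),
                r_version = R.version.string),
           extra)
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$clinical_panel_params <- NULL
    rec$config <- cfg
  }
  jsonlite::write_json(rec, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rec)
}

#' Simulate a cohort and write its tables
#'
#' Generates a longitudinal or single-timepoint synthetic cohort and writes
#' `observations.tsv`, `clinical.tsv`, `truth.tsv` and a `provenance.json`
#' (config, seed, package and R versions) to `outdir`.
#'
#' @param config a [cohort_config()].
#' @param outdir output directory, created if needed.
#' @param mode `"longitudinal"` or `"single-timepoint"`.
#' @return the generated `ch_cohort`, invisibly.
#' @export
run_simulate <- function(config, outdir,
                         mode = c("longitudinal", "single-timepoint")) {
  mode <- match.arg(mode)
  cohort <- if (mode == "longitudinal")
    generate_longitudinal_cohort(config) else
      generate_single_timepoint_cohort(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(cohort$observations, file.path(outdir, "observations.tsv"))
  write_tsv_table(cohort$clinical, file.path(outdir, "clinical.tsv"))
  write_tsv_table(cohort$truth, file.path(outdir, "truth.tsv"))
  write_provenance(outdir, config, list(mode = mode))
  invisible(cohort)
}

#' Single-timepoint analysis: prevalence and clone size versus age
#'
#' Calls CHDMs, summarizes the cohort, and fits the two cross-sectional
#' models: logistic regression of carrier status on age and OLS of
#' ln(max VAF) on age among carriers (each carrier contributes their largest
#' clone).
#'
#' @param observations observation table (generator schema).
#' @param clinical one clinical record per individual (the DNA timepoint).
#' @param min_alt_reads,vaf_floor_pct detection parameters, see
#'   [call_observations()].
#' @param chip_threshold_pct CHIP cut-off in percent.
#' @return list of class `ch_st_report`: `calls`, `summary`
#'   ([summarize_cohort()]), `carriers` (per-carrier max-VAF table),
#'   `fit_prevalence` ([fit_carrier_vs_age()]), `fit_size`
#'   ([fit_logvaf_vs_age()]).
#' @export
run_single_timepoint <- function(observations, clinical,
                                 min_alt_reads = 3, vaf_floor_pct = 0.01,
                                 chip_threshold_pct = 2) {
  if (nrow(observations) == 0 && nrow(clinical) == 0)
    stop("empty input", call. = FALSE)
  calls <- call_observations(observations, min_alt_reads, vaf_floor_pct)
  clinical <- derive_clinical(clinical)
  summ <- summarize_cohort(clinical, calls, chip_threshold_pct)
  det <- calls[calls$detected %in% TRUE, , drop = FALSE]
  carriers <- if (nrow(det) > 0) {
    mx <- aggregate(vaf_pct ~ individual_id, det, max)
    merge(mx, unique(det[, c("individual_id", "age_years")]),
          by = "individual_id")
  } else det[, c("individual_id", "vaf_pct", "age_years")]
  cohort <- clinical[, c("individual_id", "age_years"), drop = FALSE]
  cohort$carrier <- cohort$individual_id %in% carriers$individual_id
  report <- list(calls = calls, summary = summ, carriers = carriers,
                 fit_prevalence = fit_carrier_vs_age(cohort),
                 fit_size = fit_logvaf_vs_age(carriers))
  class(report) <- "ch_st_report"
  report
}

#' Longitudinal analysis: trajectories, growth rates and metabolic
#' associations
#'
#' Runs the full multiple-timepoint pipeline: replicate-aware calling,
#' trajectory assembly and classification, dominant-trajectory selection
#' (excluding shrinking-dominant individuals), the random-intercept /
#' random-slope growth model on ln(VAF) versus age, and Spearman correlation
#' of per-individual growth rates with clinical covariates averaged over the
#' first three follow-up visits (primary family Bonferroni-corrected;
#' triglycerides and non-HDL-C secondary, unadjusted). A sensitivity analysis
#' repeats the growth model and the HDL-C correlation with shrinking-dominant
#' individuals retained.
#'
#' @param observations longitudinal observation table (generator schema).
#' @param clinical visit-level clinical table.
#' @param min_alt_reads,vaf_floor_pct detection parameters.
#' @param chip_threshold_pct CHIP cut-off, percent.
#' @param trajectory_delta_pp growing/shrinking threshold, VAF percentage
#'   points.
#' @param min_traceable_timepoints detections needed for a traceable
#'   trajectory.
#' @param response_scale `"log"` (default) or `"raw"`, see
#'   [fit_mixed_growth()].
#' @param bonferroni_m Bonferroni family size for the primary covariates.
#' @return list of class `ch_long_report`: `calls`, `trajectories`,
#'   `dominant`, `n_excluded_shrinking`, `growth` (`ch_growth_fit`),
#'   `covariate_means`, `associations` (primary + secondary + sensitivity
#'   rows), and `growth_sensitivity`.
#' @export
run_longitudinal <- function(observations, clinical,
                             min_alt_reads = 3, vaf_floor_pct = 0.01,
                             chip_threshold_pct = 2,
                             trajectory_delta_pp = 0.5,
                             min_traceable_timepoints = 3,
                             response_scale = "log",
                             bonferroni_m = length(primary_covariates())) {
  if (nrow(observations) == 0) stop("empty input", call. = FALSE)
  calls <- call_observations(observations, min_alt_reads, vaf_floor_pct)
  traj <- build_trajectories(calls, trajectory_delta_pp,
                             min_traceable_timepoints, chip_threshold_pct)
  dom <- select_dominant(traj, include_shrinking = FALSE)
  n_excl <- sum(dom$excluded)
  if (n_excl > 0)
    message("excluding ", n_excl,
            " individual(s) with a shrinking dominant trajectory")

  clinical <- derive_clinical(clinical)
  cov_means <- average_first_three(clinical)

  dom_kept <- dom[!dom$excluded, , drop = FALSE]
  growth <- fit_mixed_growth(trajectory_points(calls, dom_kept),
                             response_scale = response_scale)

  assoc_primary <- correlate_growth(growth$estimates, cov_means,
                                    family = "primary", m = bonferroni_m)
  assoc_secondary <- correlate_growth(growth$estimates, cov_means,
                                      covariates =
                                        intersect(secondary_covariates(),
                                                  names(cov_means)),
                                      family = "secondary", m = NA)

  dom_all <- select_dominant(traj, include_shrinking = TRUE)
  growth_sens <- fit_mixed_growth(trajectory_points(calls, dom_all),
                                  response_scale = response_scale)
  assoc_sens <- correlate_growth(growth_sens$estimates, cov_means,
                                 covariates = intersect("hdl_c_mmol_l",
                                                        names(cov_means)),
                                 family = "sensitivity", m = NA)
  associations <- rbind(assoc_primary, assoc_secondary, assoc_sens)
  class(associations) <- c("ch_associations", "data.frame")

  report <- list(calls = calls, trajectories = traj, dominant = dom,
                 n_excluded_shrinking = n_excl, growth = growth,
                 covariate_means = cov_means, associations = associations,
                 growth_sensitivity = growth_sens)
  class(report) <- "ch_long_report"
  report
}

#' Detected points of selected dominant trajectories
#'
#' Long table of (individual, age, VAF) for the detected timepoints of each
#' selected dominant trajectory — the input to [fit_mixed_growth()].
#'
#' @param calls called observation table.
#' @param dominant rows of a [select_dominant()] result to keep.
#' @return data.frame `individual_id`, `age_years`, `vaf_pct`.
#' @export
trajectory_points <- function(calls, dominant) {
  idx <- paste(calls$individual_id, calls$gene, calls$hgvs_p) %in%
    paste(dominant$individual_id, dominant$gene, dominant$hgvs_p)
  pts <- calls[idx & calls$detected %in% TRUE,
               c("individual_id", "age_years", "vaf_pct"), drop = FALSE]
  pts[order(pts$individual_id, pts$age_years), , drop = FALSE]
}

#' @export
print.ch_st_report <- function(x, ...) {
  print(x$summary)
  print(x$fit_prevalence)
  print(x$fit_size)
  invisible(x)
}

#' @export
print.ch_long_report <- function(x, ...) {
  print(x$trajectories)
  cat("Individuals excluded for shrinking dominant trajectory:",
      x$n_excluded_shrinking, "\n")
  print(x$growth)
  cat("\nAssociations with averaged clinical covariates:\n")
  print(as.data.frame(x$associations), row.names = FALSE, digits = 3)
  invisible(x)
}
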
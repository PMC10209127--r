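# Association of per-individual clone growth rates with metabolic covariates:
# derived clinical indices, averaging over the first three follow-up visits,
# and Spearman correlation with Bonferroni control over the primary family.

#' Covariates of the primary association family
#'
#' The ten metabolic covariates tested against clone growth with Bonferroni
#' correction. Triglycerides and non-HDL cholesterol are secondary,
#' explorative covariates reported without adjustment (see
#' [secondary_covariates()]).
#' @return character vector of clinical column names.
#' @export
primary_covariates <- function() {
  c("bmi", "glucose_mmol_l", "insulin_mu_l", "homa_ir", "total_chol_mmol_l",
    "hdl_c_mmol_l", "ldl_c_mmol_l", "crp_mg_l", "sbp_mmhg", "dbp_mmhg")
}

#' @rdname primary_covariates
#' @export
secondary_covariates <- function() {
  c("triglycerides_mmol_l", "non_hdl_c_mmol_l")
}

#' Complete a clinical record with derived indices and flags
#'
#' Adds to a visit-level clinical table:
#' * `homa_ir` = insulin (mU/L) x glucose (mmol/L) / 22.5;
#' * `ldl_c_mmol_l` by the Friedewald equation, total cholesterol -
#'   triglycerides/2.2 - HDL-C (all mmol/L), set `NA` when triglycerides
#'   exceed 4.5 mmol/L (outside the equation's validity);
#' * `non_hdl_c_mmol_l` = total cholesterol - HDL-C;
#' * `diabetes`: glucose >= 7.0 mmol/L or anti-diabetes medication;
#' * `hypertension`: SBP >= 140 or DBP >= 90 mmHg or blood-pressure
#'   medication.
#'
#' @param clinical data.frame in the generator's clinical schema
#'   (`glucose_mmol_l`, `insulin_mu_l`, `total_chol_mmol_l`, `hdl_c_mmol_l`,
#'   `triglycerides_mmol_l`, `sbp_mmhg`, `dbp_mmhg`, and optional
#'   `diabetes_med`, `bp_med`). Missing source columns leave the derived
#'   column absent.
#' @param tg_friedewald_max Friedewald validity bound, mmol/L.
#' @return the input with derived columns appended.
#' @export
#' @examples
#' derive_clinical(data.frame(total_chol_mmol_l = 5.48,
#'                            triglycerides_mmol_l = 1.95,
#'                            hdl_c_mmol_l = 1.38))$ldl_c_mmol_l  # 3.21
derive_clinical <- function(clinical, tg_friedewald_max = 4.5) {
  has <- function(...) all(c(...) %in% names(clinical))
  if (has("insulin_mu_l", "glucose_mmol_l"))
    clinical$homa_ir <- clinical$insulin_mu_l * clinical$glucose_mmol_l / 22.5
  if (has("total_chol_mmol_l", "triglycerides_mmol_l", "hdl_c_mmol_l")) {
    ldl <- clinical$total_chol_mmol_l - clinical$triglycerides_mmol_l / 2.2 -
      clinical$hdl_c_mmol_l
    ldl[clinical$triglycerides_mmol_l > tg_friedewald_max] <- NA_real_
    clinical$ldl_c_mmol_l <- ldl
  }
  if (has("total_chol_mmol_l", "hdl_c_mmol_l"))
    clinical$non_hdl_c_mmol_l <- clinical$total_chol_mmol_l -
      clinical$hdl_c_mmol_l
  if (has("glucose_mmol_l")) {
    med <- if ("diabetes_med" %in% names(clinical))
      clinical$diabetes_med %in% TRUE else FALSE
    clinical$diabetes <- clinical$glucose_mmol_l >= 7.0 | med
  }
  if (has("sbp_mmhg", "dbp_mmhg")) {
    med <- if ("bp_med" %in% names(clinical))
      clinical$bp_med %in% TRUE else FALSE
    clinical$hypertension <- clinical$sbp_mmhg >= 140 |
      clinical$dbp_mmhg >= 90 | med
  }
  clinical
}

#' Average covariates over the first three follow-up visits
#'
#' For each individual, takes the unweighted mean of each covariate over the
#' values available at the first `n_visits` scheduled post-baseline
#' timepoints (baseline excluded); visits an individual missed are simply
#' skipped. Individuals with no record at any of those visits are dropped
#' with a warning.
#'
#' @param clinical visit-level clinical table with `individual_id` and
#'   `timepoint_years` (ideally after [derive_clinical()]).
#' @param covariates columns to average; defaults to the union of primary and
#'   secondary families, intersected with what is present.
#' @param n_visits number of scheduled follow-up visits to average over.
#' @return data.frame, one row per individual: `individual_id`, `n_visits`
#'   (records used) and one column per covariate.
#' @export
average_first_three <- function(clinical,
                                covariates = NULL,
                                n_visits = 3) {
  if (is.null(covariates))
    covariates <- intersect(c(primary_covariates(), secondary_covariates()),
                            names(clinical))
  fu <- sort(unique(clinical$timepoint_years[clinical$timepoint_years > 0]))
  if (length(fu) == 0) stop("no follow-up visits in clinical table",
                            call. = FALSE)
  fu <- fu[seq_len(min(n_visits, length(fu)))]
  sub <- clinical[clinical$timepoint_years %in% fu, , drop = FALSE]
  all_ids <- unique(clinical$individual_id)
  lost <- setdiff(all_ids, unique(sub$individual_id))
  if (length(lost))
    warning(length(lost), " individual(s) with no record at the first ",
            n_visits, " follow-up visits were excluded")
  if (nrow(sub) == 0) stop("no individuals with follow-up records",
                           call. = FALSE)
  out <- data.frame(individual_id = sort(unique(sub$individual_id)),
                    stringsAsFactors = FALSE)
  out$n_visits <- as.integer(table(sub$individual_id)[out$individual_id])
  for (v in covariates) {
    m <- tapply(sub[[v]], sub$individual_id, function(x) mean(x, na.rm = TRUE))
    out[[v]] <- as.numeric(m[out$individual_id])
  }
  out
}

# Spearman rho and two-sided p; exact null distribution when free of ties and
# small n (stats::cor.test AS89), asymptotic otherwise. Zero-variance input
# gives NA/NA.
spearman_test <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2 || sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Correlate clone growth rates with averaged clinical covariates
#'
#' Spearman rank correlation (average ranks for ties) between per-individual
#' growth rates and each covariate, with two-sided p-values and Bonferroni
#' correction over the primary covariate family. Secondary covariates are
#' reported unadjusted and labelled as such.
#'
#' @param rates data.frame with `individual_id` and `rate_pct_per_year`
#'   (or `slope_log_per_year`; ranks are identical as the transform is
#'   monotone), e.g. `fit_mixed_growth(...)$estimates`.
#' @param covariate_means output of [average_first_three()].
#' @param covariates covariate columns to test; default
#'   [primary_covariates()] intersected with what is present.
#' @param family label recorded in the result (`"primary"`, `"secondary"`,
#'   `"sensitivity"`, ...).
#' @param m Bonferroni family size; defaults to the number of primary
#'   covariates. Set `NA` to skip adjustment (secondary analyses).
#' @param min_n minimum paired observations required per covariate.
#' @return data.frame of class `ch_associations`: `covariate`, `n`,
#'   `spearman_r`, `p_raw`, `p_bonferroni`, `family`.
#' @export
correlate_growth <- function(rates, covariate_means,
                             covariates = NULL,
                             family = "primary",
                             m = NULL,
                             min_n = 5) {
  rate_col <- if ("rate_pct_per_year" %in% names(rates))
    "rate_pct_per_year" else "slope_log_per_year"
  if (!all(c("individual_id", rate_col) %in% names(rates)))
    stop("rates need individual_id and a rate/slope column", call. = FALSE)
  if (is.null(covariates))
    covariates <- intersect(primary_covariates(), names(covariate_means))
  if (is.null(m)) m <- length(covariates)
  merged <- merge(rates[, c("individual_id", rate_col)], covariate_means,
                  by = "individual_id")
  res <- lapply(covariates, function(v) {
    st <- spearman_test(merged[[rate_col]], merged[[v]])
    if (st$n < min_n)
      stop("covariate ", v, ": fewer than ", min_n, " paired observations",
           call. = FALSE)
    data.frame(covariate = v, n = st$n, spearman_r = st$rho, p_raw = st$p,
               p_bonferroni = if (is.na(m)) NA_real_ else
                 pmin(1, m * st$p), family = family,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("ch_associations", "data.frame")
  out
}
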
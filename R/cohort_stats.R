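# Descriptive cohort summaries (Table-1 style) and between-group tests.

#' Summarize a single-timepoint cohort
#'
#' Computes carrier prevalence, the distribution of CHDM counts per carrier,
#' the CHIP fraction among carriers, and mean (SD) / n (%) summaries of the
#' clinical panel at the DNA timepoint.
#'
#' @param clinical one clinical record per individual (the DNA timepoint).
#' @param calls called observation table from [call_observations()] for the
#'   same individuals.
#' @param chip_threshold_pct CHIP VAF cut-off in percent.
#' @param continuous,categorical clinical columns to summarize; defaults
#'   cover the generator's panel.
#' @return list of class `ch_cohort_summary`: `n`, `n_carriers`,
#'   `prevalence_pct`, `chdm_per_carrier` (table), `n_chip_carriers`,
#'   `chip_pct_of_carriers`, and a `variables` data.frame of formatted
#'   summaries.
#' @export
summarize_cohort <- function(clinical, calls, chip_threshold_pct = 2,
                             continuous = NULL, categorical = NULL) {
  if (nrow(clinical) == 0) stop("empty cohort", call. = FALSE)
  if (anyDuplicated(clinical$individual_id))
    stop("expected one clinical record per individual", call. = FALSE)
  det <- calls[calls$detected %in% TRUE, , drop = FALSE]
  n <- nrow(clinical)
  per_carrier <- table(det$individual_id)
  n_carriers <- length(per_carrier)
  chip_by_ind <- tapply(annotate_chip(det$vaf_pct, chip_threshold_pct),
                        det$individual_id, any)
  n_chip <- sum(unlist(chip_by_ind))
  if (is.null(continuous))
    continuous <- intersect(c("age_years", "bmi", "glucose_mmol_l",
                              "insulin_mu_l", "homa_ir", "total_chol_mmol_l",
                              "hdl_c_mmol_l", "ldl_c_mmol_l",
                              "triglycerides_mmol_l", "crp_mg_l",
                              "sbp_mmhg", "dbp_mmhg"), names(clinical))
  if (is.null(categorical))
    categorical <- intersect(c("sex", "smoker", "diabetes", "hypertension"),
                             names(clinical))
  rows <- list()
  for (v in continuous) {
    x <- clinical[[v]]
    rows[[v]] <- data.frame(variable = v, type = "continuous",
                            summary = sprintf("%.3g (%.3g)", mean(x, na.rm = TRUE),
                                              sd(x, na.rm = TRUE)),
                            stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- clinical[[v]]
    if (is.character(x) || is.factor(x)) x <- x == sort(unique(as.character(x)))[1]
    k <- sum(x %in% TRUE)
    rows[[v]] <- data.frame(variable = v, type = "categorical",
                            summary = sprintf("%d (%.1f%%)", k, 100 * k / n),
                            stringsAsFactors = FALSE)
  }
  structure(list(n = n, n_carriers = n_carriers,
                 prevalence_pct = round(100 * n_carriers / n, 1),
                 chdm_per_carrier = per_carrier,
                 n_chip_carriers = n_chip,
                 chip_pct_of_carriers = if (n_carriers > 0)
                   round(100 * n_chip / n_carriers, 1) else NA_real_,
                 variables = do.call(rbind, rows)),
            class = "ch_cohort_summary")
}

#' @export
print.ch_cohort_summary <- function(x, ...) {
  cat("Cohort: n =", x$n, "\n")
  cat("CHDM carriers:", x$n_carriers,
      sprintf("(%.1f%%)", x$prevalence_pct), "\n")
  cat("CHIP carriers:", x$n_chip_carriers,
      sprintf("(%.1f%% of carriers)", x$chip_pct_of_carriers), "\n")
  if (length(x$chdm_per_carrier))
    print(table(factor(x$chdm_per_carrier)))
  print(x$variables, row.names = FALSE)
  invisible(x)
}

#' Compare two cohorts variable by variable
#'
#' Two-sample t-test for continuous variables, chi-square for categorical
#' (without continuity correction by default; set `correct = TRUE` for the
#' Yates-corrected variant) and Wilcoxon rank-sum where requested (e.g. for
#' age differences).
#'
#' @param a,b per-individual clinical data.frames for the two groups.
#' @param continuous,categorical,wilcoxon character vectors of column names
#'   to test with each method.
#' @param correct apply Yates continuity correction in chi-square tests?
#' @return data.frame `variable`, `test`, `statistic`, `p_value`.
#'   Zero-variance continuous variables yield `NA` with a warning.
#' @export
compare_groups <- function(a, b, continuous = character(),
                           categorical = character(),
                           wilcoxon = character(), correct = FALSE) {
  rows <- list()
  for (v in continuous) {
    x <- a[[v]]; y <- b[[v]]
    if (sd(x, na.rm = TRUE) == 0 && sd(y, na.rm = TRUE) == 0) {
      warning("zero variance in '", v, "': t-test undefined")
      rows[[paste0("t_", v)]] <- data.frame(variable = v, test = "t",
                                            statistic = NA_real_,
                                            p_value = NA_real_)
      next
    }
    tt <- t.test(x, y)
    rows[[paste0("t_", v)]] <- data.frame(variable = v, test = "t",
                                          statistic = unname(tt$statistic),
                                          p_value = tt$p.value)
  }
  for (v in categorical) {
    tab <- rbind(table(factor(a[[v]] %in% TRUE, levels = c(FALSE, TRUE))),
                 table(factor(b[[v]] %in% TRUE, levels = c(FALSE, TRUE))))
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    rows[[paste0("chisq_", v)]] <- data.frame(variable = v, test = "chisq",
                                              statistic = unname(ct$statistic),
                                              p_value = ct$p.value)
  }
  for (v in wilcoxon) {
    wt <- suppressWarnings(wilcox.test(a[[v]], b[[v]]))
    rows[[paste0("wilcox_", v)]] <- data.frame(variable = v, test = "wilcoxon",
                                               statistic = unname(wt$statistic),
                                               p_value = wt$p.value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chi-square test of carrier prevalence between two cohorts
#'
#' @param carriers_a,n_a carriers and total in group A.
#' @param carriers_b,n_b carriers and total in group B.
#' @param correct Yates continuity correction?
#' @return `htest` from [stats::chisq.test()] on the 2x2 table.
#' @export
#' @examples
#' prevalence_test(216, 1050, 189, 841)$p.value
prevalence_test <- function(carriers_a, n_a, carriers_b, n_b,
                            correct = FALSE) {
  tab <- matrix(c(carriers_a, n_a - carriers_a,
                  carriers_b, n_b - carriers_b), nrow = 2, byrow = TRUE)
  chisq.test(tab, correct = correct)
}
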
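# Clone growth-rate estimation.
#
# Cross-sectional: OLS of log VAF on age (clone size vs ageing) and logistic
# regression of carrier status on age (prevalence vs ageing).
# Longitudinal: a random-intercept / random-slope linear mixed model of
# ln(VAF) on age. Because ln(VAF) is modelled linear in age, the fixed age
# coefficient plus each individual's predicted random slope is that
# individual's per-year log growth, and 100 * (exp(slope) - 1) is the
# proportionate annual growth rate in percent (7%/yr corresponds to a log
# slope of ln(1.07)).

#' Convert a log-VAF slope to a proportionate annual rate
#'
#' @param slope_log_per_year per-year change in ln(VAF).
#' @return percent change in VAF per year, `100 * (exp(slope) - 1)`.
#' @export
#' @examples
#' rate_from_slope(0.059)  # ~6% per year
rate_from_slope <- function(slope_log_per_year) {
  100 * (exp(slope_log_per_year) - 1)
}

#' Inverse of [rate_from_slope()]
#' @param rate_pct_per_year percent change in VAF per year (> -100).
#' @return per-year log-VAF slope, `ln(1 + rate/100)`.
#' @export
slope_from_rate <- function(rate_pct_per_year) {
  log(1 + rate_pct_per_year / 100)
}

#' Effect of age on clone size in a single-timepoint cohort
#'
#' Ordinary least squares of ln(VAF) on age, one row per carrier, using each
#' carrier's largest clone. The age coefficient is the per-year log change in
#' clone size across the age gradient; `pct_per_year` converts it to the
#' percent difference in clone size per year of age.
#'
#' @param carriers data.frame with one row per carrier and columns
#'   `age_years` and `vaf_pct` (> 0).
#' @return object of class `ch_st_fit`: list with `logvaf_age_coef`, `se`,
#'   `p_value`, `pct_per_year`, `n` and the underlying `lm` fit.
#' @export
fit_logvaf_vs_age <- function(carriers) {
  if (!all(c("age_years", "vaf_pct") %in% names(carriers)))
    stop("carriers need columns age_years and vaf_pct", call. = FALSE)
  carriers <- carriers[complete.cases(carriers[, c("age_years", "vaf_pct")]), ]
  if (nrow(carriers) < 3)
    stop("insufficient data: need at least 3 carriers", call. = FALSE)
  if (any(carriers$vaf_pct <= 0))
    stop("VAF must be positive to take logs", call. = FALSE)
  fit <- lm(log(vaf_pct) ~ age_years, data = carriers)
  sm <- summary(fit)$coefficients
  structure(list(logvaf_age_coef = unname(coef(fit)["age_years"]),
                 se = sm["age_years", "Std. Error"],
                 p_value = sm["age_years", "Pr(>|t|)"],
                 pct_per_year = rate_from_slope(unname(coef(fit)["age_years"])),
                 n = nrow(carriers), fit = fit),
            class = "ch_st_fit")
}

#' Effect of age on CHDM carrier prevalence
#'
#' Maximum-likelihood logistic regression of carrier status on age.
#'
#' @param cohort data.frame with logical/0-1 `carrier` and `age_years`.
#' @return list of class `ch_logit_fit` with `log_odds_per_year`, `se`,
#'   `p_value`, `n` and the `glm` fit.
#' @export
fit_carrier_vs_age <- function(cohort) {
  if (!all(c("carrier", "age_years") %in% names(cohort)))
    stop("cohort needs columns carrier and age_years", call. = FALSE)
  y <- as.logical(cohort$carrier)
  if (all(y) || all(!y))
    stop("carrier status does not vary: logistic fit undefined", call. = FALSE)
  fit <- withCallingHandlers(
    glm(y ~ age_years, data = cohort, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop("complete separation: age perfectly predicts carrier status",
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  structure(list(log_odds_per_year = unname(coef(fit)["age_years"]),
                 se = sm["age_years", "Std. Error"],
                 p_value = sm["age_years", "Pr(>|z|)"],
                 n = nrow(cohort), fit = fit),
            class = "ch_logit_fit")
}

#' Per-individual clone growth rates from a random-slope mixed model
#'
#' Fits `ln(VAF) ~ age + (1 + age | individual)` by restricted maximum
#' likelihood (age is centred internally for numerical stability; reported
#' intercepts refer to age 0). Each individual's growth slope is the fixed
#' age effect plus their predicted (BLUP) random slope; partial pooling
#' shrinks noisy individual slopes towards the population slope. If the
#' random-effects covariance is singular the model is refitted with
#' uncorrelated random intercept and slope (and a message is emitted).
#' With a single individual the model reduces to OLS for that individual.
#'
#' @param points long data.frame: `individual_id`, `age_years`, `vaf_pct`
#'   (percent, > 0 on the log scale), one row per detected timepoint of each
#'   individual's dominant trajectory. Individuals with fewer than 2 points
#'   are dropped with a warning.
#' @param response_scale `"log"` (default) models ln(VAF) so slopes convert
#'   to proportionate annual rates; `"raw"` models VAF in percent, in which
#'   case slopes are additive percentage points per year and
#'   `rate_pct_per_year` is `NA`.
#' @return object of class `ch_growth_fit`: `fixed_slope`, `fixed_rate`,
#'   `mean_rate` (mean per-individual rate), `estimates` (data.frame
#'   `individual_id`, `slope_log_per_year`, `rate_pct_per_year`, `intercept`,
#'   `n_points`), `singular`, `convergence` (character, empty if clean),
#'   `response_scale` and the fitted `model`.
#' @export
fit_mixed_growth <- function(points, response_scale = c("log", "raw")) {
  response_scale <- match.arg(response_scale)
  req <- c("individual_id", "age_years", "vaf_pct")
  if (!all(req %in% names(points)))
    stop("points need columns individual_id, age_years, vaf_pct",
         call. = FALSE)
  points <- points[complete.cases(points[, req]), , drop = FALSE]
  if (response_scale == "log" && any(points$vaf_pct <= 0))
    stop("VAF must be positive on the log scale", call. = FALSE)
  npts <- table(points$individual_id)
  thin <- names(npts)[npts < 2]
  if (length(thin)) {
    warning("dropping ", length(thin),
            " individual(s) with fewer than 2 points")
    points <- points[!points$individual_id %in% thin, , drop = FALSE]
  }
  if (nrow(points) == 0) stop("no usable points", call. = FALSE)
  points$.y <- if (response_scale == "log") log(points$vaf_pct) else
    points$vaf_pct
  age_center <- mean(points$age_years)
  points$.a <- points$age_years - age_center
  ids <- unique(points$individual_id)

  if (length(ids) == 1L) {
    fit <- lm(.y ~ .a, data = points)
    slope <- unname(coef(fit)[".a"])
    est <- data.frame(individual_id = ids,
                      slope_log_per_year = slope,
                      rate_pct_per_year = if (response_scale == "log")
                        rate_from_slope(slope) else NA_real_,
                      intercept = unname(coef(fit)["(Intercept)"]) -
                        slope * age_center,
                      n_points = nrow(points), stringsAsFactors = FALSE)
    return(structure(list(fixed_slope = slope,
                          fixed_rate = est$rate_pct_per_year,
                          mean_rate = est$rate_pct_per_year,
                          estimates = est, singular = FALSE,
                          convergence = character(),
                          response_scale = response_scale,
                          age_center = age_center, model = fit),
                     class = "ch_growth_fit"))
  }

  conv <- character()
  fit_once <- function(formula) {
    withCallingHandlers(
      lme4::lmer(formula, data = points, REML = TRUE),
      warning = function(w) {
        conv <<- c(conv, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  model <- fit_once(.y ~ .a + (1 + .a | individual_id))
  singular <- lme4::isSingular(model)
  if (singular) {
    message("singular random-effects covariance; refitting with ",
            "uncorrelated random intercept and slope")
    conv <- character()
    model <- fit_once(.y ~ .a + (1 + .a || individual_id))
    singular <- lme4::isSingular(model)
  }
  fe <- lme4::fixef(model)
  # with a double-bar formula the grouping factor appears twice in ranef();
  # sum contributions across all blocks
  extract_re <- function(model, ids, col) {
    out <- setNames(numeric(length(ids)), ids)
    for (el in lme4::ranef(model)) {
      if (col %in% colnames(el))
        out[rownames(el)] <- out[rownames(el)] + el[[col]]
    }
    unname(out[ids])
  }
  slope <- unname(fe[".a"]) + extract_re(model, ids, ".a")
  icept <- unname(fe["(Intercept)"]) + extract_re(model, ids, "(Intercept)") -
    slope * age_center
  est <- data.frame(individual_id = ids,
                    slope_log_per_year = slope,
                    rate_pct_per_year = if (response_scale == "log")
                      rate_from_slope(slope) else NA_real_,
                    intercept = icept,
                    n_points = as.integer(npts[ids]),
                    stringsAsFactors = FALSE)
  rownames(est) <- NULL
  structure(list(fixed_slope = unname(fe[".a"]),
                 fixed_rate = if (response_scale == "log")
                   rate_from_slope(unname(fe[".a"])) else NA_real_,
                 mean_rate = mean(est$rate_pct_per_year),
                 estimates = est, singular = singular,
                 convergence = conv, response_scale = response_scale,
                 age_center = age_center, model = model),
            class = "ch_growth_fit")
}

#' @export
print.ch_growth_fit <- function(x, digits = 3, ...) {
  cat("Random-intercept/random-slope clone growth model (",
      x$response_scale, " VAF)\n", sep = "")
  cat("  individuals:", nrow(x$estimates),
      " points:", sum(x$estimates$n_points), "\n")
  cat("  fixed slope:", format(x$fixed_slope, digits = digits),
      "per year")
  if (x$response_scale == "log")
    cat("  (", format(x$fixed_rate, digits = digits), "% per year)", sep = "")
  cat("\n")
  if (x$response_scale == "log")
    cat("  mean individual rate:", format(x$mean_rate, digits = digits),
        "% per year; range",
        paste(format(range(x$estimates$rate_pct_per_year), digits = digits),
              collapse = " to "), "\n")
  if (x$singular) cat("  note: singular random-effects covariance\n")
  if (length(x$convergence))
    cat("  convergence notes:", paste(unique(x$convergence), collapse = "; "),
        "\n")
  invisible(x)
}

#' @export
print.ch_st_fit <- function(x, digits = 3, ...) {
  cat("ln(VAF) ~ age (n = ", x$n, "): coef ",
      format(x$logvaf_age_coef, digits = digits), " per year (",
      format(x$pct_per_year, digits = digits), "%/yr), p = ",
      format(x$p_value, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
print.ch_logit_fit <- function(x, digits = 3, ...) {
  cat("carrier ~ age (n = ", x$n, "): log-odds ",
      format(x$log_odds_per_year, digits = digits), " per year, p = ",
      format(x$p_value, digits = digits), "\n", sep = "")
  invisible(x)
}
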
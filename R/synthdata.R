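# Synthetic-cohort generator: longitudinal and single-timepoint cohorts with
# the structure the downstream CHDM pipeline assumes (dual-replicate binomial
# read noise, staggered follow-up, clinical panel copula-linked to growth).

#' Default clinical panel parameters
#'
#' Per-variable marginal distributions for the generated metabolic panel of a
#' severely obese cohort: means and SDs of BMI, fasting glucose, insulin,
#' total cholesterol, HDL-C, triglycerides, blood pressure and CRP. Insulin,
#' triglycerides and CRP are right-skewed and modelled log-normal
#' (moment-matched); the rest are normal. `within_frac` is the fraction of the
#' total variation that fluctuates between visits within an individual (the
#' remainder is a stable person-level latent value).
#'
#' @return data.frame with columns `variable`, `mean`, `sd`, `dist`.
#' @export
default_clinical_panel <- function() {
  data.frame(
    variable = c("bmi", "glucose_mmol_l", "insulin_mu_l", "total_chol_mmol_l",
                 "hdl_c_mmol_l", "triglycerides_mmol_l", "sbp_mmhg",
                 "dbp_mmhg", "crp_mg_l"),
    mean = c(40.4, 5.94, 17.3, 5.48, 1.38, 1.95, 142, 82.9, 7.89),
    sd   = c(5.26, 2.38, 12.4, 1.05, 0.33, 1.37, 18.7, 9.76, 8.18),
    dist = c("normal", "normal", "lognormal", "normal", "normal",
             "lognormal", "normal", "normal", "lognormal"),
    stringsAsFactors = FALSE
  )
}

#' Cohort generator configuration
#'
#' Bundles every parameter of the synthetic-cohort generator. Defaults encode
#' the longitudinal study world: 40 individuals aged 37-60 at baseline,
#' examinations at 0/2/10/15/20 years with per-visit availability
#' 40/38/40/38/24, two technical sequencing replicates at ~3891x coverage,
#' a ~20.6% carrier prevalence at the mean age rising with age, geometric
#' clone growth with mean rate exp(growth_log_mean) - 1 (~7%/yr), and an
#' HDL-C/growth-rate rank correlation target of -0.68.
#'
#' @param n_individuals number of individuals.
#' @param baseline_age_range numeric length 2, low < high, years.
#' @param timepoints years since baseline; strictly increasing, first 0.
#' @param dropout_pattern per-timepoint availability: retention counts
#'   (values > 1, each <= `n_individuals`) or probabilities (all in `[0, 1]`).
#'   Length must equal `length(timepoints)`.
#' @param coverage_mean mean reads per technical replicate (Poisson).
#' @param n_replicates technical replicates per sample; fixed at 2.
#' @param carrier_prevalence_at_mean_age carrier fraction at the mean age.
#' @param prevalence_age_log_odds per-year log-odds slope of carriership.
#' @param growth_log_mean,growth_log_sd mean/SD of the per-year slope of
#'   ln(VAF) across individuals (per-clone true growth).
#' @param baseline_vaf_log_mean,baseline_vaf_log_sd log-scale location/spread
#'   of baseline VAF in percent (log-normal, clamped to `[0.01, 50]`).
#' @param vaf_age_log_slope single-timepoint cohorts only: per-year effect of
#'   age on ln(VAF) (clones of older carriers have grown longer), centred at
#'   the cohort mean age. Default 0.059/yr, the effect size observed in
#'   severely obese adults under usual care.
#' @param multi_clone_prob fraction of carriers with more than one clone.
#' @param screen_coverage_mean per-replicate coverage of the cross-sectional
#'   screen from which longitudinal carriers are recruited: each longitudinal
#'   individual's clone set is conditioned on at least one clone being
#'   detectable by the dual-replicate rule at this coverage (the cohort
#'   consists of known carriers by construction). `NULL` disables the screen.
#' @param screen_min_alt_reads per-replicate alt-read threshold of the screen.
#' @param hdl_growth_spearman_target target Spearman correlation between an
#'   individual's dominant true log-slope and latent HDL-C, in `[-1, 1]`.
#' @param clinical_panel_params data.frame as [default_clinical_panel()].
#' @param clinical_within_frac within-individual (visit-to-visit) fraction of
#'   each clinical variable's total variation; 0 freezes the panel per person.
#' @param seed integer seed; identical config + seed gives identical tables.
#' @param noise logical; `FALSE` switches off sequencing noise (read totals
#'   fixed at `coverage_mean`, alt reads rounded expectation) and clinical
#'   visit-to-visit noise, leaving only between-individual variation.
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_individuals = 10, seed = 7)
#' cohort <- generate_longitudinal_cohort(cfg)
#' str(cohort$truth)
cohort_config <- function(n_individuals = 40,
                          baseline_age_range = c(37, 60),
                          timepoints = c(0, 2, 10, 15, 20),
                          dropout_pattern = c(40, 38, 40, 38, 24),
                          coverage_mean = 3891,
                          n_replicates = 2,
                          carrier_prevalence_at_mean_age = 0.206,
                          prevalence_age_log_odds = 0.05,
                          growth_log_mean = log(1.07),
                          growth_log_sd = 0.06,
                          baseline_vaf_log_mean = log(0.8),
                          baseline_vaf_log_sd = 1.6,
                          vaf_age_log_slope = 0.059,
                          multi_clone_prob = 0.20,
                          screen_coverage_mean = 2840,
                          screen_min_alt_reads = 3,
                          hdl_growth_spearman_target = -0.68,
                          clinical_panel_params = default_clinical_panel(),
                          clinical_within_frac = 0.2,
                          seed = 1L,
                          noise = TRUE) {
  # the default retention counts describe a 40-person cohort; for other
  # cohort sizes fall back to the equivalent per-visit probabilities
  if (missing(dropout_pattern) && n_individuals != 40)
    dropout_pattern <- c(40, 38, 40, 38, 24) / 40
  cfg <- list(n_individuals = as.integer(n_individuals),
              baseline_age_range = as.numeric(baseline_age_range),
              timepoints = as.numeric(timepoints),
              dropout_pattern = as.numeric(dropout_pattern),
              coverage_mean = coverage_mean,
              n_replicates = as.integer(n_replicates),
              carrier_prevalence_at_mean_age = carrier_prevalence_at_mean_age,
              prevalence_age_log_odds = prevalence_age_log_odds,
              growth_log_mean = growth_log_mean,
              growth_log_sd = growth_log_sd,
              baseline_vaf_log_mean = baseline_vaf_log_mean,
              baseline_vaf_log_sd = baseline_vaf_log_sd,
              vaf_age_log_slope = vaf_age_log_slope,
              multi_clone_prob = multi_clone_prob,
              screen_coverage_mean = screen_coverage_mean,
              screen_min_alt_reads = screen_min_alt_reads,
              hdl_growth_spearman_target = hdl_growth_spearman_target,
              clinical_panel_params = clinical_panel_params,
              clinical_within_frac = clinical_within_frac,
              seed = as.integer(seed),
              noise = isTRUE(noise))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_individuals < 1)
    stop("n_individuals must be >= 1", call. = FALSE)
  if (length(cfg$baseline_age_range) != 2 ||
      cfg$baseline_age_range[1] >= cfg$baseline_age_range[2])
    stop("baseline_age_range must be (low, high) with low < high", call. = FALSE)
  tp <- cfg$timepoints
  if (tp[1] != 0 || any(diff(tp) <= 0))
    stop("timepoints must be strictly increasing and start at 0", call. = FALSE)
  if (length(cfg$dropout_pattern) != length(tp))
    stop("dropout_pattern length must equal the number of timepoints",
         call. = FALSE)
  if (any(cfg$dropout_pattern < 0))
    stop("dropout_pattern entries must be non-negative", call. = FALSE)
  if (any(cfg$dropout_pattern > 1) && any(cfg$dropout_pattern > cfg$n_individuals))
    stop("retention counts cannot exceed n_individuals", call. = FALSE)
  if (cfg$coverage_mean <= 0) stop("coverage_mean must be > 0", call. = FALSE)
  if (cfg$n_replicates != 2L)
    stop("n_replicates is fixed at 2 (dual technical replicates)", call. = FALSE)
  probs <- c(cfg$carrier_prevalence_at_mean_age, cfg$multi_clone_prob,
             cfg$clinical_within_frac)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$growth_log_sd < 0) stop("growth_log_sd must be >= 0", call. = FALSE)
  if (abs(cfg$hdl_growth_spearman_target) > 1)
    stop("hdl_growth_spearman_target must lie in [-1, 1]", call. = FALSE)
  req <- c("variable", "mean", "sd", "dist")
  if (!all(req %in% names(cfg$clinical_panel_params)))
    stop("clinical_panel_params needs columns variable/mean/sd/dist",
         call. = FALSE)
  invisible(cfg)
}

# presence matrix individuals x timepoints from counts or probabilities
draw_presence <- function(cfg) {
  n <- cfg$n_individuals
  k <- length(cfg$timepoints)
  present <- matrix(FALSE, n, k)
  counts <- any(cfg$dropout_pattern > 1) ||
    all(cfg$dropout_pattern == round(cfg$dropout_pattern) &
          cfg$dropout_pattern > 1)
  for (j in seq_len(k)) {
    pat <- cfg$dropout_pattern[j]
    if (pat > 1 || (counts && pat == round(pat) && pat >= 1)) {
      present[sample.int(n, min(n, round(pat))), j] <- TRUE
    } else {
      present[, j] <- runif(n) < pat
    }
  }
  # everyone contributes at least one visit: force baseline for empty rows
  empty <- rowSums(present) == 0
  present[empty, 1] <- TRUE
  present
}

# inverse Gaussian-copula link: latent Pearson r giving Spearman rho_s
copula_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# marginal transform of standard-normal scores
marginal_from_z <- function(z, mean, sd, dist) {
  if (dist == "lognormal") {
    sdlog <- sqrt(log(1 + (sd / mean)^2))
    meanlog <- log(mean) - sdlog^2 / 2
    qlnorm(pnorm(z), meanlog = meanlog, sdlog = sdlog)
  } else {
    mean + sd * z
  }
}

# clinical visit table for given individuals; z_hdl are the individuals'
# latent HDL copula scores (standard normal)
draw_clinical <- function(cfg, ids, ages_by_visit, tp_by_visit, visit_owner,
                          z_hdl, sex, smoker, diabetes_med, bp_med) {
  panel <- cfg$clinical_panel_params
  n <- length(ids)
  f <- if (cfg$noise) cfg$clinical_within_frac else 0
  lat <- matrix(rnorm(n * nrow(panel)), n, nrow(panel))
  lat[, which(panel$variable == "hdl_c_mmol_l")] <- z_hdl
  nv <- length(visit_owner)
  out <- data.frame(individual_id = ids[visit_owner],
                    timepoint_years = tp_by_visit,
                    age_years = ages_by_visit,
                    sex = sex[visit_owner],
                    stringsAsFactors = FALSE)
  for (v in seq_len(nrow(panel))) {
    zvis <- sqrt(1 - f^2) * lat[visit_owner, v] + f * rnorm(nv)
    out[[panel$variable[v]]] <-
      marginal_from_z(zvis, panel$mean[v], panel$sd[v], panel$dist[v])
  }
  out$smoker <- smoker[visit_owner]
  out$diabetes_med <- diabetes_med[visit_owner]
  out$bp_med <- bp_med[visit_owner]
  out
}

# probability the dual-replicate rule detects a clone of true VAF v (percent)
# at the given per-replicate coverage
screen_detect_prob <- function(vaf_pct, coverage, min_alt = 3) {
  (1 - stats::pbinom(min_alt - 1, round(coverage), vaf_pct / 100))^2
}

# truncated-normal draw below an upper bound, by inverse CDF
rnorm_below <- function(n, mean, sd, upper) {
  if (sd == 0) return(pmin(rep(mean, n), upper))
  u <- runif(n) * pnorm((upper - mean) / sd)
  mean + sd * stats::qnorm(pmax(u, 1e-12))
}

# clone table for carrier individuals: one row per clone. The clone with the
# largest baseline VAF is the dominant clone; it carries the copula-linked
# growth slope in the longitudinal generator, and subordinate clones' slopes
# are truncated so that no sibling overtakes it within the study window
# (dominance is stable by construction, so the generator's rank-correlation
# contract refers to an unambiguous clone). When screen_coverage is set, each
# carrier's clone set is conditioned on at least one clone being detectable
# by the dual-replicate rule at that coverage, emulating recruitment of known
# carriers from a cross-sectional screen.
draw_clones <- function(cfg, carrier_ids, z_slope = NULL,
                        screen_coverage = NULL, window_years = 0) {
  n <- length(carrier_ids)
  if (n == 0)
    return(data.frame(individual_id = character(), gene = character(),
                      hgvs_p = character(), vaf0_pct = numeric(),
                      log_slope_per_year = numeric(), dominant = logical()))
  multi <- runif(n) < cfg$multi_clone_prob
  # among multi-clone carriers the count of clones follows the observed
  # 2/3/4-clone split ~ 34:7:3
  n_clones <- ifelse(multi, sample(c(2L, 3L, 4L), n, replace = TRUE,
                                   prob = c(34, 7, 3) / 44), 1L)
  panel <- chdm_panel()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_clones[i]
    idx <- sample.int(nrow(panel), k, prob = panel$weight)
    repeat {
      vaf0 <- exp(rnorm(k, cfg$baseline_vaf_log_mean, cfg$baseline_vaf_log_sd))
      vaf0 <- pmin(pmax(vaf0, 0.01), 50)
      if (is.null(screen_coverage)) break
      p_det <- screen_detect_prob(vaf0, screen_coverage,
                                  cfg$screen_min_alt_reads)
      if (runif(1) < 1 - prod(1 - p_det)) break
    }
    vaf0 <- sort(vaf0, decreasing = TRUE)
    slope <- numeric(k)
    slope[1] <- if (!is.null(z_slope))
      cfg$growth_log_mean + cfg$growth_log_sd * z_slope[i] else
        rnorm(1, cfg$growth_log_mean, cfg$growth_log_sd)
    if (k > 1) {
      upper <- if (window_years > 0)
        slope[1] + log(vaf0[1] / vaf0[-1]) / window_years else Inf
      slope[-1] <- rnorm_below(k - 1, cfg$growth_log_mean,
                               cfg$growth_log_sd, upper)
    }
    rows[[i]] <- data.frame(individual_id = carrier_ids[i],
                            gene = panel$gene[idx],
                            hgvs_p = panel$hgvs_p[idx],
                            vaf0_pct = vaf0,
                            log_slope_per_year = slope,
                            dominant = seq_len(k) == 1L,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# replicate read counts for given true VAFs (percent)
draw_reads <- function(true_vaf_pct, coverage_mean, noise) {
  n <- length(true_vaf_pct)
  if (noise) {
    tot1 <- pmax(1L, rpois(n, coverage_mean))
    tot2 <- pmax(1L, rpois(n, coverage_mean))
    alt1 <- rbinom(n, tot1, true_vaf_pct / 100)
    alt2 <- rbinom(n, tot2, true_vaf_pct / 100)
  } else {
    tot1 <- tot2 <- rep(round(coverage_mean), n)
    alt1 <- round(tot1 * true_vaf_pct / 100)
    alt2 <- round(tot2 * true_vaf_pct / 100)
  }
  data.frame(alt_reads_rep1 = alt1, total_reads_rep1 = tot1,
             alt_reads_rep2 = alt2, total_reads_rep2 = tot2)
}

#' Generate a synthetic longitudinal CHDM cohort
#'
#' Simulates a cohort of known CHDM carriers followed over repeated
#' examinations. Every individual carries at least one clone whose true VAF
#' follows geometric growth, `min(50, vaf0 * exp(log_slope * t))` percent at
#' `t` years after baseline. Each sampled visit yields two technical-replicate
#' read-count pairs (totals Poisson around `coverage_mean`, alt reads binomial
#' in the true VAF) and a clinical-panel record. HDL-C is tied to the
#' dominant clone's true log-slope through a Gaussian copula so that their
#' rank correlation equals `hdl_growth_spearman_target` in expectation.
#'
#' @param config a [cohort_config()].
#' @return list of class `ch_cohort` with data.frames
#'   `observations` (`individual_id`, `gene`, `hgvs_p`, `timepoint_years`,
#'   `age_years`, `alt_reads_rep1`, `total_reads_rep1`, `alt_reads_rep2`,
#'   `total_reads_rep2`), `clinical` (one row per individual and visit) and
#'   `truth` (planted clones: `vaf0_pct`, `log_slope_per_year`, `dominant`).
#' @export
#' @examples
#' cohort <- generate_longitudinal_cohort(cohort_config(n_individuals = 5))
#' table(cohort$observations$timepoint_years)
generate_longitudinal_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  ids <- sprintf("S%04d", seq_len(n))
  age0 <- runif(n, config$baseline_age_range[1], config$baseline_age_range[2])
  sex <- ifelse(runif(n) < 0.701, "F", "M")
  smoker <- runif(n) < 0.25
  diabetes_med <- runif(n) < 0.15
  bp_med <- runif(n) < 0.30

  # copula: z_slope drives the dominant clone's growth; z_hdl its HDL partner
  r <- copula_pearson(config$hdl_growth_spearman_target)
  z_slope <- rnorm(n)
  z_hdl <- r * z_slope + sqrt(1 - r^2) * rnorm(n)

  truth <- draw_clones(config, ids, z_slope = z_slope,
                       screen_coverage = config$screen_coverage_mean,
                       window_years = max(config$timepoints))
  present <- draw_presence(config)

  owner <- rep(seq_len(n), times = rowSums(present))
  tp_by_visit <- unlist(apply(present, 1, function(p) config$timepoints[p],
                              simplify = FALSE))
  ages_by_visit <- age0[owner] + tp_by_visit
  clinical <- draw_clinical(config, ids, ages_by_visit, tp_by_visit, owner,
                            z_hdl, sex, smoker, diabetes_med, bp_med)

  # observation rows: each clone assayed at each of its owner's visits
  visit_idx <- split(seq_along(owner), ids[owner])
  obs_list <- lapply(seq_len(nrow(truth)), function(ci) {
    vi <- visit_idx[[truth$individual_id[ci]]]
    tp <- tp_by_visit[vi]
    true_vaf <- pmin(50, truth$vaf0_pct[ci] *
                       exp(truth$log_slope_per_year[ci] * tp))
    cbind(data.frame(individual_id = truth$individual_id[ci],
                     gene = truth$gene[ci], hgvs_p = truth$hgvs_p[ci],
                     timepoint_years = tp, age_years = ages_by_visit[vi],
                     true_vaf_pct = true_vaf, stringsAsFactors = FALSE))
  })
  obs <- do.call(rbind, obs_list)
  obs <- obs[order(obs$individual_id, obs$gene, obs$hgvs_p,
                   obs$timepoint_years), , drop = FALSE]
  reads <- draw_reads(obs$true_vaf_pct, config$coverage_mean, config$noise)
  obs <- cbind(obs[, c("individual_id", "gene", "hgvs_p", "timepoint_years",
                       "age_years")], reads)
  rownames(obs) <- NULL
  clinical <- clinical[order(clinical$individual_id,
                             clinical$timepoint_years), , drop = FALSE]
  rownames(clinical) <- NULL
  structure(list(observations = obs, clinical = clinical, truth = truth,
                 config = config),
            class = "ch_cohort")
}

#' Generate a synthetic single-timepoint CHDM cohort
#'
#' Simulates a cross-sectional cohort assayed once. Carrier status follows a
#' logistic model in age whose intercept is calibrated so the prevalence at
#' the cohort mean age equals `carrier_prevalence_at_mean_age`; baseline VAFs
#' are log-normal clamped to `[0.01, 50]` percent; read counts are drawn as in
#' [generate_longitudinal_cohort()]. Non-carriers contribute no observation
#' rows (their assay found nothing) but do appear in the clinical table.
#'
#' @param config a [cohort_config()]; `timepoints`/`dropout_pattern` are not
#'   used beyond validation.
#' @return list of class `ch_cohort` with `observations`, `clinical` and
#'   `truth` (planted clones of carriers).
#' @export
#' @examples
#' cfg <- cohort_config(n_individuals = 200, coverage_mean = 2840, seed = 3)
#' cohort <- generate_single_timepoint_cohort(cfg)
#' mean(table(factor(cohort$truth$individual_id,
#'                   levels = cohort$clinical$individual_id)) > 0)
generate_single_timepoint_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_individuals
  ids <- sprintf("S%04d", seq_len(n))
  age <- runif(n, config$baseline_age_range[1], config$baseline_age_range[2])
  sex <- ifelse(runif(n) < 0.701, "F", "M")
  smoker <- runif(n) < 0.25
  diabetes_med <- runif(n) < 0.15
  bp_med <- runif(n) < 0.30

  p <- plogis(qlogis(config$carrier_prevalence_at_mean_age) +
                config$prevalence_age_log_odds * (age - mean(age)))
  carrier <- runif(n) < p

  z_hdl <- rnorm(n) # no growth information in a single timepoint
  clinical <- draw_clinical(config, ids, age, rep(0, n), seq_len(n),
                            z_hdl, sex, smoker, diabetes_med, bp_med)

  truth <- draw_clones(config, ids[carrier])
  if (nrow(truth) > 0) {
    age_of <- setNames(age, ids)
    # clones of older carriers have grown longer: log-linear age effect on
    # clone size, centred at the cohort mean age
    truth$vaf0_pct <- pmin(pmax(
      truth$vaf0_pct * exp(config$vaf_age_log_slope *
                             (age_of[truth$individual_id] - mean(age))),
      0.01), 50)
    reads <- draw_reads(truth$vaf0_pct, config$coverage_mean, config$noise)
    obs <- cbind(data.frame(individual_id = truth$individual_id,
                            gene = truth$gene, hgvs_p = truth$hgvs_p,
                            timepoint_years = 0,
                            age_years = unname(age_of[truth$individual_id]),
                            stringsAsFactors = FALSE),
                 reads)
  } else {
    obs <- cbind(data.frame(individual_id = character(), gene = character(),
                            hgvs_p = character(), timepoint_years = numeric(),
                            age_years = numeric()),
                 draw_reads(numeric(), config$coverage_mean, config$noise))
  }
  obs <- obs[order(obs$individual_id, obs$gene, obs$hgvs_p), , drop = FALSE]
  rownames(obs) <- NULL
  structure(list(observations = obs, clinical = clinical, truth = truth,
                 config = config),
            class = "ch_cohort")
}

#' @export
print.ch_cohort <- function(x, ...) {
  cat("Synthetic CHDM cohort:",
      length(unique(x$clinical$individual_id)), "individuals,",
      nrow(x$truth), "planted clones,",
      nrow(x$observations), "observation rows\n")
  invisible(x)
}
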
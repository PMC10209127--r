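test_that("slope/rate conversion is exact and invertible", {
  expect_equal(rate_from_slope(0.059), 100 * (exp(0.059) - 1))
  expect_equal(slope_from_rate(rate_from_slope(0.0677)), 0.0677)
  expect_equal(rate_from_slope(0), 0)
  # rate is strictly increasing in slope and bounded below by -100
  s <- seq(-0.5, 0.5, by = 0.01)
  expect_true(all(diff(rate_from_slope(s)) > 0))
  expect_true(all(rate_from_slope(s) > -100))
})

test_that("log clone size vs age regression recovers exact and null effects", {
  age <- seq(40, 70, length.out = 60)
  noiseless <- data.frame(age_years = age,
                          vaf_pct = exp(0.059 * age - 4))
  fit <- suppressWarnings(fit_logvaf_vs_age(noiseless)) # exact fit by design
  expect_equal(fit$logvaf_age_coef, 0.059, tolerance = 1e-10)
  expect_equal(round(fit$pct_per_year, 2), 6.08) # "6% larger per year"
  set.seed(61)
  null <- data.frame(age_years = runif(1000, 40, 70),
                     vaf_pct = exp(rnorm(1000, 0, 1)))
  f0 <- fit_logvaf_vs_age(null)
  expect_lt(abs(f0$logvaf_age_coef), 3 * f0$se)
  expect_error(fit_logvaf_vs_age(noiseless[1:2, ]), "insufficient")
  expect_error(fit_logvaf_vs_age(data.frame(age_years = 1:5,
                                            vaf_pct = c(1, 2, 0, 1, 2))),
               "positive")
})

test_that("logistic prevalence model recovers a planted age slope", {
  set.seed(62)
  n <- 10000
  age <- runif(n, 37, 70)
  p <- plogis(qlogis(0.2) + 0.05 * (age - mean(age)))
  d <- data.frame(age_years = age, carrier = runif(n) < p)
  fit <- fit_carrier_vs_age(d)
  expect_lt(abs(fit$log_odds_per_year - 0.05), 2 * fit$se)
  # null slope
  d0 <- data.frame(age_years = age, carrier = runif(n) < 0.2)
  f0 <- fit_carrier_vs_age(d0)
  expect_lt(abs(f0$log_odds_per_year), 3 * f0$se)
})

test_that("degenerate carrier inputs raise informative errors", {
  expect_error(fit_carrier_vs_age(data.frame(age_years = 1:10,
                                             carrier = TRUE)),
               "does not vary")
  sep <- data.frame(age_years = c(40:49, 60:69),
                    carrier = rep(c(FALSE, TRUE), each = 10))
  expect_error(fit_carrier_vs_age(sep), "separation")
})

test_that("a single noiseless exponential clone is interpolated exactly", {
  b <- 0.084
  pts <- data.frame(individual_id = "A", age_years = c(45, 47, 55, 60, 65),
                    vaf_pct = 1.3 * exp(b * (c(45, 47, 55, 60, 65) - 45)))
  fit <- fit_mixed_growth(pts)
  expect_equal(fit$estimates$slope_log_per_year, b, tolerance = 1e-8)
  expect_equal(fit$estimates$rate_pct_per_year, rate_from_slope(b),
               tolerance = 1e-6)
})

test_that("mixed-model slopes match per-individual OLS in the dense,
           near-noiseless, high-variance limit", {
  set.seed(63)
  n_id <- 12
  slopes <- rnorm(n_id, 0.05, 0.5) # large between-individual variance
  pts <- do.call(rbind, lapply(seq_len(n_id), function(i) {
    age <- seq(40, 60, length.out = 50)
    data.frame(individual_id = sprintf("I%02d", i), age_years = age,
               vaf_pct = exp(log(2) + slopes[i] * (age - 50) +
                               rnorm(50, 0, 1e-3)))
  }))
  fit <- fit_mixed_growth(pts)
  ols <- sapply(split(pts, pts$individual_id),
                function(d) unname(coef(lm(log(vaf_pct) ~ age_years, d))[2]))
  expect_equal(fit$estimates$slope_log_per_year,
               unname(ols[fit$estimates$individual_id]), tolerance = 1e-6)
})

test_that("partial pooling keeps individual slopes between OLS and the
           fixed effect", {
  set.seed(64)
  n_id <- 25
  slopes <- rnorm(n_id, 0.07, 0.05)
  pts <- do.call(rbind, lapply(seq_len(n_id), function(i) {
    age <- c(50, 52, 60, 65, 70)
    data.frame(individual_id = sprintf("I%02d", i), age_years = age,
               vaf_pct = exp(log(1.5) + slopes[i] * (age - 50) +
                               rnorm(5, 0, 0.1)))
  }))
  fit <- suppressMessages(fit_mixed_growth(pts))
  ols <- sapply(split(pts, pts$individual_id),
                function(d) unname(coef(lm(log(vaf_pct) ~ age_years, d))[2]))
  lo <- pmin(ols[fit$estimates$individual_id], fit$fixed_slope)
  hi <- pmax(ols[fit$estimates$individual_id], fit$fixed_slope)
  span <- hi - lo
  expect_true(all(fit$estimates$slope_log_per_year >= lo - 0.05 * span - 1e-8))
  expect_true(all(fit$estimates$slope_log_per_year <= hi + 0.05 * span + 1e-8))
})

test_that("REML recovers the fixed slope with nominal interval coverage", {
  set.seed(65)
  true_b <- log(1.07)
  n_sims <- 120
  out <- replicate(n_sims, {
    n_id <- 20
    b_i <- rnorm(n_id, true_b, 0.06)
    pts <- do.call(rbind, lapply(seq_len(n_id), function(i) {
      age <- 45 + c(0, 2, 10, 15, 20) + runif(1, 0, 10)
      data.frame(individual_id = sprintf("I%02d", i), age_years = age,
                 vaf_pct = exp(rnorm(1, 0, 1) + b_i[i] * (age - 50) +
                                 rnorm(5, 0, 0.12)))
    }))
    fit <- suppressMessages(fit_mixed_growth(pts))
    se <- sqrt(vcov(fit$model)[2, 2])
    c(est = fit$fixed_slope, cover = abs(fit$fixed_slope - true_b) < 1.96 * se)
  })
  est <- out["est", ]
  mc_err <- 3 * sd(est) / sqrt(n_sims)
  expect_lt(abs(mean(est) - true_b), mc_err)
  expect_gte(mean(out["cover", ]), 0.90)
  expect_lte(mean(out["cover", ]), 0.99)
})

test_that("raw response scale fits additive slopes without rate conversion", {
  pts <- data.frame(individual_id = rep(c("A", "B"), each = 4),
                    age_years = rep(c(50, 55, 60, 65), 2),
                    vaf_pct = c(1, 2, 3, 4, 2, 2.5, 3, 3.5))
  fit <- suppressMessages(fit_mixed_growth(pts, response_scale = "raw"))
  expect_true(is.na(fit$fixed_rate))
  expect_equal(fit$fixed_slope, mean(c(0.2, 0.1)), tolerance = 0.05)
})

test_that("individuals with fewer than two points are dropped with warning", {
  pts <- data.frame(individual_id = c("A", "A", "A", "B"),
                    age_years = c(50, 55, 60, 50),
                    vaf_pct = c(1, 2, 3, 1))
  expect_warning(fit <- fit_mixed_growth(pts), "fewer than 2")
  expect_equal(fit$estimates$individual_id, "A")
})
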
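test_that("derived clinical indices follow the standard formulae", {
  rec <- data.frame(total_chol_mmol_l = 5.48, triglycerides_mmol_l = 1.95,
                    hdl_c_mmol_l = 1.38, insulin_mu_l = 17.3,
                    glucose_mmol_l = 5.94, sbp_mmhg = 139, dbp_mmhg = 89)
  d <- derive_clinical(rec)
  expect_equal(round(d$ldl_c_mmol_l, 2), 3.21) # Friedewald on group means
  expect_equal(d$homa_ir, 17.3 * 5.94 / 22.5, tolerance = 1e-12)
  expect_equal(round(d$homa_ir, 3), 4.567)
  expect_equal(d$non_hdl_c_mmol_l, 5.48 - 1.38)
  expect_false(d$hypertension) # both just below the cut-offs, no medication
  expect_false(d$diabetes)
  # boundary: either pressure at the cut-off, or medication, flips the flag
  expect_true(derive_clinical(transform(rec, sbp_mmhg = 140))$hypertension)
  expect_true(derive_clinical(transform(rec, dbp_mmhg = 90))$hypertension)
  rec$bp_med <- TRUE
  expect_true(derive_clinical(rec)$hypertension)
  # Friedewald is invalid above 4.5 mmol/L triglycerides
  expect_true(is.na(derive_clinical(
    transform(rec, triglycerides_mmol_l = 4.6))$ldl_c_mmol_l))
})

test_that("averaging spans the first three follow-up visits, skipping gaps", {
  cl <- data.frame(individual_id = c("A", "A", "A", "A", "B", "B", "C"),
                   timepoint_years = c(0, 2, 10, 15, 2, 15, 0),
                   hdl_c_mmol_l = c(9, 1.2, 1.4, 1.6, 1.2, 1.6, 1.0))
  expect_warning(m <- average_first_three(cl, covariates = "hdl_c_mmol_l"),
                 "excluded")
  expect_equal(m$hdl_c_mmol_l[m$individual_id == "A"], 1.4) # baseline ignored
  expect_equal(m$hdl_c_mmol_l[m$individual_id == "B"], 1.4) # missing skipped
  expect_false("C" %in% m$individual_id) # baseline-only individual dropped
  # a constant covariate averages to the constant under any missingness
  cl$glucose_mmol_l <- 5.5
  expect_warning(m2 <- average_first_three(cl, covariates = "glucose_mmol_l"))
  expect_true(all(m2$glucose_mmol_l == 5.5))
})

test_that("Spearman correlation respects rank invariance and exact small-n p", {
  rates <- data.frame(individual_id = letters[1:5],
                      rate_pct_per_year = c(1, 2, 3, 4, 5))
  cm <- data.frame(individual_id = letters[1:5],
                   up = exp(c(1, 2, 3, 4, 5)), # monotone transform
                   down = c(5, 4, 3, 2, 1))
  res <- correlate_growth(rates, cm, covariates = c("up", "down"), m = 2)
  expect_equal(res$spearman_r[res$covariate == "up"], 1)
  expect_equal(res$spearman_r[res$covariate == "down"], -1)
  # exact permutation null: perfect inversion of 5 ranks has p = 2/120
  expect_equal(res$p_raw[res$covariate == "down"], 2 / 120, tolerance = 1e-12)
  expect_equal(res$p_bonferroni, pmin(1, 2 * res$p_raw))
})

test_that("Spearman p-values agree with exhaustive permutation for n <= 7", {
  perm_oracle <- function(x, y) {
    n <- length(x)
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    }
    all_rho <- vapply(perms(seq_len(n)),
                      function(p) cor(x, y[p], method = "spearman"), 0)
    obs <- cor(x, y, method = "spearman")
    min(1, 2 * min(mean(all_rho <= obs + 1e-12),
                   mean(all_rho >= obs - 1e-12)))
  }
  set.seed(71)
  for (n in 5:7) {
    for (rep in 1:3) {
      x <- sample(100, n); y <- sample(100, n) # tie-free
      got <- chtrace:::spearman_test(x, y)
      expect_equal(got$p, perm_oracle(x, y), tolerance = 1e-8)
      expect_equal(got$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    }
  }
})

test_that("Bonferroni adjustment is monotone and correctly capped", {
  set.seed(72)
  rates <- data.frame(individual_id = sprintf("i%02d", 1:30),
                      rate_pct_per_year = rnorm(30))
  cm <- data.frame(individual_id = rates$individual_id,
                   a = rnorm(30), b = rates$rate_pct_per_year + rnorm(30, 0, 0.1))
  res <- correlate_growth(rates, cm, covariates = c("a", "b"), m = 10)
  expect_equal(res$p_bonferroni, pmin(1, 10 * res$p_raw))
  o <- order(res$p_raw)
  expect_true(all(diff(res$p_bonferroni[o]) >= 0))
})

test_that("Spearman is antisymmetric and NA on zero variance", {
  set.seed(73)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(chtrace:::spearman_test(x, -y)$rho,
               -chtrace:::spearman_test(x, y)$rho)
  expect_true(is.na(chtrace:::spearman_test(x, rep(1, 20))$rho))
  rates <- data.frame(individual_id = letters[1:6], rate_pct_per_year = 1:6)
  cm <- data.frame(individual_id = letters[1:6], flat = rep(2, 6))
  res <- correlate_growth(rates, cm, covariates = "flat", m = 1)
  expect_true(is.na(res$spearman_r))
  # too few paired observations is an error
  expect_error(correlate_growth(rates[1:4, ], cm, covariates = "flat", m = 1),
               "fewer than")
})

test_that("secondary covariates are reported without adjustment", {
  set.seed(74)
  rates <- data.frame(individual_id = sprintf("i%02d", 1:20),
                      rate_pct_per_year = rnorm(20))
  cm <- data.frame(individual_id = rates$individual_id,
                   triglycerides_mmol_l = rnorm(20),
                   non_hdl_c_mmol_l = rnorm(20))
  res <- correlate_growth(rates, cm, covariates = secondary_covariates(),
                          family = "secondary", m = NA)
  expect_true(all(is.na(res$p_bonferroni)))
  expect_true(all(res$family == "secondary"))
})
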
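test_that("trajectory assembly applies the event/traceable partition rules", {
  calls <- stack_calls(
    make_calls("A", vafs = c(1.0, 1.3, 1.8, 2.4, 2.9),
               detected_at = c(0, 2, 10, 15, 20)),
    make_calls("B", detected_at = c(0, 10), vafs = c(0.5, 0.9)),
    make_calls("C", detected_at = 20, vafs = 2.5))
  tr <- build_trajectories(calls)
  expect_equal(nrow(tr), 3)
  a <- tr[tr$individual_id == "A", ]
  expect_equal(a$category, "growing") # delta 1.9 >= 0.5
  expect_true(a$reached_chip)
  expect_false(a$late_appearing)
  b <- tr[tr$individual_id == "B", ]
  expect_equal(b$category, "event") # two detections only
  expect_true(b$disappeared) # last detection before final sampled visit
  cc <- tr[tr$individual_id == "C", ]
  expect_equal(cc$category, "event")
  expect_true(cc$late_appearing) # large clone appearing at last visit
  expect_false(cc$disappeared)
  # partition: every detected CHDM belongs to exactly one trajectory
  expect_equal(sum(tr$category == "event") + sum(tr$category != "event"),
               nrow(tr))
})

test_that("0.5-percentage-point rule classifies traceable trajectories", {
  expect_equal(classify_trajectory(1.0, 1.3, 3), "static")   # delta 0.3
  expect_equal(classify_trajectory(1.0, 1.5, 3), "growing")  # boundary 0.5
  expect_equal(classify_trajectory(3.0, 1.2, 3), "shrinking")
  expect_equal(classify_trajectory(1.5, 1.0, 4), "shrinking") # boundary -0.5
  expect_error(classify_trajectory(1, 2, 2), "traceable")
})

test_that("shrinking below CHIP level is captured by the flags", {
  calls <- make_calls("D", detected_at = c(0, 10, 20), vafs = c(3.0, 2.1, 1.2),
                      sampled = c(0, 10, 20))
  tr <- build_trajectories(calls)
  expect_equal(tr$category, "shrinking")
  expect_true(tr$reached_chip)
  expect_lt(tr$vaf_final, 2)
})

test_that("duplicate mutation-timepoint rows are rejected", {
  calls <- rbind(make_calls("A", vafs = c(1, 1, 1, 1, 1)),
                 make_calls("A", vafs = c(1, 1, 1, 1, 1)))
  expect_error(build_trajectories(calls), "duplicate")
})

test_that("classification matches a straight-line oracle on random cases", {
  # independent re-implementation of the three predicates
  oracle <- function(n_det, vafs) {
    if (n_det <= 2) return("event")
    d <- vafs[n_det] - vafs[1]
    if (d >= 0.5) return("growing")
    if (d <= -0.5) return("shrinking")
    "static"
  }
  set.seed(515)
  for (i in 1:1000) {
    n_det <- sample(1:5, 1)
    tps <- sort(sample(c(0, 2, 10, 15, 20), n_det))
    vafs <- round(runif(n_det, 0.01, 5), 3)
    calls <- make_calls("X", detected_at = tps, vafs = vafs)
    tr <- build_trajectories(calls)
    expect_identical(tr$category, oracle(n_det, vafs))
  }
})

test_that("classification ignores intermediate-point perturbations", {
  set.seed(33)
  for (i in 1:50) {
    vafs <- runif(5, 0.1, 4)
    calls1 <- make_calls("A", vafs = vafs)
    vafs2 <- vafs
    vafs2[2:4] <- runif(3, 0.1, 4) # first/final fixed
    calls2 <- make_calls("A", vafs = vafs2)
    expect_identical(build_trajectories(calls1)$category,
                     build_trajectories(calls2)$category)
  }
})

test_that("dominant selection takes the max-VAF trajectory, stably", {
  calls <- stack_calls(
    make_calls("A", gene = "DNMT3A", hgvs = "p.R882H",
               vafs = c(1, 2, 3, 4, 4.1)),
    make_calls("A", gene = "TET2", hgvs = "p.Q1523*",
               vafs = c(0.5, 1, 1.5, 1.8, 2.0)))
  tr <- build_trajectories(calls)
  dom <- select_dominant(tr)
  expect_equal(dom$gene, "DNMT3A")
  expect_false(dom$excluded)
  # stability under input reordering
  tr2 <- build_trajectories(calls[rev(seq_len(nrow(calls))), ])
  expect_equal(select_dominant(tr2)$gene, "DNMT3A")

  # tie on max VAF -> larger final VAF; then lexicographic mutation id
  tie <- stack_calls(
    make_calls("B", gene = "TET2", hgvs = "p.R544*",
               detected_at = c(0, 10, 20), vafs = c(2.0, 1.0, 0.8)),
    make_calls("B", gene = "ASXL1", hgvs = "p.G646fs",
               detected_at = c(0, 10, 20), vafs = c(0.9, 1.0, 2.0)))
  domb <- select_dominant(build_trajectories(tie))
  expect_equal(domb$gene, "ASXL1") # same max 2.0, larger final VAF
})

test_that("shrinking-dominant individuals are excluded unless sensitivity", {
  calls <- make_calls("E", detected_at = c(0, 10, 20), vafs = c(3, 2, 1),
                      sampled = c(0, 10, 20))
  tr <- build_trajectories(calls)
  expect_true(select_dominant(tr)$excluded)
  expect_false(select_dominant(tr, include_shrinking = TRUE)$excluded)
  # an individual with only events never enters the growth analysis
  ev <- make_calls("F", detected_at = c(0, 10), vafs = c(1, 1.2))
  expect_equal(nrow(select_dominant(build_trajectories(ev))), 0)
})

test_that("event + traceable counts partition a synthetic cohort's CHDMs", {
  co <- generate_longitudinal_cohort(small_long_config(seed = 77))
  tr <- build_trajectories(call_observations(co$observations))
  expect_equal(sum(tr$category == "event") +
                 sum(tr$category %in% c("growing", "static", "shrinking")),
               nrow(tr))
  expect_true(all(tr$n_detected[tr$category == "event"] <= 2))
  expect_true(all(tr$n_detected[tr$category != "event"] >= 3))
  expect_true(all(tr$late_appearing[tr$late_appearing] ==
                    (tr$category[tr$late_appearing] == "event")))
})
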
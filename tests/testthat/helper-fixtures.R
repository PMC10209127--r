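# Shared fixtures, built in code.

# Small longitudinal config for fast end-to-end tests
small_long_config <- function(seed = 1, ...) {
  cohort_config(n_individuals = 20,
                dropout_pattern = c(1, 0.95, 1, 0.95, 0.6),
                seed = seed, ...)
}

# Build a called-observations table from compact per-mutation descriptions.
# sampled: timepoints at which the individual was assayed; detected_at /
# vafs: where the mutation was called and with what VAF. age0 sets baseline
# age so age_years = age0 + timepoint.
make_calls <- function(individual = "A", gene = "DNMT3A", hgvs = "p.R882H",
                       sampled = c(0, 2, 10, 15, 20),
                       detected_at = sampled, vafs = NULL, age0 = 50) {
  stopifnot(length(detected_at) == length(vafs) || is.null(vafs))
  det <- sampled %in% detected_at
  vaf <- rep(NA_real_, length(sampled))
  if (!is.null(vafs)) vaf[det] <- vafs
  data.frame(individual_id = individual, gene = gene, hgvs_p = hgvs,
             timepoint_years = sampled, age_years = age0 + sampled,
             alt_reads_rep1 = 10L, total_reads_rep1 = 1000L,
             alt_reads_rep2 = 10L, total_reads_rep2 = 1000L,
             detected = det, vaf_pct = vaf,
             stringsAsFactors = FALSE)
}

# Stack several make_calls() tables
stack_calls <- function(...) do.call(rbind, list(...))
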
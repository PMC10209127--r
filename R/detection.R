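# Replicate-aware CHDM calling from dual technical-replicate read counts.
# Stand-in for an smMIP consensus pipeline: a mutation is called only when
# both independent replicates support it.

#' Call CHDMs from replicate read-count pairs
#'
#' Applies the dual-replicate detection rule to an observation table: a
#' mutation is `detected` at a sample if and only if the alt-read count
#' reaches `min_alt_reads` in *both* technical replicates and the mean
#' replicate VAF is at least `vaf_floor_pct`. The reported VAF is the
#' unweighted arithmetic mean of the two replicate VAFs, in percent, and is
#' `NA` for undetected rows.
#'
#' @param observations data.frame with integer columns `alt_reads_rep1`,
#'   `total_reads_rep1`, `alt_reads_rep2`, `total_reads_rep2` (the schema
#'   written by the cohort generators).
#' @param min_alt_reads minimum alt reads required in each replicate.
#' @param vaf_floor_pct minimum mean VAF (percent) for a call; the assay's
#'   validated floor (default 0.01%).
#' @return the input with logical `detected` and numeric `vaf_pct` appended.
#' @export
#' @examples
#' obs <- data.frame(alt_reads_rep1 = c(5, 3, 0), total_reads_rep1 = 2840,
#'                   alt_reads_rep2 = c(6, 2, 0), total_reads_rep2 = 2840)
#' call_observations(obs)[, c("detected", "vaf_pct")]
call_observations <- function(observations, min_alt_reads = 3,
                              vaf_floor_pct = 0.01) {
  req <- c("alt_reads_rep1", "total_reads_rep1",
           "alt_reads_rep2", "total_reads_rep2")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols))
    stop("observations lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  a1 <- observations$alt_reads_rep1; t1 <- observations$total_reads_rep1
  a2 <- observations$alt_reads_rep2; t2 <- observations$total_reads_rep2
  if (any(a1 < 0 | a2 < 0, na.rm = TRUE))
    stop("negative alt read counts", call. = FALSE)
  if (any(t1 <= 0 | t2 <= 0, na.rm = TRUE))
    stop("replicate totals must be positive", call. = FALSE)
  if (any(a1 > t1 | a2 > t2, na.rm = TRUE))
    stop("alt reads exceed total reads: malformed input", call. = FALSE)
  if (min_alt_reads < 1 || vaf_floor_pct < 0)
    stop("min_alt_reads must be >= 1 and vaf_floor_pct >= 0", call. = FALSE)
  vaf <- 100 * (a1 / t1 + a2 / t2) / 2
  detected <- a1 >= min_alt_reads & a2 >= min_alt_reads & vaf >= vaf_floor_pct
  observations$detected <- detected
  observations$vaf_pct <- ifelse(detected, vaf, NA_real_)
  observations
}

#' Flag CHIP-sized clones
#'
#' CHIP (clonal haematopoiesis of indeterminate potential) is conventionally
#' defined by a VAF of at least 2% in peripheral blood.
#'
#' @param vaf_pct numeric VAF in percent; `NA` propagates.
#' @param threshold_pct CHIP cut-off, default 2.
#' @return logical vector, `TRUE` where `vaf_pct >= threshold_pct`.
#' @export
#' @examples
#' annotate_chip(c(1.99, 2, 31.15))
annotate_chip <- function(vaf_pct, threshold_pct = 2) {
  if (any(vaf_pct < 0, na.rm = TRUE))
    stop("VAF cannot be negative", call. = FALSE)
  vaf_pct >= threshold_pct
}
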
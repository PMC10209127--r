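# Assembly and classification of per-individual CHDM trajectories.
#
# A mutation detected at >= 3 timepoints in one individual is a traceable
# trajectory; 1-2 detections make it an event. Traceable trajectories are
# growing / shrinking / static according to whether the VAF at the final
# detected timepoint is at least 0.5 percentage points above / below / within
# 0.5 pp of the VAF at the first detected timepoint. First/final refer to
# *detected* timepoints: VAF is undefined where the clone was not called, and
# undetected visits inside a trajectory are gaps, not zeros.

#' Classify traceable trajectories
#'
#' @param vaf_first,vaf_final VAF (percent) at the first and final timepoint
#'   at which the mutation was detected.
#' @param n_detected number of timepoints with a detection; classification is
#'   only defined for traceable trajectories (`n_detected >= min_timepoints`)
#'   and calling this on an event is an error.
#' @param delta_pp classification threshold in VAF percentage points (0.5).
#' @param min_timepoints detections required for a traceable trajectory (3).
#' @return character vector in `c("growing", "shrinking", "static")`.
#' @export
#' @examples
#' classify_trajectory(1.0, 1.5, 3)   # boundary: +0.5 pp counts as growing
classify_trajectory <- function(vaf_first, vaf_final, n_detected,
                                delta_pp = 0.5, min_timepoints = 3) {
  if (any(n_detected < min_timepoints))
    stop("classification applies to traceable trajectories only (>= ",
         min_timepoints, " detections)", call. = FALSE)
  delta <- vaf_final - vaf_first
  ifelse(delta >= delta_pp, "growing",
         ifelse(delta <= -delta_pp, "shrinking", "static"))
}

#' Build per-individual CHDM trajectories from called observations
#'
#' Groups detected observations by (individual, gene, protein change), orders
#' each group by age, and classifies it. Every detected CHDM belongs to
#' exactly one trajectory. The full called table (including undetected rows)
#' should be supplied so each individual's sampled timepoints are known:
#' these determine the `late_appearing` annotation (an event whose detection
#' is at the individual's final sampled timepoint with VAF at or above the
#' CHIP threshold — the abrupt appearance of a large clone) and the
#' `disappeared` flag (no detection at the individual's final sampled
#' timepoint despite earlier detection).
#'
#' @param calls data.frame from [call_observations()] with columns
#'   `individual_id`, `gene`, `hgvs_p`, `timepoint_years`, `age_years`,
#'   `detected`, `vaf_pct`.
#' @param delta_pp growth/shrink threshold in VAF percentage points.
#' @param min_timepoints detections required for a traceable trajectory.
#' @param chip_threshold_pct CHIP VAF cut-off used for `reached_chip` and
#'   `late_appearing`.
#' @return data.frame of class `ch_trajectories`: one row per trajectory with
#'   `n_detected`, `category` (`event`/`growing`/`static`/`shrinking`),
#'   `late_appearing`, `reached_chip`, `disappeared`, `vaf_first`,
#'   `vaf_final`, `vaf_max`.
#' @export
build_trajectories <- function(calls, delta_pp = 0.5, min_timepoints = 3,
                               chip_threshold_pct = 2) {
  req <- c("individual_id", "gene", "hgvs_p", "timepoint_years", "age_years",
           "detected", "vaf_pct")
  missing_cols <- setdiff(req, names(calls))
  if (length(missing_cols))
    stop("calls lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  key <- paste(calls$individual_id, calls$gene, calls$hgvs_p,
               calls$timepoint_years, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (individual, mutation, timepoint) rows in input",
         call. = FALSE)
  # each individual's final sampled timepoint, from all assayed rows
  last_sampled <- tapply(calls$timepoint_years, calls$individual_id, max)

  det <- calls[calls$detected %in% TRUE, , drop = FALSE]
  if (nrow(det) == 0)
    return(structure(data.frame(individual_id = character(),
                                gene = character(), hgvs_p = character(),
                                n_detected = integer(), category = character(),
                                late_appearing = logical(),
                                reached_chip = logical(),
                                disappeared = logical(),
                                vaf_first = numeric(), vaf_final = numeric(),
                                vaf_max = numeric()),
                     class = c("ch_trajectories", "data.frame")))
  grp <- paste(det$individual_id, det$gene, det$hgvs_p, sep = "\r")
  pieces <- split(det, grp)
  rows <- lapply(pieces, function(d) {
    d <- d[order(d$age_years), , drop = FALSE]
    n <- nrow(d)
    first_vaf <- d$vaf_pct[1]
    final_vaf <- d$vaf_pct[n]
    final_tp <- d$timepoint_years[n]
    ind_last <- unname(last_sampled[d$individual_id[1]])
    is_event <- n < min_timepoints
    data.frame(
      individual_id = d$individual_id[1], gene = d$gene[1],
      hgvs_p = d$hgvs_p[1], n_detected = n,
      category = if (is_event) "event" else
        classify_trajectory(first_vaf, final_vaf, n, delta_pp, min_timepoints),
      late_appearing = is_event && final_tp == ind_last &&
        final_vaf >= chip_threshold_pct,
      reached_chip = any(d$vaf_pct >= chip_threshold_pct),
      disappeared = final_tp < ind_last,
      vaf_first = first_vaf, vaf_final = final_vaf, vaf_max = max(d$vaf_pct),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$individual_id, out$gene, out$hgvs_p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ch_trajectories", "data.frame")
  out
}

#' Select each individual's dominant trajectory
#'
#' The dominant trajectory is the traceable trajectory with the highest VAF at
#' any timepoint; it carries the individual into the growth analysis. Ties on
#' the maximum VAF are broken by the larger VAF at the final detected
#' timepoint, then lexicographically on the mutation label, so selection is
#' stable under input reordering. Individuals whose dominant trajectory is
#' shrinking are flagged `excluded` (shrinkage is thought to reflect negative
#' selection by other, undetected clones) unless `include_shrinking = TRUE`
#' (the sensitivity analysis). Individuals with no traceable trajectory do not
#' appear in the result.
#'
#' @param trajectories a [build_trajectories()] table.
#' @param include_shrinking keep shrinking-dominant individuals (sensitivity
#'   analysis)?
#' @return data.frame with one row per individual holding the dominant
#'   trajectory plus a logical `excluded` column.
#' @export
select_dominant <- function(trajectories, include_shrinking = FALSE) {
  tr <- trajectories[trajectories$category != "event", , drop = FALSE]
  if (nrow(tr) == 0) {
    out <- tr
    out$excluded <- logical(0)
    return(out)
  }
  mut_id <- paste(tr$gene, tr$hgvs_p)
  ord <- order(tr$individual_id, -tr$vaf_max, -tr$vaf_final, mut_id)
  tr <- tr[ord, , drop = FALSE]
  dom <- tr[!duplicated(tr$individual_id), , drop = FALSE]
  dom$excluded <- dom$category == "shrinking" & !include_shrinking
  rownames(dom) <- NULL
  dom
}

#' @export
print.ch_trajectories <- function(x, ...) {
  cat("CHDM trajectories:", nrow(x), "total;",
      sum(x$category == "event"), "events,",
      sum(x$category != "event"), "traceable (",
      sum(x$category == "growing"), "growing /",
      sum(x$category == "static"), "static /",
      sum(x$category == "shrinking"), "shrinking )\n")
  invisible(x)
}
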
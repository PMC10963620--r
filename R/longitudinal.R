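# Longitudinal pairing of per-ROI puncta counts, percent change in PSDs,
# ROI- and plate-level QC gates, forward propagation of exclusions, and
# assay-quality statistics.

#' Percent change in PSDs relative to baseline
#'
#' `100 * (count_t - count_t0) / count_t0` for the same ROI's paired counts.
#' Bounded below by -100 when counts are non-negative; scale-invariant in the
#' counts. A zero baseline is an error (pre-empted in practice by the
#' 50-puncta ROI gate).
#'
#' @param count_t,count_t0 Puncta counts (vectorised).
#' @return Percent change.
#' @export
percent_change <- function(count_t, count_t0) {
  if (any(count_t0 == 0, na.rm = TRUE)) {
    stop("undefined baseline: count_t0 = 0")
  }
  100 * (count_t - count_t0) / count_t0
}

#' ROI inclusion gate on the baseline count
#'
#' ROIs with fewer than `min_count` puncta at t = 0 (default 50) are excluded
#' from later timepoints, so that sparse baselines do not amplify small
#' absolute changes. Exactly `min_count` is included.
#'
#' @param count_t0 Baseline puncta count (vectorised).
#' @param min_count Gate value.
#' @return Logical include flag.
#' @export
roi_gate <- function(count_t0, min_count = 50L) {
  !is.na(count_t0) & count_t0 >= min_count
}

#' Base-10 log transform with +101 shift
#'
#' `log10(x + 101)` maps the percent-change domain `[-100, Inf)` to
#' `[0, Inf)`; used downstream to restore normality or variance homogeneity.
#'
#' @param x Percent change, `x >= -100`.
#' @return Transformed value.
#' @export
log_shift_transform <- function(x) {
  if (any(x < -100, na.rm = TRUE)) stop("domain error: x < -100")
  log10(x + 101)
}

#' Strictly standardised mean difference (SSMD)
#'
#' `(mean(a) - mean(b)) / sqrt(var(a) + var(b))` with sample variances; the
#' assay-quality metric used to optimise filter settings between untreated
#' and network-activity-control ROIs. If both variances are zero the result
#' is `0` for equal means and a signed infinity (with a warning) otherwise.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return Dimensionless effect size.
#' @export
ssmd <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  num <- mean(group_a) - mean(group_b)
  den <- sqrt(stats::var(group_a) + stats::var(group_b))
  if (den == 0) {
    if (num == 0) return(0)
    warning("zero variance in both groups; returning signed infinity")
    return(sign(num) * Inf)
  }
  num / den
}

#' Build per-ROI change records from a table of counts
#'
#' Pairs each later timepoint with the same ROI's baseline count and computes
#' the percent change in PSDs. The ROI gate is applied: records whose
#' baseline is below `min_count` (or missing) are retained but marked
#' excluded with reason `"low_t0_count"`.
#'
#' @param counts Tibble with columns `plate_id, well_id, roi_index,
#'   treatment, role, timepoint, count` (one row per ROI x timepoint).
#' @param baseline Baseline timepoint (default 0).
#' @param min_count ROI gate value (default 50).
#' @return Change-record tibble: one row per ROI x later timepoint with
#'   `count_t0`, `count`, `pct_change`, `included`, `exclusion_reason`.
#' @export
build_change_records <- function(counts, baseline = 0, min_count = 50L) {
  counts <- tibble::as_tibble(counts)
  base <- counts |>
    dplyr::filter(.data$timepoint == baseline) |>
    dplyr::select("plate_id", "well_id", "roi_index", count_t0 = "count")
  rec <- counts |>
    dplyr::filter(.data$timepoint != baseline) |>
    dplyr::left_join(base, by = c("plate_id", "well_id", "roi_index")) |>
    dplyr::mutate(
      included = roi_gate(.data$count_t0, min_count),
      pct_change = dplyr::if_else(
        !is.na(.data$count_t0) & .data$count_t0 > 0,
        100 * (.data$count - .data$count_t0) / .data$count_t0,
        NA_real_
      ),
      exclusion_reason = dplyr::if_else(.data$included, "none", "low_t0_count")
    ) |>
    dplyr::arrange(.data$plate_id, .data$well_id, .data$roi_index,
                   .data$timepoint)
  dplyr::select(rec, "plate_id", "well_id", "roi_index", "treatment", "role",
                "timepoint", "count_t0", "count", "pct_change", "included",
                "exclusion_reason")
}

#' Plate-level quality-control gates
#'
#' Evaluated on one plate's change records at the control timepoint (24 h):
#' * `low_rois`: fail if more than `max_frac_low` (default 50%) of the
#'   plate's ROIs had fewer than 50 baseline puncta;
#' * `untreated`: fail if untreated wells lost more than 10% of PSDs
#'   (mean change strictly below -10%), indicating a compromised culture;
#' * `diffuse_control` (positive-control-A, e.g. 2-BP): fail unless the
#'   diffuse-label control lost at least 10% (mean change of -10% passes);
#' * `activity_control` (positive-control-B, e.g. Pic/4-AP): fail unless the
#'   network-activity control lost at least 10%.
#'
#' Control means are taken over ROIs passing the ROI gate. Vehicle wells
#' never gate a plate.
#'
#' @param records Change records of one plate at one timepoint (normally
#'   24 h), as from [build_change_records()].
#' @param max_frac_low,untreated_min_change,control_max_change Gate
#'   thresholds (defaults 0.5, -10, -10).
#' @return An object of class `plate_qc` with per-gate pass flags and
#'   `plate_included`.
#' @export
plate_gate <- function(records, max_frac_low = 0.5,
                       untreated_min_change = -10, control_max_change = -10) {
  records <- tibble::as_tibble(records)
  plate <- unique(records$plate_id)
  if (length(plate) != 1L) stop("plate_gate expects records of a single plate")
  tps <- unique(records$timepoint)
  if (length(tps) != 1L) stop("plate_gate expects records of a single timepoint")
  for (role in c("untreated", "positive-control-A", "positive-control-B")) {
    if (!any(records$role == role)) {
      stop("plate ", plate, " is missing control group: ", role)
    }
  }
  grp_mean <- function(role) {
    x <- records$pct_change[records$role == role & records$included]
    if (length(x) == 0L) NA_real_ else mean(x)
  }
  frac_low <- mean(is.na(records$count_t0) | records$count_t0 < 50)
  unt <- grp_mean("untreated")
  pos_a <- grp_mean("positive-control-A")
  pos_b <- grp_mean("positive-control-B")
  gates <- c(
    low_rois = frac_low <= max_frac_low,
    untreated = !is.na(unt) && unt >= untreated_min_change,
    diffuse_control = !is.na(pos_a) && pos_a <= control_max_change,
    activity_control = !is.na(pos_b) && pos_b <= control_max_change
  )
  structure(
    list(plate_id = plate, timepoint = tps, frac_low_rois = frac_low,
         untreated_mean_change = unt, posA_mean_change = pos_a,
         posB_mean_change = pos_b, gates = gates,
         plate_included = all(gates)),
    class = "plate_qc"
  )
}

#' @export
print.plate_qc <- function(x, ...) {
  cat(sprintf("<plate_qc> plate %s at %g h: %s\n", x$plate_id, x$timepoint,
              if (x$plate_included) "PASS" else "FAIL"))
  cat(sprintf("  low-baseline ROIs: %.1f%% (%s)\n", 100 * x$frac_low_rois,
              if (x$gates[["low_rois"]]) "pass" else "fail"))
  cat(sprintf("  untreated mean change: %+.1f%% (%s)\n",
              x$untreated_mean_change,
              if (x$gates[["untreated"]]) "pass" else "fail"))
  cat(sprintf("  diffuse-label control: %+.1f%% (%s)\n", x$posA_mean_change,
              if (x$gates[["diffuse_control"]]) "pass" else "fail"))
  cat(sprintf("  activity control: %+.1f%% (%s)\n", x$posB_mean_change,
              if (x$gates[["activity_control"]]) "pass" else "fail"))
  invisible(x)
}

#' Propagate outlier exclusions forward in time
#'
#' An ROI flagged as an outlier at one timepoint is excluded from all later
#' timepoints (reason `"outlier_prior_timepoint"`); earlier timepoints are
#' unchanged. Idempotent.
#'
#' @param records Change-record tibble spanning multiple timepoints, with
#'   `exclusion_reason == "outlier"` set where the outlier test flagged ROIs.
#' @return Updated records.
#' @export
propagate_exclusions <- function(records) {
  records <- tibble::as_tibble(records)
  flagged <- records |>
    dplyr::filter(.data$exclusion_reason == "outlier") |>
    dplyr::select("plate_id", "well_id", "roi_index",
                  outlier_t = "timepoint")
  if (nrow(flagged) == 0L) return(records)
  out <- flagged |>
    dplyr::group_by(.data$plate_id, .data$well_id, .data$roi_index) |>
    dplyr::summarise(outlier_t = min(.data$outlier_t), .groups = "drop")
  records |>
    dplyr::left_join(out, by = c("plate_id", "well_id", "roi_index")) |>
    dplyr::mutate(
      hit = !is.na(.data$outlier_t) & .data$timepoint > .data$outlier_t &
        .data$exclusion_reason != "outlier",
      included = dplyr::if_else(.data$hit, FALSE, .data$included),
      exclusion_reason = dplyr::if_else(.data$hit, "outlier_prior_timepoint",
                                        .data$exclusion_reason)
    ) |>
    dplyr::select(-"outlier_t", -"hit")
}
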
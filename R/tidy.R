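# broom-style tidiers for the package's result objects.

#' Tidy a puncta-detection result
#'
#' @param x A `psd_puncta` object from [count_puncta()] or [apply_filters()].
#' @param ... Unused.
#' @return The per-candidate tibble (without the pixel list-column).
#' @method tidy psd_puncta
#' @export
tidy.psd_puncta <- function(x, ...) {
  dplyr::select(x$puncta, -dplyr::any_of("pixels"))
}

#' @rdname tidy.psd_puncta
#' @method glance psd_puncta
#' @export
glance.psd_puncta <- function(x, ...) {
  tibble::tibble(
    count = x$count,
    n_candidates = nrow(x$puncta),
    n_rejected = nrow(x$puncta) - x$count,
    threshold_used = x$threshold_used %||% NA_real_
  )
}

#' Tidy an outlier-test result
#'
#' @param x A `rout_result` from [rout_outliers()].
#' @param ... Unused.
#' @return Per-point tibble with residuals, statistics, p-values and flags.
#' @method tidy rout_result
#' @export
tidy.rout_result <- function(x, ...) x$stats

#' @rdname tidy.rout_result
#' @method glance rout_result
#' @export
glance.rout_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$stats),
    n_outliers = length(x$outlier_indices),
    robust_center = x$robust_center,
    rsdr = x$rsdr,
    q = x$q
  )
}

#' Tidy a plate QC report
#'
#' @param x A `plate_qc` object from [plate_gate()].
#' @param ... Unused.
#' @return One row per gate with its pass flag.
#' @method tidy plate_qc
#' @export
tidy.plate_qc <- function(x, ...) {
  tibble::tibble(
    plate_id = x$plate_id,
    gate = names(x$gates),
    pass = unname(x$gates)
  )
}

#' @rdname tidy.plate_qc
#' @method glance plate_qc
#' @export
glance.plate_qc <- function(x, ...) {
  tibble::tibble(
    plate_id = x$plate_id,
    timepoint = x$timepoint,
    frac_low_rois = x$frac_low_rois,
    untreated_mean_change = x$untreated_mean_change,
    posA_mean_change = x$posA_mean_change,
    posB_mean_change = x$posB_mean_change,
    plate_included = x$plate_included
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
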
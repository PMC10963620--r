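# Run configuration: every printed cutoff of the assay is data here, not
# code. Defaults are the assay's standard settings.

#' Default pipeline configuration
#'
#' Nested parameter list covering detection (filter sigmas, kernel sizes,
#' object cutoffs), QC gate thresholds, outlier removal, and the synthetic
#' scene defaults used by [cmd_simulate()]. Round-trips losslessly through
#' [write_config()]/[read_config()].
#'
#' Detection defaults: soma DoG sigmas (1, 30) px; process DoG sigmas
#' (8, 9) px with the sign-corrected Laplacian; puncta blur sigma 5 px;
#' top-hat radius 5 px; 256-bin triangle thresholds; 8-connectivity;
#' elongation bound 10 px; size window 6--200 px; SNR bound 1.2 with a
#' 1--5 px background annulus (widened to at most 11 px). Gate defaults:
#' 50 baseline puncta per ROI, 50% low-ROI plate rule, 10% control rules.
#' Outlier removal: ROUT Q = 10% per (plate, treatment, timepoint).
#'
#' @return Nested named list of class `psd_config`.
#' @export
default_config <- function() {
  structure(list(
    detect = list(
      soma_sigma = c(1, 30),
      process_sigma = c(8, 9),
      laplace_sign = "positive",
      blur_sigma = 5,
      tophat_radius = 5L,
      hist_bins = 256L,
      connectivity = 8L,
      elongation_max = 10,
      size_range = c(6L, 200L),
      snr_min = 1.2,
      mask_rule = "any_pixel",
      snr_inner = 1L,
      snr_outer = 5L,
      snr_outer_max = 11L
    ),
    gates = list(
      min_puncta_t0 = 50L,
      max_frac_low = 0.5,
      untreated_min_change = -10,
      control_max_change = -10,
      gate_timepoint = 24
    ),
    outliers = list(
      q = 0.10,
      group_by = c("plate_id", "treatment", "timepoint")
    ),
    io = list(
      pixel_size = 0.15,
      z_step = 1,
      bits = 16L
    ),
    scene = unclass(scene_params())
  ), class = c("psd_config", "list"))
}

#' Read/write a configuration file
#'
#' YAML round-trip of the nested configuration; missing keys fall back to
#' [default_config()] values.
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (section in names(raw)) {
    for (key in names(raw[[section]])) {
      val <- raw[[section]][[key]]
      old <- cfg[[section]][[key]]
      if (!is.null(old) && is.integer(old)) val <- as.integer(val)
      cfg[[section]][[key]] <- val
    }
  }
  cfg
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
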
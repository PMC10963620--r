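# ggplot2 visualisations of detection results, outlier tests and group-level
# percent change.

#' Overlay accepted puncta on the puncta-channel projection
#'
#' @param object A `psd_puncta` from [count_puncta()] (needs the stored
#'   projection).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psd_puncta
#' @export
autoplot.psd_puncta <- function(object, ...) {
  if (is.null(object$projection)) {
    stop("no stored projection; run count_puncta() to keep one")
  }
  img <- object$projection
  df <- tibble::tibble(
    row = as.vector(row(img)), col = as.vector(col(img)),
    intensity = as.vector(img)
  )
  acc <- object$puncta[object$puncta$accepted, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(data = acc,
                        ggplot2::aes(x = .data$centroid_c,
                                     y = .data$centroid_r),
                        colour = "red", shape = 1, size = 2,
                        inherit.aes = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%d accepted puncta", object$count),
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot an outlier test
#'
#' Strip plot of the group's values with flagged outliers highlighted and
#' the robust centre marked.
#'
#' @param object A `rout_result` from [rout_outliers()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rout_result
#' @export
autoplot.rout_result <- function(object, ...) {
  df <- object$stats
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$value,
                                   colour = .data$outlier)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$robust_center,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = NULL, y = "% change in PSDs",
                  colour = "outlier",
                  title = sprintf("ROUT at Q = %g", object$q)) +
    ggplot2::theme_minimal()
}

#' Dot plot of percent change by treatment group
#'
#' One dot per included ROI, with the group mean and its standard error,
#' mirroring the assay's control summary plots.
#'
#' @param records Change-record tibble (e.g. from [cmd_quantify()]).
#' @param timepoint Timepoint to display (default 24 h).
#' @return A ggplot.
#' @export
plot_change_groups <- function(records, timepoint = 24) {
  df <- dplyr::filter(tibble::as_tibble(records),
                      .data$timepoint == !!timepoint, .data$included)
  summ <- df |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      mean = mean(.data$pct_change),
      sem = stats::sd(.data$pct_change) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$treatment,
                                   y = .data$pct_change)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5,
                         colour = "grey40") +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      colour = "red", linewidth = 0.8
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "% change in PSDs") +
    ggplot2::theme_minimal()
}
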
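# Punctum detection in the PSD95-eGFP channel: enhancement, segmentation,
# object geometry, local SNR, and the four-filter exclusion cascade
# (elongation -> mask -> size -> SNR). All intensity measurements are taken
# from the original puncta channel prior to any processing.

#' Enhance punctate structures
#'
#' Gaussian low-pass blur (sigma 5 px), grayscale white top-hat with a square
#' structuring element (5 px radius) to remove background larger than the
#' element, then squaring to accentuate high-intensity regions. The output is
#' non-negative and scales quadratically with input amplitude.
#'
#' @param puncta_plane Numeric matrix (puncta-channel plane).
#' @param blur_sigma Gaussian sigma in pixels.
#' @param tophat_radius Structuring-element radius in pixels (square element
#'   of side `2*radius + 1`).
#' @return Non-negative matrix of the same shape.
#' @export
enhance_puncta <- function(puncta_plane, blur_sigma = 5, tophat_radius = 5L) {
  stopifnot(is.matrix(puncta_plane))
  g <- gaussian_kernel(blur_sigma)
  blurred <- conv2_replicate(puncta_plane, outer(g, g))
  gray_tophat(blurred, as.integer(tophat_radius))^2
}

#' Maximum extension of an object (elongation measure)
#'
#' The maximum Euclidean distance from any member pixel centre to the object
#' centroid. Zero if and only if the object is a single pixel.
#'
#' @param pixels Two-column matrix of (row, col) member pixels.
#' @return Distance in pixels.
#' @export
max_extension <- function(pixels) {
  stopifnot(is.matrix(pixels), ncol(pixels) == 2L, nrow(pixels) >= 1L)
  ctr <- colMeans(pixels)
  sqrt(max((pixels[, 1L] - ctr[1L])^2 + (pixels[, 2L] - ctr[2L])^2))
}

#' Segment punctum candidates from the enhanced image
#'
#' Triangle-thresholds the enhanced image, labels connected components
#' (8-connected), and measures geometry per component. Mean intensities come
#' from the original (unprocessed) puncta channel.
#'
#' @param enhanced Output of [enhance_puncta()].
#' @param original Original puncta-channel plane, same shape.
#' @param bins Histogram bins for the triangle threshold.
#' @param connectivity 4 or 8 (default 8).
#' @return A tibble with one row per candidate: `label`, `area`,
#'   `centroid_r`, `centroid_c`, `max_extension`, `mean_intensity`, and a
#'   `pixels` list-column of (row, col) matrices. The threshold is attached
#'   as attribute `threshold`.
#' @export
segment_candidates <- function(enhanced, original, bins = 256L,
                               connectivity = 8L) {
  if (!identical(dim(enhanced), dim(original))) {
    stop("enhanced and original planes must share the same shape")
  }
  thr <- triangle_threshold(enhanced, bins)
  lab <- label_components(enhanced > thr, connectivity)
  n_lab <- max(lab)
  empty <- tibble::tibble(
    label = integer(0), area = integer(0),
    centroid_r = numeric(0), centroid_c = numeric(0),
    max_extension = numeric(0), mean_intensity = numeric(0),
    pixels = list()
  )
  if (n_lab == 0L) return(structure(empty, threshold = thr))
  n <- nrow(enhanced)
  idx <- which(lab > 0L)
  l <- lab[idx]
  r <- ((idx - 1L) %% n) + 1L
  cc <- ((idx - 1L) %/% n) + 1L
  area <- tabulate(l, n_lab)
  cr <- rowsum(r, l)[, 1L] / area
  ccol <- rowsum(cc, l)[, 1L] / area
  d2 <- (r - cr[l])^2 + (cc - ccol[l])^2
  mext <- sqrt(as.numeric(tapply(d2, l, max)))
  mint <- rowsum(original[idx], l)[, 1L] / area
  ord <- order(l)
  pix <- split.data.frame(cbind(r, cc)[ord, , drop = FALSE], l[ord])
  pix <- lapply(pix, function(m) {
    dimnames(m) <- list(NULL, c("row", "col"))
    m
  })
  out <- tibble::tibble(
    label = seq_len(n_lab),
    area = as.integer(area),
    centroid_r = as.numeric(cr),
    centroid_c = as.numeric(ccol),
    max_extension = mext,
    mean_intensity = as.numeric(mint),
    pixels = unname(pix)
  )
  structure(out, threshold = thr)
}

#' Local signal-to-noise ratio of a punctum
#'
#' `SNR = mean punctum intensity / mean local background intensity`, both on
#' the original puncta channel. The local background is the annulus between
#' dilations of the object by `inner` and `outer` pixels, excluding pixels of
#' any candidate object; if empty, the outer radius widens in 2-px steps to
#' `outer_max`, then falls back to the median of the plane's non-candidate
#' pixels (restricted to the neurite mask when one is supplied). A zero
#' background yields `Inf` (such puncta are retained by the SNR criterion).
#'
#' @param pixels Two-column (row, col) matrix of the object's pixels.
#' @param original Original puncta-channel plane.
#' @param candidate_mask Logical matrix marking pixels of all candidates.
#' @param inner,outer,outer_max Annulus radii in pixels.
#' @param mask Optional neurite mask used for the fallback background region.
#' @return A list with `snr`, `mean_intensity`, `background_mean`.
#' @export
local_snr <- function(pixels, original, candidate_mask,
                      inner = 1L, outer = 5L, outer_max = 11L, mask = NULL) {
  mean_int <- mean(original[pixels])
  bg <- local_background(pixels, original, candidate_mask,
                         inner, outer, outer_max, mask)
  snr <- if (bg > 0) mean_int / bg else Inf
  list(snr = snr, mean_intensity = mean_int, background_mean = bg)
}

local_background <- function(pixels, original, candidate_mask,
                             inner = 1L, outer = 5L, outer_max = 11L,
                             mask = NULL) {
  n <- nrow(original)
  m <- ncol(original)
  for (r_out in seq(outer, outer_max, by = 2L)) {
    pad <- r_out + 1L
    i0 <- max(1L, min(pixels[, 1L]) - pad)
    i1 <- min(n, max(pixels[, 1L]) + pad)
    j0 <- max(1L, min(pixels[, 2L]) - pad)
    j1 <- min(m, max(pixels[, 2L]) + pad)
    sub <- matrix(0, i1 - i0 + 1L, j1 - j0 + 1L)
    sub[cbind(pixels[, 1L] - i0 + 1L, pixels[, 2L] - j0 + 1L)] <- 1
    ring <- (gray_dilate(sub, r_out) > 0) & !(gray_dilate(sub, inner) > 0) &
      !candidate_mask[i0:i1, j0:j1, drop = FALSE]
    if (any(ring)) {
      return(mean(original[i0:i1, j0:j1, drop = FALSE][ring]))
    }
  }
  free <- !candidate_mask
  if (!is.null(mask)) {
    both <- free & unclass(mask)
    if (any(both)) return(median(original[both]))
  }
  if (any(free)) median(original[free]) else 0
}

#' Apply the four-filter exclusion cascade to punctum candidates
#'
#' Filters are applied in the fixed order elongation -> mask -> size -> SNR:
#' * elongation: `max_extension` above `elongation_max` (default 10) excluded
#'   (exactly 10 is retained);
#' * mask: at least one object pixel must lie in the final neurite mask
#'   (switch to centroid containment with `mask_rule = "centroid"`);
#' * size: area within `size_range` pixels (default 6--200, both inclusive);
#' * SNR: local SNR below `snr_min` (default 1.2) excluded (exactly 1.2 is
#'   retained). SNR is computed only for candidates surviving the first three
#'   filters, on the original channel, when `original` is supplied; otherwise
#'   a pre-computed `snr` column is used.
#'
#' Each rejected candidate carries the first criterion it failed.
#'
#' @param candidates Candidate tibble from [segment_candidates()] (or any
#'   tibble with the same columns).
#' @param mask Final neurite mask ([neurite_mask()]).
#' @param original Original puncta-channel plane (for SNR measurement);
#'   optional if `candidates` already has an `snr` column.
#' @param elongation_max,size_range,snr_min Filter cutoffs.
#' @param mask_rule `"any_pixel"` (default) or `"centroid"`.
#' @param snr_inner,snr_outer,snr_outer_max Background annulus radii.
#' @return An object of class `psd_puncta`: a list with `puncta` (the
#'   candidate tibble plus per-filter flags, `accepted`, `reject_reason`,
#'   `snr`, `background_mean`), `count` (number accepted), and
#'   `threshold_used` when available.
#' @export
apply_filters <- function(candidates, mask, original = NULL,
                          elongation_max = 10, size_range = c(6L, 200L),
                          snr_min = 1.2,
                          mask_rule = c("any_pixel", "centroid"),
                          snr_inner = 1L, snr_outer = 5L, snr_outer_max = 11L) {
  mask_rule <- match.arg(mask_rule)
  cand <- tibble::as_tibble(candidates)
  n_cand <- nrow(cand)
  pass_elong <- cand$max_extension <= elongation_max
  if (mask_rule == "any_pixel") {
    pass_mask <- vapply(cand$pixels, function(px) any(mask[px]), logical(1L))
  } else {
    ri <- pmin(pmax(round(cand$centroid_r), 1L), nrow(mask))
    ci <- pmin(pmax(round(cand$centroid_c), 1L), ncol(mask))
    pass_mask <- mask[cbind(ri, ci)]
  }
  if (n_cand == 0L) pass_mask <- logical(0)
  pass_size <- cand$area >= size_range[1L] & cand$area <= size_range[2L]
  survives3 <- pass_elong & pass_mask & pass_size

  snr <- rep(NA_real_, n_cand)
  bg <- rep(NA_real_, n_cand)
  if (!is.null(original)) {
    cand_mask <- matrix(FALSE, nrow(original), ncol(original))
    for (px in cand$pixels) cand_mask[px] <- TRUE
    for (i in which(survives3)) {
      res <- local_snr(cand$pixels[[i]], original, cand_mask,
                       inner = snr_inner, outer = snr_outer,
                       outer_max = snr_outer_max, mask = mask)
      snr[i] <- res$snr
      bg[i] <- res$background_mean
      cand$mean_intensity[i] <- res$mean_intensity
    }
  } else {
    if (!"snr" %in% names(cand)) {
      stop("supply `original` or candidates with a pre-computed `snr` column")
    }
    snr <- cand$snr
    if ("background_mean" %in% names(cand)) bg <- cand$background_mean
  }
  pass_snr <- !is.na(snr) & snr >= snr_min
  accepted <- survives3 & pass_snr
  reason <- rep(NA_character_, n_cand)
  reason[survives3 & !pass_snr] <- "snr"
  reason[pass_elong & pass_mask & !pass_size] <- "size"
  reason[pass_elong & !pass_mask] <- "mask"
  reason[!pass_elong] <- "elongation"

  cand$snr <- snr
  cand$background_mean <- bg
  cand$pass_elongation <- pass_elong
  cand$pass_mask <- pass_mask
  cand$pass_size <- pass_size
  cand$pass_snr <- ifelse(survives3, pass_snr, NA)
  cand$accepted <- accepted
  cand$reject_reason <- reason

  structure(
    list(puncta = cand, count = sum(accepted),
         threshold_used = attr(candidates, "threshold", exact = TRUE)),
    class = "psd_puncta"
  )
}

#' Count synaptic puncta in a two-channel ROI image pair
#'
#' Full per-ROI pipeline: maximum-project both channels, build the neurite
#' mask (soma excluded) from the structural channel, enhance and segment the
#' puncta channel, and apply the four-filter cascade. Intensities are
#' measured on the original (unprocessed) puncta projection.
#'
#' @param roi An `roi_pair` (see [read_roi_pair()]).
#' @param config Parameter list from [default_config()]; `config$detect`
#'   holds all filter settings.
#' @return A `psd_puncta` object with `meta`, `puncta` tibble, `count`,
#'   `threshold_used`, `mask`, and the puncta-channel projection
#'   (`projection`).
#' @export
count_puncta <- function(roi, config = default_config()) {
  stopifnot(inherits(roi, "roi_pair"))
  dc <- config$detect
  struct_proj <- max_project(roi$structure)
  puncta_proj <- max_project(roi$puncta)
  soma <- soma_mask(struct_proj, sigma = dc$soma_sigma, bins = dc$hist_bins)
  proc <- process_mask(struct_proj, sigma = dc$process_sigma,
                       bins = dc$hist_bins, laplace_sign = dc$laplace_sign)
  mask <- neurite_mask(soma, proc)
  enh <- enhance_puncta(puncta_proj, blur_sigma = dc$blur_sigma,
                        tophat_radius = dc$tophat_radius)
  cand <- segment_candidates(enh, puncta_proj, bins = dc$hist_bins,
                             connectivity = dc$connectivity)
  res <- apply_filters(cand, mask, puncta_proj,
                       elongation_max = dc$elongation_max,
                       size_range = dc$size_range, snr_min = dc$snr_min,
                       mask_rule = dc$mask_rule, snr_inner = dc$snr_inner,
                       snr_outer = dc$snr_outer,
                       snr_outer_max = dc$snr_outer_max)
  res$meta <- roi$meta
  res$mask <- mask
  res$projection <- puncta_proj
  res
}

#' @export
print.psd_puncta <- function(x, ...) {
  cat(sprintf("<psd_puncta> %d accepted / %d candidates\n",
              x$count, nrow(x$puncta)))
  if (!is.null(x$meta) && nrow(x$meta)) print(x$meta)
  invisible(x)
}
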
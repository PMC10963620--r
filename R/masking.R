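# Neurite mask construction from the structural (cell-fill) channel: a loose
# soma-scale mask and a neurite-scale process mask, combined so that somatic
# areas are excluded from puncta analysis.

#' Difference-of-Gaussians band-pass filter
#'
#' `G(sigma_small) * I - G(sigma_large) * I`, each Gaussian truncated at 4
#' sigma and applied with edge-replicate borders. Both kernels sum to one, so
#' the response to a constant image is zero (DC rejection) and the filter is
#' linear in the image.
#'
#' @param plane Numeric matrix.
#' @param sigma_small,sigma_large Gaussian standard deviations in pixels,
#'   `0 < sigma_small < sigma_large`.
#' @return Real-valued matrix (may be negative).
#' @export
dog_filter <- function(plane, sigma_small, sigma_large) {
  stopifnot(is.matrix(plane))
  if (!(sigma_small > 0 && sigma_large > sigma_small)) {
    stop("require 0 < sigma_small < sigma_large")
  }
  k_small <- gaussian_kernel(sigma_small)
  k_large <- gaussian_kernel(sigma_large)
  # embed the narrow kernel in the wide kernel's support, convolve once
  h_small <- (length(k_small) - 1L) %/% 2L
  h_large <- (length(k_large) - 1L) %/% 2L
  k1 <- numeric(length(k_large))
  k1[h_large + 1L + (-h_small:h_small)] <- k_small
  conv2_replicate(plane, outer(k1, k1) - outer(k_large, k_large))
}

#' Discrete Laplacian filter
#'
#' 3x3 4-neighbour stencil (centre -4, edge neighbours +1), with the response
#' negated so that bright ridges and blobs give positive values; the process
#' mask thresholds the positive band. Set `negate = FALSE` for the raw
#' stencil response.
#'
#' @param plane Numeric matrix.
#' @param negate Flip the sign so bright structures respond positively
#'   (default `TRUE`).
#' @return Real-valued matrix.
#' @export
laplace_filter <- function(plane, negate = TRUE) {
  stopifnot(is.matrix(plane))
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, 3L)
  out <- conv2_replicate(plane, k)
  if (negate) -out else out
}

#' Triangle auto-threshold
#'
#' Computes the threshold maximising the perpendicular distance from the
#' histogram to the chord joining the histogram peak and the far end of the
#' longer tail. The histogram uses `bins` bins over the min-max-scaled image
#' (the standard triangle-method convention). Binarise as `plane > threshold`.
#'
#' A single-valued (degenerate) image returns that value, so the binary image
#' is empty.
#'
#' @param plane Numeric matrix with at least one pixel.
#' @param bins Number of histogram bins (default 256).
#' @return Threshold on the intensity scale of `plane`.
#' @export
triangle_threshold <- function(plane, bins = 256L) {
  stopifnot(length(plane) >= 1L)
  lo <- min(plane)
  hi <- max(plane)
  if (!(hi > lo)) return(hi)
  s <- (plane - lo) / (hi - lo)
  h <- tabulate(pmin(bins, floor(s * bins) + 1L), nbins = bins)
  pk <- which.max(h)
  nz <- which(h > 0L)
  first <- nz[1L]
  last <- nz[length(nz)]
  # side with the longer tail from the peak; ties go to the upper tail
  end <- if ((last - pk) >= (pk - first)) last else first
  if (end == pk) return(lo + (pk - 0.5) / bins * (hi - lo))
  ii <- if (end > pk) pk:end else end:pk
  dx <- end - pk
  dy <- h[end] - h[pk]
  d <- abs(dy * (ii - pk) - dx * (h[ii] - h[pk])) / sqrt(dx^2 + dy^2)
  t_bin <- ii[which.max(d)]
  lo + (t_bin - 0.5) / bins * (hi - lo)
}

new_binary_mask <- function(pixels, kind) {
  structure(pixels, kind = kind, class = c("binary_mask", class(pixels)))
}

#' Soma mask from the structural channel
#'
#' A loose threshold for soma-scale bright regions: triangle threshold of the
#' wide-band DoG response (sigmas 1 and 30 px by default).
#'
#' @param structure Numeric matrix (structural-channel plane, typically a
#'   maximum projection).
#' @param sigma Length-2 vector of DoG sigmas in pixels.
#' @param bins Histogram bins for the triangle threshold.
#' @return Logical matrix of class `binary_mask` (`kind = "soma"`).
#' @export
soma_mask <- function(structure, sigma = c(1, 30), bins = 256L) {
  f <- dog_filter(structure, sigma[1L], sigma[2L])
  new_binary_mask(f > triangle_threshold(f, bins), "soma")
}

#' Cell-process (neurite) mask from the structural channel
#'
#' Narrow-band DoG (sigmas 8 and 9 px by default) followed by the Laplacian
#' and a triangle threshold of the positive response band yields a mask of
#' neurite-scale ridges; flat bright regions are rejected by the band-pass.
#'
#' @inheritParams soma_mask
#' @param laplace_sign `"positive"` (default) thresholds the sign-corrected
#'   Laplacian response; `"absolute"` thresholds its absolute value.
#' @return Logical matrix of class `binary_mask` (`kind = "process"`).
#' @export
process_mask <- function(structure, sigma = c(8, 9), bins = 256L,
                         laplace_sign = c("positive", "absolute")) {
  laplace_sign <- match.arg(laplace_sign)
  f <- laplace_filter(dog_filter(structure, sigma[1L], sigma[2L]))
  if (laplace_sign == "absolute") f <- abs(f)
  new_binary_mask(f > triangle_threshold(f, bins), "process")
}

#' Final neurite mask with somatic areas excluded
#'
#' `final = process AND (NOT soma)`; the output never intersects the soma
#' mask, so somatic puncta are excluded from all further analysis.
#'
#' @param soma,process Logical matrices of identical shape.
#' @return Logical matrix of class `binary_mask` (`kind = "final"`).
#' @export
neurite_mask <- function(soma, process) {
  if (!identical(dim(soma), dim(process))) {
    stop("soma and process masks must share the same shape")
  }
  new_binary_mask(unclass(process) & !unclass(soma), "final")
}
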
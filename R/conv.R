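# Low-level image primitives: FFT convolution with edge-replicate padding,
# separable grayscale box morphology, 8-connected component labeling.

#' Normalised 1-D Gaussian kernel
#'
#' Kernel is truncated at 4 standard deviations and normalised to unit sum.
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @return Numeric vector of odd length `2*ceiling(4*sigma) + 1`.
#' @keywords internal
gaussian_kernel <- function(sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' 2-D convolution with edge replication
#'
#' Convolves an image with a kernel, handling borders by replicating the
#' nearest edge pixel. Computed by FFT on the padded image; the kernel may be
#' larger than the image. All kernels used in the pipeline are symmetric, so
#' convolution and correlation coincide.
#'
#' @param x Numeric matrix (image plane).
#' @param k Numeric matrix (kernel, odd dimensions).
#' @return Numeric matrix of the same dimensions as `x`.
#' @keywords internal
conv2_replicate <- function(x, k) {
  stopifnot(is.matrix(x), is.matrix(k))
  if (nrow(k) %% 2L == 0L || ncol(k) %% 2L == 0L) {
    stop("kernel dimensions must be odd")
  }
  kh <- (nrow(k) - 1L) %/% 2L
  kw <- (ncol(k) - 1L) %/% 2L
  n <- nrow(x)
  m <- ncol(x)
  ri <- c(rep(1L, kh), seq_len(n), rep(n, kh))
  ci <- c(rep(1L, kw), seq_len(m), rep(m, kw))
  p <- x[ri, ci, drop = FALSE]
  np <- nrow(p)
  mp <- ncol(p)
  kp <- matrix(0, np, mp)
  kp[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  # circular shift so the kernel center sits at index (1, 1)
  kp <- kp[((seq_len(np) - 1L + kh) %% np) + 1L,
           ((seq_len(mp) - 1L + kw) %% mp) + 1L, drop = FALSE]
  y <- Re(stats::fft(stats::fft(p) * stats::fft(kp), inverse = TRUE)) / (np * mp)
  y[kh + seq_len(n), kw + seq_len(m), drop = FALSE]
}

# Running min/max along one margin with a window of half-width r.
# Pixels outside the image act as +Inf (min) or -Inf (max), i.e. the border
# window simply shrinks.
minmax_1d <- function(x, r, op, margin) {
  pad <- if (identical(op, pmin)) Inf else -Inf
  out <- x
  for (d in seq_len(r)) {
    if (margin == 1L) {
      fwd <- rbind(x[-seq_len(d), , drop = FALSE], matrix(pad, d, ncol(x)))
      bwd <- rbind(matrix(pad, d, ncol(x)), x[seq_len(nrow(x) - d), , drop = FALSE])
    } else {
      fwd <- cbind(x[, -seq_len(d), drop = FALSE], matrix(pad, nrow(x), d))
      bwd <- cbind(matrix(pad, nrow(x), d), x[, seq_len(ncol(x) - d), drop = FALSE])
    }
    out <- op(out, fwd, bwd)
  }
  out
}

#' Grayscale erosion/dilation with a square structuring element
#'
#' @param x Numeric matrix.
#' @param radius Structuring-element radius in pixels; the element is the
#'   `(2*radius+1)` square.
#' @return Numeric matrix.
#' @keywords internal
gray_erode <- function(x, radius) {
  minmax_1d(minmax_1d(x, radius, pmin, 1L), radius, pmin, 2L)
}

#' @rdname gray_erode
#' @keywords internal
gray_dilate <- function(x, radius) {
  minmax_1d(minmax_1d(x, radius, pmax, 1L), radius, pmax, 2L)
}

#' Grayscale white top-hat (image minus its opening)
#'
#' @inheritParams gray_erode
#' @keywords internal
gray_tophat <- function(x, radius) {
  x - gray_dilate(gray_erode(x, radius), radius)
}

#' Label connected components of a binary image
#'
#' Components are computed over the pixel adjacency graph (via igraph), using
#' 8-connectivity by default as is standard for spot detection.
#'
#' @param bin Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape; 0 is background, components are
#'   numbered from 1.
#' @export
label_components <- function(bin, connectivity = 8L) {
  stopifnot(is.matrix(bin), connectivity %in% c(4L, 8L))
  if (!is.logical(bin)) bin <- bin > 0
  lab <- matrix(0L, nrow(bin), ncol(bin))
  idx <- which(bin)
  if (length(idx) == 0L) return(lab)
  n <- nrow(bin)
  m <- ncol(bin)
  r <- ((idx - 1L) %% n) + 1L
  cc <- ((idx - 1L) %/% n) + 1L
  key <- integer(n * m)
  key[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (off in offs) {
    r2 <- r + off[1L]
    c2 <- cc + off[2L]
    ok <- r2 >= 1L & r2 <= n & c2 >= 1L & c2 <= m
    j <- (c2[ok] - 1L) * n + r2[ok]
    hit <- key[j] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(which(ok)[hit], key[j][hit]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}
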
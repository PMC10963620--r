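# Independent oracle implementations used to validate the pipeline's
# primitives. These deliberately use different algorithms/code paths than the
# package (shift-and-add convolution, BFS flood fill, explicit point-line
# geometry, a literal re-implementation of the outlier procedure).

# Dense shift-and-add convolution with edge replication.
oracle_conv2 <- function(x, k) {
  kh <- (nrow(k) - 1L) %/% 2L
  kw <- (ncol(k) - 1L) %/% 2L
  n <- nrow(x)
  m <- ncol(x)
  out <- matrix(0, n, m)
  for (di in -kh:kh) {
    ri <- pmin(pmax(seq_len(n) + di, 1L), n)
    for (dj in -kw:kw) {
      ci <- pmin(pmax(seq_len(m) + dj, 1L), m)
      out <- out + k[kh + 1L + di, kw + 1L + dj] * x[ri, ci]
    }
  }
  out
}

oracle_gauss1d <- function(sigma) {
  h <- max(1L, ceiling(4 * sigma))
  v <- exp(-((-h):h)^2 / (2 * sigma^2))
  v / sum(v)
}

oracle_dog <- function(x, s1, s2) {
  k1 <- oracle_gauss1d(s1)
  k2 <- oracle_gauss1d(s2)
  oracle_conv2(x, outer(k1, k1)) - oracle_conv2(x, outer(k2, k2))
}

# BFS flood-fill component count.
oracle_component_count <- function(bin, connectivity = 8L) {
  n <- nrow(bin)
  m <- ncol(bin)
  seen <- matrix(FALSE, n, m)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L) {
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  count <- 0L
  for (start in which(bin)) {
    i0 <- ((start - 1L) %% n) + 1L
    j0 <- ((start - 1L) %/% n) + 1L
    if (seen[i0, j0]) next
    count <- count + 1L
    queue <- list(c(i0, j0))
    seen[i0, j0] <- TRUE
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      for (r in seq_len(nrow(offs))) {
        i <- p[1L] + offs[r, 1L]
        j <- p[2L] + offs[r, 2L]
        if (i >= 1L && i <= n && j >= 1L && j <= m &&
            bin[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE
          queue[[length(queue) + 1L]] <- c(i, j)
        }
      }
    }
  }
  count
}

# Exhaustive chord-distance triangle threshold (explicit line equation).
oracle_triangle <- function(plane, bins = 256L) {
  lo <- min(plane)
  hi <- max(plane)
  if (!(hi > lo)) return(hi)
  s <- (plane - lo) / (hi - lo)
  h <- tabulate(pmin(bins, floor(s * bins) + 1L), nbins = bins)
  pk <- which.max(h)
  nz <- which(h > 0L)
  end <- if ((nz[length(nz)] - pk) >= (pk - nz[1L])) nz[length(nz)] else nz[1L]
  if (end == pk) return(lo + (pk - 0.5) / bins * (hi - lo))
  # line through (pk, h[pk]) and (end, h[end]) as a*x + b*y + c = 0
  a <- h[end] - h[pk]
  b <- -(end - pk)
  cc <- -(a * pk + b * h[pk])
  ii <- if (end > pk) pk:end else end:pk
  d <- abs(a * ii + b * h[ii] + cc) / sqrt(a^2 + b^2)
  t_bin <- ii[which.max(d)]
  lo + (t_bin - 0.5) / bins * (hi - lo)
}

# Literal re-implementation of the constant-model ROUT procedure.
oracle_rout <- function(values, q = 0.10) {
  n <- length(values)
  if (n < 3L) return(integer(0))
  resid <- values - median(values)
  rsdr <- quantile(abs(resid), 0.6827, names = FALSE) * sqrt(n / (n - 1))
  tt <- if (rsdr > 0) abs(resid) / rsdr else ifelse(resid == 0, 0, Inf)
  p <- 2 * pt(-tt, df = n - 1)
  ord <- order(p, -abs(resid))
  flagged <- integer(0)
  for (i in seq_len(n)) {
    if (p[ord[i]] < q * i / n) flagged <- c(flagged, ord[i]) else break
  }
  sort(flagged)
}

# Exhaustive optimal one-to-one assignment (small instances): maximum number
# of matches within tolerance, by recursion over detected points.
oracle_max_matching <- function(det, tru, tol) {
  ok <- sqrt(outer(det[, 1L], tru[, 1L], "-")^2 +
               outer(det[, 2L], tru[, 2L], "-")^2) <= tol
  best <- 0L
  recurse <- function(i, used) {
    if (i > nrow(ok)) return(0L)
    top <- recurse(i + 1L, used)  # skip detected i
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      top <- max(top, 1L + recurse(i + 1L, used))
      used[j] <- FALSE
    }
    top
  }
  if (nrow(ok) == 0L || ncol(ok) == 0L) return(0L)
  recurse(1L, rep(FALSE, ncol(ok)))
}

# Small, fast scene settings for unit tests.
small_scene_params <- function(seed = 1L, ...) {
  args <- list(size = 128L, n_planes = 3L, n_branches = 6L,
               branch_length = 90L, n_puncta = 10L, soma_margin = 30L,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scene_params, args)
}
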
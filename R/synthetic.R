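# Seeded synthetic two-channel scenes with ground truth: neurite arbors with
# somata in the structural channel, Gaussian puncta on the neurites in the
# puncta channel, Poisson shot noise plus Gaussian read noise, and
# longitudinal transforms (punctum loss, synaptogenesis drift, bleaching,
# diffuse-label redistribution) for whole-plate fixtures.

#' Scene generator parameters
#'
#' Defaults emulate the assay's acquisition geometry (0.15 um/px, 10 z-planes
#' at 1 um) at a reduced field size, with punctum spacing (18 px = 2.7 um)
#' and lognormal amplitude spread chosen so that enhanced objects fall inside
#' the 6--200 px size window and standard puncta have local SNR of about
#' 2--4.
#'
#' @param size Image side length in pixels.
#' @param pixel_size Lateral pixel size (um/px).
#' @param n_planes,z_step Z geometry; signal is split over 3 adjacent planes
#'   (weights 0.5/1/0.5) so the maximum projection recovers the 2-D design.
#' @param n_somata,soma_radius,soma_margin Somata count, radius (px) and the
#'   exclusion radius around soma centres within which no puncta are placed
#'   (the loose soma mask extends well beyond the soma proper).
#' @param n_branches,branch_length,branch_width,branch_jitter Neurite arbor:
#'   branches per soma, their length and width in px, and the angular jitter
#'   (radians/step) of the random walk that draws them.
#' @param n_puncta Number of puncta to place on the neurite skeleton.
#' @param min_separation Minimum punctum separation (Chebyshev, px).
#' @param amplitude,amplitude_sdlog Lognormal punctum peak amplitude
#'   (photons) above background: `rlnorm(log(amplitude), amplitude_sdlog)`.
#' @param punctum_sigma Gaussian sigma of a rendered punctum (px).
#' @param background,bleed Puncta-channel background level and diffuse
#'   neurite bleed-through (photons).
#' @param struct_background,struct_neurite,struct_soma Structural-channel
#'   levels (photons).
#' @param read_noise Gaussian read-noise sigma (photons), added to Poisson
#'   shot noise.
#' @param off_neurite_fraction Fraction of puncta placed anywhere in the
#'   field instead of on the skeleton (default 0).
#' @param seed Integer seed fixing all randomness of the scene.
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(size = 384L, pixel_size = 0.15, n_planes = 10L,
                         z_step = 1, n_somata = 1L, soma_radius = 14L,
                         soma_margin = 45L, n_branches = 16L,
                         branch_length = 260L, branch_width = 3L,
                         branch_jitter = 0.08, n_puncta = 70L,
                         min_separation = 18L, amplitude = 800,
                         amplitude_sdlog = 0.35, punctum_sigma = 1.8,
                         background = 100, bleed = 10,
                         struct_background = 20, struct_neurite = 300,
                         struct_soma = 800, read_noise = 3,
                         off_neurite_fraction = 0, seed = 1L) {
  p <- as.list(environment())
  counts <- c("size", "n_planes", "n_somata", "n_branches", "branch_length",
              "n_puncta")
  for (f in counts) {
    if (p[[f]] < 0) stop(f, " must be non-negative")
  }
  if (p$size < 32L) stop("size must be at least 32 px")
  if (p$punctum_sigma <= 0) stop("punctum_sigma must be positive")
  if (p$off_neurite_fraction < 0 || p$off_neurite_fraction > 1) {
    stop("off_neurite_fraction must be in [0, 1]")
  }
  structure(p, class = "scene_params")
}

# Soma centres: single soma at the centre, otherwise a jittered grid.
soma_centres <- function(size, n_somata) {
  if (n_somata == 0L) return(matrix(numeric(0), 0L, 2L))
  if (n_somata == 1L) return(matrix(size / 2, 1L, 2L))
  g <- ceiling(sqrt(n_somata))
  pts <- expand.grid(i = seq_len(g), j = seq_len(g))[seq_len(n_somata), ]
  cbind(size * (pts$i - 0.5) / g, size * (pts$j - 0.5) / g)
}

# Draw the skeleton, soma and thickened-neurite geometry for a scene.
draw_geometry <- function(p) {
  size <- p$size
  sk <- matrix(FALSE, size, size)
  soma <- matrix(FALSE, size, size)
  excl <- matrix(FALSE, size, size)
  ctr <- soma_centres(size, p$n_somata)
  rg <- row(sk)
  cg <- col(sk)
  for (s in seq_len(nrow(ctr))) {
    d2 <- (rg - ctr[s, 1L])^2 + (cg - ctr[s, 2L])^2
    soma[d2 <= p$soma_radius^2] <- TRUE
    excl[d2 <= p$soma_margin^2] <- TRUE
    for (b in seq_len(p$n_branches)) {
      ang <- runif(1, 0, 2 * pi)
      pos <- ctr[s, ] + p$soma_radius * c(cos(ang), sin(ang))
      for (step in seq_len(p$branch_length)) {
        ang <- ang + rnorm(1, 0, p$branch_jitter)
        pos <- pos + c(cos(ang), sin(ang))
        i <- round(pos[1L])
        j <- round(pos[2L])
        if (i < 2L || j < 2L || i > size - 1L || j > size - 1L) break
        sk[i, j] <- TRUE
      }
    }
  }
  thick_r <- max(0L, (as.integer(p$branch_width) - 1L) %/% 2L)
  neurite <- if (thick_r > 0L) gray_dilate(sk + 0, thick_r) > 0 else sk
  list(skeleton = sk, soma = soma, neurite = neurite | soma,
       punctum_zone = excl)
}

# Sample punctum positions on the skeleton with a Chebyshev separation.
sample_positions <- function(geom, p) {
  size <- p$size
  pool <- which(geom$skeleton & !geom$punctum_zone)
  n_off <- round(p$n_puncta * p$off_neurite_fraction)
  if (n_off > 0L) {
    pool_off <- setdiff(which(!geom$neurite), pool)
    pool <- c(sample(pool), sample(pool_off))
  } else {
    pool <- sample(pool)
  }
  sep <- as.integer(p$min_separation)
  taken <- matrix(FALSE, size, size)
  keep <- integer(0)
  for (ix in pool) {
    if (length(keep) >= p$n_puncta) break
    i <- ((ix - 1L) %% size) + 1L
    j <- ((ix - 1L) %/% size) + 1L
    if (taken[i, j]) next
    keep <- c(keep, ix)
    taken[max(1L, i - sep):min(size, i + sep),
          max(1L, j - sep):min(size, j + sep)] <- TRUE
  }
  if (length(keep) < p$n_puncta) {
    warning(sprintf("placed %d of %d puncta (skeleton capacity reached)",
                    length(keep), p$n_puncta))
  }
  tibble::tibble(
    row = ((keep - 1L) %% size) + 1L,
    col = ((keep - 1L) %/% size) + 1L
  )
}

# Additive 2-D expected punctum field from a truth table.
puncta_field <- function(truth, p) {
  size <- p$size
  field <- matrix(0, size, size)
  if (nrow(truth) == 0L) return(field)
  h <- as.integer(ceiling(3 * p$punctum_sigma))
  o <- (-h):h
  stamp <- outer(exp(-o^2 / (2 * p$punctum_sigma^2)),
                 exp(-o^2 / (2 * p$punctum_sigma^2)))
  for (q in seq_len(nrow(truth))) {
    ii <- (truth$row[q] - h):(truth$row[q] + h)
    jj <- (truth$col[q] - h):(truth$col[q] + h)
    oi <- ii >= 1L & ii <= size
    oj <- jj >= 1L & jj <= size
    field[ii[oi], jj[oj]] <- field[ii[oi], jj[oj]] +
      truth$amplitude[q] * stamp[oi, oj]
  }
  field
}

# Render both channels as noisy z-stacks. `extra_puncta_2d` is an additive
# expected field in the puncta channel sharing the structure's z profile
# (used for diffuse-label redistribution).
render_channels <- function(geom, truth, p, extra_puncta_2d = NULL) {
  size <- p$size
  nz <- as.integer(p$n_planes)
  zc <- max(1L, (nz + 1L) %/% 2L)
  wz <- function(z, centre) {
    if (z == centre) 1 else if (abs(z - centre) == 1L) 0.5 else 0
  }
  struct_pattern <- p$struct_neurite * (geom$neurite & !geom$soma) +
    p$struct_soma * geom$soma
  bleed_pattern <- p$bleed * geom$neurite
  if (!is.null(extra_puncta_2d)) bleed_pattern <- bleed_pattern + extra_puncta_2d
  h <- as.integer(ceiling(3 * p$punctum_sigma))
  o <- (-h):h
  stamp <- outer(exp(-o^2 / (2 * p$punctum_sigma^2)),
                 exp(-o^2 / (2 * p$punctum_sigma^2)))
  noisy <- function(expected) {
    pmax(matrix(rpois(length(expected), pmax(expected, 0)) +
                  rnorm(length(expected), 0, p$read_noise), size, size), 0)
  }
  s_planes <- vector("list", nz)
  p_planes <- vector("list", nz)
  for (z in seq_len(nz)) {
    s_exp <- p$struct_background + wz(z, zc) * struct_pattern
    p_exp <- p$background + wz(z, zc) * bleed_pattern
    if (nrow(truth)) {
      sel <- which(abs(truth$z - z) <= 1L)
      for (q in sel) {
        w <- wz(z, truth$z[q])
        ii <- (truth$row[q] - h):(truth$row[q] + h)
        jj <- (truth$col[q] - h):(truth$col[q] + h)
        oi <- ii >= 1L & ii <= size
        oj <- jj >= 1L & jj <= size
        p_exp[ii[oi], jj[oj]] <- p_exp[ii[oi], jj[oj]] +
          w * truth$amplitude[q] * stamp[oi, oj]
      }
    }
    s_planes[[z]] <- noisy(s_exp)
    p_planes[[z]] <- noisy(p_exp)
  }
  list(structure = zstack(s_planes, p$z_step, p$pixel_size),
       puncta = zstack(p_planes, p$z_step, p$pixel_size))
}

#' Generate a ground-truthed synthetic scene
#'
#' Renders somata as bright disks and neurites as random branched curves into
#' the structural channel, and Gaussian puncta on the neurite skeleton (plus
#' diffuse neurite bleed-through) into the puncta channel. Signal is split
#' across 3 adjacent z-planes so the maximum projection recovers the design;
#' Poisson shot noise and Gaussian read noise are applied per plane. All
#' randomness is fixed by `params$seed`.
#'
#' @param params A [scene_params()] list.
#' @return Object of class `synthetic_scene`: `structure` and `puncta`
#'   ([zstack()]s), `truth_skeleton`, `truth_soma`, `truth_neurite` (logical
#'   matrices), `truth_puncta` (tibble: row, col, amplitude, z), `params`.
#' @export
make_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  geom <- draw_geometry(params)
  pos <- sample_positions(geom, params)
  truth <- tibble::tibble(
    row = pos$row, col = pos$col,
    amplitude = rlnorm(nrow(pos), log(params$amplitude),
                       params$amplitude_sdlog),
    z = if (params$n_planes >= 3L) {
      sample(2:(params$n_planes - 1L), nrow(pos), replace = TRUE)
    } else {
      rep(1L, nrow(pos))
    }
  )
  ch <- render_channels(geom, truth, params)
  structure(
    list(structure = ch$structure, puncta = ch$puncta,
         truth_skeleton = geom$skeleton, truth_soma = geom$soma,
         truth_neurite = geom$neurite, punctum_zone = geom$punctum_zone,
         truth_puncta = truth, params = params),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d plane(s), %d puncta (seed %d)\n",
              x$params$size, x$params$size, x$params$n_planes,
              nrow(x$truth_puncta), x$params$seed))
  invisible(x)
}

#' Longitudinal loss specification
#'
#' Controls how [advance_timepoint()] evolves a scene: per-treatment loss
#' fractions, photobleaching, and the synaptogenesis drift of untreated
#' wells. Defaults emulate the assay's control behaviours: untreated wells
#' gain about 5% of puncta per day while the network-activity control loses
#' about 17%.
#'
#' @param loss_fraction Named numeric vector of Bernoulli loss fractions per
#'   treatment label; unlisted treatments fall back to `default_loss`.
#' @param default_loss Loss fraction for unlisted treatments.
#' @param bleaching Multiplicative amplitude factor per timepoint, in (0, 1].
#' @param new_puncta_rate Expected number of new puncta per existing punctum
#'   per timepoint (applied to untreated/vehicle wells by the plate fixture).
#' @return List of class `loss_spec`.
#' @export
loss_spec <- function(loss_fraction = c(untreated = 0, vehicle = 0,
                                        `pic-4ap` = 0.17, drug = 0.25),
                      default_loss = 0, bleaching = 1,
                      new_puncta_rate = 0.05) {
  if (any(loss_fraction < 0 | loss_fraction > 1)) {
    stop("loss fractions must be in [0, 1]")
  }
  if (!(bleaching > 0 && bleaching <= 1)) stop("bleaching must be in (0, 1]")
  structure(list(loss_fraction = loss_fraction, default_loss = default_loss,
                 bleaching = bleaching, new_puncta_rate = new_puncta_rate),
            class = "loss_spec")
}

lookup_loss <- function(spec, treatment) {
  if (!is.null(treatment) && treatment %in% names(spec$loss_fraction)) {
    unname(spec$loss_fraction[[treatment]])
  } else {
    spec$default_loss
  }
}

#' Advance a synthetic scene by one timepoint
#'
#' Removes a Bernoulli(`loss_fraction`) subset of the truth puncta, adds new
#' puncta at `new_puncta_rate` per surviving punctum, scales amplitudes by
#' the bleaching factor, and re-renders both channels with fresh noise. The
#' neurite geometry is preserved (the same cells are re-imaged).
#'
#' @param scene A [make_scene()] result.
#' @param spec A [loss_spec()].
#' @param treatment Treatment label used to look up the loss fraction.
#' @param seed Seed for the removal/addition/noise randomness.
#' @param new_rate Overrides `spec$new_puncta_rate` (e.g. 0 for treated
#'   wells); default 0.
#' @return A new `synthetic_scene` at the next timepoint.
#' @export
advance_timepoint <- function(scene, spec = loss_spec(), treatment = NULL,
                              seed = scene$params$seed + 1L, new_rate = 0) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(spec, "loss_spec"))
  set.seed(seed)
  p <- scene$params
  loss <- lookup_loss(spec, treatment)
  truth <- scene$truth_puncta
  keep <- if (nrow(truth)) rbinom(nrow(truth), 1L, 1 - loss) == 1L else logical(0)
  truth <- truth[keep, , drop = FALSE]
  truth$amplitude <- truth$amplitude * spec$bleaching
  n_new <- if (new_rate > 0 && nrow(truth)) rpois(1L, new_rate * nrow(truth)) else 0L
  if (n_new > 0L) {
    geom <- list(skeleton = scene$truth_skeleton, soma = scene$truth_soma,
                 neurite = scene$truth_neurite,
                 punctum_zone = scene$punctum_zone)
    # block positions already occupied by surviving puncta
    sep <- as.integer(p$min_separation)
    blocked <- matrix(FALSE, p$size, p$size)
    for (q in seq_len(nrow(truth))) {
      blocked[max(1L, truth$row[q] - sep):min(p$size, truth$row[q] + sep),
              max(1L, truth$col[q] - sep):min(p$size, truth$col[q] + sep)] <- TRUE
    }
    geom$punctum_zone <- geom$punctum_zone | blocked
    p_new <- p
    p_new$n_puncta <- n_new
    pos <- suppressWarnings(sample_positions(geom, p_new))
    if (nrow(pos)) {
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        row = pos$row, col = pos$col,
        amplitude = rlnorm(nrow(pos), log(p$amplitude), p$amplitude_sdlog),
        z = if (p$n_planes >= 3L) {
          sample(2:(p$n_planes - 1L), nrow(pos), replace = TRUE)
        } else {
          rep(1L, nrow(pos))
        }
      ))
    }
  }
  geom <- list(skeleton = scene$truth_skeleton, soma = scene$truth_soma,
               neurite = scene$truth_neurite)
  ch <- render_channels(geom, truth, p)
  out <- scene
  out$structure <- ch$structure
  out$puncta <- ch$puncta
  out$truth_puncta <- truth
  out
}

#' Diffuse-label control transform
#'
#' Emulates blocked PSD95 palmitoylation (2-BP): each punctum's integrated
#' intensity is redistributed uniformly along the neurite, conserving total
#' expected channel intensity, and the truth puncta list is emptied. The
#' assay should not identify the resulting diffuse labelling as PSDs.
#'
#' @param scene A [make_scene()] result.
#' @param seed Seed for the fresh rendering noise.
#' @return A new `synthetic_scene` with `truth_puncta` empty.
#' @export
make_diffuse_control <- function(scene, seed = scene$params$seed + 1L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  set.seed(seed)
  p <- scene$params
  total_flux <- sum(puncta_field(scene$truth_puncta, p))
  n_px <- sum(scene$truth_neurite)
  diffuse <- matrix(0, p$size, p$size)
  if (n_px > 0L) diffuse[scene$truth_neurite] <- total_flux / n_px
  truth <- scene$truth_puncta[0L, , drop = FALSE]
  geom <- list(skeleton = scene$truth_skeleton, soma = scene$truth_soma,
               neurite = scene$truth_neurite)
  ch <- render_channels(geom, truth, p, extra_puncta_2d = diffuse)
  out <- scene
  out$structure <- ch$structure
  out$puncta <- ch$puncta
  out$truth_puncta <- truth
  out
}

#' Score detections against ground truth
#'
#' Greedy nearest-neighbour one-to-one matching within a tolerance:
#' `precision = matched / detected`, `recall = matched / truth`, with the
#' empty-set conventions precision = 1 when nothing was detected and
#' recall = 1 when there is no truth.
#'
#' @param truth Tibble or matrix of true centroids (row, col).
#' @param detected A `psd_puncta` object, or a tibble with `centroid_r`,
#'   `centroid_c` (accepted puncta only).
#' @param tol Matching tolerance in pixels (> 0).
#' @return Tibble with `n_truth`, `n_detected`, `matched`, `precision`,
#'   `recall`, `f1`.
#' @export
score_detection <- function(truth, detected, tol = 2) {
  stopifnot(tol > 0)
  if (inherits(detected, "psd_puncta")) {
    detected <- detected$puncta[detected$puncta$accepted, ]
  }
  det <- cbind(detected$centroid_r, detected$centroid_c)
  tru <- if (is.matrix(truth)) truth else cbind(truth$row, truth$col)
  n_det <- nrow(det)
  n_tru <- nrow(tru)
  matched <- 0L
  if (n_det > 0L && n_tru > 0L) {
    d <- sqrt(outer(det[, 1L], tru[, 1L], "-")^2 +
                outer(det[, 2L], tru[, 2L], "-")^2)
    used <- rep(FALSE, n_tru)
    for (i in order(apply(d, 1L, min))) {
      j <- which.min(ifelse(used, Inf, d[i, ]))
      if (length(j) && is.finite(d[i, j]) && d[i, j] <= tol) {
        matched <- matched + 1L
        used[j] <- TRUE
      }
    }
  }
  precision <- if (n_det == 0L) 1 else matched / n_det
  recall <- if (n_tru == 0L) 1 else matched / n_tru
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble::tibble(n_truth = n_tru, n_detected = n_det, matched = matched,
                 precision = precision, recall = recall, f1 = f1)
}

#' Write a full synthetic plate fixture to disk
#'
#' Generates a directory tree of two-channel TIFF pairs for a plate (wells x
#' ROIs x timepoints) together with `manifest.csv` and a ground-truth table
#' `truth.csv`, emulating the assay's control layout: untreated wells drift
#' up by the synaptogenesis rate, the diffuse-label control redistributes
#' punctum intensity, the network-activity control loses its configured
#' fraction (default 17%), and drug wells lose their configured fractions.
#'
#' @param dir Output directory (created).
#' @param layout Tibble with one row per well: `well_id`, `treatment`,
#'   `role`. Default: one untreated, one diffuse-label control, one activity
#'   control, one drug well.
#' @param spec A [loss_spec()].
#' @param plate_id Plate identifier.
#' @param n_rois ROIs per well.
#' @param timepoints Hours, starting at the baseline 0.
#' @param params [scene_params()] shared by all ROIs (per-ROI seeds derived
#'   from `seed`).
#' @param seed Base seed.
#' @return Invisibly, a list with `manifest` and `truth` tibbles (also
#'   written as CSV).
#' @export
make_plate_fixture <- function(dir,
                               layout = tibble::tibble(
                                 well_id = c("A1", "A2", "A3", "A4"),
                                 treatment = c("untreated", "2-bp",
                                               "pic-4ap", "drug"),
                                 role = c("untreated", "positive-control-A",
                                          "positive-control-B", "drug")
                               ),
                               spec = loss_spec(), plate_id = "P1",
                               n_rois = 2L, timepoints = c(0, 24),
                               params = scene_params(), seed = 1L) {
  stopifnot(timepoints[1L] == 0, length(timepoints) >= 2L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tidyr::crossing(
    tibble::tibble(plate_id = plate_id), layout,
    roi_index = seq_len(n_rois)
  ) |>
    dplyr::mutate(timepoints = paste(timepoints, collapse = ";")) |>
    dplyr::select("plate_id", "well_id", "roi_index", "treatment", "role",
                  "timepoints")
  truth_rows <- list()
  for (w in seq_len(nrow(layout))) {
    for (r in seq_len(n_rois)) {
      p <- params
      p$seed <- as.integer(seed + 131L * w + 17L * r)
      scene <- make_scene(p)
      role <- layout$role[w]
      treatment <- layout$treatment[w]
      for (ti in seq_along(timepoints)) {
        t_h <- timepoints[ti]
        if (ti > 1L) {
          step_seed <- p$seed + 7919L * ti
          scene <- if (role == "positive-control-A") {
            make_diffuse_control(scene, seed = step_seed)
          } else if (role %in% c("untreated", "vehicle")) {
            advance_timepoint(scene, spec, treatment, seed = step_seed,
                              new_rate = spec$new_puncta_rate)
          } else {
            advance_timepoint(scene, spec, treatment, seed = step_seed)
          }
        }
        write_stack(scene$structure,
                    roi_image_path(dir, plate_id, layout$well_id[w], r, t_h,
                                   "structure"))
        write_stack(scene$puncta,
                    roi_image_path(dir, plate_id, layout$well_id[w], r, t_h,
                                   "puncta"))
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          plate_id = plate_id, well_id = layout$well_id[w], roi_index = r,
          treatment = treatment, role = role, timepoint = t_h,
          n_truth_puncta = nrow(scene$truth_puncta)
        )
      }
    }
  }
  truth <- dplyr::bind_rows(truth_rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  readr::write_csv(truth, file.path(dir, "truth.csv"))
  invisible(list(manifest = manifest, truth = truth))
}
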
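# Reading/writing multi-page TIFF z-stacks, plate manifests and the tabular
# outputs consumed by downstream statistics.

#' Construct a z-stack
#'
#' A z-stack is an ordered list of equally shaped image planes (numeric
#' matrices with non-negative intensities) plus acquisition geometry.
#'
#' @param planes List of numeric matrices, all with identical dimensions.
#' @param z_step Plane spacing in micrometres.
#' @param pixel_size Lateral pixel size in micrometres per pixel.
#' @return An object of class `zstack`.
#' @export
zstack <- function(planes, z_step = 1, pixel_size = 0.15) {
  stopifnot(is.list(planes), length(planes) >= 1L)
  dims <- dim(planes[[1L]])
  for (p in planes) {
    if (!is.matrix(p)) stop("all planes must be matrices")
    if (!identical(dim(p), dims)) stop("all planes must share the same shape")
    if (any(p < 0)) stop("intensities must be non-negative")
  }
  structure(
    list(planes = planes, z_step = z_step, pixel_size = pixel_size),
    class = "zstack"
  )
}

#' @export
dim.zstack <- function(x) c(dim(x$planes[[1L]]), length(x$planes))

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<zstack> %d x %d px, %d plane(s), z step %g um, %g um/px\n",
              d[1L], d[2L], d[3L], x$z_step, x$pixel_size))
  invisible(x)
}

#' Maximum-intensity projection of a z-stack
#'
#' All 2-D processing in the pipeline operates on the maximum projection of
#' each channel, the representation in which puncta are counted.
#'
#' @param stack A [zstack()].
#' @return A numeric matrix with `out[r, c] = max` over planes.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  Reduce(pmax, stack$planes)
}

#' Read a multi-page grayscale TIFF as a z-stack
#'
#' Raw 8/16-bit sample values are preserved bit-exact (no rescaling) and
#' promoted to double for processing.
#'
#' @param path TIFF file path.
#' @inheritParams zstack
#' @return A [zstack()].
#' @export
read_stack <- function(path, z_step = 1, pixel_size = 0.15) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF has zero pages: ", path)
  planes <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first sample if multi-sample
    matrix(as.numeric(p), nrow(p), ncol(p))
  })
  zstack(planes, z_step = z_step, pixel_size = pixel_size)
}

#' Write a z-stack as a multi-page grayscale TIFF
#'
#' Intensities are stored as unsigned integers of the requested bit depth;
#' values are clamped to the representable range, so a stack of integral
#' intensities in range round-trips bit-exactly through [read_stack()].
#'
#' @param stack A [zstack()].
#' @param path Output file path.
#' @param bits 8 or 16.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "zstack"), bits %in% c(8L, 16L))
  top <- 2^bits - 1
  pages <- lapply(stack$planes, function(p) pmin(pmax(round(p), 0), top) / top)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Default on-disk layout for a ROI/timepoint image
#'
#' `<root>/<plate>/<well>/roi<index>_<t>h_<channel>.tif`.
#'
#' @param root Image root directory.
#' @param plate_id,well_id,roi_index,timepoint Identity of the image.
#' @param channel `"structure"` (cell fill) or `"puncta"`.
#' @return File path.
#' @export
roi_image_path <- function(root, plate_id, well_id, roi_index, timepoint,
                           channel = c("structure", "puncta")) {
  channel <- match.arg(channel)
  file.path(root, plate_id, well_id,
            sprintf("roi%d_%gh_%s.tif", as.integer(roi_index),
                    as.numeric(timepoint), channel))
}

#' Read a two-channel ROI image pair
#'
#' Reads the structural (cell-fill) and puncta channels for one ROI and one
#' timepoint and attaches its plate/well/ROI/treatment identity.
#'
#' @param structure_path,puncta_path Multi-page TIFF paths.
#' @param meta A one-row data frame (manifest row) with at least `plate_id`,
#'   `well_id`, `roi_index`, `timepoint`; `treatment` and `role` are carried
#'   through when present.
#' @inheritParams zstack
#' @return An object of class `roi_pair` with elements `structure`, `puncta`
#'   (both [zstack()]) and `meta` (a tibble row).
#' @export
read_roi_pair <- function(structure_path, puncta_path, meta,
                          z_step = 1, pixel_size = 0.15) {
  s <- read_stack(structure_path, z_step = z_step, pixel_size = pixel_size)
  p <- read_stack(puncta_path, z_step = z_step, pixel_size = pixel_size)
  roi_pair(s, p, meta)
}

#' @rdname read_roi_pair
#' @param structure,puncta [zstack()]s for the two channels.
#' @export
roi_pair <- function(structure, puncta, meta) {
  stopifnot(inherits(structure, "zstack"), inherits(puncta, "zstack"))
  if (!identical(dim(structure), dim(puncta))) {
    stop("structure and puncta stacks must share the same shape")
  }
  meta <- tibble::as_tibble(as.list(meta)[!vapply(as.list(meta), is.null, TRUE)])
  structure(list(structure = structure, puncta = puncta, meta = meta),
            class = "roi_pair")
}

#' @export
print.roi_pair <- function(x, ...) {
  d <- dim(x$structure)
  cat(sprintf("<roi_pair> %d x %d px, %d plane(s)\n", d[1L], d[2L], d[3L]))
  print(x$meta)
  invisible(x)
}

manifest_roles <- c("untreated", "positive-control-A", "positive-control-B",
                    "drug", "vehicle")

#' Read and validate a plate manifest
#'
#' The manifest maps `(plate_id, well_id, roi_index)` to a treatment label, a
#' control role and the timepoints available. Roles: `untreated`,
#' `positive-control-A` (diffuse-label control), `positive-control-B`
#' (network-activity control), `drug`, `vehicle`. `timepoints` is a
#' `;`-separated list of hours (e.g. `"0;24;48"`).
#'
#' @param path CSV path with columns `plate_id, well_id, roi_index, treatment,
#'   role, timepoints`.
#' @return A tibble, one row per ROI, with `timepoints` parsed to a list of
#'   numeric vectors.
#' @export
read_manifest <- function(path) {
  man <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           plate_id = readr::col_character(),
                           well_id = readr::col_character(),
                           roi_index = readr::col_integer(),
                           treatment = readr::col_character(),
                           role = readr::col_character(),
                           timepoints = readr::col_character()
                         ))
  validate_manifest(man)
}

#' @rdname read_manifest
#' @param manifest A data frame in manifest form (as from [read_manifest()]).
#' @export
validate_manifest <- function(manifest) {
  need <- c("plate_id", "well_id", "roi_index", "treatment", "role", "timepoints")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(manifest$role), manifest_roles)
  if (length(bad)) stop("unknown manifest roles: ", paste(bad, collapse = ", "))
  key <- paste(manifest$plate_id, manifest$well_id, manifest$roi_index)
  if (anyDuplicated(key)) stop("duplicate (plate, well, roi) rows in manifest")
  no_unt <- setdiff(unique(manifest$plate_id),
                    unique(manifest$plate_id[manifest$role == "untreated"]))
  if (length(no_unt)) {
    stop("plates without an untreated group: ", paste(no_unt, collapse = ", "))
  }
  man <- tibble::as_tibble(manifest)
  if (is.character(man$timepoints)) {
    man$timepoints <- lapply(strsplit(man$timepoints, ";", fixed = TRUE),
                             as.numeric)
  }
  man
}

counts_table_cols <- c("plate_id", "well_id", "roi_index", "treatment", "role",
                       "timepoint", "count_t0", "count", "pct_change",
                       "included", "exclusion_reason")

#' Write/read the per-ROI change-record table
#'
#' One row per (plate, well, roi, later timepoint) with paired counts, percent
#' change in PSDs, inclusion flag and exclusion reason. Excluded rows are
#' retained with their reason, never dropped. Columns are written in a stable
#' order and round-trip losslessly.
#'
#' @param records Change-record tibble (see [build_change_records()]).
#' @param path CSV path.
#' @export
write_counts_table <- function(records, path) {
  records <- tibble::as_tibble(records)
  chr_cols <- c("plate_id", "well_id", "treatment", "role", "exclusion_reason")
  for (col in counts_table_cols) {
    if (!col %in% names(records)) {
      records[[col]] <- if (col %in% chr_cols) {
        rep(NA_character_, nrow(records))
      } else if (col == "roi_index") {
        rep(NA_integer_, nrow(records))
      } else if (col == "included") {
        rep(NA, nrow(records))
      } else {
        rep(NA_real_, nrow(records))
      }
    }
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(records[counts_table_cols], path, na = "")
  invisible(path)
}

#' @rdname write_counts_table
#' @export
read_counts_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = "",
                  col_types = readr::cols(
                    plate_id = readr::col_character(),
                    well_id = readr::col_character(),
                    roi_index = readr::col_integer(),
                    treatment = readr::col_character(),
                    role = readr::col_character(),
                    timepoint = readr::col_double(),
                    count_t0 = readr::col_double(),
                    count = readr::col_double(),
                    pct_change = readr::col_double(),
                    included = readr::col_logical(),
                    exclusion_reason = readr::col_character()
                  ))
}
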
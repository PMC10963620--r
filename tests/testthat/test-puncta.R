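# Punctum enhancement, segmentation, geometry, local SNR, and the
# four-filter exclusion cascade.

test_that("enhance_puncta flattens constants and is homogeneous of degree 2", {
  expect_equal(enhance_puncta(matrix(100, 48, 48)), matrix(0, 48, 48),
               tolerance = 1e-9)
  set.seed(41)
  x <- matrix(rexp(48 * 48, 1 / 50), 48, 48)
  expect_equal(enhance_puncta(2 * x), 4 * enhance_puncta(x),
               tolerance = 1e-8)
  # additive offsets cancel (blur is linear, top-hat removes constants)
  expect_equal(enhance_puncta(x + 77), enhance_puncta(x), tolerance = 1e-7)
  expect_true(all(enhance_puncta(x) >= 0))
})

test_that("enhance_puncta equals brute-force blur -> top-hat -> square", {
  # isolated Gaussian spot on flat background, checked in the interior
  x <- matrix(10, 64, 64)
  o <- (-4):4
  stamp <- 300 * outer(exp(-o^2 / 4), exp(-o^2 / 4))
  x[28 + o + 4, 36 + o + 4] <- x[28 + o + 4, 36 + o + 4] + stamp
  g <- oracle_gauss1d(5)
  blurred <- oracle_conv2(x, outer(g, g))
  # brute-force grayscale opening with an 11x11 box, evaluated per pixel
  r <- 5L
  n <- 64L
  ero <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    ero[i, j] <- min(blurred[max(1, i - r):min(n, i + r),
                             max(1, j - r):min(n, j + r)])
  }
  opn <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    opn[i, j] <- max(ero[max(1, i - r):min(n, i + r),
                         max(1, j - r):min(n, j + r)])
  }
  expect_equal(enhance_puncta(x), (blurred - opn)^2, tolerance = 1e-8)
})

test_that("segmentation separates spots and uses 8-connectivity", {
  img <- matrix(0, 64, 64)
  o <- (-3):3
  stamp <- 200 * outer(exp(-o^2 / 3), exp(-o^2 / 3))
  img[17 + o, 17 + o] <- stamp
  img[47 + o, 47 + o] <- stamp
  cand <- segment_candidates(enhance_puncta(img), img)
  expect_equal(nrow(cand), 2L)

  bin <- matrix(FALSE, 6, 6)
  bin[2, 2] <- TRUE
  bin[3, 3] <- TRUE
  expect_equal(max(label_components(bin, 8L)), 1L)
  expect_equal(max(label_components(bin, 4L)), 2L)
})

test_that("component labeling matches BFS flood fill on random fields", {
  set.seed(42)
  for (i in 1:10) {
    bin <- matrix(runif(900) < 0.35, 30, 30)
    expect_equal(max(label_components(bin, 8L)),
                 oracle_component_count(bin, 8L))
    expect_equal(max(label_components(bin, 4L)),
                 oracle_component_count(bin, 4L))
  }
})

test_that("max_extension: single pixel, 21-px line, and L-shape oracle", {
  expect_equal(max_extension(cbind(5L, 9L)), 0)
  line <- cbind(10L, 1:21)
  expect_equal(max_extension(line), 10)
  set.seed(43)
  for (i in 1:20) {
    px <- unique(cbind(sample.int(12, 15, TRUE), sample.int(12, 15, TRUE)))
    ctr <- colMeans(px)
    brute <- max(sqrt((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2))
    expect_equal(max_extension(px), brute)
  }
})

test_that("local SNR is the ratio of object mean to annulus mean", {
  # spot of amplitude A on flat background B; annulus is pure background
  img <- matrix(100, 40, 40)
  px <- as.matrix(expand.grid(row = 19:22, col = 19:22))
  img[px] <- 220
  cand_mask <- matrix(FALSE, 40, 40)
  cand_mask[px] <- TRUE
  res <- local_snr(px, img, cand_mask)
  expect_equal(res$mean_intensity, 220)
  expect_equal(res$background_mean, 100)
  expect_equal(res$snr, 2.2)
  # zero background -> Inf sentinel
  img0 <- matrix(0, 40, 40)
  img0[px] <- 50
  expect_equal(local_snr(px, img0, cand_mask)$snr, Inf)
  # annulus excludes other candidates: surround the spot with a bright ring
  # of candidate pixels and check the background ignores it
  ring_mask <- cand_mask
  img2 <- img
  for (i in 15:26) for (j in 15:26) {
    if (max(abs(i - 20.5), abs(j - 20.5)) > 2 &&
        max(abs(i - 20.5), abs(j - 20.5)) <= 4) {
      ring_mask[i, j] <- TRUE
      img2[i, j] <- 10000
    }
  }
  res2 <- local_snr(px, img2, ring_mask)
  expect_equal(res2$background_mean, 100)
})

test_that("filter cascade enforces the printed boundary values", {
  mk <- function(area, mext, snr) {
    # synthetic candidate with a mask-overlapping pixel set
    tibble::tibble(
      label = 1L, area = as.integer(area), centroid_r = 5, centroid_c = 5,
      max_extension = mext, mean_intensity = 10, snr = snr,
      pixels = list(cbind(row = 5L, col = 5L))
    )
  }
  mask <- matrix(TRUE, 10, 10)
  run <- function(area, mext, snr) {
    apply_filters(mk(area, mext, snr), mask)$count
  }
  expect_equal(run(5, 1, 2), 0L)    # below size window
  expect_equal(run(6, 1, 2), 1L)    # lower size boundary retained
  expect_equal(run(200, 1, 2), 1L)  # upper size boundary retained
  expect_equal(run(201, 1, 2), 0L)  # above size window
  expect_equal(run(50, 10, 2), 1L)  # elongation exactly 10 retained
  expect_equal(run(50, 10.01, 2), 0L)
  expect_equal(run(50, 1, 1.19), 0L)
  expect_equal(run(50, 1, 1.2), 1L) # SNR exactly 1.2 retained
  # mask criterion: no overlap -> rejected with reason "mask"
  res <- apply_filters(mk(50, 1, 2), matrix(FALSE, 10, 10))
  expect_equal(res$count, 0L)
  expect_equal(res$puncta$reject_reason, "mask")
})

test_that("rejection reasons follow the cascade order", {
  cand <- tibble::tibble(
    label = 1:3,
    area = c(3L, 50L, 50L),
    centroid_r = 5, centroid_c = 5,
    max_extension = c(12, 12, 2),
    mean_intensity = 10,
    snr = c(2, 2, 1.0),
    pixels = list(cbind(row = 5L, col = 5L), cbind(row = 5L, col = 5L),
                  cbind(row = 5L, col = 5L))
  )
  res <- apply_filters(cand, matrix(TRUE, 10, 10))
  # elongation fails before size; SNR is only reached by survivors
  expect_equal(res$puncta$reject_reason, c("elongation", "elongation", "snr"))
})

test_that("tightening any cutoff never increases the accepted count", {
  set.seed(44)
  mask <- matrix(runif(400) > 0.4, 20, 20)
  cand <- tibble::tibble(
    label = 1:200,
    area = sample(1:250, 200, TRUE),
    centroid_r = runif(200, 1, 20), centroid_c = runif(200, 1, 20),
    max_extension = runif(200, 0, 15),
    mean_intensity = 10,
    snr = runif(200, 0.5, 3),
    pixels = lapply(1:200, function(i) {
      cbind(row = sample.int(20, 1), col = sample.int(20, 1))
    })
  )
  base <- apply_filters(cand, mask)$count
  expect_lte(apply_filters(cand, mask, size_range = c(10L, 150L))$count, base)
  expect_lte(apply_filters(cand, mask, elongation_max = 5)$count, base)
  expect_lte(apply_filters(cand, mask, snr_min = 2)$count, base)
})

test_that("count_puncta returns zero on blank channels and finds bright puncta", {
  blank <- zstack(list(matrix(0, 96, 96)))
  pair <- roi_pair(blank, blank, list(plate_id = "P", well_id = "W",
                                      roi_index = 1L, timepoint = 0))
  expect_equal(count_puncta(pair)$count, 0L)

  sc <- suppressWarnings(make_scene(small_scene_params(seed = 45L)))
  pair2 <- roi_pair(sc$structure, sc$puncta,
                    list(plate_id = "P", well_id = "W", roi_index = 1L,
                         timepoint = 0))
  res <- count_puncta(pair2)
  score <- score_detection(sc$truth_puncta, res)
  expect_gte(score$precision, 0.8)
  expect_gte(score$recall, 0.6)
})
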
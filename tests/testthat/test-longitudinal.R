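# Percent change, gates, exclusion propagation and assay-quality statistics.

test_that("percent_change arithmetic and scale invariance", {
  expect_equal(percent_change(73, 100), -27)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(105, 100), 5)
  expect_error(percent_change(10, 0), "baseline")
  set.seed(51)
  a <- sample(1:500, 50)
  b <- sample(1:500, 50)
  expect_equal(percent_change(3 * a, 3 * b), percent_change(a, b))
})

test_that("ROI gate boundary sits at 50 baseline puncta", {
  expect_false(roi_gate(49))
  expect_true(roi_gate(50))
  expect_false(roi_gate(0))
  expect_false(roi_gate(NA))
})

test_that("log(X+101) transform hits its closed-form anchors", {
  expect_equal(log_shift_transform(-100), 0)
  expect_equal(log_shift_transform(-1), 2)
  expect_equal(log_shift_transform(899), 3)
  expect_error(log_shift_transform(-100.5), "domain")
})

test_that("ssmd reproduces its closed form", {
  expect_equal(ssmd(c(1, 2, 3), c(1, 2, 3)), 0)
  # mean 0 sd 3 vs mean -4 sd 4 -> 0.8
  a <- c(-3, 0, 3)
  b <- c(-8, -4, 0)
  expect_equal(ssmd(a, b), (mean(a) - mean(b)) / sqrt(var(a) + var(b)))
  expect_equal(ssmd(a, b), 0.8)
  set.seed(52)
  for (i in 1:10) {
    x <- rnorm(20, 2, 3)
    y <- rnorm(15, -1, 5)
    expect_equal(ssmd(x, y),
                 (sum(x) / 20 - sum(y) / 15) /
                   sqrt(sum((x - mean(x))^2) / 19 + sum((y - mean(y))^2) / 14))
  }
  expect_warning(out <- ssmd(c(1, 1), c(0, 0)), "zero variance")
  expect_equal(out, Inf)
  expect_equal(ssmd(c(1, 1), c(1, 1)), 0)
})

make_records <- function(n_per_group = 4,
                         unt = 5, posA = -27, posB = -17,
                         count_t0 = 100, plate = "P1", timepoint = 24) {
  grp <- tibble::tibble(
    treatment = rep(c("untreated", "2-bp", "pic-4ap", "drugX"),
                    each = n_per_group),
    role = rep(c("untreated", "positive-control-A", "positive-control-B",
                 "drug"), each = n_per_group),
    pct_change = rep(c(unt, posA, posB, -5), each = n_per_group)
  )
  tibble::tibble(
    plate_id = plate,
    well_id = rep(sprintf("A%d", 1:4), each = n_per_group),
    roi_index = rep(seq_len(n_per_group), times = 4),
    treatment = grp$treatment, role = grp$role, timepoint = timepoint,
    count_t0 = count_t0,
    count = round(count_t0 * (1 + grp$pct_change / 100)),
    pct_change = grp$pct_change,
    included = TRUE, exclusion_reason = "none"
  )
}

test_that("plate gates pass/fail exactly per the quoted rules", {
  # healthy plate: untreated +5, controls -27 / -17
  qc <- plate_gate(make_records())
  expect_true(qc$plate_included)
  expect_true(all(qc$gates))

  # untreated mean -11 fails; exactly -10 passes
  expect_false(plate_gate(make_records(unt = -11))$gates[["untreated"]])
  expect_true(plate_gate(make_records(unt = -10))$gates[["untreated"]])

  # positive controls must lose at least 10%: -10 passes, -9.9 fails
  expect_true(plate_gate(make_records(posA = -10))$gates[["diffuse_control"]])
  expect_false(plate_gate(make_records(posA = -9.9))$gates[["diffuse_control"]])
  expect_true(plate_gate(make_records(posB = -10))$gates[["activity_control"]])
  expect_false(plate_gate(make_records(posB = -9.9))$gates[["activity_control"]])

  # >50% of ROIs below 50 baseline puncta excludes the plate
  rec <- make_records(n_per_group = 25)
  rec$count_t0[seq_len(51)] <- 49
  rec$included[seq_len(51)] <- FALSE
  expect_false(plate_gate(rec)$gates[["low_rois"]])
  rec$count_t0[seq_len(51)] <- 50
  rec$included[seq_len(51)] <- TRUE
  expect_true(plate_gate(rec)$gates[["low_rois"]])

  # missing control group is a configuration error
  expect_error(plate_gate(make_records()[1:8, ]), "missing control group")
})

test_that("plate gate decisions match a brute-force restatement of the rules", {
  set.seed(53)
  for (i in 1:25) {
    rec <- make_records(n_per_group = 6,
                        unt = runif(1, -15, 5),
                        posA = runif(1, -15, -5),
                        posB = runif(1, -15, -5))
    n_low <- sample(0:20, 1)
    low <- sample(nrow(rec), min(n_low, nrow(rec)))
    rec$count_t0[low] <- sample(0:49, length(low), TRUE)
    rec$included[low] <- FALSE
    qc <- plate_gate(rec)
    inc <- rec$included
    brute <- c(
      mean(rec$count_t0 < 50) <= 0.5,
      mean(rec$pct_change[inc & rec$role == "untreated"]) >= -10,
      mean(rec$pct_change[inc & rec$role == "positive-control-A"]) <= -10,
      mean(rec$pct_change[inc & rec$role == "positive-control-B"]) <= -10
    )
    # degenerate draws where a control group is fully below the ROI gate
    if (any(is.na(brute))) next
    expect_equal(unname(qc$gates), brute)
    expect_equal(qc$plate_included, all(brute))
  }
})

test_that("build_change_records pairs baselines and gates sparse ROIs", {
  counts <- tibble::tibble(
    plate_id = "P1", well_id = "A1", roi_index = rep(1:3, each = 2),
    treatment = "untreated", role = "untreated",
    timepoint = rep(c(0, 24), 3),
    count = c(100, 95, 40, 60, 80, 100)
  )
  rec <- build_change_records(counts)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$pct_change, c(-5, 50, 25))
  expect_equal(rec$included, c(TRUE, FALSE, TRUE))
  expect_equal(rec$exclusion_reason[2L], "low_t0_count")
  # missing baseline -> excluded
  rec2 <- build_change_records(counts[counts$timepoint == 24 |
                                        counts$roi_index != 1, ])
  expect_false(rec2$included[rec2$roi_index == 1])
})

test_that("outlier exclusions propagate forward only, idempotently", {
  rec <- tidyr::crossing(
    tibble::tibble(plate_id = "P1", well_id = "A1", roi_index = 1:3,
                   treatment = "drugX", role = "drug"),
    timepoint = c(24, 48, 72)
  ) |>
    dplyr::mutate(count_t0 = 100, count = 90, pct_change = -10,
                  included = TRUE, exclusion_reason = "none")
  rec$exclusion_reason[rec$roi_index == 2 & rec$timepoint == 24] <- "outlier"
  rec$included[rec$roi_index == 2 & rec$timepoint == 24] <- FALSE
  out <- propagate_exclusions(rec)
  hit <- out[out$roi_index == 2, ]
  expect_equal(hit$exclusion_reason[order(hit$timepoint)],
               c("outlier", "outlier_prior_timepoint",
                 "outlier_prior_timepoint"))
  expect_true(all(out$included[out$roi_index != 2]))
  # idempotent
  expect_equal(propagate_exclusions(out), out)
  # outlier only at the last timepoint leaves earlier ones unchanged
  rec2 <- rec
  rec2$exclusion_reason[] <- "none"
  rec2$included[] <- TRUE
  rec2$exclusion_reason[rec2$roi_index == 1 & rec2$timepoint == 72] <- "outlier"
  out2 <- propagate_exclusions(rec2)
  expect_true(all(out2$included[out2$timepoint < 72 & out2$roi_index == 1]))
  # no outliers -> identity
  expect_equal(propagate_exclusions(rec2[rec2$exclusion_reason == "none", ]),
               rec2[rec2$exclusion_reason == "none", ])
})
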
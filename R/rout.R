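# FDR-based robust outlier flagging of per-ROI percent changes, following the
# published robust-regression-and-outlier-removal (ROUT) procedure
# specialised to a constant model (the data are one-dimensional %-change
# samples, so the robust fit is the sample median).

#' ROUT-style outlier detection at maximum desired FDR Q
#'
#' Procedure:
#' 1. robust centre = median of the values (constant-model robust fit);
#' 2. residual scale RSDR = 68.27th percentile of the absolute residuals,
#'    corrected by `sqrt(n / (n - k))` with `k = 1` fitted parameter;
#' 3. each point's two-tailed tail probability from a t distribution on
#'    `residual / RSDR` with `n - k` degrees of freedom;
#' 4. FDR detection at rate `q`: stepping inward from the most extreme point
#'    (rank `i` = 1), a point is an outlier if its p-value is below
#'    `q * i / n`; stop at the first non-significant point.
#'
#' Fewer than 3 values never yield outliers. If the RSDR is zero (more than
#' ~68% of the values identical), points off the median have an infinite
#' statistic and zero p-value; with all values equal there are no outliers.
#'
#' @param values Numeric vector (percent changes of one experiment group).
#' @param q Maximum desired false-discovery rate, in (0, 1); default 0.10.
#' @return An object of class `rout_result` with `inlier_indices`,
#'   `outlier_indices`, `robust_center`, `rsdr`, `q`, and a per-point `stats`
#'   tibble (`value`, `residual`, `statistic`, `p_value`, `outlier`).
#' @export
rout_outliers <- function(values, q = 0.10) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (!(q > 0 && q < 1)) stop("q must be in (0, 1)")
  n <- length(values)
  k <- 1L
  center <- median(values)
  resid <- values - center
  rsdr <- if (n > k) {
    unname(quantile(abs(resid), 0.6827, names = FALSE)) * sqrt(n / (n - k))
  } else {
    0
  }
  stat <- if (rsdr > 0) abs(resid) / rsdr else ifelse(resid == 0, 0, Inf)
  pval <- 2 * pt(-stat, df = max(n - k, 1L))
  outlier <- rep(FALSE, n)
  if (n >= 3L) {
    ord <- order(pval, -abs(resid))
    for (i in seq_len(n)) {
      if (pval[ord[i]] < q * i / n) outlier[ord[i]] <- TRUE else break
    }
  }
  structure(
    list(
      inlier_indices = which(!outlier),
      outlier_indices = which(outlier),
      robust_center = center,
      rsdr = rsdr,
      q = q,
      stats = tibble::tibble(
        index = seq_len(n), value = values, residual = resid,
        statistic = stat, p_value = pval, outlier = outlier
      )
    ),
    class = "rout_result"
  )
}

#' @export
print.rout_result <- function(x, ...) {
  cat(sprintf(
    "<rout_result> n = %d, Q = %g: %d outlier(s); centre %.3g, RSDR %.3g\n",
    nrow(x$stats), x$q, length(x$outlier_indices), x$robust_center, x$rsdr))
  invisible(x)
}

#' Flag outlier ROIs within each experiment group
#'
#' Runs [rout_outliers()] on the percent changes of the included records of
#' each group (an "experiment": by default one treatment on one plate at one
#' timepoint) and marks flagged records excluded with reason `"outlier"`.
#' Groups are independent; records already excluded are never re-flagged.
#' Feed the result to [propagate_exclusions()] so outliers at one timepoint
#' are excluded from later ones.
#'
#' @param records Change-record tibble.
#' @param q Maximum desired FDR (default 0.10).
#' @param group_by Grouping columns defining one experiment.
#' @return List with `records` (updated tibble) and `audit` (per-point
#'   outlier audit tibble: group, index, value, statistic, flagged, q).
#' @export
apply_outlier_removal <- function(records, q = 0.10,
                                  group_by = c("plate_id", "treatment",
                                               "timepoint")) {
  records <- tibble::as_tibble(records)
  records$.row <- seq_len(nrow(records))
  eligible <- records[records$included & !is.na(records$pct_change), ]
  audits <- list()
  flag_rows <- integer(0)
  if (nrow(eligible)) {
    keys <- eligible[group_by]
    split_idx <- split(seq_len(nrow(eligible)),
                       interaction(keys, drop = TRUE, lex.order = TRUE))
    for (g in names(split_idx)) {
      rows <- split_idx[[g]]
      res <- rout_outliers(eligible$pct_change[rows], q = q)
      flag_rows <- c(flag_rows, eligible$.row[rows][res$outlier_indices])
      audits[[g]] <- tibble::tibble(
        group = g,
        index = seq_along(rows),
        value = res$stats$value,
        statistic = res$stats$statistic,
        flagged = res$stats$outlier,
        q = q
      )
    }
  }
  records$included[flag_rows] <- FALSE
  records$exclusion_reason[flag_rows] <- "outlier"
  records$.row <- NULL
  list(records = records,
       audit = if (length(audits)) dplyr::bind_rows(audits) else
         tibble::tibble(group = character(0), index = integer(0),
                        value = numeric(0), statistic = numeric(0),
                        flagged = logical(0), q = numeric(0)))
}
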
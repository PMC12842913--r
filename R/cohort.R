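# Cohort-level aggregation: reader-style rating tallies with exact binomial
# confidence intervals, and summaries of per-scan QA records.

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed from the beta inversion of the binomial tails:
#' `lower = qbeta(alpha/2, k, n - k + 1)`,
#' `upper = qbeta(1 - alpha/2, k + 1, n - k)`, with the conventional
#' boundary cases `lower = 0` for `k = 0` and `upper = 1` for `k = n`. For
#' `k = n` the lower bound has the closed form `(alpha/2)^(1/n)`.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param conf Confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)` of proportions.
#' @export
exact_binomial_ci <- function(k, n, conf = 0.95) {
  if (!is.numeric(k) || !is.numeric(n) || length(k) != 1L || length(n) != 1L ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop_ldctqa("'k' and 'n' must be integers with 0 <= k <= n, n >= 1",
                "ldctqa_invalid_input")
  if (conf <= 0 || conf >= 1)
    stop_ldctqa("'conf' must be in (0, 1)", "ldctqa_invalid_input")
  alpha <- 1 - conf
  lower <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

RATING_LABELS <- c("Perfect", "Nearly Perfect", "Good", "Acceptable",
                   "Poor", "Insufficient")  # ratings 6 down to 1

#' Tally quality ratings with cumulative at-least proportions
#'
#' Ratings use a 6-point scale (6 = Perfect ... 1 = Insufficient). For each
#' label the tally reports how many scans received exactly that rating and
#' the cumulative proportion rated at least that well, with an exact 95%
#' binomial confidence interval per cumulative proportion. Underlying
#' values are stored at full precision; the print method rounds percentages
#' to one decimal.
#'
#' @param ratings Integer vector of ratings in 1..6.
#' @param conf Confidence level for the intervals.
#' @return An object of class `rating_tally`: `counts` (named, Perfect
#'   first), `n`, `cumulative_percent`, and `ci_percent` (2-column matrix).
#' @export
tally_ratings <- function(ratings, conf = 0.95) {
  if (length(ratings) < 1L)
    stop_ldctqa("need at least one rating", "ldctqa_invalid_input")
  if (!is.numeric(ratings) || any(ratings != round(ratings)) ||
      any(ratings < 1) || any(ratings > 6))
    stop_ldctqa("ratings must be integers in 1..6", "ldctqa_invalid_input")
  n <- length(ratings)
  counts <- vapply(6:1, function(r) sum(ratings == r), integer(1))
  names(counts) <- RATING_LABELS
  k_at_least <- cumsum(counts)
  ci <- t(vapply(k_at_least, function(k) exact_binomial_ci(k, n, conf),
                 numeric(2))) * 100
  rownames(ci) <- RATING_LABELS
  structure(list(counts = counts, n = n,
                 cumulative_percent = 100 * k_at_least / n,
                 ci_percent = ci, conf = conf),
            class = "rating_tally")
}

#' @export
print.rating_tally <- function(x, ...) {
  cat(sprintf("<rating_tally> n = %d\n", x$n))
  for (lbl in RATING_LABELS)
    cat(sprintf("  %-15s %3d  %5.1f%%  [CI: %.1f-%.1f%%]\n", lbl,
                x$counts[[lbl]], x$cumulative_percent[[lbl]],
                x$ci_percent[lbl, 1], x$ci_percent[lbl, 2]))
  invisible(x)
}

record_field <- function(records, field, default = NA) {
  vapply(records, function(r) {
    v <- r[[field]]
    if (is.null(v) || length(v) != 1L) default else as.numeric(v)
  }, numeric(1))
}

#' Summarize per-scan QA records into a cohort report
#'
#' Directional overscan statistics are conditional: the mean and SD of the
#' caudal (cranial) overscan are computed only over scans where that
#' overscan is positive, so an underscanned or exactly-bounded scan does not
#' drag the mean toward zero. Underscan rates are plain proportions. Scans
#' without a noise value are excluded from the noise statistics and counted
#' in `n_noise_excluded`. Stored values are full precision; the print
#' method shows rates with two decimals in percent.
#'
#' @param records A data frame with columns `caudal_overscan_mm`,
#'   `cranial_overscan_mm`, `underscan_caudal`, `underscan_cranial`, and
#'   optionally `sigma_norm` and `fraction_nonlung_slices` (NA where
#'   unavailable); or a list of per-scan QA reports / lists with those
#'   fields (see [run_scan()], [read_qa_records()]).
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(records) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records) && length(records) > 0) {
    flat <- lapply(records, function(r) {
      cov <- if (!is.null(r$coverage)) r$coverage else r
      noise <- r$noise
      data.frame(
        caudal_overscan_mm = as.numeric(cov$caudal_overscan_mm %||% NA),
        cranial_overscan_mm = as.numeric(cov$cranial_overscan_mm %||% NA),
        underscan_caudal = isTRUE(as.logical(cov$underscan_caudal)),
        underscan_cranial = isTRUE(as.logical(cov$underscan_cranial)),
        sigma_norm = as.numeric(
          if (is.list(noise)) noise$sigma_norm %||% NA else r$sigma_norm %||% NA),
        fraction_nonlung_slices = as.numeric(cov$fraction_nonlung_slices %||% NA))
    })
    df <- do.call(rbind, flat)
  } else {
    stop_ldctqa("'records' must be a non-empty data frame or list",
                "ldctqa_invalid_input")
  }
  n <- nrow(df)
  if (n < 1) stop_ldctqa("no records to summarize", "ldctqa_invalid_input")

  cond_stats <- function(x) {
    x <- x[!is.na(x) & x > 0]
    list(mean = if (length(x)) mean(x) else NA_real_,
         sd = if (length(x) > 1) sd(x) else if (length(x) == 1) 0 else NA_real_,
         n = length(x))
  }
  noise <- df$sigma_norm
  noise_ok <- !is.na(noise)
  structure(list(
    n_scans = n,
    caudal_overscan = cond_stats(df$caudal_overscan_mm),
    cranial_overscan = cond_stats(df$cranial_overscan_mm),
    underscan_rate = c(
      caudal = mean(df$underscan_caudal, na.rm = TRUE),
      cranial = mean(df$underscan_cranial, na.rm = TRUE),
      both = mean(df$underscan_caudal & df$underscan_cranial, na.rm = TRUE)),
    sigma_norm = list(mean = if (any(noise_ok)) mean(noise[noise_ok]) else NA_real_,
                      sd = if (sum(noise_ok) > 1) sd(noise[noise_ok]) else NA_real_),
    n_noise_excluded = sum(!noise_ok),
    mean_fraction_nonlung = if ("fraction_nonlung_slices" %in% names(df))
      mean(df$fraction_nonlung_slices, na.rm = TRUE) else NA_real_
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d scans\n", x$n_scans))
  fmt_cond <- function(s, what)
    cat(sprintf("  %s overscan (where present, n = %d): %.2f +/- %.2f mm\n",
                what, s$n, s$mean, s$sd))
  fmt_cond(x$caudal_overscan, "caudal")
  fmt_cond(x$cranial_overscan, "cranial")
  cat(sprintf("  underscan: caudal %.2f%%, cranial %.2f%%, both %.2f%%\n",
              100 * x$underscan_rate["caudal"],
              100 * x$underscan_rate["cranial"],
              100 * x$underscan_rate["both"]))
  cat(sprintf("  sigma_norm: %.2f +/- %.2f HU (%d scans without noise)\n",
              x$sigma_norm$mean, x$sigma_norm$sd, x$n_noise_excluded))
  if (!is.na(x$mean_fraction_nonlung))
    cat(sprintf("  mean fraction of slices without lung: %.2f%%\n",
                100 * x$mean_fraction_nonlung))
  invisible(x)
}

#' Read per-scan QA records from a directory
#'
#' @param dir Directory containing per-scan `*.json` reports written by
#'   [write_report()].
#' @return A list of reports suitable for [summarize_cohort()].
#' @export
read_qa_records <- function(dir) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0)
    stop_ldctqa(sprintf("no .json records in '%s'", dir),
                "ldctqa_missing_input")
  lapply(files, read_report)
}
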
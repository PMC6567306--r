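# Detection of singular low-similarity days and descending trend shifts in
# a similarity series. The underlying method flags these patterns by eye on
# plots; the explicit rules here (one-sided robust z-score for outliers,
# single change point by least-squares segmentation for trends) make the
# same judgements reproducible. All thresholds are configuration.

#' Flag singular low-similarity days
#'
#' A day is flagged iff its index falls below
#' `median - k * MAD` (MAD with the consistency constant 1.4826), or below
#' the absolute `floor` when one is set. One-sided by design: only
#' unusually LOW similarity indicates deviating activity; an unusually
#' high index just means a day very close to the reference routine. When
#' more than half the values are identical the MAD collapses to 0; a small
#' dispersion floor `eps` keeps genuinely deviant days flaggable.
#'
#' @param series a `similarity_series` with at least 7 days
#' @param k robust z-score threshold (default 3)
#' @param floor optional absolute index threshold
#' @param eps dispersion substituted when MAD = 0 (default 0.01)
#' @return data.frame `date, daily_index, robust_z` of the flagged days
#' @export
detect_outlier_days <- function(series, k = 3, floor = NULL, eps = 0.01) {
  x <- series$daily_index
  if (length(x) < 7)
    stop("need at least 7 days of similarity values")
  med <- stats::median(x)
  s <- stats::mad(x)          # 1.4826 * median(|x - median|)
  if (s == 0) s <- eps
  z <- (x - med) / s
  flag <- z < -k
  if (!is.null(floor)) flag <- flag | x < floor
  out <- data.frame(date = series$date[flag], daily_index = x[flag],
                    robust_z = z[flag])
  rownames(out) <- NULL
  out[order(out$date), , drop = FALSE]
}

# SSE of the best piecewise-constant fit with a single split before
# index c (segments 1..c-1 and c..n).
two_segment_sse <- function(x, c_) {
  a <- x[seq_len(c_ - 1)]
  b <- x[c_:length(x)]
  sum((a - mean(a))^2) + sum((b - mean(b))^2)
}

#' Locate a single descending shift in the similarity series
#'
#' Exhaustive scan over all admissible split points of the best two-segment
#' piecewise-constant fit. A change point is reported only when (a) it
#' reduces the residual sum of squares of the one-segment fit by more than
#' `min_reduction`, and (b) the mean after the split is below the mean
#' before it — a sustained descending trend is the deviation signal; an
#' index that shifts upward means the routine moved closer to the
#' reference, which is not an alarm.
#'
#' @param series a `similarity_series` of length at least `2 * min_segment`
#' @param min_segment minimum days per segment (default 5)
#' @param min_reduction minimum fractional SSE reduction (default 0.3)
#' @return `NULL`, or a list with `change_index` (first day of the new
#'   regime), `change_date`, `mean_before`, `mean_after`, `sse_reduction`
#' @export
detect_trend_shift <- function(series, min_segment = 5, min_reduction = 0.3) {
  x <- series$daily_index
  n <- length(x)
  if (n < 2 * min_segment)
    stop(sprintf("need at least %d days, have %d", 2 * min_segment, n))
  sse0 <- sum((x - mean(x))^2)
  splits <- (min_segment + 1):(n - min_segment + 1)
  sse <- vapply(splits, function(c_) two_segment_sse(x, c_), numeric(1))
  best <- splits[which.min(sse)]
  reduction <- if (sse0 > 0) 1 - min(sse) / sse0 else 0
  mean_before <- mean(x[seq_len(best - 1)])
  mean_after <- mean(x[best:n])
  if (reduction <= min_reduction || mean_after >= mean_before) return(NULL)
  list(change_index = best,
       change_date = series$date[best],
       mean_before = mean_before,
       mean_after = mean_after,
       sse_reduction = reduction)
}

#' Full anomaly report for a similarity series
#'
#' Composes the two detectors so each sees a series it can read cleanly.
#' A preliminary whole-series outlier pass removes singular extreme days,
#' because a handful of near-zero away-days dominates the residual sum of
#' squares and can mask a genuine regime step from the change-point scan.
#' The trend detector then runs on the cleaned series. Finally, when a
#' shift is found and both regimes are at least 7 days long, outlier days
#' are re-flagged within each regime separately — a day is judged against
#' the routine prevailing around it, so the whole lower regime is not
#' spuriously reported as outliers of the old one.
#'
#' @param series a `similarity_series`
#' @param k robust z-score threshold for outlier days
#' @param floor optional absolute index floor
#' @param min_segment,min_reduction see [detect_trend_shift()]
#' @return an `anomaly_report`: list with `outlier_days` (data.frame),
#'   `trend_change` (list or `NULL`) and `params_used`
#' @export
detect_anomalies <- function(series, k = 3, floor = NULL, min_segment = 5,
                             min_reduction = 0.3) {
  no_flags <- data.frame(date = as.Date(character()),
                         daily_index = numeric(), robust_z = numeric())
  prelim <- if (nrow(series) >= 7)
    detect_outlier_days(series, k = k, floor = floor)
  else no_flags
  clean <- series[!(series$date %in% prelim$date), , drop = FALSE]
  trend <- if (nrow(clean) >= 2 * min_segment)
    detect_trend_shift(clean, min_segment, min_reduction)
  else NULL
  if (!is.null(trend)) {
    # map the split back onto the full series
    trend$change_index <- match(trend$change_date, series$date)
  }
  segs <- if (!is.null(trend) &&
                trend$change_index - 1 >= 7 &&
                nrow(series) - trend$change_index + 1 >= 7) {
    list(series[seq_len(trend$change_index - 1), , drop = FALSE],
         series[trend$change_index:nrow(series), , drop = FALSE])
  } else list(series)
  outliers <- do.call(rbind, lapply(segs, function(seg) {
    if (nrow(seg) >= 7) detect_outlier_days(seg, k = k, floor = floor)
    else no_flags
  }))
  outliers <- outliers[order(outliers$date), , drop = FALSE]
  rownames(outliers) <- NULL
  structure(list(outlier_days = outliers, trend_change = trend,
                 params_used = list(k = k, floor = floor,
                                    min_segment = min_segment,
                                    min_reduction = min_reduction)),
            class = "anomaly_report")
}

#' @export
print.anomaly_report <- function(x, ...) {
  cat("<anomaly_report>\n")
  if (nrow(x$outlier_days) == 0) {
    cat("  no outlier days\n")
  } else {
    cat(sprintf("  %d outlier day(s):\n", nrow(x$outlier_days)))
    for (i in seq_len(nrow(x$outlier_days)))
      cat(sprintf("    %s  index %.3f  (robust z %.1f)\n",
                  x$outlier_days$date[i], x$outlier_days$daily_index[i],
                  x$outlier_days$robust_z[i]))
  }
  if (is.null(x$trend_change)) {
    cat("  no descending trend shift\n")
  } else {
    tc <- x$trend_change
    cat(sprintf(
      "  descending shift at %s: mean %.3f -> %.3f (SSE reduction %.0f%%)\n",
      tc$change_date, tc$mean_before, tc$mean_after,
      100 * tc$sse_reduction))
  }
  invisible(x)
}

#' Write an anomaly report to JSON (plus a readable text summary)
#'
#' @param report an `anomaly_report`
#' @param path output `.json` path; a `.txt` sibling is written next to it
#' @return `path`, invisibly
#' @export
write_anomaly_report <- function(report, path) {
  payload <- list(
    outlier_days = if (nrow(report$outlier_days) == 0) list() else
      lapply(seq_len(nrow(report$outlier_days)), function(i) list(
        date = as.character(report$outlier_days$date[i]),
        daily_index = report$outlier_days$daily_index[i],
        robust_z = report$outlier_days$robust_z[i])),
    trend_change = if (is.null(report$trend_change)) NULL else list(
      change_date = as.character(report$trend_change$change_date),
      mean_before = report$trend_change$mean_before,
      mean_after = report$trend_change$mean_after,
      sse_reduction = report$trend_change$sse_reduction),
    params_used = report$params_used)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  txt <- sub("\\.json$", ".txt", path)
  con <- file(txt, "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(path)
}
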
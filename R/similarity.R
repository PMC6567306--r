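# Reference-set construction and SSIM-based similarity series.

#' SSIM constants
#'
#' The stabilizing constants of the structural similarity index:
#' `C1 = (k1 * L)^2`, `C2 = (k2 * L)^2`, with the customary defaults
#' `k1 = 0.01`, `k2 = 0.03` and dynamic range `L = 255` for 8-bit images.
#'
#' @param k1,k2 small positive constants, much less than 1
#' @param L dynamic range of pixel values
#' @return an `ssim_params` object
#' @export
ssim_params <- function(k1 = 0.01, k2 = 0.03, L = 255) {
  stopifnot(k1 > 0, k1 < 1, k2 > 0, k2 < 1, L > 0)
  structure(list(k1 = k1, k2 = k2, L = L,
                 C1 = (k1 * L)^2, C2 = (k2 * L)^2),
            class = "ssim_params")
}

#' Structural similarity index of two images
#'
#' The global (single-window, whole-image) SSIM:
#' \deqn{SSIM(x,y) = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'   {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' with means, population variances (divisor N = pixel count) and
#' covariance computed over the whole image. Symmetric in its arguments;
#' exactly 1 for identical images; bounded by 1 in absolute value.
#'
#' @param x,y numeric matrices of the same shape with values in `[0, L]`
#' @param params an `ssim_params` object
#' @return a scalar in `[-1, 1]`
#' @export
ssim <- function(x, y, params = ssim_params()) {
  if (!all(dim(x) == dim(y))) stop("images must have the same shape")
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  ((2 * mx * my + params$C1) * (2 * cxy + params$C2)) /
    ((mx^2 + my^2 + params$C1) * (vx + vy + params$C2))
}

#' Build the 24 hourly reference images over a window of days
#'
#' For each hour of the day the per-place counts are averaged over the
#' window days (sensor data is averaged, not pixels — with count-mode
#' rendering the two agree by linearity of superposition, and quantization
#' is applied once, after averaging) and rendered to a grayscale map.
#'
#' @param counts an `hourly_counts` object covering the window
#' @param window `Date` vector: either `c(start, end)` or the full day
#'   sequence to average over
#' @param params a `pheromone_params`
#' @param cap white-point cap; defaults to `params$intensity_cap` or, when
#'   that is `NULL`, to [intensity_cap()] of the full `counts` interval so
#'   reference and daily images share one grayscale scale
#' @param method provenance tag: `"manual"`, `"min_dispersion"` or
#'   `"min_sleep_std"`
#' @return a `reference_set`: list of 24 integer images plus the window,
#'   method and cap used
#' @export
build_reference_set <- function(counts, window, params, cap = NULL,
                                method = "manual") {
  window <- as.Date(window)
  if (length(window) == 2 && window[2] > window[1])
    window <- seq(window[1], window[2], by = "day")
  if (length(window) < 1) stop("reference window must cover at least 1 day")
  have <- as.character(attr(counts, "dates"))
  missing_days <- setdiff(as.character(window), have)
  if (length(missing_days) > 0)
    stop("window day(s) not covered by counts: ",
         paste(missing_days, collapse = ", "))
  cap <- cap %||% params$intensity_cap %||% intensity_cap(counts)
  sub <- counts[, , as.character(window), drop = FALSE]
  mean_counts <- apply(sub, c(1, 2), mean)   # places x 24, real-valued
  ker <- place_kernels(params)
  places <- attr(counts, "places")
  fields <- ker[, places, drop = FALSE] %*% mean_counts
  n <- params$grid_size
  images <- lapply(seq_len(24), function(h)
    quantize_to_grayscale(matrix(fields[, h], nrow = n), cap))
  structure(list(hourly_images = images, window = window, method = method,
                 cap = cap),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> 24 hourly images, window %s .. %s (%s)\n",
              min(x$window), max(x$window), x$method))
  invisible(x)
}

#' Select a low-variability reference window
#'
#' `min_dispersion` slides a `length_days` window over the available days
#' and scores each by the summed across-day standard deviation of every
#' (place, hour) count; the lowest-scoring window — the most uniform week —
#' wins, earliest on ties. `min_sleep_std` instead minimizes the standard
#' deviation of the per-day sleep duration, which requires `sleep_durations`
#' (e.g. from annotations or simulation ground truth).
#'
#' @param counts an `hourly_counts` object
#' @param length_days window length in days (default 7)
#' @param criterion `"min_dispersion"` or `"min_sleep_std"`
#' @param sleep_durations numeric vector of per-day sleep hours, aligned
#'   with `attr(counts, "dates")` (required for `min_sleep_std`)
#' @return list with `start`, `end`, `days` (`Date` vector), `score` and
#'   `method`
#' @export
select_reference_window <- function(counts, length_days = 7,
                                    criterion = c("min_dispersion",
                                                  "min_sleep_std"),
                                    sleep_durations = NULL) {
  criterion <- match.arg(criterion)
  dates <- attr(counts, "dates")
  n_days <- length(dates)
  if (n_days < length_days)
    stop(sprintf("need at least %d consecutive days, have %d",
                 length_days, n_days))
  n_win <- n_days - length_days + 1
  scores <- vapply(seq_len(n_win), function(i) {
    idx <- i:(i + length_days - 1)
    if (criterion == "min_dispersion") {
      sub <- counts[, , idx, drop = FALSE]
      sum(apply(sub, c(1, 2), stats::sd))
    } else {
      if (is.null(sleep_durations) || length(sleep_durations) != n_days)
        stop("min_sleep_std needs one sleep duration per day")
      stats::sd(sleep_durations[idx])
    }
  }, numeric(1))
  best <- which.min(scores)   # which.min returns the earliest minimum
  days <- dates[best:(best + length_days - 1)]
  list(start = days[1], end = days[length_days], days = days,
       score = scores[best], method = criterion)
}

#' Per-day sleep durations from an activity-annotation CSV
#'
#' Reads `start,end,activity` rows (ISO timestamps) and sums the duration
#' of activities matching `pattern` per calendar day of the activity start.
#' Days without a matching annotation get 0.
#'
#' @param path annotation CSV path
#' @param dates `Date` vector defining the output alignment
#' @param pattern case-insensitive regex selecting sleep-like activities
#' @return numeric vector of hours, one per element of `dates`
#' @export
sleep_durations_from_annotations <- function(path, dates,
                                             pattern = "sleep|bed") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("start", "end", "activity") %in% names(df)))
  df <- df[grepl(pattern, df$activity, ignore.case = TRUE), , drop = FALSE]
  out <- stats::setNames(numeric(length(dates)), as.character(dates))
  if (nrow(df) > 0) {
    s <- parse_naive_time(gsub("T", " ", df$start))
    e <- parse_naive_time(gsub("T", " ", df$end))
    day <- as.character(as.Date(s, tz = "UTC"))
    dur <- as.numeric(difftime(e, s, units = "hours"))
    agg <- tapply(dur, day, sum)
    hit <- intersect(names(agg), names(out))
    out[hit] <- agg[hit]
  }
  unname(out)
}

#' Similarity of each day's maps against the reference set
#'
#' For every day, each hourly image is compared with the reference image of
#' the same hour by SSIM; the daily index is the unweighted mean of the
#' hourly values over the selected hour subset. `hours = 7:9` restricts the
#' index to the 7-10 a.m. morning window, `hours = 0:5` to the
#' midnight-to-6-a.m. night window.
#'
#' @param day_maps a `day_maps` object from [render_day_maps()] (rendered
#'   with the same parameters and cap as the reference)
#' @param reference a `reference_set`
#' @param hours integer subset of `0:23` to aggregate over (default all)
#' @param params an `ssim_params` object
#' @return a `similarity_series`: data.frame with `date`, `daily_index` and
#'   one `hNN` column per selected hour; the hour subset is kept in the
#'   `hours` attribute
#' @export
similarity_series <- function(day_maps, reference, hours = 0:23,
                              params = ssim_params()) {
  hours <- sort(unique(as.integer(hours)))
  if (length(hours) == 0) stop("hour subset must not be empty")
  stopifnot(all(hours >= 0 & hours <= 23))
  dates <- attr(day_maps, "dates")
  per_hour <- t(vapply(day_maps, function(day) {
    vapply(hours, function(h)
      ssim(day[[h + 1]]$image, reference$hourly_images[[h + 1]], params),
      numeric(1))
  }, numeric(length(hours))))
  colnames(per_hour) <- sprintf("h%02d", hours)
  df <- data.frame(date = as.Date(dates),
                   daily_index = rowMeans(per_hour),
                   per_hour, check.names = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("similarity_series", "data.frame"),
            hours = hours, reference_window = reference$window)
}

#' @export
print.similarity_series <- function(x, ...) {
  hrs <- attr(x, "hours")
  cat(sprintf(
    "<similarity_series> %d day(s), hours %s, index %.3f .. %.3f\n",
    nrow(x),
    if (is.null(hrs) || length(hrs) %in% c(0, 24)) "0-23"
    else paste(hrs, collapse = ","),
    min(x$daily_index), max(x$daily_index)))
  invisible(x)
}

#' Write a similarity series as CSV
#' @param series a `similarity_series`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_similarity_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Plot a similarity series
#'
#' Index versus date, with the reference window shaded and any annotated
#' outlier days and change point marked.
#'
#' @param series a `similarity_series`
#' @param report optional `anomaly_report` to overlay
#' @param path optional output path (`.png` or `.svg`); `NULL` plots to the
#'   active device
#' @return `path` (or `NULL`), invisibly
#' @export
plot_similarity <- function(series, report = NULL, path = NULL) {
  draw <- function() {
    graphics::plot(series$date, series$daily_index, type = "o", pch = 16,
                   cex = 0.6, ylim = c(min(0, min(series$daily_index)), 1),
                   xlab = "date", ylab = "similarity index",
                   main = "Daily similarity vs. reference routine")
    rw <- attr(series, "reference_window")
    if (!is.null(rw))
      graphics::rect(min(rw), graphics::par("usr")[3], max(rw) + 1,
                     graphics::par("usr")[4],
                     col = grDevices::adjustcolor("steelblue", 0.15),
                     border = NA)
    if (!is.null(report)) {
      if (nrow(report$outlier_days) > 0)
        graphics::points(report$outlier_days$date,
                         report$outlier_days$daily_index,
                         col = "red", pch = 4, cex = 1.4, lwd = 2)
      if (!is.null(report$trend_change))
        graphics::abline(v = report$trend_change$change_date,
                         col = "darkorange", lty = 2, lwd = 2)
    }
  }
  if (is.null(path)) {
    draw()
  } else {
    if (grepl("\\.svg$", path)) grDevices::svg(path, width = 8, height = 4)
    else grDevices::png(path, width = 960, height = 480)
    on.exit(grDevices::dev.off())
    draw()
  }
  invisible(path)
}

#' Read a similarity series written by [write_similarity_csv()]
#' @param path CSV path
#' @return a `similarity_series`
#' @export
read_similarity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$date <- as.Date(df$date)
  hcols <- grep("^h[0-9]{2}$", names(df), value = TRUE)
  structure(df, class = c("similarity_series", "data.frame"),
            hours = as.integer(sub("^h", "", hcols)))
}
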
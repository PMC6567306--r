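# Reading, preprocessing and place-mapping of binary-sensor event logs.
#
# An event log is a data.frame with columns
#   timestamp (POSIXct, naive local time stored as UTC),
#   sensor_id (character), value (character),
#   sensor_type (one of "motion", "door", "pressure", "other"),
# sorted non-decreasing by timestamp, with class "event_log" and attributes
# `dialect` and `parse_report`.

SENSOR_TYPES <- c("motion", "door", "pressure", "other")

new_event_log <- function(df, dialect = "synthetic", parse_report = NULL) {
  stopifnot(all(c("timestamp", "sensor_id", "value", "sensor_type") %in%
                  names(df)))
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            class = c("event_log", "data.frame"),
            dialect = dialect,
            parse_report = parse_report %||%
              list(n_lines = nrow(df), n_skipped = 0L, bad_lines = integer()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of events in a log
#' @param log an `event_log`
#' @return integer count of events
#' @export
n_events <- function(log) nrow(log)

#' @export
print.event_log <- function(x, ...) {
  rep_ <- attr(x, "parse_report")
  cat(sprintf("<event_log> %d events (%s dialect", nrow(x),
              attr(x, "dialect")))
  if (!is.null(rep_) && rep_$n_skipped > 0)
    cat(sprintf(", %d lines skipped", rep_$n_skipped))
  cat(")\n")
  if (nrow(x) > 0)
    cat(sprintf("  %s .. %s | sensors: %d\n",
                format(min(x$timestamp)), format(max(x$timestamp)),
                length(unique(x$sensor_id))))
  invisible(x)
}

#' Infer sensor type from its id
#'
#' CASAS ids encode the sensor class in the first letter: `M` for PIR motion
#' detectors and `D` for magnetic door contacts. Anything else is "other".
#'
#' @param sensor_id character vector of sensor ids
#' @return character vector of types
#' @export
infer_sensor_type <- function(sensor_id) {
  first <- toupper(substr(sensor_id, 1L, 1L))
  ifelse(first == "M", "motion", ifelse(first == "D", "door", "other"))
}

parse_naive_time <- function(x) {
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
}

#' Read a CASAS-style whitespace-delimited sensor log
#'
#' Each non-blank line is `date time sensor value [annotation ...]`, e.g.
#' `2014-04-01 07:12:03.25 M004 ON`. Trailing fields beyond the fourth are
#' ignored. Sensor types are inferred from the id prefix unless overridden.
#'
#' @param path path to the text log
#' @param strict if `TRUE`, a malformed line is an error; otherwise it is
#'   skipped and counted in the parse report
#' @param type_overrides optional named character vector `sensor_id -> type`
#'   overriding the prefix inference (e.g. marking pressure sensors)
#' @return an `event_log` sorted by timestamp
#' @export
read_casas_log <- function(path, strict = FALSE, type_overrides = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0)
    return(new_event_log(empty_events(), dialect = "casas"))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(parts)
  ts <- rep(as.POSIXct(NA), length(lines))
  ok <- nf >= 4
  if (any(ok)) {
    stamp <- vapply(parts[ok], function(p) paste(p[1], p[2]), character(1))
    ts[ok] <- parse_naive_time(stamp)
  }
  bad <- which(!ok | is.na(ts))
  if (strict && length(bad) > 0)
    stop(sprintf("malformed line(s) at %s in %s",
                 paste(utils::head(bad, 5), collapse = ", "), path))
  good <- setdiff(seq_along(lines), bad)
  df <- data.frame(
    timestamp = ts[good],
    sensor_id = vapply(parts[good], `[[`, character(1), 3L),
    value = vapply(parts[good], `[[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
  df$sensor_type <- infer_sensor_type(df$sensor_id)
  if (!is.null(type_overrides)) {
    hit <- df$sensor_id %in% names(type_overrides)
    df$sensor_type[hit] <- unname(type_overrides[df$sensor_id[hit]])
  }
  stopifnot(all(df$sensor_type %in% SENSOR_TYPES))
  new_event_log(df, dialect = "casas",
                parse_report = list(n_lines = length(lines),
                                    n_skipped = length(bad),
                                    bad_lines = bad))
}

#' Read a generic CSV sensor log
#'
#' Expected header: `timestamp,sensor_id,value,sensor_type` with ISO-8601
#' timestamps. This dialect covers Kasteren-style deployments where pressure
#' sensors are declared explicitly.
#'
#' @inheritParams read_casas_log
#' @return an `event_log`
#' @export
read_generic_csv <- function(path, strict = FALSE) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("timestamp", "sensor_id", "value", "sensor_type")
  if (!all(req %in% names(df)))
    stop("generic CSV must have columns ", paste(req, collapse = ", "))
  ts <- parse_naive_time(gsub("T", " ", df$timestamp))
  bad <- which(is.na(ts) | !nzchar(df$sensor_id) |
                 !(df$sensor_type %in% SENSOR_TYPES))
  if (strict && length(bad) > 0)
    stop(sprintf("malformed row(s) at %s in %s",
                 paste(utils::head(bad, 5), collapse = ", "), path))
  good <- setdiff(seq_len(nrow(df)), bad)
  out <- data.frame(timestamp = ts[good],
                    sensor_id = as.character(df$sensor_id[good]),
                    value = as.character(df$value[good]),
                    sensor_type = df$sensor_type[good],
                    stringsAsFactors = FALSE)
  new_event_log(out, dialect = "generic_csv",
                parse_report = list(n_lines = nrow(df),
                                    n_skipped = length(bad),
                                    bad_lines = bad))
}

empty_events <- function() {
  data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
             sensor_id = character(), value = character(),
             sensor_type = character(), stringsAsFactors = FALSE)
}

# values that mean "deactivation" for an automatically-resetting sensor
OFF_VALUES <- c("OFF", "0", "CLOSE", "FALSE", "ABSENT")

#' Remove motion-detector OFF events
#'
#' PIR motion detectors turn OFF automatically a few seconds after being
#' triggered, so their OFF events carry no information about the resident's
#' activity and are dropped. Door-contact events are kept in both states by
#' default (opening and closing a door are both genuine interactions).
#'
#' @param log an `event_log`
#' @param drop_door_close also drop door-contact CLOSE events
#' @return the filtered `event_log`
#' @export
filter_off_events <- function(log, drop_door_close = FALSE) {
  drop <- log$sensor_type == "motion" & toupper(log$value) %in% OFF_VALUES
  if (drop_door_close)
    drop <- drop | (log$sensor_type == "door" &
                      toupper(log$value) %in% OFF_VALUES)
  keep_events(log, !drop)
}

keep_events <- function(log, keep) {
  out <- log[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes_to_keep <- attributes(log)[c("dialect", "parse_report")]
  structure(out, class = class(log),
            dialect = attributes_to_keep$dialect,
            parse_report = attributes_to_keep$parse_report)
}

# Greedy per-group rate limiter: keep an element iff it is >= gap seconds
# after the last KEPT element of the same group. Anchoring on the last kept
# event (not the last seen one) is what a hardware rate limiter does and
# keeps the rule deterministic.
greedy_min_gap <- function(times_s, group, gap_s, eligible = NULL) {
  n <- length(times_s)
  keep <- rep(TRUE, n)
  if (n == 0) return(keep)
  if (is.null(eligible)) eligible <- rep(TRUE, n)
  idx <- split(seq_len(n)[eligible], group[eligible])
  for (ii in idx) {
    if (length(ii) < 2) next
    last_kept <- times_s[ii[1]]
    for (j in ii[-1]) {
      if (times_s[j] - last_kept >= gap_s) {
        last_kept <- times_s[j]
      } else {
        keep[j] <- FALSE
      }
    }
  }
  keep
}

#' Debounce repeated firings of the same sensor
#'
#' Repeated signals from one sensor arriving faster than `min_gap_s` are
#' treated as a single activity event: a greedy forward pass keeps an event
#' iff it is at least `min_gap_s` seconds after the last kept event of that
#' sensor. Different sensors never suppress each other.
#'
#' @param log a time-sorted `event_log`
#' @param min_gap_s minimum gap in seconds (default 60, one event per minute)
#' @return the debounced `event_log`
#' @export
debounce_events <- function(log, min_gap_s = 60) {
  keep <- greedy_min_gap(as.numeric(log$timestamp), log$sensor_id, min_gap_s)
  keep_events(log, keep)
}

#' Mute pressure sensors after each accounted event
#'
#' Pressure sensors under beds and couches fire continuously while the
#' resident rests. Each sensor is muted for `mute_min` minutes after every
#' accounted event (greedy forward pass), so a rest period contributes a
#' bounded number of events. Other sensor types are untouched.
#'
#' @param log a time-sorted `event_log`
#' @param mute_min muting window in minutes (default 10)
#' @return the muted `event_log`
#' @export
mute_pressure_sensors <- function(log, mute_min = 10) {
  keep <- greedy_min_gap(as.numeric(log$timestamp), log$sensor_id,
                         mute_min * 60, eligible = log$sensor_type == "pressure")
  keep_events(log, keep)
}

#' Construct a sensor-to-place mapping
#'
#' The living environment is abstracted to a small ordered set of
#' behaviorally significant places (default `P1`..`P4` = bedroom, kitchen,
#' bathroom, living room); each binary sensor belongs to exactly one place.
#'
#' @param sensors named list: place name -> character vector of sensor ids
#' @param places ordered place names (default `names(sensors)`)
#' @param labels optional human-readable labels, same length as `places`
#' @return a `place_mapping` object
#' @export
place_mapping <- function(sensors, places = names(sensors), labels = NULL) {
  stopifnot(is.list(sensors), length(places) >= 1,
            all(places %in% names(sensors)))
  sensors <- sensors[places]
  if (any(lengths(sensors) < 1))
    stop("every place needs at least one sensor")
  all_ids <- unlist(sensors, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("sensor(s) mapped to more than one place: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  sensor_to_place <- rep(places, lengths(sensors))
  names(sensor_to_place) <- all_ids
  structure(list(places = places, sensors = sensors,
                 sensor_to_place = sensor_to_place,
                 labels = labels %||% places),
            class = "place_mapping")
}

#' @export
print.place_mapping <- function(x, ...) {
  cat("<place_mapping>\n")
  for (p in x$places)
    cat(sprintf("  %s (%s): %s\n", p,
                x$labels[match(p, x$places)],
                paste(x$sensors[[p]], collapse = " ")))
  invisible(x)
}

#' Read a place mapping from a YAML or JSON config
#'
#' The config holds a `places:` list and a `sensors:` map from place name to
#' sensor-id list, optionally `labels:`. See the configs shipped under
#' `inst/extdata/` for the two example deployments.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return a `place_mapping`
#' @export
read_place_mapping <- function(path) {
  stopifnot(file.exists(path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  sensors <- lapply(cfg$sensors, as.character)
  place_mapping(sensors, places = as.character(cfg$places),
                labels = if (!is.null(cfg$labels)) as.character(cfg$labels))
}

#' Example mapping for the CASAS HH126 deployment
#'
#' Four places — P1 bedroom, P2 kitchen, P3 bathroom, P4 living room — with
#' the motion detectors of the HH126 smart-home testbed assigned to them.
#'
#' @return a `place_mapping`
#' @export
hh126_mapping <- function() {
  read_place_mapping(system.file("extdata", "hh126_places.yaml",
                                 package = "pheromap", mustWork = TRUE))
}

#' Example mapping for the Kasteren House C deployment
#' @return a `place_mapping`
#' @export
kasteren_c_mapping <- function() {
  read_place_mapping(system.file("extdata", "kasteren_c_places.yaml",
                                 package = "pheromap", mustWork = TRUE))
}

#' Tag each event with its place
#'
#' @param log an `event_log`
#' @param mapping a `place_mapping`
#' @param unmapped what to do with events of sensors absent from the
#'   mapping: `"drop"` (default; the count is recorded in the
#'   `n_unmapped_dropped` attribute) or `"error"`
#' @return the `event_log` with an added `place` column
#' @export
map_to_places <- function(log, mapping, unmapped = c("drop", "error")) {
  unmapped <- match.arg(unmapped)
  stopifnot(inherits(mapping, "place_mapping"))
  place <- unname(mapping$sensor_to_place[log$sensor_id])
  miss <- is.na(place)
  if (any(miss) && unmapped == "error")
    stop("unmapped sensor id(s): ",
         paste(sort(unique(log$sensor_id[miss])), collapse = ", "))
  log$place <- place
  out <- keep_events(log, !miss)
  attr(out, "n_unmapped_dropped") <- sum(miss)
  out
}

#' Bin place-tagged events into hourly counts
#'
#' Counts events per (place, hour-of-day, day) over `days` (default: every
#' calendar day from the first to the last event). Hour bins are half-open
#' `[h:00, h+1:00)`; days with no events yield all-zero slices, which
#' downstream reads as time away from home.
#'
#' @param log a place-tagged `event_log` (see [map_to_places()])
#' @param mapping the `place_mapping` used (fixes the place order)
#' @param days optional `Date` vector of days to cover
#' @return an `hourly_counts` object: integer array `place x 24 x day` with
#'   attributes `places` and `dates`
#' @export
hourly_counts <- function(log, mapping, days = NULL) {
  stopifnot("place" %in% names(log))
  places <- mapping$places
  if (is.null(days)) {
    if (nrow(log) == 0) return(new_hourly_counts(places, as.Date(character())))
    rng <- as.Date(range(log$timestamp), tz = "UTC")
    days <- seq(rng[1], rng[2], by = "day")
  }
  if (length(days) == 0) return(new_hourly_counts(places, days))
  arr <- array(0L, dim = c(length(places), 24L, length(days)),
               dimnames = list(places, sprintf("h%02d", 0:23),
                               as.character(days)))
  if (nrow(log) > 0) {
    d <- as.character(as.Date(log$timestamp, tz = "UTC"))
    h <- as.integer(format(log$timestamp, "%H", tz = "UTC"))
    inside <- d %in% as.character(days) & log$place %in% places
    if (any(inside)) {
      tab <- table(factor(log$place[inside], levels = places),
                   factor(h[inside], levels = 0:23),
                   factor(d[inside], levels = as.character(days)))
      arr <- arr + array(as.integer(tab), dim = dim(arr),
                         dimnames = dimnames(arr))
    }
  }
  structure(arr, class = "hourly_counts", places = places, dates = days)
}

new_hourly_counts <- function(places, dates) {
  arr <- array(0L, dim = c(length(places), 24L, length(dates)),
               dimnames = list(places, sprintf("h%02d", 0:23),
                               as.character(dates)))
  structure(arr, class = "hourly_counts", places = places, dates = dates)
}

#' @export
print.hourly_counts <- function(x, ...) {
  cat(sprintf("<hourly_counts> %d place(s) x 24 h x %d day(s), %d events\n",
              dim(x)[1], dim(x)[3], sum(x)))
  invisible(x)
}

#' Write hourly counts as a daily-activity CSV
#'
#' One row per (day, place), columns `date,place,h00..h23`.
#'
#' @param counts an `hourly_counts` object
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_daily_activity <- function(counts, path) {
  dates <- attr(counts, "dates")
  places <- attr(counts, "places")
  rows <- do.call(rbind, lapply(seq_along(dates), function(i) {
    data.frame(date = as.character(dates[i]), place = places,
               matrix(counts[, , i], nrow = length(places),
                      dimnames = list(NULL, sprintf("h%02d", 0:23))),
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily-activity CSV back into hourly counts
#' @param path CSV written by [write_daily_activity()]
#' @return an `hourly_counts` object
#' @export
read_daily_activity <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  dates <- as.Date(unique(df$date))
  places <- unique(df$place)
  out <- new_hourly_counts(places, dates)
  hcols <- sprintf("h%02d", 0:23)
  for (i in seq_len(nrow(df)))
    out[df$place[i], , as.character(df$date[i])] <-
      as.integer(df[i, hcols])
  out
}

#' Remove all events of given sensors (simulated sensor fault)
#'
#' @param log an `event_log`
#' @param dead_sensors character vector of sensor ids to silence
#' @return the `event_log` without those sensors' events
#' @export
inject_sensor_fault <- function(log, dead_sensors) {
  keep_events(log, !(log$sensor_id %in% dead_sensors))
}

#' Run the full preprocessing pipeline on a raw log
#'
#' Fixed stage order: motion-OFF filtering, per-sensor debouncing,
#' pressure-sensor muting, place mapping. Each stage is idempotent. The
#' returned log carries a `stage_counts` attribute with an exact event
#' ledger: `parsed = kept + filtered_off + debounced_away + muted +
#' unmapped_dropped`.
#'
#' @param log a raw `event_log`
#' @param mapping a `place_mapping`
#' @param min_gap_s debounce gap in seconds
#' @param mute_min pressure-sensor muting window in minutes
#' @param drop_door_close also drop door CLOSE events
#' @param unmapped policy for unmapped sensors, see [map_to_places()]
#' @return a place-tagged, preprocessed `event_log`
#' @export
preprocess_events <- function(log, mapping, min_gap_s = 60, mute_min = 10,
                              drop_door_close = FALSE,
                              unmapped = c("drop", "error")) {
  n0 <- nrow(log)
  a <- filter_off_events(log, drop_door_close = drop_door_close)
  b <- debounce_events(a, min_gap_s = min_gap_s)
  c_ <- mute_pressure_sensors(b, mute_min = mute_min)
  d <- map_to_places(c_, mapping, unmapped = unmapped)
  attr(d, "stage_counts") <- list(
    parsed = n0,
    filtered_off = n0 - nrow(a),
    debounced_away = nrow(a) - nrow(b),
    muted = nrow(b) - nrow(c_),
    unmapped_dropped = nrow(c_) - nrow(d),
    kept = nrow(d))
  d
}
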
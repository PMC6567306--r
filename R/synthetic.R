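# Synthetic daily-routine simulator.
#
# Emulates the statistical structure the monitoring method assumes: a
# stable per-place, per-hour rate of accounted sensor events (4 places x 24
# hours), motion sensors that fire ON and reset OFF a few seconds later,
# occasional sub-minute double-fires, injectable anomalous days, a
# mid-series sensor-set change and sensor faults. Counts are Poisson — the
# simplest point process consistent with "events per hour" — with times
# uniform within the hour.

#' A daily routine profile
#'
#' @param rate `n_places x 24` matrix of expected accounted events per hour
#'   (rows named by place); defaults to a single-resident routine with
#'   night-time bedroom activity, kitchen peaks at the three meals,
#'   morning/evening bathroom use and afternoon/evening living-room use
#' @param sensors_per_place named list place -> sensor ids (default: the
#'   HH126-style motion-sensor layout)
#' @param sleep_hours hours of the day attributed to bedroom rest (used for
#'   ground-truth sleep durations)
#' @return a `routine_profile`
#' @export
routine_profile <- function(rate = NULL, sensors_per_place = NULL,
                            sleep_hours = c(23, 0:6)) {
  if (is.null(sensors_per_place))
    sensors_per_place <- list(
      P1 = c("M010", "M011", "M013"),
      P2 = c("M003", "M004", "M005", "M015"),
      P3 = c("M012", "M014"),
      P4 = c("M001", "M002", "M006", "M007", "M008", "M009"))
  if (is.null(rate)) rate <- default_routine_rates()
  stopifnot(ncol(rate) == 24, all(rate >= 0),
            !is.null(rownames(rate)),
            all(rownames(rate) %in% names(sensors_per_place)),
            all(lengths(sensors_per_place) >= 1))
  structure(list(rate = rate,
                 sensors_per_place = sensors_per_place[rownames(rate)],
                 sleep_hours = sleep_hours),
            class = "routine_profile")
}

default_routine_rates <- function() {
  # Occupancy is strongly bimodal: a person moving in a room with several
  # per-sensor-debounced PIRs produces on the order of 10-20 accounted
  # events per hour, while an empty room produces almost none.
  r <- matrix(0, 4, 24, dimnames = list(c("P1", "P2", "P3", "P4"),
                                        sprintf("h%02d", 0:23)))
  # P1 bedroom: restless turns during sleep, bursts waking up / going to bed
  r["P1", c(24, 1:7)] <- 3          # 23:00 and 00-06
  r["P1", 8] <- 12                  # 07: waking up
  r["P1", 23] <- 10                 # 22: going to bed
  r["P1", 9:22] <- 0.2
  # P2 kitchen: breakfast, lunch, dinner peaks
  r["P2", 8:10] <- c(15, 10, 6)     # 07-09
  r["P2", 13:14] <- c(10, 6)        # 12-13
  r["P2", 19:20] <- c(12, 8)        # 18-19
  r["P2", c(11:12, 15:18, 21:22)] <- 0.3
  # P3 bathroom: morning and bedtime peaks, sparse otherwise
  r["P3", 8] <- 8
  r["P3", 23] <- 6
  r["P3", 9:22] <- 1
  r["P3", c(1:7, 24)] <- 0.3
  # P4 living room: midday, afternoon and evening presence
  r["P4", 11:13] <- 6
  r["P4", 15:18] <- 8
  r["P4", 20:22] <- 12
  r["P4", c(9, 10, 14, 19)] <- 1
  r
}

#' A simulation scenario
#'
#' @param n_days number of days to simulate
#' @param seed RNG seed; a fixed seed gives a byte-identical log
#' @param start_date first simulated day
#' @param anomalies list of `list(day, type, magnitude)` with `day` a
#'   1-based day index, `type` one of `"shifted_sleep"`, `"missed_meal"`,
#'   `"away_day"`, `"profile_swap"`; see [apply_anomaly()]
#' @param sensor_change optional `list(day, place, added_sensors)`: before
#'   `day` the listed sensors do not exist, so the place runs on a reduced
#'   pool and a proportionally reduced event rate; from `day` on the full
#'   pool and rate apply (each sensor contributes equally to the place's
#'   data flow, so adding sensors steps the flow up)
#' @param faults optional `list(days, dead_sensors)`: events of the dead
#'   sensors are removed on the given day indices
#' @param double_fire_rate probability that an event fires a sub-minute
#'   duplicate (exercises debouncing; default 0.1)
#' @return a `scenario_spec`
#' @export
scenario_spec <- function(n_days, seed = 1,
                          start_date = as.Date("2021-03-01"),
                          anomalies = list(), sensor_change = NULL,
                          faults = NULL, double_fire_rate = 0.1) {
  stopifnot(n_days >= 1, double_fire_rate >= 0, double_fire_rate <= 1)
  for (a in anomalies)
    stopifnot(a$day >= 1, a$day <= n_days)
  if (!is.null(sensor_change))
    stopifnot(sensor_change$day >= 1, sensor_change$day <= n_days)
  structure(list(n_days = as.integer(n_days), seed = as.integer(seed),
                 start_date = as.Date(start_date), anomalies = anomalies,
                 sensor_change = sensor_change, faults = faults,
                 double_fire_rate = double_fire_rate),
            class = "scenario_spec")
}

#' Read a scenario from a YAML file
#' @param path YAML with the fields of [scenario_spec()]
#' @return a `scenario_spec`
#' @export
read_scenario_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  scenario_spec(n_days = cfg$n_days, seed = cfg$seed %||% 1,
                start_date = cfg$start_date %||% as.Date("2021-03-01"),
                anomalies = cfg$anomalies %||% list(),
                sensor_change = cfg$sensor_change,
                faults = cfg$faults,
                double_fire_rate = cfg$double_fire_rate %||% 0.1)
}

#' Modify one day's rate matrix to inject an anomaly
#'
#' * `shifted_sleep` — rotates the bedroom (`P1`) rate vector circularly by
#'   `magnitude` hours: the same sleep happens at a deviating time.
#' * `missed_meal` — zeroes the kitchen (`P2`) rates over `meal_hours`.
#' * `away_day` — scales all rates by `1 - magnitude`: the resident is away
#'   (magnitude 1 means a fully empty home).
#' * `profile_swap` — exchanges the rate rows of `places`: known behaviors
#'   occurring in the wrong rooms.
#'
#' @param day_rates place x 24 rate matrix
#' @param type anomaly type
#' @param magnitude hours for `shifted_sleep`, fraction in `[0, 1]` for
#'   `away_day`; ignored otherwise
#' @param meal_hours hours zeroed by `missed_meal` (default 7-9, breakfast)
#' @param places the two places exchanged by `profile_swap`
#' @return the modified rate matrix
#' @export
apply_anomaly <- function(day_rates, type, magnitude = 1,
                          meal_hours = 7:9, places = c("P1", "P4")) {
  switch(type,
    shifted_sleep = {
      sh <- as.integer(magnitude) %% 24
      day_rates["P1", ] <- day_rates["P1", c(seq_len(24 - sh) + sh,
                                             seq_len(sh))]
      day_rates
    },
    missed_meal = {
      day_rates["P2", meal_hours + 1] <- 0
      day_rates
    },
    away_day = {
      stopifnot(magnitude >= 0, magnitude <= 1)
      day_rates * (1 - magnitude)
    },
    profile_swap = {
      stopifnot(length(places) == 2, all(places %in% rownames(day_rates)))
      day_rates[places, ] <- day_rates[rev(places), ]
      day_rates
    },
    stop("unknown anomaly type: ", type))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

#' Simulate a sensor event log for a scenario
#'
#' Per day, place and hour the accounted event count is drawn
#' `Poisson(rate)`, times are uniform within the hour, and each event is
#' assigned a sensor uniformly from the place's active pool. Every event is
#' emitted as a motion ON plus an automatic OFF 5 seconds later, and with
#' probability `double_fire_rate` a sub-minute duplicate ON/OFF pair
#' follows — so OFF-filtering and debouncing are both exercised
#' downstream. Deterministic for a fixed seed.
#'
#' @param profile a `routine_profile`
#' @param spec a `scenario_spec`
#' @return an `event_log` (casas dialect) with a `ground_truth` attribute:
#'   `anomaly_days` (dates), `change_date` (or `NULL`), per-day
#'   `sleep_hours` and the per-day rate matrices actually used
#' @export
generate_routine_log <- function(profile, spec) {
  places <- rownames(profile$rate)
  dates <- spec$start_date + seq_len(spec$n_days) - 1
  anomalies_by_day <- split(spec$anomalies,
                            vapply(spec$anomalies, `[[`, numeric(1), "day"))
  sc <- spec$sensor_change
  rows <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_days), function(d) {
      rates <- profile$rate
      pools <- profile$sensors_per_place
      if (!is.null(sc) && d < sc$day) {
        before <- setdiff(pools[[sc$place]], sc$added_sensors)
        if (length(before) == 0)
          stop("sensor_change would leave ", sc$place, " with no sensors")
        rates[sc$place, ] <- rates[sc$place, ] *
          length(before) / length(pools[[sc$place]])
        pools[[sc$place]] <- before
      }
      for (a in anomalies_by_day[[as.character(d)]] %||% list())
        rates <- apply_anomaly(rates, a$type, a$magnitude %||% 1)
      day_events(rates, pools, dates[d], spec$double_fire_rate)
    })
  })
  df <- do.call(rbind, rows)
  if (!is.null(spec$faults)) {
    bad_day <- as.Date(df$timestamp, tz = "UTC") %in%
      dates[spec$faults$days]
    df <- df[!(bad_day & df$sensor_id %in% spec$faults$dead_sensors), ,
             drop = FALSE]
  }
  gt <- ground_truth(profile, spec, dates, anomalies_by_day)
  log <- new_event_log(df %||% empty_events(), dialect = "synthetic")
  attr(log, "ground_truth") <- gt
  log
}

day_events <- function(rates, pools, date, double_fire_rate) {
  out <- list()
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  for (p in rownames(rates)) {
    for (h in 0:23) {
      n <- stats::rpois(1, rates[p, h + 1])
      if (n == 0) next
      secs <- sort(stats::runif(n, 0, 3600))
      ids <- sample(pools[[p]], n, replace = TRUE)
      dup <- stats::runif(n) < double_fire_rate
      on_t <- c(secs, secs[dup] + stats::runif(sum(dup), 5, 30))
      on_id <- c(ids, ids[dup])
      out[[length(out) + 1]] <- data.frame(
        timestamp = day0 + h * 3600 + c(on_t, on_t + 5),
        sensor_id = c(on_id, on_id),
        value = rep(c("ON", "OFF"), each = length(on_t)),
        sensor_type = "motion", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty_events())
  do.call(rbind, out)
}

ground_truth <- function(profile, spec, dates, anomalies_by_day) {
  sleep_len <- length(profile$sleep_hours)
  sleep <- rep(sleep_len, spec$n_days)
  for (d in names(anomalies_by_day))
    for (a in anomalies_by_day[[d]])
      if (a$type == "away_day")
        sleep[as.integer(d)] <- sleep_len * (1 - (a$magnitude %||% 1))
  list(anomaly_days = dates[vapply(spec$anomalies, `[[`, numeric(1), "day")],
       change_date = if (!is.null(spec$sensor_change))
         dates[spec$sensor_change$day],
       dates = dates,
       sleep_durations = sleep)
}

#' Write the simulation ground truth as JSON
#' @param log an `event_log` from [generate_routine_log()]
#' @param path output `.json` path
#' @return `path`, invisibly
#' @export
write_ground_truth <- function(log, path) {
  gt <- attr(log, "ground_truth")
  stopifnot(!is.null(gt))
  jsonlite::write_json(
    list(anomaly_days = as.character(gt$anomaly_days),
         change_date = if (!is.null(gt$change_date))
           as.character(gt$change_date),
         sleep_durations = gt$sleep_durations),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write an event log in the CASAS text dialect
#'
#' One line per event: `YYYY-MM-DD HH:MM:SS.ff SENSOR VALUE`.
#'
#' @param log an `event_log`
#' @param path output text path
#' @return `path`, invisibly
#' @export
write_casas_log <- function(log, path) {
  lines <- sprintf("%s %s %s",
                   format(log$timestamp, "%Y-%m-%d %H:%M:%OS2", tz = "UTC"),
                   log$sensor_id, log$value)
  writeLines(lines, path)
  invisible(path)
}

#' Preset scenario: three anomalous days in a 60-day routine
#'
#' Two away-days (magnitude 0.8) and one 4-hour sleep shift injected at
#' days 15, 25 and 45 of an otherwise stationary 60-day routine.
#'
#' @param seed RNG seed
#' @param n_days scenario length (default 60)
#' @return a `scenario_spec`
#' @export
scenario_outliers <- function(seed = 1, n_days = 60) {
  scenario_spec(n_days, seed = seed, anomalies = list(
    list(day = 15, type = "away_day", magnitude = 0.8),
    list(day = 25, type = "shifted_sleep", magnitude = 4),
    list(day = 45, type = "away_day", magnitude = 0.8)))
}

#' Preset scenario: kitchen sensor set upgraded mid-series
#'
#' Until day 40 the kitchen runs on a single sensor (a quarter of its
#' eventual data flow); from day 40 three further kitchen sensors come
#' online, stepping the kitchen event flow up — the analogue of a
#' deployment upgrade that the similarity series must flag as a regime
#' change.
#'
#' @param seed RNG seed
#' @param n_days scenario length (default 60)
#' @param change_day first day of the upgraded sensor set (default 40)
#' @return a `scenario_spec`
#' @export
scenario_sensor_change <- function(seed = 1, n_days = 60, change_day = 40) {
  scenario_spec(n_days, seed = seed,
                sensor_change = list(day = change_day, place = "P2",
                                     added_sensors = c("M003", "M004",
                                                       "M005")))
}

#' Preset scenario: anomalous days plus a sensor-set change
#'
#' Combines three anomalous days (days 15, 25, 35) with the day-40 kitchen
#' upgrade of [scenario_sensor_change()].
#'
#' @inheritParams scenario_sensor_change
#' @return a `scenario_spec`
#' @export
scenario_full <- function(seed = 1, n_days = 60, change_day = 40) {
  scenario_spec(n_days, seed = seed,
                anomalies = list(
                  list(day = 15, type = "away_day", magnitude = 0.8),
                  list(day = 25, type = "shifted_sleep", magnitude = 4),
                  list(day = 35, type = "away_day", magnitude = 0.8)),
                sensor_change = list(day = change_day, place = "P2",
                                     added_sensors = c("M003", "M004",
                                                       "M005")))
}
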
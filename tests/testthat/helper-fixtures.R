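# Fixtures built in code.

# A raw event data.frame at given second offsets from a base midnight.
events_at <- function(secs, sensor_id = "M001", value = "ON",
                      sensor_type = "motion",
                      base = as.POSIXct("2021-03-01 00:00:00", tz = "UTC")) {
  data.frame(timestamp = base + secs,
             sensor_id = rep_len(sensor_id, length(secs)),
             value = rep_len(value, length(secs)),
             sensor_type = rep_len(sensor_type, length(secs)),
             stringsAsFactors = FALSE)
}

as_log <- function(...) {
  pheromap:::new_event_log(do.call(rbind, list(...)))
}

# A random raw log of up to n_max events over a few hours, mixing motion,
# door and pressure sensors with ON/OFF values.
random_log <- function(n_max = 50) {
  n <- sample.int(n_max, 1)
  ids <- c("M001", "M002", "M010", "D001", "PR1", "PR2")
  types <- c(M001 = "motion", M002 = "motion", M010 = "motion",
             D001 = "door", PR1 = "pressure", PR2 = "pressure")
  id <- sample(ids, n, replace = TRUE)
  df <- data.frame(
    timestamp = as.POSIXct("2021-03-01 00:00:00", tz = "UTC") +
      sort(round(stats::runif(n, 0, 4 * 3600))),
    sensor_id = id,
    value = sample(c("ON", "OFF"), n, replace = TRUE),
    sensor_type = unname(types[id]),
    stringsAsFactors = FALSE)
  pheromap:::new_event_log(df)
}

# An hourly_counts array with each day equal to `day_matrix` (places x 24).
constant_counts <- function(day_matrix, n_days,
                            start = as.Date("2021-03-01")) {
  dates <- start + seq_len(n_days) - 1
  arr <- array(rep(day_matrix, n_days),
               dim = c(nrow(day_matrix), 24, n_days),
               dimnames = list(rownames(day_matrix), sprintf("h%02d", 0:23),
                               as.character(dates)))
  structure(arr, class = "hourly_counts",
            places = rownames(day_matrix), dates = dates)
}

# A similarity_series with given daily_index values (dates consecutive).
fake_series <- function(values, start = as.Date("2021-03-01")) {
  df <- data.frame(date = start + seq_along(values) - 1,
                   daily_index = values)
  structure(df, class = c("similarity_series", "data.frame"), hours = 0:23)
}

tiny_params <- function(n = 16, sigma = 6) {
  pheromone_params(grid_size = n, sigma = sigma,
                   place_positions = list(P1 = c(4, 4), P2 = c(4, 11),
                                          P3 = c(11, 4), P4 = c(11, 11)),
                   intensity_cap = 10)
}
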
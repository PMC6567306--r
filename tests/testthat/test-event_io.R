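test_that("CASAS lines parse into typed, time-sorted events", {
  path <- withr::local_tempfile(lines = c(
    "2014-04-01 07:12:03 M004 ON",
    "2014-04-01 07:10:00.123456 D001 OPEN some annotation here",
    "",
    "2014-04-01 06:59:59 M010 OFF"))
  log <- read_casas_log(path)
  expect_s3_class(log, "event_log")
  expect_equal(nrow(log), 3)
  # sorted ascending even though the file is out of order
  expect_equal(log$sensor_id, c("M010", "D001", "M004"))
  expect_equal(log$sensor_type, c("motion", "door", "motion"))
  expect_equal(log$value, c("OFF", "OPEN", "ON"))
  expect_equal(format(log$timestamp[3], "%H:%M:%S", tz = "UTC"), "07:12:03")
})

test_that("malformed lines are skipped leniently and fatal in strict mode", {
  path <- withr::local_tempfile(lines = c(
    "2014-04-01 07:12:03 M004 ON",
    "2014-04-01 07:13:00 M004"))      # only 3 fields
  log <- read_casas_log(path)
  expect_equal(nrow(log), 1)
  expect_equal(attr(log, "parse_report")$n_skipped, 1)
  expect_error(read_casas_log(path, strict = TRUE), "malformed")
  empty <- withr::local_tempfile(lines = character())
  expect_equal(nrow(read_casas_log(empty)), 0)
})

test_that("generic CSV dialect round-trips pressure sensors", {
  path <- withr::local_tempfile(lines = c(
    "timestamp,sensor_id,value,sensor_type",
    "2008-11-20T08:00:00,S07,1,motion",
    "2008-11-20T02:00:00,S05,1,pressure"))
  log <- read_generic_csv(path)
  expect_equal(log$sensor_id, c("S05", "S07"))
  expect_equal(log$sensor_type, c("pressure", "motion"))
})

test_that("motion OFF events are removed, other sensors untouched", {
  log <- as_log(events_at(c(0, 10), "M004", c("ON", "OFF")),
                events_at(20, "D001", "OPEN", "door"))
  out <- filter_off_events(log)
  expect_equal(out$sensor_id, c("M004", "D001"))
  expect_equal(out$value, c("ON", "OPEN"))
  # degenerate: only OFF motion events -> empty
  expect_equal(nrow(filter_off_events(as_log(
    events_at(c(0, 5), "M004", "OFF")))), 0)
  # door CLOSE kept by default, dropped on request
  doors <- as_log(events_at(c(0, 10), "D001", c("OPEN", "CLOSE"), "door"))
  expect_equal(nrow(filter_off_events(doors)), 2)
  expect_equal(filter_off_events(doors, drop_door_close = TRUE)$value,
               "OPEN")
})

test_that("debouncing keeps events >= 60 s after the last kept one", {
  # gap anchored on last KEPT event: 30 s suppressed, 90 s kept
  log <- as_log(events_at(c(0, 30, 90)))
  expect_equal(as.numeric(debounce_events(log)$timestamp) -
                 as.numeric(log$timestamp[1]), c(0, 90))
  # 59 s suppressed; 61 s is >= 60 s after the kept event at 0 s
  log2 <- as_log(events_at(c(0, 59, 61)))
  expect_equal(as.numeric(debounce_events(log2)$timestamp) -
                 as.numeric(log2$timestamp[1]), c(0, 61))
  # different sensors never suppress each other
  log3 <- as_log(events_at(0, "M001"), events_at(0, "M002"))
  expect_equal(nrow(debounce_events(log3)), 2)
})

test_that("pressure sensors are muted 10 min after each accounted event", {
  log <- as_log(events_at(c(0, 5, 12) * 60, "PR1", "1", "pressure"))
  out <- mute_pressure_sensors(log)
  expect_equal(as.numeric(out$timestamp) - as.numeric(log$timestamp[1]),
               c(0, 12 * 60))
  # single event always accounted; motion events untouched
  expect_equal(nrow(mute_pressure_sensors(as_log(
    events_at(0, "PR1", "1", "pressure")))), 1)
  mixed <- as_log(events_at(c(0, 30, 60), "M001"))
  expect_equal(nrow(mute_pressure_sensors(mixed)), 3)
})

test_that("sensors map to their places per the HH126 layout", {
  mapping <- hh126_mapping()
  log <- as_log(events_at(0, "M010"), events_at(10, "M003"),
                events_at(20, "X999"))
  out <- map_to_places(log, mapping)
  expect_equal(out$place[out$sensor_id == "M010"], "P1")
  expect_equal(out$place[out$sensor_id == "M003"], "P2")
  expect_false("X999" %in% out$sensor_id)
  expect_equal(attr(out, "n_unmapped_dropped"), 1)
  expect_error(map_to_places(log, mapping, unmapped = "error"), "X999")
})

test_that("place mappings validate their invariants", {
  expect_error(place_mapping(list(P1 = character(), P2 = "M1")),
               "at least one sensor")
  expect_error(place_mapping(list(P1 = "M1", P2 = "M1")),
               "more than one place")
  km <- kasteren_c_mapping()
  expect_equal(km$sensor_to_place[["S05"]], "P1")
  expect_equal(length(km$sensors$P2), 9)
})

test_that("hourly binning is half-open and conserves events", {
  mapping <- place_mapping(list(P1 = "M010", P2 = "M003"))
  log <- map_to_places(as_log(
    events_at(c(10 * 3600 + 300, 10 * 3600 + 3599, 11 * 3600), "M003")),
    mapping)
  hc <- hourly_counts(log, mapping)
  expect_equal(unname(hc["P2", "h10", 1]), 2)
  expect_equal(unname(hc["P2", "h11", 1]), 1)
  expect_equal(sum(hc), nrow(log))
  # empty day range -> empty; no events -> zero matrix
  expect_equal(dim(hourly_counts(log, mapping, days = as.Date(character())))[3],
               0)
  zero <- hourly_counts(log, mapping,
                        days = as.Date("2021-04-01"))
  expect_true(all(zero == 0))
  expect_equal(dim(zero), c(2, 24, 1))
})

test_that("daily-activity CSV round-trips the counts", {
  mapping <- place_mapping(list(P1 = "M010", P2 = "M003"))
  log <- map_to_places(as_log(events_at(c(100, 4000), "M010"),
                              events_at(7300, "M003")), mapping)
  hc <- hourly_counts(log, mapping)
  path <- withr::local_tempfile(fileext = ".csv")
  write_daily_activity(hc, path)
  back <- read_daily_activity(path)
  expect_equal(unclass(back), unclass(hc), ignore_attr = TRUE)
})

test_that("sensor faults silence exactly the listed sensors", {
  log <- as_log(events_at(0, "M004"), events_at(10, "M008"),
                events_at(20, "M001"))
  expect_equal(inject_sensor_fault(log, c("M004", "M008"))$sensor_id,
               "M001")
  expect_equal(nrow(inject_sensor_fault(log, character())), 3)
})

test_that("each preprocessing stage matches its loop oracle and is idempotent", {
  withr::local_seed(421)
  for (i in 1:50) {
    log <- random_log()
    a <- filter_off_events(log)
    expect_equal(a$timestamp, oracle_filter_off(log)$timestamp)
    b <- debounce_events(a)
    expect_equal(b$timestamp, oracle_debounce(a)$timestamp)
    expect_equal(b$sensor_id, oracle_debounce(a)$sensor_id)
    c_ <- mute_pressure_sensors(b)
    expect_equal(c_$timestamp, oracle_mute(b)$timestamp)
    # idempotence of every stage
    expect_identical(nrow(filter_off_events(a)), nrow(a))
    expect_identical(debounce_events(b)$timestamp, b$timestamp)
    expect_identical(mute_pressure_sensors(c_)$timestamp, c_$timestamp)
  }
})

test_that("debounced logs never contain same-sensor gaps below the minimum", {
  withr::local_seed(99)
  for (i in 1:20) {
    out <- debounce_events(random_log())
    for (id in unique(out$sensor_id)) {
      t <- as.numeric(out$timestamp[out$sensor_id == id])
      if (length(t) > 1) expect_true(all(diff(t) >= 60))
    }
  }
})

test_that("the stage ledger accounts for every parsed event", {
  withr::local_seed(7)
  mapping <- place_mapping(list(P1 = c("M001", "M002"), P2 = "M010",
                                P3 = "D001", P4 = c("PR1", "PR2")))
  log <- random_log(200)
  out <- preprocess_events(log, mapping)
  sc <- attr(out, "stage_counts")
  expect_equal(sc$parsed, nrow(log))
  expect_equal(sc$parsed, sc$kept + sc$filtered_off + sc$debounced_away +
                 sc$muted + sc$unmapped_dropped)
  expect_equal(sc$kept, nrow(out))
})
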
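test_that("SSIM is 1 for identical images, symmetric, and bounded", {
  withr::local_seed(5)
  for (i in 1:20) {
    x <- matrix(sample(0:255, 64, replace = TRUE), 8)
    y <- matrix(sample(0:255, 64, replace = TRUE), 8)
    expect_identical(ssim(x, x), 1)
    expect_equal(ssim(x, y), ssim(y, x))
    expect_lte(abs(ssim(x, y)), 1)
  }
  expect_error(ssim(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("SSIM of black vs white equals the closed form", {
  p <- ssim_params()
  expect_equal(p$C1, 6.5025)
  expect_equal(p$C2, 58.5225)
  x <- matrix(0, 16, 16)
  y <- matrix(255, 16, 16)
  # means 0 and 255, all variances 0: C1*C2 / ((255^2 + C1) * C2)
  expect_equal(ssim(x, y, p), 6.5025 / 65031.5025, tolerance = 1e-12)
})

test_that("SSIM agrees with the loop-based oracle on random images", {
  withr::local_seed(6)
  for (i in 1:20) {
    x <- matrix(runif(144, 0, 255), 12)
    y <- matrix(runif(144, 0, 255), 12)
    expect_equal(ssim(x, y), oracle_ssim(x, y), tolerance = 1e-9)
  }
})

test_that("a reference over identical days reproduces any single day", {
  day <- matrix(0, 4, 24, dimnames = list(paste0("P", 1:4), NULL))
  day["P1", 1:8] <- 3
  day["P2", 8:10] <- c(15, 10, 6)
  day["P4", 20:22] <- 12
  hc <- constant_counts(day, 5)
  params <- pheromone_params(intensity_cap = 15)
  ref <- build_reference_set(hc, attr(hc, "dates"), params)
  single <- render_day_maps(hc, params)[[1]]
  for (h in 1:24)
    expect_identical(ref$hourly_images[[h]], single[[h]]$image)
  # one-day window: reference equals that day
  ref1 <- build_reference_set(hc, attr(hc, "dates")[1], params)
  for (h in 1:24)
    expect_identical(ref1$hourly_images[[h]], single[[h]]$image)
})

test_that("averaging happens on counts before quantization", {
  day1 <- matrix(0, 1, 24, dimnames = list("P1", NULL))
  day2 <- day1
  day1["P1", 1] <- 2
  day2["P1", 1] <- 4
  dates <- as.Date("2021-03-01") + 0:1
  arr <- array(c(day1, day2), dim = c(1, 24, 2),
               dimnames = list("P1", sprintf("h%02d", 0:23),
                               as.character(dates)))
  hc <- structure(arr, class = "hourly_counts", places = "P1",
                  dates = dates)
  params <- pheromone_params(place_positions = list(P1 = c(64, 64)),
                             intensity_cap = 4)
  ref <- build_reference_set(hc, dates, params)
  # mean count 3 at the source pixel -> 255 * 3/4
  expect_equal(ref$hourly_images[[1]][65, 65], floor(255 * 3 / 4 + 0.5))
  expect_error(build_reference_set(hc, as.Date("2020-01-01"), params),
               "not covered")
})

test_that("the lowest-dispersion window is selected, earliest on ties", {
  withr::local_seed(8)
  day <- matrix(2, 2, 24, dimnames = list(c("P1", "P2"), NULL))
  hc <- constant_counts(day, 21)
  noise <- array(rpois(2 * 24 * 21, 5), dim = dim(hc))
  noise[, , 8:14] <- 0    # one exactly constant week amid noisy weeks
  hc2 <- hc
  hc2[] <- hc[] + noise
  sel <- select_reference_window(hc2, 7)
  expect_equal(sel$days, attr(hc, "dates")[8:14])
  expect_equal(sel$score, 0)
  # all days identical -> tie broken by the earliest window
  sel_tie <- select_reference_window(hc, 7)
  expect_equal(sel_tie$days, attr(hc, "dates")[1:7])
  expect_error(select_reference_window(constant_counts(day, 5), 7),
               "at least 7")
})

test_that("sleep-duration criterion picks the most uniform week", {
  day <- matrix(1, 1, 24, dimnames = list("P1", NULL))
  hc <- constant_counts(day, 14)
  sleep <- c(6, 9, 7, 10, 8, 5, 9, rep(8, 7))
  sel <- select_reference_window(hc, 7, criterion = "min_sleep_std",
                                 sleep_durations = sleep)
  expect_equal(sel$days, attr(hc, "dates")[8:14])
  expect_equal(sel$score, 0)
  expect_error(select_reference_window(hc, 7, criterion = "min_sleep_std"),
               "sleep duration")
})

test_that("sleep durations are extracted from annotation intervals", {
  path <- withr::local_tempfile(lines = c(
    "start,end,activity",
    "2021-03-01 23:00:00,2021-03-02 06:00:00,Sleeping",
    "2021-03-02 22:00:00,2021-03-03 06:30:00,go to bed",
    "2021-03-02 12:00:00,2021-03-02 12:30:00,Lunch"))
  dates <- as.Date("2021-03-01") + 0:2
  out <- sleep_durations_from_annotations(path, dates)
  expect_equal(out, c(7, 8.5, 0))
})

test_that("days identical to the reference score a daily index of 1", {
  day <- matrix(0, 4, 24, dimnames = list(paste0("P", 1:4), NULL))
  day["P1", 1:7] <- 3
  day["P2", 8] <- 15
  hc <- constant_counts(day, 7)
  params <- pheromone_params(intensity_cap = 15)
  maps <- render_day_maps(hc, params)
  ref <- build_reference_set(hc, attr(hc, "dates"), params)
  series <- similarity_series(maps, ref)
  expect_equal(series$daily_index, rep(1, 7))
  expect_equal(nrow(series), 7)
})

test_that("the daily index is the mean of the selected hourly SSIMs", {
  withr::local_seed(9)
  day <- matrix(rpois(4 * 24, 5), 4, 24,
                dimnames = list(paste0("P", 1:4), NULL))
  hc <- constant_counts(day, 3)
  hc[, , 2] <- rpois(4 * 24, 5)
  params <- pheromone_params(intensity_cap = 10)
  maps <- render_day_maps(hc, params)
  ref <- build_reference_set(hc, attr(hc, "dates")[1], params)
  full <- similarity_series(maps, ref)
  morning <- similarity_series(maps, ref, hours = 7:9)
  expect_equal(morning$daily_index,
               unname(rowMeans(full[, c("h07", "h08", "h09")])))
  expect_equal(names(morning), c("date", "daily_index", "h07", "h08", "h09"))
  expect_error(similarity_series(maps, ref, hours = integer()), "empty")
})

test_that("the index degrades monotonically as one place drifts from the reference", {
  day <- matrix(0, 4, 24, dimnames = list(paste0("P", 1:4), NULL))
  day["P2", 8:10] <- c(15, 10, 6)
  day["P1", 1:7] <- 3
  params <- pheromone_params(intensity_cap = 15)
  hc_ref <- constant_counts(day, 1)
  ref <- build_reference_set(hc_ref, attr(hc_ref, "dates"), params)
  idx <- sapply(seq(1, 0, by = -0.25), function(scale) {
    test_day <- day
    test_day["P2", ] <- day["P2", ] * scale
    hc <- constant_counts(test_day, 1)
    similarity_series(render_day_maps(hc, params), ref)$daily_index
  })
  expect_equal(idx[1], 1)
  expect_true(all(diff(idx) <= 1e-12))
})

test_that("similarity CSV and plot are written", {
  s <- fake_series(c(0.9, 0.8, 1.0))
  attr(s, "reference_window") <- s$date[1:2]
  csv <- withr::local_tempfile(fileext = ".csv")
  write_similarity_csv(s, csv)
  back <- read.csv(csv)
  expect_equal(back$daily_index, s$daily_index)
  fig <- withr::local_tempfile(fileext = ".png")
  plot_similarity(s, path = fig)
  expect_true(file.size(fig) > 0)
})
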
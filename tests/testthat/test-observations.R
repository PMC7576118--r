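test_that("observation CSVs round-trip with categories preserved", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_obs_csv(f, list(
    obs_row(category = "ewe", distance = 5),
    obs_row(category = "ram", distance = 12, camera_id = "C02"),
    obs_row(category = "unknown", distance = 3)))
  obs <- read_observations(f)
  expect_s3_class(obs, "ct_observations")
  expect_equal(nrow(obs), 3)
  expect_equal(as.character(obs$category), c("ewe", "ram", "unknown"))

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, f2)
  obs2 <- read_observations(f2)
  expect_equal(as.data.frame(obs2), as.data.frame(obs))
})

test_that("row-level validation errors name the offending rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_obs_csv(f, list(obs_row(), obs_row(distance = -1),
                        obs_row(category = "lamb")))
  expect_error(read_observations(f), "negative distance in row\\(s\\) 2")
  expect_error(read_observations(f), "unknown category in row\\(s\\) 3")

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_obs_csv(f2, list(obs_row(distance = 55)))
  expect_error(read_observations(f2), "exceeds maximum")
  expect_error(read_observations(f2, max_distance = 60), NA)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("camera_id,when,species,category,distance\nC01,x,b,ewe,1", f3)
  expect_error(read_observations(f3), "missing column")
})

test_that("deployment validation enforces interval and parameter rules", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_dep_csv(f)
  dep <- read_deployments(f)
  expect_s3_class(dep, "ct_deployments")
  expect_equal(dep$trigger_interval_t, c(15, 15))
  expect_equal(dep$fov_theta, c(50, 50))

  bad <- as.data.frame(dep)
  bad$end[1] <- bad$start[1]
  expect_error(validate_deployments(bad), "end <= start")
  overlapping <- rbind(as.data.frame(dep),
                       as.data.frame(dep)[1, , drop = FALSE])
  expect_error(validate_deployments(overlapping), "overlapping")
  bad_t <- as.data.frame(dep); bad_t$trigger_interval_t <- 0
  expect_error(validate_deployments(bad_t), "trigger_interval_t")
})

test_that("solar windows match the NOAA calculator and offsets", {
  # independent NOAA-algorithm values for 2017-12-21 at 32.7 N, 108.7 W,
  # UTC-7: sunrise 433.18 min, sunset 1033.09 min after local midnight
  st <- sun_times(as.Date("2017-12-21"), 32.7, -108.7, -7)
  expect_lt(abs(st$sunrise - 433.18), 2)
  expect_lt(abs(st$sunset - 1033.09), 2)

  w <- solar_window("2017-12-21", 32.7, -108.7, -7)
  midnight <- as.POSIXct("2017-12-21 00:00:00", tz = "UTC")
  expect_equal(as.numeric(w$window_start - midnight, units = "mins"),
               st$sunrise - 60)
  expect_equal(as.numeric(w$window_end - midnight, units = "mins"),
               st$sunset + 120)

  expect_error(sun_times(as.Date("2018-06-21"), 70, 0, 0),
               "unsupported latitude")
})

test_that("window length increases from winter to summer solstice", {
  dates <- seq(as.Date("2017-12-21"), as.Date("2018-06-21"), by = "14 day")
  lens <- vapply(dates, function(d) {
    w <- solar_window(d, 32.7, -108.7, -7)
    as.numeric(w$window_end - w$window_start, units = "mins")
  }, numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("censoring keeps in-window records and reports the fraction", {
  wins <- flat_windows("2017-10-01", "2017-10-10")
  f <- withr::local_tempfile(fileext = ".csv")
  write_obs_csv(f, list(
    obs_row(timestamp = "2017-10-05 12:00:00"),
    obs_row(timestamp = "2017-10-05 23:59:00"),
    obs_row(timestamp = "2017-10-06 06:00:00")))
  obs <- read_observations(f)
  cen <- censor_records(obs, wins)
  expect_equal(nrow(cen$records), 2)
  expect_equal(cen$censored_fraction, 1 / 3)

  all_in <- censor_records(obs[c(1, 3), ], wins)
  expect_equal(all_in$censored_fraction, 0)

  expect_error(
    censor_records(obs, flat_windows("2017-10-01", "2017-10-04")),
    "missing availability window")
})

test_that("snapshot effort follows the wedge-scaled definition", {
  wins <- flat_windows("2017-10-05", "2017-10-05",
                       from = "10:00:00", to = "11:00:00")
  dep <- validate_deployments(data.frame(
    camera_id = "C01", latitude = 32.7, longitude = -108.7,
    start = as.POSIXct("2017-10-01 00:00:00", tz = "UTC"),
    end = as.POSIXct("2017-11-01 00:00:00", tz = "UTC"),
    trigger_interval_t = 15, fov_theta = 50))
  period <- survey_period("fall", "2017-10-01", "2017-10-31")
  eff <- compute_effort(dep, wins, period)
  expect_equal(eff$available_seconds, 3600)
  expect_equal(eff$snapshots, 240)
  expect_equal(eff$effective_effort, 240 * 50 / 360)

  # full-circle identity and inverse proportionality in t
  eff360 <- compute_effort(dep, wins, period, theta = 360)
  expect_equal(eff360$effective_effort, eff360$snapshots)
  eff30 <- compute_effort(dep, wins, period, t = 30)
  expect_equal(eff30$snapshots, eff$snapshots / 2)
})

test_that("effort is bounded by period length and ignores out-of-period time", {
  wins <- flat_windows("2017-10-01", "2017-10-31")
  dep <- validate_deployments(data.frame(
    camera_id = "C01", latitude = 32.7, longitude = -108.7,
    start = as.POSIXct("2017-09-01 00:00:00", tz = "UTC"),
    end = as.POSIXct("2017-12-01 00:00:00", tz = "UTC"),
    trigger_interval_t = 15, fov_theta = 50))
  period <- survey_period("w1", "2017-10-01", "2017-10-07")
  eff <- compute_effort(dep, wins, period)
  expect_lte(eff$available_seconds, 7 * 86400)
  expect_equal(eff$available_seconds, 7 * 12 * 3600)

  # operational gap (hole between intervals) is not imputed
  dep2 <- validate_deployments(data.frame(
    camera_id = c("C01", "C01"), latitude = 32.7, longitude = -108.7,
    start = as.POSIXct(c("2017-10-01 00:00:00", "2017-10-05 00:00:00"),
                       tz = "UTC"),
    end = as.POSIXct(c("2017-10-03 00:00:00", "2017-10-08 00:00:00"),
                     tz = "UTC"),
    trigger_interval_t = 15, fov_theta = 50))
  eff2 <- compute_effort(dep2, wins, period)
  expect_equal(eff2$available_seconds, (2 + 3) * 12 * 3600)

  dep_out <- validate_deployments(data.frame(
    camera_id = "C01", latitude = 32.7, longitude = -108.7,
    start = as.POSIXct("2018-05-01 00:00:00", tz = "UTC"),
    end = as.POSIXct("2018-06-01 00:00:00", tz = "UTC"),
    trigger_interval_t = 15, fov_theta = 50))
  expect_warning(compute_effort(dep_out, wins, period), "zero effort")
})
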
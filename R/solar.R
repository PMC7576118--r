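#' Sunrise and sunset by solar position
#'
#' Computes local sunrise and sunset times for a date and place using the
#' NOAA solar-position equations (Julian-century formulation with apparent
#' solar longitude, obliquity correction and the equation of time), with the
#' standard refraction-corrected zenith of 90.833 degrees. Times are local
#' standard time under a fixed UTC offset; no daylight-saving shifts are
#' applied, matching field cameras whose clocks keep a fixed offset.
#'
#' @param date a `Date` (or string coercible to one).
#' @param latitude,longitude decimal degrees; longitude positive east.
#' @param utc_offset hours relative to UTC (e.g. -7 for Mountain Standard
#'   Time).
#' @return list with `sunrise` and `sunset` in minutes after local midnight.
#' @examples
#' sun_times(as.Date("2017-12-21"), 32.7, -108.7, -7)
#' @export
sun_times <- function(date, latitude, longitude, utc_offset) {
  if (abs(latitude) >= 66)
    stop("unsupported latitude: |latitude| must be < 66 degrees ",
         "(polar day/night not handled)")
  date <- as.Date(date)

  solar_pos <- function(minutes_local) {
    jd <- as.numeric(date) + 2440587.5 + minutes_local / 1440 -
      utc_offset / 24
    tc <- (jd - 2451545) / 36525
    L0 <- (280.46646 + tc * (36000.76983 + tc * 3.032e-4)) %% 360
    M  <- 357.52911 + tc * (35999.05029 - 1.537e-4 * tc)
    ecc <- 0.016708634 - tc * (4.2037e-5 + 1.267e-7 * tc)
    ctr <- sin(d2r(M)) * (1.914602 - tc * (0.004817 + 1.4e-5 * tc)) +
      sin(d2r(2 * M)) * (0.019993 - 1.01e-4 * tc) +
      sin(d2r(3 * M)) * 2.89e-4
    omega <- 125.04 - 1934.136 * tc
    lambda <- L0 + ctr - 0.00569 - 0.00478 * sin(d2r(omega))
    eps0 <- 23 + (26 + (21.448 - tc * (46.815 + tc * (5.9e-4 -
      tc * 0.001813))) / 60) / 60
    eps <- eps0 + 0.00256 * cos(d2r(omega))
    decl <- r2d(asin(sin(d2r(eps)) * sin(d2r(lambda))))
    vy <- tan(d2r(eps / 2))^2
    eqtime <- 4 * r2d(
      vy * sin(2 * d2r(L0)) - 2 * ecc * sin(d2r(M)) +
        4 * ecc * vy * sin(d2r(M)) * cos(2 * d2r(L0)) -
        0.5 * vy^2 * sin(4 * d2r(L0)) - 1.25 * ecc^2 * sin(2 * d2r(M)))
    list(decl = decl, eqtime = eqtime)
  }

  hour_angle <- function(decl) {
    cos_ha <- cos(d2r(90.833)) / (cos(d2r(latitude)) * cos(d2r(decl))) -
      tan(d2r(latitude)) * tan(d2r(decl))
    r2d(acos(pmin(1, pmax(-1, cos_ha))))
  }

  sp <- solar_pos(720)
  noon <- 720 - 4 * longitude - sp$eqtime + utc_offset * 60
  sunrise <- noon - 4 * hour_angle(sp$decl)
  sunset  <- noon + 4 * hour_angle(sp$decl)
  for (i in 1:2) {   # refine declination/eqtime at the event times
    s1 <- solar_pos(sunrise); s2 <- solar_pos(sunset)
    sunrise <- 720 - 4 * longitude - s1$eqtime + utc_offset * 60 -
      4 * hour_angle(s1$decl)
    sunset  <- 720 - 4 * longitude - s2$eqtime + utc_offset * 60 +
      4 * hour_angle(s2$decl)
  }
  list(sunrise = sunrise, sunset = sunset)
}

d2r <- function(x) x * pi / 180
r2d <- function(x) x * 180 / pi

#' Diel availability window for one date
#'
#' The availability window runs from one hour before sunrise to two hours
#' after sunset, the period a diurnal ungulate is taken to be active and
#' hence available for detection. Effort and detections outside the window
#' are censored.
#'
#' @inheritParams sun_times
#' @return data frame with `date`, `window_start`, `window_end` (`POSIXct`,
#'   carried in UTC but representing local standard clock time).
#' @seealso [availability_windows()] for a range of dates.
#' @export
solar_window <- function(date, latitude, longitude, utc_offset) {
  date <- as.Date(date)
  st <- sun_times(date, latitude, longitude, utc_offset)
  midnight <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  start <- midnight + (st$sunrise - 60) * 60
  end <- midnight + (st$sunset + 120) * 60
  stopifnot(start < end)
  data.frame(date = date, window_start = start, window_end = end)
}

#' Availability windows over a date range
#'
#' @param start_date,end_date inclusive date range.
#' @inheritParams sun_times
#' @return data frame with one row per date, as [solar_window()].
#' @export
availability_windows <- function(start_date, end_date, latitude, longitude,
                                 utc_offset) {
  dates <- seq(as.Date(start_date), as.Date(end_date), by = "day")
  do.call(rbind, lapply(dates, solar_window, latitude = latitude,
                        longitude = longitude, utc_offset = utc_offset))
}
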
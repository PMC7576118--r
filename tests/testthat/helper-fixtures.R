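# Independent simulation oracle: radial distances from a point-transect
# half-normal detection process, by rejection sampling (availability r,
# thinned by exp(-r^2 / 2 sigma^2)). Deliberately does not reuse the
# package's density code.
sim_hn_distances <- function(n, sigma, w, seed) {
  set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    r <- w * sqrt(runif(4 * n))          # availability: f0(r) = 2r/w^2
    keep <- runif(length(r)) < exp(-r^2 / (2 * sigma^2))
    out <- c(out, r[keep])
  }
  out[seq_len(n)]
}

# tiny observation/deployment CSV fixtures written on the fly
write_obs_csv <- function(path, rows) {
  df <- do.call(rbind, lapply(rows, as.data.frame))
  write.csv(df, path, row.names = FALSE)
  path
}

obs_row <- function(camera_id = "C01", timestamp = "2017-10-05 12:00:00",
                    species = "bighorn", category = "ewe",
                    distance = 5) {
  list(camera_id = camera_id, timestamp = timestamp, species = species,
       category = category, distance = distance)
}

write_dep_csv <- function(path,
                          camera_ids = c("C01", "C02"),
                          start = "2017-10-01 00:00:00",
                          end = "2018-02-01 00:00:00") {
  df <- data.frame(camera_id = camera_ids, latitude = 32.7,
                   longitude = -108.7, start = start, end = end)
  write.csv(df, path, row.names = FALSE)
  path
}

# flat availability windows (06:00 - 18:00) over a date range, bypassing
# the solar calculation where tests need exact arithmetic
flat_windows <- function(start_date, end_date, from = "06:00:00",
                         to = "18:00:00") {
  dates <- seq(as.Date(start_date), as.Date(end_date), by = "day")
  data.frame(
    date = dates,
    window_start = as.POSIXct(paste(format(dates), from), tz = "UTC"),
    window_end = as.POSIXct(paste(format(dates), to), tz = "UTC"))
}
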
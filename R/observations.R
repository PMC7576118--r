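#' Observation and deployment data
#'
#' Camera-trap observations are one row per detected individual: an image
#' with k classified animals contributes k rows, each with its own measured
#' radial distance. Categories follow the closed vocabulary
#' `ram`, `ewe`, `young`, `adult_unknown` (adult-sized, sex undiscernible)
#' and `unknown` (undiscernible animal); `unknown` is excluded from
#' category-specific strata but counted in totals.
#'
#' @name observation-data
NULL

CATEGORY_LEVELS <- c("ram", "ewe", "young", "adult_unknown", "unknown")

#' Column mapping for observation files
#'
#' @param camera_id,timestamp,species,category,distance column names in the
#'   input file holding each field.
#' @return named list used by [read_observations()].
#' @export
obs_schema <- function(camera_id = "camera_id", timestamp = "timestamp",
                       species = "species", category = "category",
                       distance = "distance") {
  list(camera_id = camera_id, timestamp = timestamp, species = species,
       category = category, distance = distance)
}

#' Read camera-trap observation records
#'
#' Reads a CSV (UTF-8, header row) of per-individual detections, applies a
#' column mapping and validates every row. Rows failing validation are
#' reported by row index and the read errors out rather than silently
#' dropping them.
#'
#' @param path CSV file.
#' @param schema column mapping from [obs_schema()].
#' @param max_distance maximum admissible radial distance in metres
#'   (default 40).
#' @param tz_format timestamp format string (default `"%Y-%m-%d %H:%M:%S"`).
#' @return data frame of class `ct_observations` with columns `camera_id`,
#'   `timestamp` (POSIXct, local standard time carried in UTC), `species`,
#'   `category` (factor on the closed vocabulary) and `distance` (metres).
#' @export
read_observations <- function(path, schema = obs_schema(),
                              max_distance = 40,
                              tz_format = "%Y-%m-%d %H:%M:%S") {
  if (!file.exists(path)) stop("observation file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unlist(schema), names(raw))
  if (length(missing_cols))
    stop("schema error: missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  x <- data.frame(
    camera_id = as.character(raw[[schema$camera_id]]),
    timestamp = as.POSIXct(as.character(raw[[schema$timestamp]]),
                           format = tz_format, tz = "UTC"),
    species   = as.character(raw[[schema$species]]),
    category  = as.character(raw[[schema$category]]),
    distance  = suppressWarnings(as.numeric(raw[[schema$distance]])),
    stringsAsFactors = FALSE
  )
  validate_observations(x, max_distance = max_distance)
}

#' Validate an observation data frame
#'
#' @param x data frame with the `ct_observations` columns.
#' @param max_distance maximum admissible distance (metres).
#' @return `x` with class `ct_observations`; errors list offending rows.
#' @export
validate_observations <- function(x, max_distance = 40) {
  bad <- character(0)
  row_ids <- seq_len(nrow(x))
  flag <- function(cond, what) {
    if (any(cond)) bad <<- c(bad, paste0(
      what, " in row(s) ", paste(row_ids[cond], collapse = ", ")))
  }
  flag(is.na(x$timestamp), "unparsable timestamp")
  flag(is.na(x$distance), "unparsable distance")
  flag(!is.na(x$distance) & x$distance < 0, "negative distance")
  flag(!is.na(x$distance) & x$distance > max_distance,
       paste0("distance exceeds maximum (", max_distance, " m)"))
  flag(!(x$category %in% CATEGORY_LEVELS), "unknown category")
  if (length(bad))
    stop("observation validation failed:\n  ",
         paste(bad, collapse = "\n  "))
  x$category <- factor(x$category, levels = CATEGORY_LEVELS)
  class(x) <- c("ct_observations", "data.frame")
  x
}

#' Write observation records
#'
#' Round-trips with [read_observations()]: all fields are preserved for
#' valid rows.
#'
#' @param x `ct_observations` data frame.
#' @param path output CSV path.
#' @export
write_observations <- function(x, path) {
  out <- as.data.frame(x)
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  out$category <- as.character(out$category)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read camera deployment metadata
#'
#' One row per operational interval: a camera that failed and was restored
#' appears as several rows whose intervals are the periods it was running
#' (gaps are not imputed). Optional `trigger_interval_t` (seconds, default
#' 15) and `fov_theta` (degrees, default 50) columns override the
#' camera-level defaults.
#'
#' @param path CSV with columns `camera_id`, `latitude`, `longitude`,
#'   `start`, `end` and optionally `trigger_interval_t`, `fov_theta`.
#' @param trigger_interval_t,fov_theta defaults applied where the file has
#'   no column.
#' @return data frame of class `ct_deployments`.
#' @export
read_deployments <- function(path, trigger_interval_t = 15, fov_theta = 50) {
  if (!file.exists(path)) stop("deployment file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("camera_id", "latitude", "longitude", "start", "end")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("schema error: missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  x <- data.frame(
    camera_id = as.character(raw$camera_id),
    latitude = as.numeric(raw$latitude),
    longitude = as.numeric(raw$longitude),
    start = as.POSIXct(raw$start, format = "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    end = as.POSIXct(raw$end, format = "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    trigger_interval_t = if ("trigger_interval_t" %in% names(raw))
      as.numeric(raw$trigger_interval_t) else trigger_interval_t,
    fov_theta = if ("fov_theta" %in% names(raw))
      as.numeric(raw$fov_theta) else fov_theta,
    stringsAsFactors = FALSE
  )
  validate_deployments(x)
}

#' Validate deployment metadata
#'
#' Checks per-camera operational intervals are ordered and non-overlapping,
#' `trigger_interval_t > 0` and `0 < fov_theta <= 360`.
#'
#' @param x data frame with the `ct_deployments` columns.
#' @return `x` with class `ct_deployments`.
#' @export
validate_deployments <- function(x) {
  if (any(is.na(x$start) | is.na(x$end)))
    stop("deployment validation failed: unparsable interval timestamps")
  if (any(x$end <= x$start))
    stop("deployment validation failed: interval end <= start")
  if (any(x$trigger_interval_t <= 0))
    stop("deployment validation failed: trigger_interval_t must be > 0")
  if (any(x$fov_theta <= 0 | x$fov_theta > 360))
    stop("deployment validation failed: fov_theta must be in (0, 360]")
  for (cam in unique(x$camera_id)) {
    iv <- x[x$camera_id == cam, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
      stop("deployment validation failed: overlapping operational ",
           "intervals for camera ", cam)
  }
  x <- x[order(x$camera_id, x$start), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("ct_deployments", "data.frame")
  x
}

#' Define a survey period
#'
#' @param label period label, e.g. `"fall"` or `"spring"`.
#' @param start_date,end_date inclusive calendar dates.
#' @return list of class `survey_period`.
#' @export
survey_period <- function(label, start_date, end_date) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  stopifnot(start_date <= end_date)
  structure(list(label = label, start_date = start_date,
                 end_date = end_date), class = "survey_period")
}

#' Default fall and spring survey periods
#'
#' Fall runs 1 October 2017 to 31 January 2018 and spring 1 March 2018 to
#' 1 May 2018; both are configurable via [survey_period()].
#'
#' @return named list of two `survey_period` objects.
#' @export
default_periods <- function() {
  list(fall = survey_period("fall", "2017-10-01", "2018-01-31"),
       spring = survey_period("spring", "2018-03-01", "2018-05-01"))
}

#' Censor records to diel availability windows
#'
#' Keeps records whose timestamp falls inside the availability window of
#' its calendar date; reports the censored fraction.
#'
#' @param records `ct_observations` data frame.
#' @param windows data frame from [availability_windows()].
#' @return list with `records` (retained rows), `censored_fraction`,
#'   `n_total` and `n_censored`.
#' @export
censor_records <- function(records, windows) {
  if (nrow(records) == 0)
    return(list(records = records, censored_fraction = 0,
                n_total = 0L, n_censored = 0L))
  rec_date <- as.Date(records$timestamp, tz = "UTC")
  idx <- match(rec_date, windows$date)
  if (anyNA(idx))
    stop("missing availability window for date(s): ",
         paste(unique(format(rec_date[is.na(idx)])), collapse = ", "))
  inside <- records$timestamp >= windows$window_start[idx] &
    records$timestamp <= windows$window_end[idx]
  list(records = records[inside, , drop = FALSE],
       censored_fraction = 1 - mean(inside),
       n_total = nrow(records),
       n_censored = sum(!inside))
}

#' Snapshot effort per camera
#'
#' Survey effort for a camera-trap point survey is the number of trigger
#' opportunities: operating seconds within the survey period and the diel
#' availability windows, divided by the snapshot interval `t`. Because the
#' camera samples a wedge of `theta` degrees rather than a full circle,
#' effective effort scales the snapshot count by `theta/360`. Snapshot
#' counts are kept real-valued: effort is a rate denominator, not an event
#' count.
#'
#' @param deployments `ct_deployments` data frame.
#' @param windows availability windows covering the survey period.
#' @param period a [survey_period()].
#' @param t snapshot (trigger) interval in seconds; defaults to the
#'   per-deployment `trigger_interval_t`.
#' @param theta field-of-view angle in degrees; defaults to the
#'   per-deployment `fov_theta`.
#' @return data frame of class `ct_effort` with one row per camera:
#'   `camera_id`, `available_seconds`, `snapshots`, `effective_effort`.
#' @export
compute_effort <- function(deployments, windows, period, t = NULL,
                           theta = NULL) {
  p_start <- as.POSIXct(paste(format(period$start_date), "00:00:00"),
                        tz = "UTC")
  p_end <- as.POSIXct(paste(format(period$end_date + 1), "00:00:00"),
                      tz = "UTC")
  cams <- unique(deployments$camera_id)
  out <- data.frame(camera_id = cams, available_seconds = 0,
                    snapshots = 0, effective_effort = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cams)) {
    dep <- deployments[deployments$camera_id == cams[i], , drop = FALSE]
    t_i <- if (is.null(t)) dep$trigger_interval_t[1] else t
    th_i <- if (is.null(theta)) dep$fov_theta[1] else theta
    secs <- 0
    for (j in seq_len(nrow(dep))) {
      lo <- pmax(as.numeric(dep$start[j]), as.numeric(p_start),
                 as.numeric(windows$window_start))
      hi <- pmin(as.numeric(dep$end[j]), as.numeric(p_end),
                 as.numeric(windows$window_end))
      secs <- secs + sum(pmax(0, hi - lo))
    }
    out$available_seconds[i] <- secs
    out$snapshots[i] <- secs / t_i
    out$effective_effort[i] <- secs / t_i * th_i / 360
  }
  if (all(out$available_seconds == 0))
    warning("zero effort: no overlap between operational intervals, ",
            "availability windows and the survey period")
  class(out) <- c("ct_effort", "data.frame")
  out
}
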
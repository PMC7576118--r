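#' Analysis configuration for the end-to-end pipeline
#'
#' @param observations a `ct_observations` data frame, or a path to a CSV
#'   readable by [read_observations()].
#' @param deployments a `ct_deployments` data frame, or a path readable by
#'   [read_deployments()].
#' @param periods named list of [survey_period()]s (default
#'   [default_periods()]).
#' @param strata named list mapping stratum labels to the category levels
#'   pooled into them. The default analyses rams, ewes, young, and adults
#'   (rams + ewes + adult-unknown pooled); the `unknown` category enters no
#'   stratum but is counted in totals.
#' @param latitude,longitude,utc_offset site location for the diel
#'   windows.
#' @param t,theta snapshot interval (s) and field of view (deg).
#' @param w truncation distance (m).
#' @param area_A study-area size (km^2).
#' @param alpha study-wide error rate (default 0.1; 90% intervals and GOF
#'   gate at p >= 0.1).
#' @param grid candidate detection models (default [candidate_grid()]).
#' @param gof_bins initial GOF bin count.
#' @param min_n minimum distances required to fit a stratum (default 10).
#' @param output_dir optional directory; when set, [run_analysis()] writes
#'   the report CSVs there.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(observations, deployments,
                            periods = default_periods(),
                            strata = list(
                              rams = "ram", ewes = "ewe", young = "young",
                              adults = c("ram", "ewe", "adult_unknown")),
                            latitude = 32.7, longitude = -108.7,
                            utc_offset = -7, t = 15, theta = 50, w = 40,
                            area_A = 6.2, alpha = 0.1,
                            grid = candidate_grid(w), gof_bins = 5,
                            min_n = 10, output_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.character(observations))
    observations <- read_observations(observations, max_distance = w)
  if (is.character(deployments))
    deployments <- read_deployments(deployments)
  structure(list(observations = observations, deployments = deployments,
                 periods = periods, strata = strata, latitude = latitude,
                 longitude = longitude, utc_offset = utc_offset, t = t,
                 theta = theta, w = w, area_A = area_A, alpha = alpha,
                 grid = grid, gof_bins = gof_bins, min_n = min_n,
                 output_dir = output_dir), class = "analysis_config")
}

#' Run the full camera-trap distance-sampling analysis
#'
#' For each survey period: build daily availability windows, censor
#' records, compute snapshot effort; then for each stratum fit the
#' candidate detection models to that stratum's distances, gate and rank
#' them by goodness of fit and AIC, estimate abundance under every
#' competing model and model-average whenever two or more compete. Strata
#' with too few observations yield explicit `SKIPPED` rows rather than
#' silent omission. The run is deterministic given the config and inputs.
#'
#' @param config an [analysis_config()].
#' @return list of class `report_bundle`: `estimates` (one row per
#'   stratum x period), `model_table` (all candidate fits), `effort`
#'   (per period), `censoring` (summary per period), and `log` (character
#'   vector). When `config$output_dir` is set the tables are also written
#'   as CSV.
#' @export
run_analysis <- function(config) {
  logline <- character(0)
  say <- function(...) logline <<- c(logline, sprintf(...))
  say("ctds run: %d observation records, %d cameras, alpha = %.2f",
      nrow(config$observations),
      length(unique(config$deployments$camera_id)), config$alpha)

  est_rows <- list(); model_rows <- list(); effort_rows <- list()
  cens_rows <- list()
  for (pname in names(config$periods)) {
    period <- config$periods[[pname]]
    windows <- availability_windows(period$start_date, period$end_date,
                                    config$latitude, config$longitude,
                                    config$utc_offset)
    in_period <- as.Date(config$observations$timestamp, tz = "UTC") >=
      period$start_date &
      as.Date(config$observations$timestamp, tz = "UTC") <=
      period$end_date
    obs_p <- config$observations[in_period, , drop = FALSE]
    cen <- censor_records(obs_p, windows)
    if (cen$censored_fraction > 0.05)
      say("WARNING: censored fraction %.1f%% in period %s exceeds 5%%",
          100 * cen$censored_fraction, pname)
    cens_rows[[pname]] <- data.frame(
      period = pname, n_total = cen$n_total, n_censored = cen$n_censored,
      censored_fraction = cen$censored_fraction)
    effort <- compute_effort(config$deployments, windows, period,
                             t = config$t, theta = config$theta)
    effort_rows[[pname]] <- cbind(period = pname, as.data.frame(effort))
    recs <- cen$records

    for (sname in names(config$strata)) {
      cats <- config$strata[[sname]]
      sub <- recs[as.character(recs$category) %in% cats, , drop = FALSE]
      if (nrow(sub) < config$min_n) {
        say("stratum %s/%s SKIPPED: only %d observations (min %d)",
            sname, pname, nrow(sub), config$min_n)
        est_rows[[paste(sname, pname)]] <- skipped_row(sname, pname,
                                                       nrow(sub))
        next
      }
      res <- tryCatch({
        fits <- lapply(config$grid, function(cf)
          fit_detection(sub$distance, cf))
        for (i in seq_along(fits))
          if (!fits[[i]]$rejected)
            fits[[i]]$gof <- gof_chi2(fits[[i]], n_bins = config$gof_bins)
        ms <- rank_models(fits, gof_alpha = config$alpha)
        counts <- table(factor(sub$camera_id,
                               levels = effort$camera_id))
        counts <- setNames(as.numeric(counts), names(counts))
        ests <- lapply(ms$competing, function(j)
          estimate_abundance(counts, effort, ms$fits[[j]],
                             theta = config$theta, area_A = config$area_A,
                             w = config$w, alpha = config$alpha,
                             stratum = sname, period = pname))
        est <- model_average(ests, ms$table$weight[ms$competing])
        model_rows[[paste(sname, pname)]] <-
          cbind(stratum = sname, period = pname, ms$table)
        say("stratum %s/%s: n = %d, %d competing model(s), N = %.2f",
            sname, pname, est$n_obs, length(ms$competing), est$N_hat)
        data.frame(
          stratum = sname, period = pname, status = "OK",
          n_obs = est$n_obs, N_hat = est$N_hat, D_hat = est$D_hat,
          ci_low = est$ci_low, ci_high = est$ci_high,
          cv = est$cv_total, cv_encounter = est$cv_encounter,
          cv_detection = est$cv_detection,
          n_models = length(ms$competing), stringsAsFactors = FALSE)
      }, error = function(e) {
        say("stratum %s/%s ERROR: %s", sname, pname, conditionMessage(e))
        skipped_row(sname, pname, nrow(sub), status = "ERROR")
      })
      est_rows[[paste(sname, pname)]] <- res
    }
  }

  bundle <- structure(list(
    estimates = do.call(rbind, est_rows),
    model_table = do.call(rbind, model_rows),
    effort = do.call(rbind, effort_rows),
    censoring = do.call(rbind, cens_rows),
    log = logline, config = config), class = "report_bundle")
  rownames(bundle$estimates) <- NULL
  if (!is.null(bundle$model_table)) rownames(bundle$model_table) <- NULL
  rownames(bundle$effort) <- NULL
  rownames(bundle$censoring) <- NULL

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) if (!is.null(df))
      write.csv(df, file.path(config$output_dir, name), row.names = FALSE)
    wr(bundle$estimates, "estimates.csv")
    wr(bundle$model_table, "model_comparison.csv")
    wr(bundle$effort, "effort.csv")
    wr(bundle$censoring, "censoring.csv")
    writeLines(bundle$log, file.path(config$output_dir, "run_log.txt"))
  }
  bundle
}

skipped_row <- function(stratum, period, n, status = "SKIPPED") {
  data.frame(stratum = stratum, period = period, status = status,
             n_obs = n, N_hat = NA_real_, D_hat = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, cv = NA_real_,
             cv_encounter = NA_real_, cv_detection = NA_real_,
             n_models = 0L, stringsAsFactors = FALSE)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Camera-trap distance-sampling report\n")
  print(x$estimates, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Compare abundance estimates with census values
#'
#' Joins estimates with independent census counts by stratum and period
#' and reports the signed and absolute differences and whether the census
#' lies inside each estimate's confidence interval. Census rows with no
#' matching estimate are listed, not fatal.
#'
#' @param estimates data frame with columns `stratum`, `period`, `N_hat`,
#'   `ci_low`, `ci_high` — e.g. the `estimates` element of a
#'   [run_analysis()] bundle, or an externally printed results table.
#' @param census data frame with columns `stratum`, `period`, `N`.
#' @return list of class `census_comparison`: `table` (per matched row:
#'   difference, abs_difference, inside_ci), `mean_abs_difference`,
#'   `all_inside_ci`, `unmatched` (census rows without an estimate).
#' @export
compare_to_census <- function(estimates, census) {
  if (inherits(estimates, "report_bundle"))
    estimates <- estimates$estimates
  keye <- paste(estimates$stratum, estimates$period)
  keyc <- paste(census$stratum, census$period)
  m <- match(keyc, keye)
  unmatched <- census[is.na(m), , drop = FALSE]
  matched <- which(!is.na(m))
  idx <- m[matched]
  tab <- data.frame(
    stratum = census$stratum[matched], period = census$period[matched],
    census_N = census$N[matched], N_hat = estimates$N_hat[idx],
    ci_low = estimates$ci_low[idx], ci_high = estimates$ci_high[idx],
    stringsAsFactors = FALSE)
  tab$difference <- tab$N_hat - tab$census_N
  tab$abs_difference <- abs(tab$difference)
  tab$inside_ci <- tab$census_N >= tab$ci_low & tab$census_N <= tab$ci_high
  structure(list(
    table = tab,
    mean_abs_difference = mean(tab$abs_difference, na.rm = TRUE),
    all_inside_ci = all(tab$inside_ci, na.rm = TRUE),
    unmatched = unmatched), class = "census_comparison")
}

#' @export
print.census_comparison <- function(x, ...) {
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("mean |difference| = %.2f; all censuses inside CI: %s\n",
              x$mean_abs_difference, x$all_inside_ci))
  if (nrow(x$unmatched))
    cat("unmatched census rows:",
        paste(x$unmatched$stratum, x$unmatched$period, collapse = "; "),
        "\n")
  invisible(x)
}

#' Printed seasonal results table bundled with the package
#'
#' Loads the published seasonal abundance table (point estimates, 90%
#' limits, CVs and the drive-count censuses) shipped as a plain-text CSV,
#' for use as input to [compare_to_census()] and the survey-design
#' planner.
#'
#' @return data frame with columns `stratum`, `period`, `census_N`,
#'   `ci_low`, `N_hat`, `ci_high`, `cv`.
#' @export
printed_results_table <- function() {
  read.csv(system.file("extdata", "seasonal_results_printed.csv",
                       package = "ctds"), stringsAsFactors = FALSE)
}
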
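#' Encounter-rate statistics across cameras
#'
#' The encounter rate is total detections over total effort. Its variance
#' is the effort-weighted between-camera estimator
#' `var = K/(K-1) * sum(e_k^2 (n_k/e_k - rate)^2) / (sum e_k)^2`,
#' the standard empirical estimator for replicate point surveys; it
#' captures whatever spatial and temporal clumping the animals exhibit
#' without assuming a count distribution.
#'
#' @param counts named numeric vector of detections per camera; cameras
#'   with effort but no detections must appear (as zeros) or be inferable
#'   from `effort`.
#' @param effort `ct_effort` data frame (or named vector of per-camera
#'   effort). Cameras present in `effort` but absent from `counts` are
#'   treated as zero-count cameras.
#' @return list with `rate`, `var_rate`, `cv`, `df` (`K - 1`).
#' @export
encounter_rate_stats <- function(counts, effort) {
  if (is.data.frame(effort)) {
    e <- setNames(effort$effective_effort, effort$camera_id)
  } else e <- effort
  e <- e[e > 0]
  K <- length(e)
  if (K < 2)
    stop("encounter-rate variance undefined: need >= 2 cameras with ",
         "positive effort")
  n <- setNames(numeric(K), names(e))
  common <- intersect(names(counts), names(e))
  n[common] <- counts[common]
  E <- sum(e)
  if (E <= 0) stop("zero total effort")
  rate <- sum(n) / E
  v <- K / (K - 1) * sum(e^2 * (n / e - rate)^2) / E^2
  cv <- if (rate > 0) sqrt(v) / rate else NA_real_
  list(rate = rate, var_rate = v, cv = cv, df = K - 1)
}

#' Log-normal confidence interval for an abundance estimate
#'
#' Distance-sampling abundance estimates are skewed, so the conventional
#' interval is log-normal: `C = exp(t_{1-alpha/2, df} * sqrt(log(1+cv^2)))`
#' and the bounds are `(N/C, N*C)`. With `df = Inf` the t quantile reduces
#' to the normal quantile.
#'
#' @param N_hat point estimate.
#' @param cv_total total coefficient of variation.
#' @param alpha two-sided error rate (default 0.1 for a 90% interval).
#' @param df degrees of freedom for the t quantile (default `Inf`).
#' @return numeric vector `c(low, high)`.
#' @export
lognormal_ci <- function(N_hat, cv_total, alpha = 0.1, df = Inf) {
  if (cv_total == 0) {
    warning("cv = 0: degenerate interval")
    return(c(low = N_hat, high = N_hat))
  }
  q <- qt(1 - alpha / 2, df)
  C <- exp(q * sqrt(log(1 + cv_total^2)))
  c(low = N_hat / C, high = N_hat * C)
}

# Satterthwaite combination of encounter-rate and detection df
satterthwaite_df <- function(cv_e, df_e, cv_p, df_p) {
  cv2 <- cv_e^2 + cv_p^2
  if (cv2 == 0) return(Inf)
  denom <- cv_e^4 / df_e + if (cv_p > 0 && is.finite(df_p))
    cv_p^4 / df_p else 0
  if (denom == 0) return(Inf)
  max(1, cv2^2 / denom)
}

#' Estimate density and abundance from a camera-trap survey
#'
#' The point-transect estimator for snapshot-based camera sampling: each
#' snapshot samples a wedge of area `a0 = (theta/360) * pi * w^2`, so
#' density is `D = n / (S * a0 * p_hat)` with `S` the summed snapshot
#' count, and `N = D * A`. The total CV combines the between-camera
#' encounter-rate CV and the detection-probability CV in quadrature, and
#' the 90% interval is log-normal with Satterthwaite degrees of freedom.
#'
#' @param counts named vector of detections per camera (cameras with zero
#'   detections inferred from `effort`).
#' @param effort `ct_effort` table for the survey period.
#' @param fit fitted `detection_fit` for this stratum.
#' @param theta field-of-view angle in degrees.
#' @param area_A study-area size in km^2.
#' @param w truncation distance in metres (defaults to the fit's).
#' @param alpha two-sided error rate for the interval (default 0.1).
#' @param stratum,period labels carried into the result.
#' @return object of class `abundance_estimate` with fields `stratum`,
#'   `period`, `n_obs`, `D_hat` (per km^2), `N_hat`, `cv_total`,
#'   `cv_encounter`, `cv_detection`, `ci_low`, `ci_high`, `df`, `var_N`.
#' @export
estimate_abundance <- function(counts, effort, fit, theta, area_A,
                               w = fit$config$truncation_w, alpha = 0.1,
                               stratum = NA_character_,
                               period = NA_character_) {
  p_hat <- fit$p_hat
  if (!is.finite(p_hat) || p_hat <= 0)
    stop("estimation error: p_hat must be positive")
  S <- sum(effort$snapshots)
  if (S <= 0) stop("estimation error: zero total effort")
  n <- sum(counts)
  a0_km2 <- (theta / 360) * pi * w^2 / 1e6
  D_hat <- n / (S * a0_km2 * p_hat)
  N_hat <- D_hat * area_A

  er <- encounter_rate_stats(counts, effort)
  cv_e <- if (is.finite(er$cv)) er$cv else 0
  var_p <- if (is.finite(fit$var_p_hat)) fit$var_p_hat else 0
  cv_p <- sqrt(var_p) / p_hat
  cv_total <- sqrt(cv_e^2 + cv_p^2)
  df_p <- max(1, fit$n_obs - fit$n_params)
  df <- satterthwaite_df(cv_e, er$df, cv_p, df_p)
  ci <- if (cv_total > 0) lognormal_ci(N_hat, cv_total, alpha, df) else
    c(low = N_hat, high = N_hat)

  structure(list(
    stratum = stratum, period = period, n_obs = n, D_hat = D_hat,
    N_hat = N_hat, cv_total = cv_total, cv_encounter = cv_e,
    cv_detection = cv_p, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
    df = df, var_N = (cv_total * N_hat)^2, alpha = alpha,
    area_A = area_A), class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("Abundance estimate%s%s: N = %.2f (D = %.3f /km^2)\n",
              if (!is.na(x$stratum)) paste0(" [", x$stratum) else "",
              if (!is.na(x$period)) paste0(", ", x$period, "]") else
                if (!is.na(x$stratum)) "]" else "",
              x$N_hat, x$D_hat))
  cat(sprintf("  %d%% CI (%.2f, %.2f)  CV = %.3f  n = %d\n",
              round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              x$cv_total, x$n_obs))
  cat(sprintf("  CV components: encounter %.3f, detection %.3f\n",
              x$cv_encounter, x$cv_detection))
  invisible(x)
}

#' Variance decomposition of an abundance estimate
#'
#' Splits the squared total CV into the fraction contributed by
#' between-camera encounter-rate variation and by detection-probability
#' uncertainty.
#'
#' @param estimate an `abundance_estimate`.
#' @return named list `encounter`, `detection`; the fractions sum to 1.
#' @export
variance_decomposition <- function(estimate) {
  tot <- estimate$cv_total^2
  if (tot <= 0) stop("cv_total must be positive")
  list(encounter = estimate$cv_encounter^2 / tot,
       detection = estimate$cv_detection^2 / tot)
}
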
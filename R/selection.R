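#' Candidate detection-model grid
#'
#' The default grid spans the key/expansion menu used in conventional
#' distance sampling: half-normal and hazard-rate with no adjustments,
#' uniform with cosine or simple-polynomial adjustments (1--2 terms),
#' half-normal with cosine or Hermite adjustments (1--2 terms) and
#' hazard-rate with simple-polynomial adjustments (1--2 terms).
#'
#' @param w truncation distance passed to every [detection_config()].
#' @return list of `detection_config` objects.
#' @export
candidate_grid <- function(w = 40) {
  grid <- list(
    detection_config("half_normal", "none", 0, w),
    detection_config("hazard_rate", "none", 0, w))
  for (n in 1:2) {
    grid <- c(grid, list(
      detection_config("uniform", "cosine", n, w),
      detection_config("uniform", "simple_polynomial", n, w),
      detection_config("half_normal", "cosine", n, w),
      detection_config("half_normal", "hermite_polynomial", n, w),
      detection_config("hazard_rate", "simple_polynomial", n, w)))
  }
  grid
}

#' Rank detection fits by AIC with a goodness-of-fit gate
#'
#' Converged, constraint-satisfying fits whose chi-square goodness-of-fit
#' p-value is at least `gof_alpha` form the candidate set; `delta_aic` is
#' computed relative to the best of these, and models within `delta_max`
#' (default 2) are the competing set over which AIC weights
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)` are normalized. Fits
#' whose GOF is not computable (too few usable bins) are not excluded by
#' the gate. Ties are broken deterministically by fewer parameters, then
#' lexicographic key name.
#'
#' @param fits list of `detection_fit` objects, each optionally carrying a
#'   `$gof` element from [gof_chi2()] (computed here if absent).
#' @param gof_alpha GOF gate level (default 0.1, the study-wide alpha).
#' @param delta_max AIC window for the competing set (default 2).
#' @return object of class `model_set`: `table` (one row per candidate
#'   fit, with `delta_aic`, `weight`, `competing`), `fits` (the candidate
#'   fits in table order) and `competing` (indices into `fits`).
#' @export
rank_models <- function(fits, gof_alpha = 0.1, delta_max = 2) {
  if (length(fits) == 0) stop("no fits supplied")
  for (i in seq_along(fits)) {
    if (is.null(fits[[i]]$gof) && !fits[[i]]$rejected)
      fits[[i]]$gof <- gof_chi2(fits[[i]])
  }
  ok <- vapply(fits, function(f) isTRUE(f$converged) && !f$rejected,
               logical(1))
  gof_p <- vapply(fits, function(f)
    if (is.null(f$gof) || !isTRUE(f$gof$computable)) NA_real_ else
      f$gof$p_value, numeric(1))
  pass <- ok & (is.na(gof_p) | gof_p >= gof_alpha)
  if (!any(pass))
    stop("empty competing set: all fits failed convergence, the ",
         "monotonicity constraint or the GOF gate (min GOF p = ",
         signif(suppressWarnings(min(gof_p[ok], na.rm = TRUE)), 3), ")")

  fits <- fits[pass]
  gof_p <- gof_p[pass]
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  npar <- vapply(fits, `[[`, integer(1), "n_params")
  key <- vapply(fits, function(f) f$config$key, character(1))
  expn <- vapply(fits, function(f) f$config$expansion, character(1))
  ord <- order(aic, npar, key)
  fits <- fits[ord]; aic <- aic[ord]; npar <- npar[ord]
  key <- key[ord]; expn <- expn[ord]; gof_p <- gof_p[ord]

  delta <- aic - min(aic)
  competing <- which(delta <= delta_max)
  wts <- numeric(length(fits))
  ew <- exp(-delta[competing] / 2)
  wts[competing] <- ew / sum(ew)

  tab <- data.frame(
    key = key, expansion = expn,
    n_adjust = vapply(fits, function(f) f$config$n_adjust, integer(1)),
    n_params = npar, aic = aic, delta_aic = delta, weight = wts,
    gof_p = gof_p, p_hat = vapply(fits, `[[`, numeric(1), "p_hat"),
    competing = seq_along(fits) %in% competing,
    stringsAsFactors = FALSE)
  structure(list(table = tab, fits = fits, competing = competing),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("Model set (", length(x$fits), " candidates, ",
      length(x$competing), " competing within 2 AIC)\n", sep = "")
  print(x$table[, c("key", "expansion", "n_adjust", "aic", "delta_aic",
                    "weight", "gof_p")], digits = 4)
  invisible(x)
}

#' Model-average abundance estimates
#'
#' Averages abundance estimates over competing models with AIC weights,
#' using the unconditional variance
#' `var = sum(w_i * (var_i + (N_i - N_bar)^2))`, which adds the
#' between-model spread to the within-model variances. CV, degrees of
#' freedom (weighted over models) and the log-normal interval are
#' recomputed from the averaged quantities.
#'
#' @param estimates list of `abundance_estimate` objects sharing stratum
#'   and period.
#' @param weights numeric weights summing to 1.
#' @return an `abundance_estimate` for the averaged model.
#' @export
model_average <- function(estimates, weights) {
  stopifnot(length(estimates) == length(weights), length(estimates) >= 1)
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  strata <- unique(vapply(estimates, `[[`, character(1), "stratum"))
  periods <- unique(vapply(estimates, `[[`, character(1), "period"))
  if (length(strata) > 1 || length(periods) > 1)
    stop("cannot average estimates from different strata or periods")
  if (length(estimates) == 1) return(estimates[[1]])

  N <- vapply(estimates, `[[`, numeric(1), "N_hat")
  v <- vapply(estimates, `[[`, numeric(1), "var_N")
  N_bar <- sum(weights * N)
  var_u <- sum(weights * (v + (N - N_bar)^2))
  cv <- if (N_bar > 0) sqrt(var_u) / N_bar else NA_real_
  df <- sum(weights * vapply(estimates, `[[`, numeric(1), "df"))
  alpha <- estimates[[1]]$alpha
  ci <- if (is.finite(cv) && cv > 0)
    lognormal_ci(N_bar, cv, alpha, df) else c(low = N_bar, high = N_bar)
  area <- estimates[[1]]$area_A
  cv_e <- sqrt(sum(weights * vapply(estimates, function(e)
    e$cv_encounter^2, numeric(1))))
  cv_d <- if (is.finite(cv)) sqrt(max(0, cv^2 - cv_e^2)) else NA_real_

  structure(list(
    stratum = strata, period = periods,
    n_obs = estimates[[1]]$n_obs, D_hat = N_bar / area, N_hat = N_bar,
    cv_total = cv, cv_encounter = cv_e, cv_detection = cv_d,
    ci_low = unname(ci[1]), ci_high = unname(ci[2]), df = df,
    var_N = var_u, alpha = alpha, area_A = area,
    n_models = length(estimates)), class = "abundance_estimate")
}
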
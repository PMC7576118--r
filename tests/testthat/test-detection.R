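hn40 <- detection_config("half_normal", truncation_w = 40)

test_that("detection keys evaluate to their closed forms", {
  p <- list(sigma = 8, adj = numeric(0))
  expect_equal(detection_g(0, hn40, p), 1)
  expect_equal(detection_g(8, hn40, p), exp(-0.5))

  unif <- detection_config("uniform", truncation_w = 40)
  r <- seq(0, 40, by = 5)
  expect_equal(detection_g(r, unif, list(adj = numeric(0))), rep(1, 9))

  hr <- detection_config("hazard_rate", truncation_w = 40)
  ph <- list(sigma = 10, b = 3, adj = numeric(0))
  expect_equal(detection_g(0, hr, ph), 1)
  expect_equal(detection_g(10, hr, ph), 1 - exp(-1))

  expect_error(detection_g(-1, hn40, p), "0 <= r")
  expect_error(detection_g(41, hn40, p), "0 <= r")
})

test_that("radial pdf has closed uniform form and integrates to one", {
  unif <- detection_config("uniform", truncation_w = 40)
  expect_equal(detection_pdf(20, unif, list(adj = numeric(0))),
               2 * 20 / 40^2)

  configs <- list(
    list(cf = unif, par = list(adj = numeric(0))),
    list(cf = hn40, par = list(sigma = 7, adj = numeric(0))),
    list(cf = detection_config("hazard_rate", truncation_w = 40),
         par = list(sigma = 9, b = 2.5, adj = numeric(0))),
    list(cf = detection_config("half_normal", "cosine", 1,
                               truncation_w = 40),
         par = list(sigma = 10, adj = 0.15)),
    list(cf = detection_config("uniform", "simple_polynomial", 2,
                               truncation_w = 40),
         par = list(adj = c(-0.4, 0.1))))
  for (cc in configs) {
    total <- integrate(function(r) detection_pdf(r, cc$cf, cc$par),
                       0, 40, rel.tol = 1e-10)$value
    expect_lt(abs(total - 1), 1e-8)
  }
})

test_that("half-normal with huge sigma limits to the triangle density", {
  p <- list(sigma = 1e7, adj = numeric(0))
  r <- c(5, 20, 35)
  expect_equal(detection_pdf(r, hn40, p), 2 * r / 40^2, tolerance = 1e-6)
})

test_that("average detection probability matches closed forms", {
  fit <- list(config = hn40, params = list(sigma = 8, adj = numeric(0)))
  closed <- (2 * 8^2 / 40^2) * (1 - exp(-40^2 / (2 * 8^2)))
  expect_lt(abs(average_p(fit) - closed), 1e-6)
  expect_equal(closed, 0.08, tolerance = 1e-4)

  unif_fit <- list(config = detection_config("uniform", truncation_w = 40),
                   params = list(adj = numeric(0)))
  expect_equal(average_p(unif_fit), 1, tolerance = 1e-9)

  # p_hat strictly increases with sigma at fixed w
  ps <- vapply(c(3, 5, 8, 12, 20), function(s)
    average_p(list(config = hn40, params = list(sigma = s,
                                                adj = numeric(0)))),
    numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("maximum likelihood recovers the half-normal scale", {
  r <- sim_hn_distances(1000, sigma = 8, w = 40, seed = 42)
  fit <- fit_detection(r, hn40)
  expect_true(fit$converged)
  expect_false(fit$rejected)
  expect_lt(abs(fit$params$sigma - 8) / 8, 0.05)
  expect_equal(fit$aic, -2 * fit$loglik + 2)
  expect_gt(fit$p_hat, 0)
  expect_lte(fit$p_hat, 1)

  # determinism: identical data and config give a bit-identical fit
  fit2 <- fit_detection(r, hn40)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$loglik, fit2$loglik)
})

test_that("optimum log-likelihood beats every multi-start initial", {
  r <- sim_hn_distances(300, sigma = 8, w = 40, seed = 9)
  fit <- fit_detection(r, hn40)
  loglik_at <- function(sigma) {
    par <- list(sigma = sigma, adj = numeric(0))
    sum(log(detection_pdf(r, hn40, par)))
  }
  for (s0 in c(sd(r) / 2, sd(r), 2 * sd(r)))
    expect_gte(fit$loglik, loglik_at(s0) - 1e-8)
})

test_that("uniform key without adjustments is the closed-form p = 1 fit", {
  r <- sim_hn_distances(50, sigma = 20, w = 40, seed = 5)
  fit <- fit_detection(r, detection_config("uniform", truncation_w = 40))
  expect_equal(fit$p_hat, 1)
  expect_equal(fit$n_params, 0L)
  expect_equal(fit$loglik, sum(log(2 * r / 40^2)))
  expect_error(fit_detection(r[1:9], hn40), "insufficient data")
})

test_that("accepted fits are monotone nonincreasing with g(0) = 1", {
  r <- sim_hn_distances(400, sigma = 10, w = 40, seed = 13)
  grid <- list(hn40,
               detection_config("half_normal", "cosine", 1,
                                truncation_w = 40),
               detection_config("uniform", "cosine", 1,
                                truncation_w = 40),
               detection_config("hazard_rate", truncation_w = 40))
  for (cf in grid) {
    fit <- fit_detection(r, cf)
    if (fit$rejected) next
    gg <- detection_g(seq(0, 40, length.out = 100), cf, fit$params)
    expect_equal(gg[1], 1)
    expect_true(all(diff(gg) <= 1e-6))
  }
})

test_that("AIC ordering is invariant to distance-unit rescaling", {
  r <- sim_hn_distances(500, sigma = 8, w = 40, seed = 21)
  cfs <- list(hn40, detection_config("hazard_rate", truncation_w = 40))
  fits_m <- lapply(cfs, function(cf) fit_detection(r, cf))
  cfs_km <- list(detection_config("half_normal", truncation_w = 0.04),
                 detection_config("hazard_rate", truncation_w = 0.04))
  fits_km <- lapply(cfs_km, function(cf) fit_detection(r / 1000, cf))
  expect_false(any(vapply(c(fits_m, fits_km), `[[`, logical(1),
                          "rejected")))
  expect_equal(diff(vapply(fits_m, `[[`, numeric(1), "aic")),
               diff(vapply(fits_km, `[[`, numeric(1), "aic")),
               tolerance = 1e-3)
})

test_that("zero distances are offset, not dropped", {
  r <- c(rep(0, 3), sim_hn_distances(60, sigma = 8, w = 40, seed = 3))
  fit <- fit_detection(r, hn40)
  expect_equal(fit$zero_offset_n, 3L)
  expect_equal(fit$n_obs, 63L)
  expect_true(is.finite(fit$loglik))
})

test_that("goodness of fit reproduces its own formula and a perfect fit", {
  # uniform key, n = 400: expected counts per equal-width bin are the
  # exact integers 16, 48, 80, 112, 144; placing observations to match
  # them makes chi-square zero
  mids <- c(4, 12, 20, 28, 36)
  r <- rep(mids, times = c(16, 48, 80, 112, 144))
  fit <- fit_detection(r, detection_config("uniform", truncation_w = 40))
  g <- gof_chi2(fit, n_bins = 5)
  expect_true(g$computable)
  expect_equal(g$chi2, 0, tolerance = 1e-6)
  expect_equal(g$p_value, 1, tolerance = 1e-6)
  expect_equal(sum(g$bins$expected), fit$n_obs, tolerance = 1e-6)

  # chi2 and df recompute from the returned bins
  rs <- sim_hn_distances(1000, sigma = 12, w = 40, seed = 8)
  f1 <- fit_detection(rs, detection_config("half_normal",
                                           truncation_w = 40))
  g1 <- gof_chi2(f1, n_bins = 5)
  expect_equal(g1$chi2,
               sum((g1$bins$observed - g1$bins$expected)^2 /
                     g1$bins$expected))
  expect_equal(g1$p_value, pchisq(g1$chi2, g1$df, lower.tail = FALSE))
  expect_equal(g1$df, nrow(g1$bins) - 1L - 1L)

  # one more fitted parameter costs one degree of freedom on the same bins
  f2 <- fit_detection(rs, detection_config("half_normal", "cosine", 1,
                                           truncation_w = 40))
  g2 <- gof_chi2(f2, n_bins = 5)
  if (g2$computable && nrow(g2$bins) == nrow(g1$bins))
    expect_equal(g2$df, g1$df - 1L)
  expect_error(gof_chi2(f1, n_bins = 2), "n_bins")
})

test_that("GOF p-values are roughly calibrated under the true model", {
  frac <- mean(vapply(1:100, function(i) {
    r <- sim_hn_distances(1000, sigma = 8, w = 40, seed = 1000 + i)
    gof_chi2(fit_detection(r, hn40), n_bins = 5)$p_value > 0.1
  }, logical(1)))
  expect_gte(frac, 0.85)   # nominal 0.90, Monte-Carlo slack below
})
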
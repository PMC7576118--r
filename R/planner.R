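#' Camera sites required for a target precision
#'
#' Between-camera encounter-rate variance scales inversely with the number
#' of sampling sites, so the CV of an abundance estimate scales with
#' `1/sqrt(K)`. The number of sites needed to move from an achieved CV
#' `cv0` at `K0` sites to a target CV is
#' `K_req = round(K0 * (cv0 / cv_target)^2)`, rounded to the nearest
#' integer and floored at 2 (a between-site variance needs at least two
#' sites).
#'
#' @param K0 current number of camera sites.
#' @param cv0 achieved coefficient of variation at `K0` sites.
#' @param cv_target desired coefficient of variation.
#' @return integer number of sites.
#' @examples
#' required_sites(11, 0.47, 0.3)   # 27
#' @export
required_sites <- function(K0, cv0, cv_target) {
  stopifnot(K0 > 0, cv0 > 0, cv_target > 0)
  k <- round(K0 * (cv0 / cv_target)^2)
  if (k < 2) {
    warning("required sites below 2; flooring at 2")
    k <- 2
  }
  as.integer(k)
}

#' Predicted CV as a function of the number of camera sites
#'
#' Splits the CV into its encounter-rate and detection components:
#' `cv(K)^2 = cv_encounter^2 * (K0 / K) + cv_detection^2`. Only the
#' encounter-rate component shrinks with more sites; the detection
#' component depends on the number of distances available to the detection
#' fit and is treated as fixed, which is accurate when encounter-rate
#' variation dominates (here it contributes > 90% of the variance).
#'
#' @param K0 number of sites at which the components were estimated.
#' @param cv_encounter,cv_detection CV components at `K0` sites.
#' @param K_range integer vector of site counts to evaluate.
#' @return data frame with columns `K` and `cv`.
#' @export
cv_curve <- function(K0, cv_encounter, cv_detection, K_range) {
  stopifnot(K0 > 0, cv_encounter >= 0, cv_detection >= 0,
            all(K_range > 0))
  data.frame(K = K_range,
             cv = sqrt(cv_encounter^2 * (K0 / K_range) +
                         cv_detection^2))
}

#' Precision plan: sites required across a set of CV targets
#'
#' @inheritParams cv_curve
#' @param cv_targets vector of target CVs.
#' @param K_max upper end of the reported CV-versus-sites curve.
#' @return object of class `precision_plan` with `K0`, `cv0` (the CV at
#'   `K0`), `targets` (data frame `cv_target`, `K_required`) and `curve`
#'   (from [cv_curve()]). Targets unreachable because the fixed detection
#'   component alone exceeds the target get `K_required = NA`.
#' @export
precision_plan <- function(K0, cv_encounter, cv_detection,
                           cv_targets = c(0.1, 0.2, 0.3, 0.4, 0.5),
                           K_max = 100) {
  cv0 <- sqrt(cv_encounter^2 + cv_detection^2)
  K_req <- vapply(cv_targets, function(tgt) {
    if (tgt^2 <= cv_detection^2) return(NA_real_)
    max(2, round(K0 * cv_encounter^2 / (tgt^2 - cv_detection^2)))
  }, numeric(1))
  structure(list(
    K0 = K0, cv0 = cv0,
    targets = data.frame(cv_target = cv_targets, K_required = K_req),
    curve = cv_curve(K0, cv_encounter, cv_detection, seq_len(K_max))),
    class = "precision_plan")
}

#' @export
print.precision_plan <- function(x, ...) {
  cat(sprintf("Precision plan: %d sites achieve CV = %.3f\n", x$K0,
              x$cv0))
  print(x$targets, row.names = FALSE)
  invisible(x)
}
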
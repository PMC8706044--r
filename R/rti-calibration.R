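#' Fit the retention-time-index calibration (RT vs LogD at pH 7)
#'
#' Ordinary least squares of `logd_ph7 ~ rt` on reference-mixture standards
#' from the RPLC regime. LogD must increase with RPLC retention, so a
#' non-positive fitted slope is an error, as are fewer than three usable
#' points or a degenerate design (all retention times equal).
#'
#' @param standards data.frame with `rt` (min) and `logd_ph7`; only rows
#'   with `rt >= min_rt` enter the fit.
#' @param min_rt lower RT bound of the RPLC regime (default 15 min).
#' @return list of class `rti_calibration`: `slope` (LogD/min),
#'   `intercept`, `r_squared`, `residual_sd`, `n_points`, `rt_range`.
#' @export
fit_calibration <- function(standards, min_rt = 15) {
  st <- standards[standards$rt >= min_rt, , drop = FALSE]
  check(nrow(st) >= 3, "need >= 3 calibration standards in the RPLC regime")
  check(stats::sd(st$rt) > 0, "degenerate calibration: all standards at one RT")
  fit <- stats::lm(logd_ph7 ~ rt, data = st)
  slope <- unname(stats::coef(fit)[2])
  check(slope > 0, "calibration slope must be positive (LogD increases with RPLC RT)")
  res <- stats::residuals(fit)
  ss_tot <- sum((st$logd_ph7 - mean(st$logd_ph7))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  resid_sd <- if (nrow(st) > 2) sqrt(sum(res^2) / (nrow(st) - 2)) else 0
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 residual_sd = resid_sd,
                 slope_se = resid_sd / sqrt(sum((st$rt - mean(st$rt))^2)),
                 n_points = nrow(st),
                 rt_range = range(st$rt)),
            class = "rti_calibration")
}

#' @export
print.rti_calibration <- function(x, ...) {
  cat(sprintf(
    "RT-LogD calibration: logd = %.4f * rt + %.4f (n = %d, R^2 = %.4f, residual SD = %.4f)\n",
    x$slope, x$intercept, x$n_points, x$r_squared, x$residual_sd))
  invisible(x)
}

#' Predict LogD(pH 7) from retention time
#'
#' Applies the fitted line. No extrapolation guard is imposed, but an
#' `out_of_range` logical attribute flags retention times outside the
#' fitted range (including HILIC-regime RTs).
#'
#' @param model an [fit_calibration()] result.
#' @param rt retention times in minutes.
#' @return predicted LogD values with attribute `out_of_range`.
#' @export
predict_logd <- function(model, rt) {
  check(inherits(model, "rti_calibration"), "model must be an rti_calibration")
  out <- model$slope * rt + model$intercept
  attr(out, "out_of_range") <- rt < model$rt_range[1] | rt > model$rt_range[2]
  out
}

#' Retention-time-index sub-score
#'
#' Bounded linear ramp in the absolute difference between the
#' calibration-predicted LogD of a feature and the database LogD of a
#' candidate: 1 at perfect agreement, 0 at or beyond `scale` LogD units.
#'
#' @param predicted_logd calibration-predicted LogD.
#' @param database_logd database LogD(pH 7).
#' @param scale LogD difference at which the score reaches 0 (> 0).
#' @return score in \[0, 1\].
#' @export
rti_subscore <- function(predicted_logd, database_logd, scale = 2) {
  check(scale > 0, "scale must be > 0")
  pmax(0, 1 - abs(as.numeric(predicted_logd) - database_logd) / scale)
}
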
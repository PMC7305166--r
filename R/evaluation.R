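#' Performance metrics for volume prediction
#'
#' The four validation statistics used throughout: Pearson correlation R,
#' scatter index SI = RMSE / mean(observed), mean absolute percentage error
#' MAPE = 100 * mean(|obs - pred| / obs), and root mean squared relative
#' error RMSRE = sqrt(mean(((obs - pred) / obs)^2)); plus, at each requested
#' threshold, the fraction of samples whose relative error falls below it.
#' All four are invariant to a common positive rescaling of both vectors
#' (a unit change mm3 to cm3 changes nothing).
#'
#' @param observed positive numeric vector (mm3).
#' @param predicted numeric vector, same length.
#' @param re_thresholds relative-error thresholds (proportions) for the
#'   `frac_re_lt` map.
#' @return A list of class `metric_set`: `R`, `SI`, `MAPE` (percent),
#'   `RMSRE`, `n`, `frac_re_lt` (named by threshold). A zero-variance input
#'   flags `R` as `NA` with a warning.
#' @export
#' @examples
#' compute_metrics(c(100, 200, 300, 400), c(110, 190, 330, 360))$MAPE  # 8.75
compute_metrics <- function(observed, predicted,
                            re_thresholds = c(0.10, 0.15)) {
  check_obs_pred(observed, predicted)
  err <- predicted - observed
  rel <- abs(err) / observed
  R <- if (stats::sd(observed) < 1e-15 || stats::sd(predicted) < 1e-15) {
    warning("zero variance: correlation undefined")
    NA_real_
  } else stats::cor(observed, predicted)
  frac <- vapply(re_thresholds, function(t) mean(rel < t), numeric(1))
  names(frac) <- paste0("<", 100 * re_thresholds, "%")
  structure(list(R = R,
                 SI = sqrt(mean(err^2)) / mean(observed),
                 MAPE = 100 * mean(rel),
                 RMSRE = sqrt(mean((err / observed)^2)),
                 n = length(observed),
                 frac_re_lt = frac),
            class = "metric_set")
}

check_obs_pred <- function(observed, predicted, min_n = 2L) {
  if (length(observed) != length(predicted)) stopf("length mismatch")
  if (length(observed) < min_n) stopf("need at least %d samples", min_n)
  if (any(!is.finite(observed)) || any(!is.finite(predicted)))
    stopf("observed and predicted must be finite")
  if (any(observed <= 0))
    stopf("observed values must be positive (relative errors undefined at 0)")
  invisible(TRUE)
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("metric_set (n=%d): R=%.4f  SI=%.4f  MAPE=%.2f%%  RMSRE=%.4f\n",
              x$n, x$R, x$SI, x$MAPE, x$RMSRE))
  cat("  relative error:",
      paste(sprintf("%s: %.1f%%", names(x$frac_re_lt), 100 * x$frac_re_lt),
            collapse = "  "), "\n")
  invisible(x)
}

#' Prediction uncertainty band (SDFE / 95% WUB)
#'
#' Forecasting errors `e = predicted - observed` yield the standard deviation
#' of the forecasting error (SDFE); the 95% uncertainty band is centered at
#' the bias-corrected prediction (`predicted - mean(e)`) with halfwidth
#' `1.96 * SDFE` (WUB is reported both as this halfwidth and as the total
#' band width, twice the halfwidth). Coverage is the observed fraction of
#' samples falling inside their band.
#'
#' @param observed positive numeric vector (mm3), length `>= 3`.
#' @param predicted numeric vector.
#' @return A list of class `uncertainty_report`: `mean_error`, `SDFE`,
#'   `wub_halfwidth`, `wub_width`, `band_coverage` (all mm3 except coverage).
#' @export
uncertainty_band <- function(observed, predicted) {
  check_obs_pred(observed, predicted, min_n = 3L)
  e <- predicted - observed
  sdfe <- stats::sd(e)
  half <- 1.96 * sdfe
  center <- predicted - mean(e)
  structure(list(mean_error = mean(e), SDFE = sdfe,
                 wub_halfwidth = half, wub_width = 2 * half,
                 band_coverage = mean(abs(observed - center) <= half)),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("uncertainty: mean error %.2f, SDFE %.2f, 95%% WUB halfwidth %.2f, coverage %.3f\n",
              x$mean_error, x$SDFE, x$wub_halfwidth, x$band_coverage))
  invisible(x)
}

#' Taylor-diagram coordinates
#'
#' The triple a Taylor diagram plots: the ratio of predicted to observed
#' standard deviation, the correlation, and the centered RMS difference.
#' They satisfy the law-of-cosines identity
#' `cRMS^2 = sd_o^2 + sd_p^2 - 2 sd_o sd_p R`.
#'
#' @param observed numeric vector.
#' @param predicted numeric vector.
#' @return A list of class `taylor_stats`: `sd_obs`, `sd_pred`, `std_ratio`,
#'   `correlation` (`NA` with a warning for a constant prediction), `crms`.
#' @export
taylor_stats <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stopf("length mismatch")
  if (length(observed) < 2) stopf("need at least 2 samples")
  so <- stats::sd(observed) * sqrt((length(observed) - 1) / length(observed))
  sp <- stats::sd(predicted) * sqrt((length(observed) - 1) / length(observed))
  if (so < 1e-15) stopf("observed series has zero variance")
  R <- if (sp < 1e-15) {
    warning("constant prediction: correlation undefined")
    NA_real_
  } else stats::cor(observed, predicted)
  crms <- sqrt(mean(((predicted - mean(predicted)) -
                       (observed - mean(observed)))^2))
  structure(list(sd_obs = so, sd_pred = sp, std_ratio = sp / so,
                 correlation = R, crms = crms),
            class = "taylor_stats")
}

#' Flatten evaluation objects to one metrics row
#'
#' One row per model x cohort x stage, for the flat CSV metrics table.
#'
#' @param metrics a `metric_set`.
#' @param taylor optional `taylor_stats`.
#' @param uncertainty optional `uncertainty_report`.
#' @param ... name = value labels prepended to the row (model, group, stage).
#' @return A one-row `data.frame`.
#' @export
metrics_row <- function(metrics, taylor = NULL, uncertainty = NULL, ...) {
  row <- data.frame(..., R = metrics$R, SI = metrics$SI, MAPE = metrics$MAPE,
                    RMSRE = metrics$RMSRE, n = metrics$n,
                    stringsAsFactors = FALSE)
  if (!is.null(taylor)) {
    row$std_ratio <- taylor$std_ratio
    row$crms <- taylor$crms
  }
  if (!is.null(uncertainty)) {
    row$SDFE <- uncertainty$SDFE
    row$wub_halfwidth <- uncertainty$wub_halfwidth
    row$band_coverage <- uncertainty$band_coverage
  }
  row
}
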
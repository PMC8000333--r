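#' Per-peak linear calibration
#'
#' Ordinary least squares of integrated peak area (AU.min) on nominal
#' concentration (ug/mL):  area = B0 + B1 conc.  The object carries
#' everything inverse prediction needs: coefficient standard errors, the
#' standard error of the estimate Sy.x = sqrt(SSR/(n-2)), R^2, the mean of
#' the calibration levels and Sxx = sum (x - xbar)^2.
#'
#' @param levels Nominal concentrations (ug/mL).
#' @param responses Peak areas (AU.min), same length.
#' @param peak_name Identifier of the calibrated peak.
#' @return An object of class `"linear_calibration"`.
#' @examples
#' cal <- fit_linear(c(100, 130, 160, 190, 220), 2 * c(100, 130, 160, 190, 220))
#' coef(cal)           # B0 = 0, B1 = 2
#' inverse_predict(cal, 320)  # 160 ug/mL
#' @export
fit_linear <- function(levels, responses, peak_name = "peak") {
  x <- as.numeric(levels); y <- as.numeric(responses)
  if (length(x) != length(y)) stop("levels and responses differ in length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 calibration points")
  if (length(unique(x)) < 2L) stop("all calibration levels identical")
  fit <- stats::lm(y ~ x)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  syx <- sqrt(ssr / (n - 2))
  sxx <- sum((x - mean(x))^2)
  structure(list(peak_name = peak_name,
                 B0 = unname(stats::coef(fit)[1L]),
                 B1 = unname(stats::coef(fit)[2L]),
                 se_B0 = syx * sqrt(1 / n + mean(x)^2 / sxx),
                 se_B1 = syx / sqrt(sxx),
                 R2 = if (sst > 0) 1 - ssr / sst else 1,
                 Syx = syx,
                 n = n, x_mean = mean(x), Sxx = sxx),
            class = "linear_calibration")
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf("Linear calibration %s: area = %.4g + %.4g x  (n = %d)\n",
              x$peak_name, x$B0, x$B1, x$n))
  cat(sprintf("  R2 = %.4f  Sy.x = %.4g  se(B0) = %.3g  se(B1) = %.3g\n",
              x$R2, x$Syx, x$se_B0, x$se_B1))
  invisible(x)
}

#' @export
coef.linear_calibration <- function(object, ...)
  c(B0 = object$B0, B1 = object$B1)

#' @export
predict.linear_calibration <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata[[1L]] else newdata
  object$B0 + object$B1 * as.numeric(x)
}

#' Retain peaks whose calibration is sufficiently linear
#'
#' Strictly-greater-than filter on R^2 (default threshold 0.99, the
#' acceptance rule that retained 23 of the 29 colistimethate peaks).
#'
#' @param models List of `"linear_calibration"` objects.
#' @param threshold R^2 cut-off; models with `R2 > threshold` are kept.
#' @return Character vector of retained peak names, in input order.
#' @export
select_calibrated_peaks <- function(models, threshold = 0.99) {
  stopifnot(length(models) >= 1L)
  keep <- vapply(models, function(m) m$R2 > threshold, logical(1))
  vapply(models[keep], `[[`, character(1), "peak_name")
}

#' Inverse prediction with a 95 % confidence interval
#'
#' Interpolates a measured response back to concentration,
#' x0 = (y - B0)/B1, with the classical inverse-prediction interval
#' half-width  t(0.975, n-2) (Sy.x/|B1|) sqrt(1/m + 1/n + (x0 - xbar)^2/Sxx)
#' where m is the number of replicate responses averaged into `response`.
#'
#' @param model A `"linear_calibration"`.
#' @param response Measured (mean) response, signal units.
#' @param m Replicate count behind `response`.
#' @return List with `estimate`, `lower`, `upper` (ug/mL) and `m`.
#' @export
inverse_predict <- function(model, response, m = 1L) {
  stopifnot(inherits(model, "linear_calibration"))
  if (abs(model$B1) < .Machine$double.eps)
    stop("slope is numerically zero; cannot invert the calibration")
  est <- (as.numeric(response) - model$B0) / model$B1
  hw <- stats::qt(0.975, model$n - 2L) * (model$Syx / abs(model$B1)) *
    sqrt(1 / m + 1 / model$n + (est - model$x_mean)^2 / model$Sxx)
  list(estimate = est, lower = est - hw, upper = est + hw, m = m)
}

#' Limits of detection and quantitation
#'
#' LOD = 3.3 sigma / slope and LOQ = 10 sigma / slope with sigma taken as
#' the calibration's standard error of the estimate Sy.x.
#'
#' @param model A `"linear_calibration"` (positive slope).
#' @return Named list `lod`, `loq` (ug/mL).
#' @export
lod_loq <- function(model) {
  stopifnot(inherits(model, "linear_calibration"))
  if (model$B1 <= 0) stop("LOD/LOQ require a positive slope")
  list(lod = 3.3 * model$Syx / model$B1, loq = 10 * model$Syx / model$B1)
}

#' ICH-style validation summary
#'
#' Summarizes back-calculated concentrations into the standard validation
#' table: accuracy as %E = 100 (mean - nominal)/nominal per level;
#' repeatability %RSD within run; intermediate precision %RSD pooled across
#' days; stability %RSD across timed re-injections; robustness %RSD across
#' deliberately perturbed runs.  %RSD uses the sample (n-1) standard
#' deviation, the pharmaceutical-validation convention.  Cells with fewer
#' than 2 values are reported as `NA`, never 0.
#'
#' @param predictions Data frame with columns `level` (nominal, ug/mL),
#'   `value` (back-calculated, ug/mL) and optional `run`, `day`,
#'   `condition` (one of `"nominal"`, `"stability"`, `"robustness"`).
#' @return Data frame, one row per level, class `"validation_report"`:
#'   columns `level`, `accuracy_pctE`, `repeatability_pctRSD`,
#'   `intermediate_pctRSD`, `stability_pctRSD`, `robustness_pctRSD`.
#' @export
validation_summary <- function(predictions) {
  df <- as.data.frame(predictions)
  stopifnot(all(c("level", "value") %in% names(df)))
  if (is.null(df$run)) df$run <- 1L
  if (is.null(df$day)) df$day <- 1L
  if (is.null(df$condition)) df$condition <- "nominal"
  pct_rsd <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) return(NA_real_)
    100 * stats::sd(v) / mean(v)
  }
  out <- lapply(sort(unique(df$level)), function(lv) {
    d <- df[df$level == lv, ]
    nom <- d[d$condition == "nominal", ]
    rep_rsd <- if (nrow(nom)) {
      per_run <- vapply(split(nom$value, interaction(nom$day, nom$run,
                                                     drop = TRUE)),
                        pct_rsd, numeric(1))
      if (all(is.na(per_run))) NA_real_ else max(per_run, na.rm = TRUE)
    } else NA_real_
    data.frame(level = lv,
               accuracy_pctE = if (nrow(nom))
                 100 * (mean(nom$value) - lv) / lv else NA_real_,
               repeatability_pctRSD = rep_rsd,
               intermediate_pctRSD = if (length(unique(nom$day)) >= 2L)
                 pct_rsd(nom$value) else NA_real_,
               stability_pctRSD = pct_rsd(d$value[d$condition == "stability"]),
               robustness_pctRSD = pct_rsd(d$value[d$condition == "robustness"]))
  })
  out <- do.call(rbind, out)
  class(out) <- c("validation_report", "data.frame")
  out
}
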
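#' Published calibration coefficients of the 23 colistimethate peaks
#'
#' Reference table of the validated UPLC-UV assay: for each of the 23
#' chromatographic peaks retained by the R^2 > 0.99 linearity filter
#' (named by retention time), the intercept `B0` and slope `B1` of the
#' area-vs-concentration calibration, their standard errors, `R2` and the
#' standard error of the estimate `Syx`.  Units: areas AU.min,
#' concentrations ug/mL.  Used for worked examples (detection and
#' quantitation limits, inverse prediction) and as the response factors of
#' the synthetic profile.
#'
#' @format Data frame with 23 rows: `peak`, `center` (min), `B0`, `B1`,
#'   `se_B0`, `se_B1`, `R2`, `Syx`.
#' @export
cms_reference_peaks <- data.frame(
  peak = c("peak_7.28", "peak_8.73", "peak_9.02", "peak_9.30", "peak_9.80",
           "peak_10.43", "peak_11.99", "peak_12.53", "peak_12.76",
           "peak_13.18", "peak_14.35", "peak_17.18", "peak_18.95",
           "peak_19.33", "peak_20.27", "peak_20.87", "peak_21.33",
           "peak_21.75", "peak_22.12", "peak_22.70", "peak_23.13",
           "peak_23.65", "peak_24.20"),
  center = c(7.28, 8.73, 9.02, 9.30, 9.80, 10.43, 11.99, 12.53, 12.76,
             13.18, 14.35, 17.18, 18.95, 19.33, 20.27, 20.87, 21.33,
             21.75, 22.12, 22.70, 23.13, 23.65, 24.20),
  B0 = c(1.13e-5, -2.6e-5, 4.36e-5, 1.05e-4, 3.06e-5, 1.77e-4, 3.45e-5,
         2.0e-6, 1.29e-4, 2.35e-5, -3e-5, 1.19e-5, 1.11e-5, 1.02e-4,
         6.23e-5, 3.0e-6, -3.8e-5, -3.2e-5, 1.63e-5, -9.4e-5, -4.7e-7,
         -6.4e-5, 4.26e-4),
  B1 = c(1.73e-6, 4.88e-6, 1.73e-6, 8.27e-6, 1.32e-6, 2.96e-5, 3.62e-5,
         3.0e-6, 7.74e-6, 1.61e-5, 1.54e-5, 1.59e-6, 1.18e-6, 1.07e-5,
         4.29e-6, 1.29e-6, 8.46e-6, 4.77e-6, 3.82e-6, 1.13e-5, 1.24e-5,
         1.08e-5, 3.72e-6),
  se_B0 = c(4.18e-6, 1.99e-5, 1.55e-5, 2.82e-5, 7.07e-6, 1.29e-4, 1.45e-4,
            6.83e-6, 1.69e-5, 3.82e-5, 4.29e-5, 5.98e-6, 5.73e-6, 2.4e-5,
            1.12e-5, 1.23e-5, 2.03e-5, 2.36e-5, 1.44e-5, 2.47e-5, 3.11e-5,
            3.77e-5, 3.07e-5),
  se_B1 = c(2.52e-8, 1.2e-7, 9.33e-8, 1.7e-7, 4.27e-8, 7.8e-7, 8.79e-7,
            4.13e-8, 1.02e-7, 2.31e-7, 2.59e-7, 3.61e-8, 3.46e-8, 1.45e-7,
            6.79e-8, 7.41e-8, 1.23e-7, 1.43e-7, 8.68e-8, 1.49e-7, 1.88e-7,
            2.28e-7, 1.86e-7),
  R2 = c(0.9994, 0.998, 0.991, 0.998, 0.997, 0.998, 0.998, 0.9994, 0.9995,
         0.9994, 0.9996, 0.998, 0.997, 0.9994, 0.9993, 0.990, 0.9994,
         0.997, 0.998, 0.9995, 0.9993, 0.998, 0.992),
  Syx = c(2.39e-6, 1.14e-5, 8.85e-6, 1.61e-5, 4.05e-6, 7.4e-5, 8.34e-5,
          3.92e-6, 9.71e-6, 2.19e-5, 2.46e-5, 3.43e-6, 3.28e-6, 1.38e-5,
          6.44e-6, 7.03e-6, 1.16e-5, 1.35e-5, 8.24e-6, 1.41e-5, 1.78e-5,
          2.16e-5, 1.76e-5),
  stringsAsFactors = FALSE)

#' Published whole-batch PLS estimates of seven production batches
#'
#' Interpolated total-content estimates (ug/mL) of the tested batches at
#' the 160 ug/mL working level, as reported for the validated one-component
#' PLS model; `b5` is the expired batch.  Used in worked examples of the
#' percent-error arithmetic.
#'
#' @format Data frame with columns `batch`, `estimate`.
#' @export
cms_batch_pls_estimates <- data.frame(
  batch = c("b1", "b2", "b3", "b4a", "b4b", "b4c", "b5"),
  estimate = c(156.01, 161.85, 171.61, 178.50, 185.21, 170.72, 179.33),
  stringsAsFactors = FALSE)
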
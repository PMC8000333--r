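#' Synthetic chromatographic profile of a multicomponent drug product
#'
#' Defines the ground-truth structure from which chromatograms are
#' simulated: 29 Gaussian peaks over a 0-34 min elution window.  The 23
#' "designed-linear" peaks sit at the retention times of the validated
#' colistimethate profile and carry its published per-peak response
#' factors (area per ug/mL, ~1e-6 to 4e-5 AU.min); the remaining 6 peaks
#' are synthetic additions at invented retention times and are designed
#' non-linear: their area follows a quadratic response and they receive
#' `nonlinear_noise_factor` times the area noise, so a strict R^2 > 0.99
#' calibration filter retains exactly the 23 linear peaks.
#'
#' @param centers Peak retention times (min), strictly increasing.
#' @param response Per-peak response factor (AU.min per ug/mL).
#' @param hwhm Per-peak half-width at half-maximum (min).
#' @param nonlinear Logical; which peaks are designed non-linear.
#' @param nonlinear_curvature Scale of the quadratic response of the
#'   non-linear peaks: their true area is `response * conc^2 /
#'   (2 * nonlinear_curvature)`; 0 disables the curvature.
#' @param drift Coefficients `c(a0, a1, a2)` of the baseline drift
#'   `a0 + a1 t + a2 t^2` (AU); the default emulates the high, slowly
#'   rising baseline of low-wavelength UV detection.
#' @param noise_sd Additive i.i.d. Gaussian intensity noise (AU).
#' @param area_rsd Relative sd of the per-injection multiplicative area
#'   noise of linear peaks.
#' @param nonlinear_noise_factor Area-noise multiplier of non-linear peaks.
#' @param dt Sampling interval (min); default 34/40000 (~0.05 s, 20 Hz).
#' @param t_max End of the elution window (min).
#' @return Object of class `"synthetic_profile"`.
#' @export
synthetic_profile <- function(centers = NULL, response = NULL, hwhm = NULL,
                              nonlinear = NULL, nonlinear_curvature = 160,
                              drift = c(0.02, 0.004, 2.6e-5),
                              noise_sd = 1e-5, area_rsd = 0.01,
                              nonlinear_noise_factor = 6,
                              dt = 34 / 40000, t_max = 34) {
  if (is.null(centers)) {
    linear_centers <- cms_reference_peaks$center
    extra_centers <- c(11.20, 15.10, 16.20, 18.10, 25.20, 26.40)
    centers <- sort(c(linear_centers, extra_centers))
    nonlinear <- centers %in% extra_centers
    response <- numeric(length(centers))
    response[!nonlinear] <-
      cms_reference_peaks$B1[match(centers[!nonlinear],
                                   cms_reference_peaks$center)]
    response[nonlinear] <- c(5e-6, 2e-5, 8e-6, 1.2e-5, 6e-6, 3e-6)
  }
  n <- length(centers)
  if (is.null(nonlinear)) nonlinear <- rep(FALSE, n)
  if (is.null(hwhm)) {
    # narrow UPLC peaks; weakest responders get the narrowest widths so
    # every component stays above the discovery threshold at all levels
    pool <- sort(rep(c(0.055, 0.07, 0.06, 0.08, 0.045, 0.075),
                     length.out = n))
    hwhm <- numeric(n)
    hwhm[order(response)] <- pool
  }
  stopifnot(length(response) == n, length(hwhm) == n,
            length(nonlinear) == n, all(diff(centers) > 0),
            all(response > 0), all(hwhm > 0))
  structure(list(centers = centers, response = response, hwhm = hwhm,
                 nonlinear = nonlinear,
                 nonlinear_curvature = nonlinear_curvature,
                 drift = drift, noise_sd = noise_sd, area_rsd = area_rsd,
                 nonlinear_noise_factor = nonlinear_noise_factor,
                 dt = dt, t_max = t_max),
            class = "synthetic_profile")
}

#' @export
print.synthetic_profile <- function(x, ...) {
  cat("Synthetic profile:", length(x$centers), "peaks (",
      sum(!x$nonlinear), "linear,", sum(x$nonlinear), "designed non-linear ),",
      sprintf("0-%g min at dt = %.4g min\n", x$t_max, x$dt))
  invisible(x)
}

# analytic true areas at a concentration, before injection noise
true_areas <- function(profile, concentration) {
  a <- profile$response * concentration
  if (any(profile$nonlinear) && profile$nonlinear_curvature > 0) {
    nl <- profile$nonlinear
    a[nl] <- profile$response[nl] * concentration^2 /
      (2 * profile$nonlinear_curvature)
  }
  a
}

#' Simulate one chromatogram with ground truth
#'
#' Builds intensity = sum of Gaussians + polynomial drift + i.i.d. Gaussian
#' noise.  Per-injection multiplicative area noise (relative sd
#' `area_rsd`, multiplied by `nonlinear_noise_factor` for the designed
#' non-linear peaks) perturbs the target areas first; the realized areas
#' are exact analytic Gaussian areas and are returned in the truth record
#' together with the drift vector.
#'
#' @param profile A [synthetic_profile()].
#' @param concentration Nominal concentration (ug/mL), > 0.
#' @param seed Integer seed; the same (profile, concentration, seed) always
#'   yields the same trace.
#' @param sample_id,role Metadata for the returned chromatogram.
#' @param area_scale Optional per-peak multiplicative perturbation (batch
#'   patterns), default 1.
#' @return List `chromatogram` (a [chromatogram()]) and `truth` (list with
#'   `areas` — named exact per-peak areas —, `heights`, `baseline`).
#' @export
make_chromatogram <- function(profile, concentration, seed = 1L,
                              sample_id = "synthetic", role = "unknown",
                              area_scale = 1) {
  stopifnot(inherits(profile, "synthetic_profile"), concentration > 0)
  set.seed(seed)
  n_pk <- length(profile$centers)
  rel <- profile$area_rsd *
    ifelse(profile$nonlinear, profile$nonlinear_noise_factor, 1)
  areas <- true_areas(profile, concentration) *
    (1 + rel * stats::rnorm(n_pk)) * area_scale
  areas <- pmax(areas, 1e-12)
  heights <- areas / (profile$hwhm * sqrt(pi / log(2)))
  tm <- seq(0, profile$t_max, by = profile$dt)
  pk <- data.frame(height = heights, center = profile$centers,
                   hwhm = profile$hwhm)
  drift <- profile$drift[1L] + profile$drift[2L] * tm +
    profile$drift[3L] * tm^2
  y <- gaussian_profile(tm, pk) + drift +
    stats::rnorm(length(tm), sd = profile$noise_sd)
  names(areas) <- sprintf("peak_%.2f", profile$centers)
  list(chromatogram = chromatogram(tm, y, sample_id = sample_id,
                                   level = concentration, role = role),
       truth = list(areas = areas, heights = heights, baseline = drift))
}

#' Simulate a calibration series with ground truth
#'
#' One chromatogram per level and replicate, at the standard 5-level
#' series (100/130/160/190/220 ug/mL, i.e. ~60-140 % of the 160 ug/mL
#' working level).  Each injection gets its own derived seed, so the full
#' series is reproducible from (profile, seed).
#'
#' @param profile A [synthetic_profile()].
#' @param levels Calibration levels (ug/mL).
#' @param replicates Independent preparations per level.
#' @param seed Integer seed.
#' @return List `chromatograms` (list of [chromatogram()]s, role
#'   `"calibration"`), `truth` (data frame: sample_id, level, replicate,
#'   one column per peak area).
#' @export
make_calibration_series <- function(profile,
                                    levels = c(100, 130, 160, 190, 220),
                                    replicates = 3L, seed = 1L) {
  stopifnot(all(levels > 0))
  chroms <- list(); rows <- list()
  k <- 0L
  for (lv in levels) for (r in seq_len(replicates)) {
    k <- k + 1L
    id <- sprintf("cal_%g_r%d", lv, r)
    sim <- make_chromatogram(profile, lv, seed = seed * 1000L + k,
                             sample_id = id, role = "calibration")
    chroms[[id]] <- sim$chromatogram
    rows[[id]] <- data.frame(sample_id = id, level = lv, replicate = r,
                             t(sim$truth$areas), check.names = FALSE)
  }
  list(chromatograms = chroms, truth = do.call(rbind, rows))
}

#' Batch perturbation profile
#'
#' @param name Batch identifier.
#' @param label `"conforming"` (peak areas perturbed within +/-3 %),
#'   `"moderate_deviation"` (+/-15 % on a peak subset) or `"expired_like"`
#'   (a subset raised ~+35 % and another lowered ~-20 %, the pattern of an
#'   aged batch in which some components degrade and feed others).
#' @param perturbation Optional explicit per-peak multiplicative vector;
#'   when `NULL` a deterministic pattern for `label` is built at
#'   simulation time.
#' @return Object of class `"batch_profile"`.
#' @export
batch_profile <- function(name, label = c("conforming",
                                          "moderate_deviation",
                                          "expired_like"),
                          perturbation = NULL) {
  label <- match.arg(label)
  if (!is.null(perturbation) && any(perturbation <= 0))
    stop("perturbations must be positive")
  structure(list(name = name, label = label, perturbation = perturbation),
            class = "batch_profile")
}

batch_perturbation <- function(bp, n_peaks, seed) {
  if (!is.null(bp$perturbation)) {
    stopifnot(length(bp$perturbation) == n_peaks)
    return(bp$perturbation)
  }
  set.seed(seed)
  switch(bp$label,
         conforming = 1 + stats::runif(n_peaks, -0.03, 0.03),
         moderate_deviation = {
           p <- 1 + stats::runif(n_peaks, -0.03, 0.03)
           idx <- seq(2L, n_peaks, by = 3L)
           p[idx] <- 1 + stats::runif(length(idx), -0.15, 0.15)
           p
         },
         expired_like = {
           p <- 1 + stats::runif(n_peaks, 0.25, 0.45)   # most peaks up
           low <- seq(3L, n_peaks, by = 5L)             # some degraded
           p[low] <- 1 - stats::runif(length(low), 0.15, 0.25)
           p
         })
}

#' Simulate a set of production batches with truth labels
#'
#' All batches are injected at the 160 ug/mL working level; each batch's
#' per-peak areas are multiplied by its perturbation pattern before the
#' trace is built.
#'
#' @param profile A [synthetic_profile()].
#' @param batch_profiles List of [batch_profile()]s (default: reference-like
#'   b1-b4 with one moderate deviation, plus an expired-like b5).
#' @param concentration Working concentration (ug/mL).
#' @param seed Integer seed.
#' @return List `chromatograms`, `truth` (data frame with sample_id,
#'   label, true areas per peak).
#' @export
make_batches <- function(profile,
                         batch_profiles = list(
                           batch_profile("b1", "moderate_deviation"),
                           batch_profile("b2", "conforming"),
                           batch_profile("b3", "conforming"),
                           batch_profile("b4", "conforming"),
                           batch_profile("b5", "expired_like")),
                         concentration = 160, seed = 1L) {
  stopifnot(length(batch_profiles) >= 1L)
  chroms <- list(); rows <- list()
  for (k in seq_along(batch_profiles)) {
    bp <- batch_profiles[[k]]
    pert <- batch_perturbation(bp, length(profile$centers),
                               seed = seed * 100L + k)
    sim <- make_chromatogram(profile, concentration,
                             seed = seed * 100L + 50L + k,
                             sample_id = bp$name, role = "batch",
                             area_scale = pert)
    chroms[[bp$name]] <- sim$chromatogram
    rows[[bp$name]] <- data.frame(sample_id = bp$name, label = bp$label,
                                  t(sim$truth$areas), check.names = FALSE)
  }
  list(chromatograms = chroms, truth = do.call(rbind, rows))
}
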
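# Independent oracles used by the property tests.  Each is written
# straight from the defining formula, separately from the package code.

# dense normal-equations solution of the Whittaker problem
whittaker_oracle <- function(y, log10_penalty) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  solve(diag(n) + 10^log10_penalty * t(D) %*% D, y)
}

# straight-from-formula evaluation of all 19 proximity measures
battery_oracle <- function(x, y, ranges = abs(x - y)) {
  s_cos <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  px <- x / sum(x); py <- y / sum(y)
  kendall_discordance <- function(x, y) {
    n <- length(x); num <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      num <- num + (s > 0) - (s < 0)
    }
    1 - 2 * num / (n * (n - 1))
  }
  gower <- mean(mapply(function(a, b, r) if (r == 0) 1 else
    1 - abs(a - b) / r, x, y, ranges))
  dists <- c(
    bray = sum(abs(x - y)) / sum(x + y),
    canberra = sum(abs(x - y) / (x + y)),
    chord = sqrt(2 * (1 - s_cos)),
    divergence = sum((x - y)^2 / (x + y)^2),
    euclidean = sqrt(sum((x - y)^2)),
    geodesic = acos(s_cos),
    hellinger = sqrt(sum((sqrt(px) - sqrt(py))^2)),
    kullback = sum(px * log(px / py)) + sum(py * log(py / px)),
    manhattan = sum(abs(x - y)),
    podani = kendall_discordance(x, y),
    soergel = sum(abs(x - y)) / sum(pmax(x, y)),
    supremum = max(abs(x - y)),
    whittaker = sum(abs(px - py)) / 2,
    bhjattacharyya = sqrt(sum((sqrt(x) - sqrt(y))^2)))
  corr <- if (sd(x) == 0 || sd(y) == 0) as.numeric(sd(x) == sd(y)) else
    cor(x, y)
  c(eJaccard = sum(x * y) / (sum(x^2) + sum(y^2) - sum(x * y)),
    cosine = s_cos,
    eDice = 2 * sum(x * y) / (sum(x^2) + sum(y^2)),
    correlation = corr,
    gower = gower,
    1 / (1 + dists))
}

# per-window SSIM by explicit loops and formula (sample var/cov, N-1)
ssim_windowed_oracle <- function(A, B, K1 = 0.01, K2 = 0.03, w = 8) {
  rng <- range(c(A, B)); A <- (A - rng[1]) / diff(rng)
  B <- (B - rng[1]) / diff(rng)
  C1 <- K1^2; C2 <- K2^2
  out <- c()
  for (i in seq_len(nrow(A) - w + 1)) for (j in seq_len(ncol(A) - w + 1)) {
    a <- as.numeric(A[i:(i + w - 1), j:(j + w - 1)])
    b <- as.numeric(B[i:(i + w - 1), j:(j + w - 1)])
    ma <- mean(a); mb <- mean(b)
    va <- sum((a - ma)^2) / (length(a) - 1)
    vb <- sum((b - mb)^2) / (length(b) - 1)
    cab <- sum((a - ma) * (b - mb)) / (length(a) - 1)
    out <- c(out, ((2 * ma * mb + C1) * (2 * cab + C2)) /
               ((ma^2 + mb^2 + C1) * (va + vb + C2)))
  }
  mean(out)
}

# small well-separated profile for fast pipeline-level tests
mini_profile <- function(n = 5, noise_sd = 5e-6, area_rsd = 0.005,
                         nonlinear = rep(FALSE, n)) {
  synthetic_profile(centers = seq(4, 30, length.out = n),
                    response = seq(4e-6, 2e-5, length.out = n),
                    hwhm = rep(c(0.06, 0.08), length.out = n),
                    nonlinear = nonlinear,
                    noise_sd = noise_sd, area_rsd = area_rsd)
}

# shared heavy end-to-end fixture, computed once per test session
.pipeline_cache <- new.env(parent = emptyenv())
full_pipeline_fixture <- function(seed = 1) {
  key <- paste0("run", seed)
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  profile <- synthetic_profile()
  cfg <- qc_config(seed = seed)
  cal <- make_calibration_series(profile, replicates = 3, seed = seed)
  lv <- vapply(cal$chromatograms, `[[`, numeric(1), "level")
  pr <- chromaqc:::process_runs(cal$chromatograms, cfg,
                                reference_run = which.max(lv), levels = lv)
  models <- lapply(pr$peak_table$peak_names, function(pk)
    fit_linear(lv, pr$peak_table$areas[, pk], peak_name = pk))
  names(models) <- pr$peak_table$peak_names
  retained <- select_calibrated_peaks(models)
  out <- list(profile = profile, cfg = cfg, cal = cal, levels = lv,
              processed = pr, models = models, retained = retained)
  .pipeline_cache[[key]] <- out
  out
}
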
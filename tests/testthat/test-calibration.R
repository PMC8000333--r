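levels5 <- c(100, 130, 160, 190, 220)

test_that("OLS calibration matches the closed-form normal equations", {
  # exact line
  cal <- fit_linear(levels5, 2 * levels5, "p")
  expect_equal(unname(coef(cal)), c(0, 2), tolerance = 1e-12)
  expect_equal(cal$R2, 1)
  expect_equal(cal$Syx, 0)
  # hand-computable five-point data set
  x <- levels5
  y <- c(1.2, 2.9, 3.4, 5.1, 5.8)
  cal2 <- fit_linear(x, y, "p2")
  n <- 5; Sxx <- sum((x - mean(x))^2)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / Sxx
  b0 <- mean(y) - b1 * mean(x)
  ssr <- sum((y - b0 - b1 * x)^2)
  syx <- sqrt(ssr / (n - 2))
  expect_equal(cal2$B1, b1, tolerance = 1e-10)
  expect_equal(cal2$B0, b0, tolerance = 1e-10)
  expect_equal(cal2$Syx, syx, tolerance = 1e-10)
  expect_equal(cal2$se_B1, syx / sqrt(Sxx), tolerance = 1e-10)
  expect_equal(cal2$se_B0, syx * sqrt(1 / n + mean(x)^2 / Sxx),
               tolerance = 1e-10)
  expect_equal(cal2$R2, 1 - ssr / sum((y - mean(y))^2), tolerance = 1e-10)
  expect_error(fit_linear(rep(160, 5), rnorm(5)), "identical")
})

test_that("estimated coefficients are unbiased over repeated sampling", {
  set.seed(31)
  b0 <- 5e-5; b1 <- 2e-6; sigma <- 4e-5
  b1_hat <- syx2 <- numeric(1000)
  for (i in 1:1000) {
    y <- b0 + b1 * levels5 + rnorm(5, sd = sigma)
    m <- fit_linear(levels5, y)
    b1_hat[i] <- m$B1; syx2[i] <- m$Syx^2
  }
  se_b1 <- sigma / sqrt(sum((levels5 - 160)^2))
  expect_lt(abs(mean(b1_hat) - b1), 3 * se_b1 / sqrt(1000))
  expect_equal(mean(syx2), sigma^2, tolerance = 0.05)
})

test_that("R2 retention filter is strictly greater-than", {
  mk <- function(r2, nm) {
    m <- fit_linear(levels5, 2 * levels5, nm); m$R2 <- r2; m
  }
  models <- list(mk(0.995, "a"), mk(0.99, "b"), mk(0.9899, "c"),
                 mk(0.9901, "d"))
  expect_equal(select_calibrated_peaks(models), c("a", "d"))
  # 29-model set designed with 23 above threshold
  set.seed(8)
  r2s <- c(runif(23, 0.991, 0.9999), runif(6, 0.90, 0.989))
  models29 <- lapply(seq_along(r2s), function(i) mk(r2s[i], paste0("m", i)))
  expect_length(select_calibrated_peaks(models29), 23L)
})

test_that("inverse prediction inverts the line and covers at 95%", {
  set.seed(12)
  y <- 1e-4 + 2e-6 * levels5 + rnorm(5, sd = 2e-6)
  m <- fit_linear(levels5, y)
  # algebraic inverse of the forward prediction
  p <- inverse_predict(m, predict(m, 160))
  expect_equal(p$estimate, 160, tolerance = 1e-9)
  expect_true(p$lower <= p$estimate && p$estimate <= p$upper)
  # zero residual variance gives a zero-width interval
  m0 <- fit_linear(levels5, 3 * levels5)
  p0 <- inverse_predict(m0, 480)
  expect_equal(p0$lower, p0$upper)
  expect_equal(p0$estimate, 160)
  m_bad <- m0; m_bad$B1 <- 0
  expect_error(inverse_predict(m_bad, 1))
})

test_that("inverse-prediction interval attains nominal coverage", {
  set.seed(77)
  b0 <- 0; b1 <- 2e-6; sigma <- 3e-6
  hits <- logical(2000)
  for (i in seq_len(2000)) {
    m <- fit_linear(levels5, b0 + b1 * levels5 + rnorm(5, sd = sigma))
    yn <- b0 + b1 * 160 + rnorm(1, sd = sigma)
    p <- inverse_predict(m, yn)
    hits[i] <- p$lower <= 160 && 160 <= p$upper
  }
  expect_equal(mean(hits), 0.95, tolerance = 0.015 / 0.95)
})

test_that("detection and quantitation limits reproduce the published rows", {
  m2270 <- fit_linear(levels5, 2 * levels5, "peak_22.70")
  m2270$Syx <- 1.41e-5; m2270$B1 <- 1.13e-5
  ll <- lod_loq(m2270)
  expect_equal(round(ll$lod, 2), 4.12)
  expect_equal(round(ll$loq, 2), 12.48)
  m2087 <- fit_linear(levels5, 2 * levels5, "peak_20.87")
  m2087$Syx <- 7.03e-6; m2087$B1 <- 1.29e-6
  ll2 <- lod_loq(m2087)
  expect_equal(round(ll2$lod, 2), 17.98)
  expect_equal(ll2$loq, 54.49, tolerance = 0.02 / 54.49)
  # LOD < LOQ always; both scale in Syx and inversely in B1
  expect_lt(ll$lod, ll$loq)
  m0 <- fit_linear(levels5, 3 * levels5)
  expect_equal(unlist(lod_loq(m0)), c(lod = 0, loq = 0))
  m_neg <- m0; m_neg$B1 <- -1
  expect_error(lod_loq(m_neg), "positive slope")
})

test_that("validation summary implements %E and sample-sd %RSD", {
  # single value: accuracy only
  rep1 <- validation_summary(data.frame(level = 160, value = 156.01))
  expect_equal(round(rep1$accuracy_pctE, 2), -2.49)
  # hand arithmetic on (150, 160, 170): sd = 10, mean = 160
  rep2 <- validation_summary(data.frame(level = 160, day = c(1, 2, 3),
                                        value = c(150, 160, 170)))
  expect_equal(rep2$intermediate_pctRSD, 6.25)
  # identical replicates give zero %RSD everywhere computable
  rep3 <- validation_summary(data.frame(
    level = 160, run = 1, day = rep(1:2, each = 3),
    condition = "nominal", value = rep(158, 6)))
  expect_equal(rep3$repeatability_pctRSD, 0)
  expect_equal(rep3$intermediate_pctRSD, 0)
  # empty cells are NA, not zero
  expect_true(is.na(rep1$stability_pctRSD))
})
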
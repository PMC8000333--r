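test_that("analytic Gaussian area matches closed form and quadrature", {
  expect_equal(gaussian_area(data.frame(height = 1, center = 5, hwhm = 1)),
               sqrt(pi / log(2)))
  # numeric-integration oracle over center +/- 10 hwhm
  set.seed(2)
  for (i in 1:5) {
    h <- runif(1, 0.1, 2); w <- runif(1, 0.02, 0.5); cc <- runif(1, 3, 30)
    tm <- seq(cc - 10 * w, cc + 10 * w, length.out = 1e4)
    num <- sum(diff(tm) * (head(h * exp(-log(2) * ((tm - cc) / w)^2), -1) +
                             tail(h * exp(-log(2) * ((tm - cc) / w)^2), -1)) / 2)
    expect_equal(gaussian_area(data.frame(height = h, center = cc, hwhm = w)),
                 num, tolerance = 1e-6)
  }
  # linearity in height and width
  a1 <- gaussian_area(data.frame(height = 1, center = 0, hwhm = 0.3))
  expect_equal(gaussian_area(data.frame(height = 2, center = 0, hwhm = 0.3)),
               2 * a1)
  expect_equal(gaussian_area(data.frame(height = 1, center = 0, hwhm = 0.6)),
               2 * a1)
  expect_error(gaussian_area(data.frame(height = -1, center = 0, hwhm = 1)))
})

test_that("LM refinement recovers exact parameters on noiseless data", {
  tm <- seq(8, 12, by = 0.002)
  truth <- data.frame(height = 1, center = 10, hwhm = 0.1)
  ch <- chromatogram(tm, chromaqc:::gaussian_profile(tm, truth))
  init <- data.frame(height = 1.1, center = 10.02, hwhm = 0.09)
  fit <- fit_peaks(ch, init)
  expect_true(fit$converged)
  expect_equal(fit$peaks$height, 1, tolerance = 1e-6)
  expect_equal(fit$peaks$center, 10, tolerance = 1e-6)
  expect_equal(fit$peaks$hwhm, 0.1, tolerance = 1e-6)
  # starting at the optimum leaves SSR at the optimum
  fit2 <- fit_peaks(ch, truth)
  expect_lt(fit2$ssr, 1e-20)
  expect_true(fit2$converged)
})

test_that("overlapping peak pair is deconvolved within 3% in area", {
  tm <- seq(9, 11.5, by = 0.002)
  truth <- data.frame(height = c(1, 0.7), center = c(10, 10.2),
                      hwhm = c(0.08, 0.08))
  set.seed(5)
  y <- chromaqc:::gaussian_profile(tm, truth) + rnorm(length(tm), sd = 0.01)
  fit <- fit_peaks(chromatogram(tm, y),
                   data.frame(height = c(0.9, 0.8), center = c(9.97, 10.24),
                              hwhm = c(0.07, 0.09)))
  expect_equal(gaussian_area(fit$peaks), gaussian_area(truth),
               tolerance = 0.03)
  # refinement never increases the SSR
  expect_lte(fit$ssr, sum((y - chromaqc:::gaussian_profile(tm,
    data.frame(height = c(0.9, 0.8), center = c(9.97, 10.24),
               hwhm = c(0.07, 0.09))))^2))
})

test_that("blocked fit equals the joint fit on separated groups", {
  tm <- seq(0, 20, by = 0.005)
  truth <- data.frame(height = c(0.5, 0.8, 0.6), center = c(4, 4.3, 15),
                      hwhm = c(0.07, 0.09, 0.06))
  set.seed(6)
  y <- chromaqc:::gaussian_profile(tm, truth) + rnorm(length(tm), sd = 0.005)
  init <- truth
  init$height <- init$height * 1.1
  ch <- chromatogram(tm, y)
  blocked <- fit_peaks(ch, init)
  joint <- fit_peaks(ch, init, block_gap = Inf)
  expect_equal(blocked$peaks, joint$peaks, tolerance = 1e-5)
})

test_that("residual-driven addition finds peaks and honours its caps", {
  tm <- seq(0, 20, by = 0.005)
  truth <- data.frame(height = c(0.04, 0.03, 0.05), center = c(5, 10, 15),
                      hwhm = c(0.06, 0.08, 0.07))
  ch <- chromatogram(tm, chromaqc:::gaussian_profile(tm, truth))
  found <- auto_add_peaks(ch, min_height = 0.005)
  expect_equal(nrow(found$peaks), 3L)
  expect_equal(found$peaks$center, truth$center, tolerance = 1e-3)
  # residual already below threshold: input returned unchanged
  again <- auto_add_peaks(ch, current = found, min_height = 0.005)
  expect_equal(again$peaks, found$peaks, tolerance = 1e-8)
  # cap on the number of peaks is respected
  capped <- auto_add_peaks(ch, max_peaks = 2, min_height = 0.005)
  expect_equal(nrow(capped$peaks), 2L)
})

test_that("retention-time matching is greedy-nearest within tolerance", {
  mk <- function(centers) {
    structure(list(peaks = data.frame(height = rep(1, length(centers)),
                                      center = centers,
                                      hwhm = rep(0.05, length(centers))),
                   ssr = 0, n_points = 100, converged = TRUE),
              class = "peak_fit")
  }
  ref <- mk(c(5, 10, 15))
  # identical sets -> identical rows
  pt <- match_peaks(list(ref, mk(c(5, 10, 15))))
  expect_equal(pt$areas[1, ], pt$areas[2, ])
  expect_equal(pt$peak_names, c("peak_5.00", "peak_10.00", "peak_15.00"))
  # +0.05 min shift within the 0.15 tolerance keeps full matching
  pt2 <- match_peaks(list(ref, mk(c(5.05, 10.05, 15.05))))
  expect_true(all(pt2$areas[2, ] > 0))
  # +0.30 min shift on one peak falls outside and yields area 0 + warning
  expect_warning(pt3 <- match_peaks(list(ref, mk(c(5, 10.30, 15)))),
                 "unmatched")
  expect_equal(unname(pt3$areas[2, "peak_10.00"]), 0)
  expect_gt(pt3$areas[2, "peak_5.00"], 0)
})

test_that("DoE responses implement the half-height resolution sum", {
  set2 <- data.frame(height = c(1, 1), center = c(10, 11),
                     hwhm = c(0.25, 0.25))
  r <- doe_responses(set2)
  expect_equal(r$sum_resolution, 1.18)
  expect_equal(r$sum_area, sum(gaussian_area(set2)))
  # coincident centers give zero resolution
  expect_equal(doe_responses(data.frame(height = c(1, 1), center = c(10, 10 + 1e-12),
                                        hwhm = c(0.2, 0.2)))$sum_resolution,
               0, tolerance = 1e-9)
  # three peaks: only the two adjacent pairs count
  set3 <- data.frame(height = 1, center = c(10, 11, 12.5),
                     hwhm = c(0.25, 0.25, 0.25))
  expect_equal(doe_responses(set3)$sum_resolution,
               1.18 * 1 / 1 + 1.18 * 1.5 / 1)
  expect_equal(doe_responses(set3[1, ])$sum_resolution, 0)
})
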
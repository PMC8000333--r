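test_that("reference-peak ratios are scale-invariant with unit reference", {
  a <- c(peak_a = 2, peak_b = 4, peak_c = 8)
  rv <- reference_ratio_vector(a, "peak_a")
  expect_equal(unname(rv), c(1, 2, 4))
  expect_equal(reference_ratio_vector(5 * a, "peak_a"), rv)
  expect_error(reference_ratio_vector(c(peak_a = 0, peak_b = 1), "peak_a"),
               "positive")
  expect_error(reference_ratio_vector(a, "peak_z"), "not present")
})

test_that("all 19 proximity measures match the formula oracle", {
  x <- c(1, 2, 3); y <- c(2, 2, 2)
  got <- similarity_battery(x, y)
  expect_length(got, 19L)
  expect_equal(got, battery_oracle(x, y), tolerance = 1e-12)
  # a second, less regular pair
  x2 <- c(0.5, 1.7, 2.2, 4.1); y2 <- c(0.6, 1.5, 2.6, 3.3)
  expect_equal(similarity_battery(x2, y2), battery_oracle(x2, y2),
               tolerance = 1e-12)
  # identical inputs score 1 on every measure
  expect_equal(unname(similarity_battery(y2, y2)), rep(1, 19L))
  # outputs live on the similarity scale
  expect_true(all(got >= 0 & got <= 1))
  expect_error(similarity_battery(1:3, 1:4), "equal length")
})

test_that("proximity battery matches the registry implementation", {
  # independent cross-check against the proximity-measure registry for
  # the measures whose registry definition coincides with ours
  skip_if_not_installed("proxy")
  x <- c(0.8, 1.9, 3.1, 4.4, 2.2); y <- c(1.0, 1.6, 3.4, 4.0, 2.9)
  got <- similarity_battery(x, y)
  pr_d <- function(meth) as.numeric(proxy::dist(rbind(x, y), method = meth))
  pr_s <- function(meth) as.numeric(proxy::simil(rbind(x, y), method = meth))
  expect_equal(got[["cosine"]], pr_s("cosine"), tolerance = 1e-12)
  expect_equal(got[["eJaccard"]], pr_s("eJaccard"), tolerance = 1e-12)
  expect_equal(got[["eDice"]], pr_s("eDice"), tolerance = 1e-12)
  expect_equal(got[["correlation"]], pr_s("correlation"), tolerance = 1e-12)
  expect_equal(got[["gower"]], pr_s("Gower"), tolerance = 1e-12)
  # Soergel is excluded: the registry's implementation departs from the
  # canonical sum|x-y| / sum max(x,y) definition, which the formula
  # oracle above already pins down
  for (meth in c("Bray", "Canberra", "Chord", "divergence", "Euclidean",
                 "Geodesic", "Hellinger", "Manhattan", "Podani",
                 "supremum", "Whittaker", "Bhjattacharyya")) {
    expect_equal(got[[tolower(meth)]], 1 / (1 + pr_d(meth)),
                 tolerance = 1e-10, label = meth)
  }
})

test_that("orthogonal vectors give the closed-form cosine and geodesic", {
  got <- similarity_battery(c(1, 0), c(0, 1))
  expect_equal(unname(got["cosine"]), 0)
  expect_equal(unname(got["geodesic"]), 1 / (1 + pi / 2))
})

test_that("ratio matrices satisfy the reciprocal identity", {
  a <- c(p1 = 2, p2 = 4)
  M <- ratio_matrix(a)
  expect_equal(unclass(M), rbind(c(1, 0.5), c(2, 1)), ignore_attr = TRUE)
  set.seed(10)
  a2 <- stats::setNames(runif(7, 0.1, 5), paste0("p", 1:7))
  M2 <- ratio_matrix(a2)
  expect_equal(diag(unclass(M2)), rep(1, 7), ignore_attr = TRUE)
  expect_equal(unclass(M2) * t(unclass(M2)), matrix(1, 7, 7),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(ratio_matrix(c(p1 = 1, p2 = 0)), "p2")
})

test_that("SSIM is 1 on identity and degrades monotonically with offset", {
  set.seed(13)
  a <- stats::setNames(runif(8, 0.5, 4), paste0("p", 1:8))
  M <- ratio_matrix(a)
  expect_equal(ssim_score(M, M), 1)
  offs <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  scores <- vapply(offs, function(d) ssim_score(M, unclass(M) + d),
                   numeric(1))
  expect_true(all(scores < 1))
  expect_true(all(diff(scores) < 0))
  # symmetric in its arguments (global mode)
  B <- unclass(M) + 0.3
  expect_equal(ssim_score(M, B), ssim_score(B, M))
  expect_error(ssim_score(M, unclass(M)[1:4, 1:4]), "dimension")
})

test_that("windowed SSIM equals the per-window formula oracle", {
  set.seed(19)
  A <- matrix(runif(144, 0, 3), 12, 12)
  B <- A + matrix(rnorm(144, sd = 0.2), 12, 12)
  expect_equal(ssim_score(A, B, mode = "windowed", window = 8),
               ssim_windowed_oracle(A, B, w = 8), tolerance = 1e-6)
  # single full-size window reduces to the global statistic
  expect_equal(ssim_score(A, B, mode = "windowed", window = 12),
               ssim_score(A, B), tolerance = 1e-12)
})

test_that("battery and SSIM ignore overall concentration scaling", {
  set.seed(23)
  areas <- stats::setNames(runif(10, 0.2, 4), paste0("p", 1:10))
  scaled <- 3.7 * areas
  rv1 <- reference_ratio_vector(areas, "p1")
  rv2 <- reference_ratio_vector(scaled, "p1")
  expect_equal(similarity_battery(rv1, rv2)[["euclidean"]], 1)
  expect_equal(ssim_score(ratio_matrix(areas), ratio_matrix(scaled)), 1)
})

test_that("heatmap export writes a faithful text twin", {
  a <- c(p1 = 1, p2 = 2, p3 = 4)
  M <- ratio_matrix(a)
  png_path <- withr::local_tempfile(fileext = ".png")
  paths <- heatmap_export(M, png_path)
  expect_true(file.exists(paths[1]))
  got <- as.matrix(read.csv(paths[2], row.names = 1, check.names = FALSE))
  expect_equal(got, round(unclass(M), 3), ignore_attr = TRUE)
  # degenerate 1x1 matrix renders without error
  expect_no_error(heatmap_export(ratio_matrix(c(p1 = 2)),
                                 withr::local_tempfile(fileext = ".png")))
})

test_that("conformity report flags the most degraded batch", {
  set.seed(30)
  ref <- stats::setNames(runif(12, 0.5, 4), paste0("p", 1:12))
  pert_small <- 1 + runif(12, -0.02, 0.02)
  pert_exp <- 1 + runif(12, 0.25, 0.45)   # most components elevated...
  pert_exp[c(3, 7, 11)] <- 0.8            # ...some degraded
  batches <- peak_table(rbind(b1 = ref * pert_small,
                              b2 = ref,
                              b5 = ref * pert_exp),
                        peak_names = names(ref))
  rep <- conformity_report(ref, batches, reference_peak = "p1")
  tab <- rep$table
  expect_equal(tab$batch[which.min(tab$ssim)], "b5")
  expect_equal(tab$batch[which.min(tab$gower)], "b5")
  # reference against itself scores 1 everywhere and conforms
  battery_cols <- names(similarity_battery(ref, ref))
  expect_equal(unname(unlist(tab[tab$batch == "b2", battery_cols])),
               rep(1, 19L))
  expect_equal(tab$ssim[tab$batch == "b2"], 1)
  expect_true(tab$conforming[tab$batch == "b2"])
  expect_false(tab$conforming[tab$batch == "b5"])
})
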
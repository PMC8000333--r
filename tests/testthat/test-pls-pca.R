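make_xy <- function(n = 8, p = 4, seed = 21, sd = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p, mean = 5), n, p,
              dimnames = list(NULL, paste0("v", 1:p)))
  beta <- runif(p, -1, 2)
  list(X = X, y = as.numeric(X %*% beta) + rnorm(n, sd = sd))
}

test_that("SIMPLS collapses to simple OLS for a single predictor", {
  set.seed(3)
  x <- matrix(runif(7, 1, 3), ncol = 1, dimnames = list(NULL, "v"))
  y <- 2 + 3 * x[, 1] + rnorm(7, sd = 0.1)
  m <- simpls_fit(x, y, 1, cv = FALSE)
  expect_equal(predict(m, x), unname(fitted(lm(y ~ x))), tolerance = 1e-10)
})

test_that("full-rank SIMPLS equals the multivariate OLS oracle", {
  d <- make_xy()
  m <- simpls_fit(d$X, d$y, n_components = 4, cv = FALSE)
  ols <- lm(d$y ~ d$X)
  expect_equal(predict(m, d$X), unname(fitted(ols)), tolerance = 1e-8)
  # scores mutually orthogonal
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))) / max(diag(G)), 1e-8)
  # in-sample SSR never increases with components
  ssr <- vapply(1:4, function(k)
    sum((d$y - predict(m, d$X, ncomp = k))^2), numeric(1))
  expect_true(all(diff(ssr) <= 1e-10))
  # exact linear y on rank-1 X: R2 = 1 at one component
  X1 <- outer(1:6, c(1, 2, 0.5))
  y1 <- X1 %*% c(1, 0, 0)
  m1 <- suppressWarnings(simpls_fit(X1, as.numeric(y1), 3, cv = FALSE))
  expect_equal(m1$R2[1], 1, tolerance = 1e-10)
})

test_that("leave-one-out CV equals a from-scratch refit oracle", {
  d <- make_xy(n = 7, p = 3, seed = 9)
  tab <- loo_cv(d$X, d$y, 3)
  expect_equal(tab$RMSEP^2, tab$MSEP, tolerance = 1e-12)
  for (k in 1:3) {
    press <- 0
    for (i in seq_len(7)) {
      m <- simpls_fit(d$X[-i, ], d$y[-i], k, cv = FALSE)
      press <- press + (predict(m, d$X[i, , drop = FALSE],
                                ncomp = min(k, m$n_components)) - d$y[i])^2
    }
    expect_equal(tab$MSEP[k], press / 7, tolerance = 1e-10)
  }
  # noiseless exact relation: RMSEP ~ 0 at sufficient components
  set.seed(2)
  X <- matrix(rnorm(24, 10), 8, 3)
  y <- as.numeric(X %*% c(1, 2, 3))
  expect_lt(loo_cv(X, y, 3)$RMSEP[3], 1e-8)
})

test_that("jack-knife prediction intervals behave as constructed", {
  # noiseless model: training rows are reproduced and intervals are tight
  set.seed(14)
  X <- matrix(runif(15, 2, 6), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(X %*% c(2, 1, 0.5))
  m <- simpls_fit(X, y, 3)
  pr <- pls_predict(m, X)
  expect_equal(pr$estimate, y, tolerance = 1e-6)
  expect_equal(pr$upper - pr$lower, rep(0, 5), tolerance = 1e-6)
  # percent error against a nominal value
  pr160 <- pls_predict(m, X, nominal = 160)
  expect_equal(pr160$pct_error, 100 * (pr$estimate - 160) / 160)
  expect_equal(round(percent_error(179.33, 160), 2), 12.08)
  expect_equal(round(percent_error(156.01, 160), 2), -2.49)
  # missing training column is reported by name
  X_bad <- X[, 1:2]
  expect_error(pls_predict(m, X_bad), "c")
})

test_that("SVD-based PCA reconstructs data and orders variance", {
  set.seed(18)
  X <- matrix(rnorm(6 * 23), 6, 23)
  p <- pca(X)
  expect_equal(p$scores %*% t(p$loadings), scale(X, scale = FALSE),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(p$explained_pct), 100, tolerance = 1e-6)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  # eigen-decomposition oracle on the covariance
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(p$eigenvalues[1:5], ev[1:5], tolerance = 1e-8)
  # collinear 2-D points: one component explains everything
  X2 <- cbind(1:8, 2 * (1:8) + 3)
  p2 <- pca(X2)
  expect_equal(p2$explained_pct[1], 100, tolerance = 1e-10)
  expect_error(pca(cbind(rnorm(5), rep(1, 5)), scale = TRUE),
               "zero-variance")
})

test_that("bootstrap of explained variance is seeded and degenerate-safe", {
  X <- cbind(1:8, 2 * (1:8), 3 * (1:8) + 2)
  b1 <- bootstrap_eigenvalues(X, n_boot = 5, seed = 42)
  b2 <- bootstrap_eigenvalues(X, n_boot = 5, seed = 42)
  expect_identical(b1, b2)
  # all rows on a line: every resample puts 100% on PC1
  expect_equal(b1$mean_pct[1], 100, tolerance = 1e-9)
  # mean bootstrap PC1 close to the plug-in PC1 on separated data
  set.seed(6)
  Xs <- rbind(matrix(rnorm(40, 0), 10, 4), matrix(rnorm(40, 8), 10, 4))
  bb <- bootstrap_eigenvalues(Xs, n_boot = 200, seed = 7)
  expect_equal(bb$mean_pct[1], pca(Xs)$explained_pct[1], tolerance = 5 / 90)
})
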
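#' SIMPLS partial least squares regression
#'
#' Fits a univariate-response PLS model by the SIMPLS algorithm: the
#' cross-covariance vector X'y is deflated directly against an orthonormal
#' basis of x-loadings, yielding mutually orthogonal score vectors without
#' deflating X itself.  Regression coefficients are available for every
#' component count up to `n_components`.  Optionally a leave-one-out
#' cross-validation table (MSEP, RMSEP per component) and the per-fold
#' coefficient sets needed for jack-knife prediction intervals are computed.
#'
#' @param X Numeric matrix, samples x peaks.
#' @param y Response vector (nominal concentration, ug/mL).
#' @param n_components Number of SIMPLS factors requested; truncated with a
#'   warning if the data rank is lower.
#' @param cv Compute the leave-one-out CV table and jack-knife coefficient
#'   sets (default TRUE).
#' @return An object of class `"simpls_model"` with elements `weights`,
#'   `x_loadings`, `y_loadings`, `scores`, `coefficients` (p x A matrix, one
#'   column per component count), `intercepts`, `R2` (fitted, per component
#'   count), `x_mean`, `y_mean`, `cv_table`, `loo_coefficients`,
#'   `selected` (component count chosen by the one-standard-rule below).
#' @details The retained component count is the smallest one whose RMSEP is
#'   within 5 % of the minimum RMSEP over all fitted counts.
#' @export
simpls_fit <- function(X, y, n_components = 2L, cv = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n == length(y), n >= 2L)
  n_components <- min(n_components, n - 1L, p)
  core <- simpls_core(X, y, n_components)
  if (core$A < n_components)
    warning("rank deficiency: fit truncated to ", core$A, " component(s)")
  A <- core$A
  xm <- colMeans(X); ym <- mean(y)
  B <- sapply(seq_len(A), function(k)
    core$R[, seq_len(k), drop = FALSE] %*% core$Q[seq_len(k)])
  B <- matrix(B, nrow = p, ncol = A)
  b0 <- ym - as.numeric(crossprod(B, xm))
  sst <- sum((y - ym)^2)
  R2 <- vapply(seq_len(A), function(k) {
    fitted <- as.numeric(X %*% B[, k]) + b0[k]
    if (sst > 0) 1 - sum((y - fitted)^2) / sst else 1
  }, numeric(1))
  obj <- structure(list(n_components = A, x_mean = xm, y_mean = ym,
                        weights = core$R, x_loadings = core$P,
                        y_loadings = core$Q, scores = core$Tm,
                        coefficients = B, intercepts = b0, R2 = R2,
                        peak_names = colnames(X),
                        cv_table = NULL, loo_coefficients = NULL,
                        selected = A),
                   class = "simpls_model")
  if (cv && n >= 3L) {
    obj$cv_table <- loo_cv(X, y, A)
    rm_min <- min(obj$cv_table$RMSEP)
    obj$selected <- obj$cv_table$ncomp[
      which(obj$cv_table$RMSEP <= 1.05 * rm_min)[1L]]
    obj$loo_coefficients <- lapply(seq_len(n), function(i) {
      f <- simpls_core(X[-i, , drop = FALSE], y[-i],
                       min(A, nrow(X) - 2L, p))
      k <- min(obj$selected, f$A)
      b <- f$R[, seq_len(k), drop = FALSE] %*% f$Q[seq_len(k)]
      list(B = as.numeric(b),
           b0 = mean(y[-i]) - sum(b * colMeans(X[-i, , drop = FALSE])))
    })
  }
  obj
}

# SIMPLS deflation; returns weights R, loadings P, y-loadings Q, scores T
simpls_core <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  S <- as.numeric(crossprod(Xc, yc))
  R <- matrix(0, p, A); P <- matrix(0, p, A); Q <- numeric(A)
  Tm <- matrix(0, n, A); V <- matrix(0, p, A)
  a_done <- 0L
  for (a in seq_len(A)) {
    r <- S
    t <- as.numeric(Xc %*% r)
    normt <- sqrt(sum(t^2))
    if (!is.finite(normt) || normt < 1e-12 * max(1, sqrt(sum(Xc^2)))) break
    t <- t / normt; r <- r / normt
    pa <- as.numeric(crossprod(Xc, t))
    qa <- sum(yc * t)
    v <- pa
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pa)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- as.numeric(v) / nv
    R[, a] <- r; P[, a] <- pa; Q[a] <- qa; Tm[, a] <- t; V[, a] <- v
    S <- S - v * sum(v * S)
    a_done <- a
  }
  idx <- seq_len(max(a_done, 0L))
  list(R = R[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       Q = Q[idx], Tm = Tm[, idx, drop = FALSE], A = a_done)
}

#' @export
print.simpls_model <- function(x, ...) {
  cat("SIMPLS PLS model:", x$n_components, "component(s) fitted,",
      x$selected, "selected\n")
  cat("  fitted R2:", paste(sprintf("%.4f", x$R2), collapse = ", "), "\n")
  if (!is.null(x$cv_table)) {
    cat("  LOO CV:\n")
    print(format(x$cv_table, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.simpls_model <- function(object, ncomp = object$selected, ...) {
  c(intercept = object$intercepts[ncomp], object$coefficients[, ncomp])
}

#' @export
predict.simpls_model <- function(object, newdata,
                                 ncomp = object$selected, ...) {
  X <- as.matrix(newdata)
  as.numeric(X %*% object$coefficients[, ncomp]) + object$intercepts[ncomp]
}

#' Leave-one-out cross-validation of a SIMPLS model
#'
#' For each component count up to `max_components`, each sample is left out
#' in turn, the model refitted, and the held-out sample predicted.
#' MSEP is the mean squared leave-one-out residual and RMSEP its square
#' root.
#'
#' @param X,y As in [simpls_fit()]; at least 3 samples.
#' @param max_components Largest component count (truncated with a warning
#'   if above the leave-one-out rank).
#' @return Data frame with columns `ncomp`, `MSEP`, `RMSEP`.
#' @export
loo_cv <- function(X, y, max_components = 2L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(n >= 3L)
  A <- min(max_components, n - 2L, ncol(X))
  if (A < max_components)
    warning("max_components reduced to ", A, " for leave-one-out fits")
  pred <- matrix(NA_real_, n, A)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    f <- simpls_core(Xi, yi, A)
    for (k in seq_len(f$A)) {
      b <- f$R[, seq_len(k), drop = FALSE] %*% f$Q[seq_len(k)]
      b0 <- mean(yi) - sum(b * colMeans(Xi))
      pred[i, k] <- sum(X[i, ] * b) + b0
    }
  }
  msep <- colMeans((pred - y)^2)
  # component counts some fold could not reach (numerical rank) are
  # dropped rather than reported from partial folds
  ok <- !is.na(msep)
  if (!all(ok))
    warning("leave-one-out rank limits the CV table to ", sum(ok),
            " component(s)")
  data.frame(ncomp = seq_len(A)[ok], MSEP = msep[ok],
             RMSEP = sqrt(msep[ok]))
}

#' Predict new samples with jack-knife confidence intervals
#'
#' Point estimates come from the full-data coefficients; uncertainty from
#' the leave-one-out coefficient sets via Tukey pseudo-values: with
#' pseudo-value  p_i = n yhat - (n-1) yhat_(i), the jack-knife variance is
#' var(p)/n and the interval uses t(0.975, n-1).  When a nominal
#' concentration is supplied the percent error 100 (estimate - nominal) /
#' nominal is reported.
#'
#' @param model A `"simpls_model"` fitted with `cv = TRUE`.
#' @param X_new Matrix (or single row) of peak areas; columns must carry the
#'   training peak names when named.
#' @param nominal Optional nominal concentration (ug/mL), e.g. 160.
#' @return Data frame with `estimate`, `lower`, `upper` and (if `nominal`
#'   given) `pct_error`.
#' @export
pls_predict <- function(model, X_new, nominal = NULL) {
  stopifnot(inherits(model, "simpls_model"))
  if (is.null(model$loo_coefficients))
    stop("model was fitted without cv = TRUE; jack-knife sets unavailable")
  X <- as.matrix(X_new)
  if (ncol(X) == 1L && length(model$x_mean) > 1L) X <- t(X)
  if (!is.null(colnames(X)) && !is.null(model$peak_names)) {
    missing <- setdiff(model$peak_names, colnames(X))
    if (length(missing))
      stop("missing peak column(s): ", paste(missing, collapse = ", "))
    X <- X[, model$peak_names, drop = FALSE]
  }
  est <- predict(model, X)
  nfold <- length(model$loo_coefficients)
  loo_pred <- sapply(model$loo_coefficients,
                     function(f) as.numeric(X %*% f$B) + f$b0)
  loo_pred <- matrix(loo_pred, nrow = nrow(X))
  pseudo <- nfold * est - (nfold - 1) * loo_pred
  v <- apply(pseudo, 1L, stats::var) / nfold
  hw <- stats::qt(0.975, nfold - 1L) * sqrt(v)
  out <- data.frame(estimate = est, lower = est - hw, upper = est + hw)
  if (!is.null(nominal)) out$pct_error <- percent_error(est, nominal)
  out
}

#' Percent error against a nominal value
#'
#' @param estimate Estimated concentration(s).
#' @param nominal Nominal concentration.
#' @return `100 * (estimate - nominal) / nominal`.
#' @export
percent_error <- function(estimate, nominal)
  100 * (as.numeric(estimate) - nominal) / nominal

#' Principal component analysis by singular value decomposition
#'
#' Mean-centered (optionally autoscaled) SVD-based PCA.  Eigenvalues are the
#' score variances `d^2/(n-1)`; the explained percentages are computed from
#' the squared singular values and sum to 100 over all components.
#'
#' @param X Numeric matrix, samples x variables (>= 2 samples).
#' @param center,scale Centering / unit-variance scaling flags.
#' @return Object of class `"pca_result"`: `scores`, `loadings`,
#'   `eigenvalues`, `explained_pct`, `center`, `scale`.
#' @export
pca <- function(X, center = TRUE, scale = FALSE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2L, ncol(X) >= 1L)
  if (scale) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance variable(s) with scale = TRUE: ",
           paste(colnames(X)[sds == 0], collapse = ", "))
  }
  Xp <- scale(X, center = center, scale = scale)
  sv <- svd(Xp)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  k <- max(k, 1L)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  ev <- sv$d^2 / (nrow(X) - 1L)
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = ev[seq_len(k)],
                 explained_pct = 100 * sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 center = center, scale = scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", ncol(x$scores), "components\n")
  cat("  explained %:",
      paste(sprintf("%.1f", x$explained_pct), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.pca_result <- function(x, comps = c(1L, 2L), ...) {
  graphics::plot(x$scores[, comps[1L]], x$scores[, comps[2L]],
                 xlab = sprintf("PC%d (%.1f%%)", comps[1L],
                                x$explained_pct[comps[1L]]),
                 ylab = sprintf("PC%d (%.1f%%)", comps[2L],
                                x$explained_pct[comps[2L]]), ...)
  graphics::text(x$scores[, comps[1L]], x$scores[, comps[2L]],
                 labels = rownames(x$scores), pos = 3, cex = 0.7)
  invisible(x)
}

#' Bootstrap distribution of PCA explained variance
#'
#' Resamples sample rows with replacement, re-runs the PCA on each
#' resample, and summarizes the per-component explained percentage by its
#' mean and a percentile interval.  Degenerate resamples (all rows
#' identical) are skipped with a warning.
#'
#' @param X Samples x variables matrix.
#' @param n_boot Number of bootstrap resamples (default 7).
#' @param seed Optional integer seed.
#' @param center,scale Passed to [pca()].
#' @param probs Percentile interval probabilities.
#' @return Data frame with `component`, `mean_pct`, `lower_pct`,
#'   `upper_pct` over the resamples.
#' @export
bootstrap_eigenvalues <- function(X, n_boot = 7L, seed = NULL,
                                  center = TRUE, scale = FALSE,
                                  probs = c(0.025, 0.975)) {
  X <- as.matrix(X)
  stopifnot(n_boot >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ncomp <- min(dim(X))
  res <- matrix(NA_real_, n_boot, ncomp)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(X), replace = TRUE)
    Xb <- X[idx, , drop = FALSE]
    if (all(apply(Xb, 2L, function(col) length(unique(col)) == 1L))) {
      warning("degenerate resample ", b, " skipped (all rows identical)")
      next
    }
    p <- pca(Xb, center = center, scale = scale)
    k <- min(ncomp, length(p$explained_pct))
    res[b, seq_len(k)] <- p$explained_pct[seq_len(k)]
  }
  data.frame(component = seq_len(ncomp),
             mean_pct = colMeans(res, na.rm = TRUE),
             lower_pct = apply(res, 2L, stats::quantile, probs = probs[1L],
                               na.rm = TRUE, names = FALSE),
             upper_pct = apply(res, 2L, stats::quantile, probs = probs[2L],
                               na.rm = TRUE, names = FALSE))
}
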
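#' Reference-peak ratio vector
#'
#' Divides every retained peak area of a sample by the area of a designated
#' reference peak (the well-resolved, most-linear peak of the profile).
#' Ratios are invariant to the overall concentration of the injected
#' solution, so batches can be compared on composition alone.
#'
#' @param areas Named numeric vector of peak areas, or a single-row
#'   [peak_table()] subset (`pt$areas[i, ]`).
#' @param reference_peak Name of the reference peak.
#' @return Named numeric vector of ratios; the reference entry equals 1.
#' @export
reference_ratio_vector <- function(areas, reference_peak) {
  a <- unlist(areas)
  if (!reference_peak %in% names(a))
    stop("reference peak ", reference_peak, " not present")
  ref <- a[[reference_peak]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference peak area must be positive (", reference_peak, ")")
  a / ref
}

#' Similarity and distance battery for peak-ratio vectors
#'
#' Computes the 19 named proximity measures used for batch comparison: the
#' similarities eJaccard, cosine, eDice, correlation (Pearson) and Gower,
#' and the distances bray, canberra, chord, divergence, euclidean,
#' geodesic, hellinger, kullback (symmetrized, on sum-normalized vectors),
#' manhattan, podani (1997 ordinal discordance, 1 - Kendall tau-a),
#' soergel, supremum, whittaker and bhjattacharyya.  Every distance d is
#' reported on a similarity-like scale through s = 1/(1 + d), so all 19
#' outputs equal 1 for identical inputs.
#'
#' @param x,y Positive numeric vectors of equal length (ratio vectors).
#' @param ranges Per-variable ranges for the Gower measure; defaults to
#'   `abs(x - y)` pooled over the pair (`pmax` of values) when `NULL`, i.e.
#'   range computed from the two vectors.  Supply pooled ranges over all
#'   samples for multi-batch comparisons.
#' @return Named numeric vector of length 19.
#' @export
similarity_battery <- function(x, y, ranges = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0) || !sum(x) || !sum(y))
    stop("ratio vectors must be non-negative with positive sum")
  xx <- sum(x^2); yy <- sum(y^2); xy <- sum(x * y)
  cosine <- xy / sqrt(xx * yy)
  if (is.null(ranges)) ranges <- abs(x - y)  # per-pair ranges, 2 rows
  gower_terms <- mapply(function(xi, yi, ri) {
    if (ri == 0) { if (xi == yi) 1 else
      stop("zero-range Gower variable with unequal values") }
    else 1 - abs(xi - yi) / ri
  }, x, y, ranges)
  px <- x / sum(x); py <- y / sum(y)
  # Kendall tau-a discordance: ties count in neither direction
  n <- length(x)
  conc <- 0; disc <- 0
  for (i in seq_len(n - 1L)) {
    s <- sign(x[(i + 1L):n] - x[i]) * sign(y[(i + 1L):n] - y[i])
    conc <- conc + sum(s > 0); disc <- disc + sum(s < 0)
  }
  podani <- 1 - 2 * (conc - disc) / (n * (n - 1))
  canb <- abs(x - y) / abs(x + y)
  canb[x + y == 0] <- 0                      # shared absence contributes 0
  d <- c(bray = sum(abs(x - y)) / sum(x + y),
         canberra = sum(canb),
         chord = sqrt(2 * (1 - cosine)),
         divergence = sum(ifelse(x + y == 0, 0, (x - y)^2 / (x + y)^2)),
         euclidean = sqrt(sum((x - y)^2)),
         geodesic = acos(min(1, max(-1, cosine))),
         hellinger = sqrt(sum((sqrt(px) - sqrt(py))^2)),
         kullback = sum(ifelse(px == 0, 0, px * log(px / py))) +
           sum(ifelse(py == 0, 0, py * log(py / px))),
         manhattan = sum(abs(x - y)),
         podani = podani,
         soergel = sum(abs(x - y)) / sum(pmax(x, y)),
         supremum = max(abs(x - y)),
         whittaker = sum(abs(px - py)) / 2,
         bhjattacharyya = sqrt(sum((sqrt(x) - sqrt(y))^2)))
  s <- c(eJaccard = xy / (xx + yy - xy),
         cosine = cosine,
         eDice = 2 * xy / (xx + yy),
         # Pearson is undefined for a constant vector: score 1 when both
         # are constant (indistinguishable profiles), 0 when only one is
         correlation = if (stats::sd(x) == 0 || stats::sd(y) == 0) {
           as.numeric(stats::sd(x) == stats::sd(y))
         } else stats::cor(x, y),
         gower = mean(gower_terms))
  c(s, 1 / (1 + d))
}

#' All-by-all peak-ratio matrix of one sample
#'
#' M[i, j] = area_i / area_j over a fixed global peak ordering, so the
#' diagonal is 1 and M[i, j] * M[j, i] = 1.  Because every entry is a
#' ratio, the matrix is invariant to the sample's overall concentration.
#'
#' @param areas Named numeric vector of peak areas (all positive).
#' @param peaks Ordered peak names to use (default: all, input order).
#' @return Square matrix of class `"ratio_matrix"`.
#' @export
ratio_matrix <- function(areas, peaks = NULL) {
  a <- unlist(areas)
  if (is.null(peaks)) peaks <- names(a)
  if (!all(peaks %in% names(a)))
    stop("missing peak(s): ",
         paste(setdiff(peaks, names(a)), collapse = ", "))
  a <- a[peaks]
  bad <- names(a)[!is.finite(a) | a <= 0]
  if (length(bad))
    stop("non-positive area for peak(s): ", paste(bad, collapse = ", "))
  M <- outer(a, a, "/")
  dimnames(M) <- list(peaks, peaks)
  class(M) <- c("ratio_matrix", class(M))
  M
}

#' Structural similarity index between two ratio matrices
#'
#' Both matrices are min-max scaled to [0, 1] using their pooled range,
#' then compared by SSIM with C1 = (K1 L)^2, C2 = (K2 L)^2 where L is the
#' dynamic range after scaling (1).  `mode = "global"` computes the single
#' SSIM statistic over all entries; `mode = "windowed"` averages it over
#' all sliding `window x window` sub-blocks (sample variance/covariance,
#' denominator N-1, in both modes).
#'
#' @param M_ref,M_test Square matrices of identical dimension and peak
#'   order.
#' @param K1,K2 Stability constants (universal defaults 0.01, 0.03).
#' @param mode `"global"` (default) or `"windowed"`.
#' @param window Window side length for windowed mode.
#' @return SSIM value in [-1, 1]; 1 iff the scaled matrices are identical.
#' @export
ssim_score <- function(M_ref, M_test, K1 = 0.01, K2 = 0.03,
                       mode = c("global", "windowed"), window = 8L) {
  mode <- match.arg(mode)
  M_ref <- unclass(as.matrix(M_ref)); M_test <- unclass(as.matrix(M_test))
  if (!all(dim(M_ref) == dim(M_test)))
    stop("matrices differ in dimension")
  if (!is.null(dimnames(M_ref)) && !is.null(dimnames(M_test)) &&
      !identical(dimnames(M_ref), dimnames(M_test)))
    stop("matrices differ in peak ordering")
  rng <- range(c(M_ref, M_test))
  span <- diff(rng)
  if (span == 0) return(1)
  A <- (M_ref - rng[1L]) / span
  B <- (M_test - rng[1L]) / span
  L <- 1
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  stat <- function(a, b) {
    ma <- mean(a); mb <- mean(b)
    va <- stats::var(as.numeric(a)); vb <- stats::var(as.numeric(b))
    cab <- stats::cov(as.numeric(a), as.numeric(b))
    ((2 * ma * mb + C1) * (2 * cab + C2)) /
      ((ma^2 + mb^2 + C1) * (va + vb + C2))
  }
  if (mode == "global") return(stat(A, B))
  n <- nrow(A)
  w <- min(window, n)
  vals <- numeric(0)
  for (i in seq_len(n - w + 1L))
    for (j in seq_len(n - w + 1L)) {
      ii <- i:(i + w - 1L); jj <- j:(j + w - 1L)
      vals <- c(vals, stat(A[ii, jj], B[ii, jj]))
    }
  mean(vals)
}

#' Export a ratio matrix as a heatmap image plus a text twin
#'
#' The heatmap keeps the fixed peak ordering (no dendrogram reordering) and
#' uses a diverging palette symmetric about the middle of the value range,
#' so low and high extremes are dark and mid values light.  The matrix is
#' also written as delimited text next to the image for diffing.
#'
#' @param M A [ratio_matrix()].
#' @param path Output PNG path; the text twin gets extension `.csv`.
#' @param digits Decimals in the text twin.
#' @return Invisible character vector `c(image, text)` of paths written.
#' @export
heatmap_export <- function(M, path, digits = 3) {
  M <- as.matrix(M)
  txt <- sub("\\.[^.]*$", ".csv", path)
  utils::write.table(round(unclass(M), digits), txt, sep = ",",
                     col.names = NA, quote = FALSE)
  pal <- grDevices::colorRampPalette(c("#313695", "#f7f7f7", "#a50026"))(63)
  grDevices::png(path, width = 600, height = 600)
  op <- graphics::par(mar = c(4, 4, 1, 1))
  n <- nrow(M)
  graphics::image(seq_len(n), seq_len(n),
                  t(unclass(M)[n:1, , drop = FALSE]),
                  col = pal, axes = FALSE, xlab = "", ylab = "")
  if (!is.null(colnames(M))) {
    graphics::axis(1, at = seq_len(n), labels = colnames(M), las = 2,
                   cex.axis = 0.6)
    graphics::axis(2, at = seq_len(n), labels = rev(rownames(M)), las = 2,
                   cex.axis = 0.6)
  }
  graphics::par(op)
  grDevices::dev.off()
  invisible(c(path, txt))
}

#' Batch-conformity report against a reference batch
#'
#' For every tested batch: the 19-measure similarity battery between its
#' reference-peak ratio vector and the reference batch's, the SSIM between
#' the two all-by-all ratio matrices, and the Euclidean distance between
#' the batch and the reference in PCA score space (PCA on the ratio vectors
#' of all samples).  The batch with the minimum SSIM is flagged
#' non-conforming when that minimum falls below `ssim_threshold`.
#'
#' @param reference Named area vector (or single peak-table row) of the
#'   reference batch.
#' @param batches A [peak_table()] of tested batches.
#' @param reference_peak Name of the ratio reference peak.
#' @param peaks Retained peak names used for ratios (default: all columns).
#' @param ssim_threshold Conformity flag threshold on SSIM.
#' @param ssim_params List of arguments passed on to [ssim_score()].
#' @return Object of class `"conformity_report"`: a list with `table` (one
#'   row per batch: battery values, `ssim`, `pca_distance`, `conforming`),
#'   `pca` and the inputs used.
#' @export
conformity_report <- function(reference, batches, reference_peak,
                              peaks = NULL, ssim_threshold = 0.95,
                              ssim_params = list()) {
  stopifnot(inherits(batches, "peak_table"))
  ref <- unlist(reference)
  if (is.null(peaks)) peaks <- batches$peak_names
  missing <- setdiff(peaks, names(ref))
  if (length(missing))
    stop("reference lacks peak(s): ", paste(missing, collapse = ", "))
  if (!all(peaks %in% batches$peak_names))
    stop("batch table lacks peak(s): ",
         paste(setdiff(peaks, batches$peak_names), collapse = ", "))
  ref <- ref[peaks]
  A <- batches$areas[, peaks, drop = FALSE]
  rv_ref <- reference_ratio_vector(ref, reference_peak)
  rv <- t(apply(A, 1L, reference_ratio_vector, reference_peak))
  pooled_ranges <- apply(rbind(rv_ref, rv), 2L,
                         function(v) diff(range(v)))
  M_ref <- ratio_matrix(ref, peaks)
  bat <- t(vapply(seq_len(nrow(A)), function(k)
    similarity_battery(rv[k, ], rv_ref, ranges = pooled_ranges),
    numeric(19L)))
  ssim <- vapply(seq_len(nrow(A)), function(k)
    do.call(ssim_score, c(list(ratio_matrix(A[k, ], peaks), M_ref),
                          ssim_params)), numeric(1))
  pc <- pca(rbind(reference = rv_ref, rv))
  d_pca <- sqrt(rowSums(sweep(pc$scores[-1L, , drop = FALSE], 2L,
                              pc$scores[1L, ])^2))
  tab <- data.frame(batch = batches$sample_ids, bat, ssim = ssim,
                    pca_distance = d_pca,
                    conforming = !(ssim == min(ssim) &
                                     ssim < ssim_threshold),
                    check.names = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, pca = pc, reference_peak = reference_peak,
                 peaks = peaks, ssim_threshold = ssim_threshold),
            class = "conformity_report")
}

#' @export
print.conformity_report <- function(x, ...) {
  cat("Batch conformity vs reference (ratio peak ", x$reference_peak,
      ", ", length(x$peaks), " peaks)\n", sep = "")
  show <- x$table[, c("batch", "cosine", "gower", "ssim", "pca_distance",
                      "conforming")]
  print(format(show, digits = 3), row.names = FALSE)
  invisible(x)
}
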
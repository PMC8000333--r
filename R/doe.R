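#' Box-Behnken design for chromatographic method optimization
#'
#' Three-level response-surface design placing runs at the edge midpoints
#' of the factor cube (all +/-1 combinations of each factor pair, the
#' remaining factor at 0) plus replicated center points.  The default
#' factor mapping is the UV-method optimization space: ammonium formate
#' concentration 1e-3 / 2e-3 / 3e-3 M, detection wavelength 214 / 217 /
#' 220 nm, column temperature 29 / 34.5 / 40 degC; with 5 center points
#' the design has 17 runs.
#'
#' @param n_factors Number of factors (3 supported).
#' @param n_center Number of center replicates.
#' @param mapping Named list, per factor `c(low, mid, high)` in actual
#'   units.
#' @return Object of class `"bbd_design"`: list with `coded` (runs x
#'   factors matrix over -1/0/+1), `n_center`, `mapping`.
#' @export
box_behnken <- function(n_factors = 3L, n_center = 5L,
                        mapping = list(
                          formate_M = c(1e-3, 2e-3, 3e-3),
                          wavelength_nm = c(214, 217, 220),
                          temperature_C = c(29, 34.5, 40))) {
  if (n_factors != 3L)
    stop("only the 3-factor Box-Behnken design is supported")
  pm <- c(-1, 1)
  edge <- NULL
  for (pair in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
    for (a in pm) for (b in pm) {
      row <- numeric(3)
      row[pair] <- c(a, b)
      edge <- rbind(edge, row)
    }
  }
  coded <- rbind(edge, matrix(0, n_center, 3L))
  fac_names <- if (!is.null(mapping)) names(mapping) else
    paste0("X", 1:3)
  dimnames(coded) <- list(NULL, fac_names)
  structure(list(coded = coded, n_center = as.integer(n_center),
                 mapping = mapping),
            class = "bbd_design")
}

#' @export
print.bbd_design <- function(x, ...) {
  cat("Box-Behnken design:", nrow(x$coded), "runs (",
      nrow(x$coded) - x$n_center, "edge +", x$n_center, "center )\n")
  invisible(x)
}

#' Map a coded design to actual factor units
#'
#' Coded -1 / 0 / +1 map to each factor's low / mid / high setting.
#'
#' @param design A `"bbd_design"`.
#' @return Runs x factors matrix in actual units.
#' @export
decode <- function(design) {
  stopifnot(inherits(design, "bbd_design"))
  if (is.null(design$mapping)) stop("design carries no factor mapping")
  coded <- design$coded
  out <- coded
  for (j in seq_len(ncol(coded))) {
    lvl <- design$mapping[[colnames(coded)[j]]]
    if (is.null(lvl)) stop("missing mapping for factor ", colnames(coded)[j])
    mid <- lvl[2L]; half <- (lvl[3L] - lvl[1L]) / 2
    out[, j] <- mid + coded[, j] * half
  }
  out
}

# candidate model terms on coded factors, as character labels
rsm_candidate_terms <- function(fac) {
  n <- length(fac)
  linear <- fac
  tw <- c(); sq <- paste0("I(", fac, "^2)")
  cub <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tw <- c(tw, paste0(fac[i], ":", fac[j]))
    cub <- c(cub, paste0("I(", fac[i], "^2):", fac[j]),
             paste0(fac[i], ":I(", fac[j], "^2)"))
  }
  list(linear = linear, interactions = tw, squares = sq, cubic = cub)
}

#' Fit a reduced response-surface model to design responses
#'
#' OLS on the coded factors starting from the estimable cubic-type
#' candidate set (linear + two-way interactions + squares + mixed
#' quadratic-by-linear terms); terms aliased on the design are dropped by
#' rank detection, then backward elimination removes the term with the
#' largest p-value above `alpha_keep`, preserving model hierarchy (a term
#' is never removed while a higher-order term containing its factors
#' remains).  The ANOVA partitions the residual into lack-of-fit and pure
#' error estimated from the replicated center points.
#'
#' @param design A `"bbd_design"`.
#' @param y Response vector, one value per design run.
#' @param alpha_keep Significance level for keeping terms.
#' @param response Response name (for reporting).
#' @return Object of class `"rsm_fit"`: the `lm` fit, retained `terms`,
#'   `anova` (model/lack-of-fit/pure-error rows), `R2`.
#' @export
fit_response_surface <- function(design, y, alpha_keep = 0.05,
                                 response = "response") {
  stopifnot(inherits(design, "bbd_design"))
  coded <- design$coded
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(coded))
  df <- as.data.frame(coded)
  fac <- colnames(coded)
  cand <- rsm_candidate_terms(fac)
  terms_now <- unlist(cand, use.names = FALSE)
  fit_with <- function(terms) {
    fml <- stats::reformulate(if (length(terms)) terms else "1",
                              response = "y")
    stats::lm(fml, data = cbind(df, y = y))
  }
  # drop aliased terms (rank deficiency) in candidate order
  repeat {
    fit <- fit_with(terms_now)
    aliased <- names(which(is.na(stats::coef(fit))))
    if (!length(aliased)) break
    drop1term <- label_match(terms_now, aliased[1L])
    terms_now <- setdiff(terms_now, drop1term)
  }
  # backward elimination with hierarchy preservation
  repeat {
    fit <- fit_with(terms_now)
    sm <- summary(fit)$coefficients
    pv <- sm[rownames(sm) != "(Intercept)", 4L]
    pv[is.na(pv)] <- 1          # zero coefficient with zero SE: drop
    removable <- terms_now[vapply(terms_now, function(tt)
      !protected_by_hierarchy(tt, terms_now), logical(1))]
    pv_rm <- pv[vapply(names(pv), function(cn)
      label_match(removable, cn) != "" , logical(1))]
    pv_rm <- pv_rm[pv_rm > alpha_keep]
    if (!length(pv_rm)) break
    worst <- names(pv_rm)[which.max(pv_rm)]
    terms_now <- setdiff(terms_now, label_match(terms_now, worst))
    if (!length(terms_now)) break
  }
  fit <- fit_with(terms_now)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- length(terms_now)
  df_res <- length(y) - df_mod - 1L
  center <- rowSums(coded != 0) == 0
  n_c <- sum(center)
  an <- list(model = list(SS = ss_mod, df = df_mod,
                          F = (ss_mod / max(df_mod, 1)) /
                            (ss_res / max(df_res, 1)),
                          p = stats::pf((ss_mod / max(df_mod, 1)) /
                                          (ss_res / max(df_res, 1)),
                                        df_mod, df_res,
                                        lower.tail = FALSE)))
  if (n_c >= 2L) {
    ss_pe <- sum((y[center] - mean(y[center]))^2)
    df_pe <- n_c - 1L
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
    an$pure_error <- list(SS = ss_pe, df = df_pe)
    an$lack_of_fit <- if (df_lof > 0) {
      Fl <- (ss_lof / df_lof) / (ss_pe / df_pe)
      list(SS = ss_lof, df = df_lof, F = Fl,
           p = stats::pf(Fl, df_lof, df_pe, lower.tail = FALSE))
    } else list(SS = ss_lof, df = df_lof, F = NA_real_, p = NA_real_)
  } else {
    an$pure_error <- NULL
    an$lack_of_fit <- NA  # unavailable without center replicates
  }
  structure(list(fit = fit, terms = terms_now, anova = an,
                 R2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 response = response, design = design),
            class = "rsm_fit")
}

# match a coefficient label back to a term label, tolerating the a:b vs
# b:a and I(x^2):y orderings lm may emit
label_match <- function(terms, label) {
  norm <- function(s) paste(sort(strsplit(s, ":", fixed = TRUE)[[1L]]),
                            collapse = ":")
  hit <- terms[vapply(terms, function(tt) norm(tt) == norm(label),
                      logical(1))]
  if (length(hit)) hit[1L] else ""
}

# factor-power vector of a term label, e.g. "I(a^2):b" -> c(a = 2, b = 1)
term_powers <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
  pw <- integer(0)
  for (p in parts) {
    if (grepl("^I\\(.*\\^2\\)$", p)) {
      v <- sub("^I\\((.*)\\^2\\)$", "\\1", p)
      pw[v] <- (if (v %in% names(pw)) pw[[v]] else 0L) + 2L
    } else {
      pw[p] <- (if (p %in% names(pw)) pw[[p]] else 0L) + 1L
    }
  }
  pw
}

# TRUE when a retained higher-order term contains `term` (so removing it
# would break model hierarchy)
protected_by_hierarchy <- function(term, terms) {
  p1 <- term_powers(term)
  any(vapply(setdiff(terms, term), function(o) {
    p2 <- term_powers(o)
    all(names(p1) %in% names(p2)) &&
      all(p1 <= p2[names(p1)]) && sum(p2) > sum(p1)
  }, logical(1)))
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat("Response surface fit (", x$response, "): ",
      length(x$terms), " terms, R2 = ", sprintf("%.4f", x$R2), "\n",
      sep = "")
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  an <- x$anova
  cat(sprintf("  model F = %.3f (p = %.4g)\n", an$model$F, an$model$p))
  if (is.list(an$lack_of_fit) && is.finite(an$lack_of_fit$F))
    cat(sprintf("  lack of fit F = %.3f (p = %.4g), pure-error df = %d\n",
                an$lack_of_fit$F, an$lack_of_fit$p, an$pure_error$df))
  invisible(x)
}

#' @export
coef.rsm_fit <- function(object, ...) stats::coef(object$fit)

#' @export
predict.rsm_fit <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  colnames(nd) <- colnames(object$design$coded)
  as.numeric(stats::predict(object$fit, nd))
}

#' Derringer-Suich desirability optimization over fitted responses
#'
#' Each maximize-goal response is scored d = clip(((yhat - L)/(U - L))^w,
#' 0, 1); the overall desirability D is the geometric mean of the d_i.  D
#' is maximized over a deterministic coded-space grid and polished by
#' Nelder-Mead (clamped to the coded cube); grid ties break to the first
#' point in row-major order.
#'
#' @param fits List of `"rsm_fit"` objects (one per response).
#' @param goals List of goals, one per fit: each a list with optional
#'   `low`, `high` (anchors; default observed min/max of that response
#'   over the design) and `weight` (default 1).
#' @param grid Points per factor in the search grid (default 21).
#' @return List with `coded` (optimal settings), `actual` (decoded),
#'   `D`, and per-response `d`.
#' @export
desirability_optimize <- function(fits, goals = NULL, grid = 21L) {
  stopifnot(length(fits) >= 1L)
  if (is.null(goals)) goals <- replicate(length(fits), list(),
                                         simplify = FALSE)
  if (length(goals) != length(fits))
    stop("one goal per fitted response is required")
  design <- fits[[1L]]$design
  k <- ncol(design$coded)
  anchors <- lapply(seq_along(fits), function(i) {
    yhat <- stats::fitted(fits[[i]]$fit)
    list(low = if (!is.null(goals[[i]]$low)) goals[[i]]$low else min(yhat),
         high = if (!is.null(goals[[i]]$high)) goals[[i]]$high else
           max(yhat),
         weight = if (!is.null(goals[[i]]$weight)) goals[[i]]$weight else 1)
  })
  Dfun <- function(x) {
    x <- pmin(1, pmax(-1, x))
    nd <- as.data.frame(matrix(x, nrow = 1L))
    d <- vapply(seq_along(fits), function(i) {
      a <- anchors[[i]]
      yh <- predict(fits[[i]], nd)
      min(1, max(0, (yh - a$low) / (a$high - a$low)))^a$weight
    }, numeric(1))
    prod(d)^(1 / length(d))
  }
  g <- seq(-1, 1, length.out = grid)
  pts <- as.matrix(expand.grid(rep(list(g), k)))
  vals <- apply(pts, 1L, Dfun)
  best <- pts[which.max(vals), ]
  pol <- stats::optim(best, function(x) -Dfun(x), method = "Nelder-Mead")
  x_opt <- pmin(1, pmax(-1, pol$par))
  if (-pol$value < max(vals)) x_opt <- best   # keep grid best on failure
  names(x_opt) <- colnames(design$coded)
  dsn <- design; dsn$coded <- matrix(x_opt, 1L,
                                     dimnames = list(NULL, names(x_opt)))
  d_each <- vapply(seq_along(fits), function(i) {
    a <- anchors[[i]]
    yh <- predict(fits[[i]], as.data.frame(t(x_opt)))
    min(1, max(0, (yh - a$low) / (a$high - a$low)))^a$weight
  }, numeric(1))
  list(coded = x_opt,
       actual = if (!is.null(design$mapping)) decode(dsn)[1L, ] else NULL,
       D = Dfun(x_opt), d = d_each)
}
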
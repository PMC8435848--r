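# Statistical layer: fixed-effects GLMs with AICc selection, univariate
# smoothing-spline additive models with GCV, and OLS regressions.
# Significance threshold is p < 0.05 throughout.

#' Small-sample corrected Akaike Information Criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1)`; converges to the AIC as n
#' grows and is undefined for `n <= k + 1`.
#'
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (!is.finite(loglik) || !is.finite(k) || !is.finite(n)) {
    stop_invalid("all arguments must be finite")
  }
  if (n <= k + 1) {
    stop_invalid("AICc undefined: n must exceed k + 1")
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a fixed-effects GLM for one response of the factorial experiment
#'
#' Temperature, N:P supply ratio and nitrate concentration enter as numeric
#' covariates (one coefficient per factor). `order` controls the highest
#' interaction order included: 1 (main effects), 2 (plus all two-way
#' interactions) or 3 (plus the three-way interaction).
#'
#' @param table data.frame containing the response and the factor columns.
#' @param response name of the response column.
#' @param order highest interaction order, 1, 2 or 3.
#' @param terms names of the factor columns.
#' @param family a [stats::family] object; default Gaussian with identity
#'   link. A Gamma log link can be selected per response.
#' @return List of class `glm_fit` with the fitted model, `coefficients`
#'   table (estimate, SE, t, p), `loglik`, `k`, `n`, `aicc`, `order`.
#' @export
fit_glm <- function(table, response, order = 1,
                    terms = c("temperature", "np_ratio", "nitrate"),
                    family = gaussian()) {
  missing <- setdiff(c(response, terms), names(table))
  if (length(missing)) {
    stop_invalid(paste("missing columns:", paste(missing, collapse = ", ")))
  }
  if (!order %in% 1:3) stop_invalid("`order` must be 1, 2 or 3")
  table <- table[complete.cases(table[, c(response, terms), drop = FALSE]), ]
  rhs <- if (!length(terms)) "1" else if (order == 1)
    paste(terms, collapse = " + ") else
    sprintf("(%s)^%d", paste(terms, collapse = " + "), order)
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- glm(fml, data = table, family = family)
  if (any(is.na(coef(fit)))) {
    stop_invalid(paste(
      "rank-deficient design; aliased terms:",
      paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  ll <- logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n <= k + 1) {
    stop_invalid(sprintf("AICc undefined: n = %d, k = %d", n, k))
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
    t = sm[, 3], p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    model = fit, coefficients = coefs, loglik = as.numeric(ll),
    k = k, n = n, aicc = aicc(as.numeric(ll), k, n),
    order = order, response = response
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("GLM fit: %s, interaction order %d, n = %d, AICc = %.2f\n",
              x$response, x$order, x$n, x$aicc))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Select among nested GLM candidates by AICc
#'
#' The lowest-AICc model is chosen when it improves on every simpler
#' candidate by at least `delta` units (default 10). Otherwise the simplest
#' model is retained, unless a more complex candidate contains an
#' interaction term significant at p < 0.05, in which case the
#' lowest-AICc such candidate is chosen.
#'
#' @param candidates list of `glm_fit` objects (nested, any order).
#' @param delta AICc improvement required to prefer a more complex model.
#' @param p_threshold significance threshold for interaction terms.
#' @return List with `chosen` (a `glm_fit`), `rule` (which rule fired) and
#'   `table` (candidate AICc summary).
#' @export
select_model <- function(candidates, delta = 10, p_threshold = 0.05) {
  if (!length(candidates)) stop_invalid("empty candidate list")
  k <- vapply(candidates, function(f) f$k, numeric(1))
  a <- vapply(candidates, function(f) f$aicc, numeric(1))
  ord <- order(k, a)  # by complexity, then fit
  candidates <- candidates[ord]; k <- k[ord]; a <- a[ord]

  tab <- data.frame(
    order = vapply(candidates, function(f) f$order, numeric(1)),
    k = k, aicc = a
  )
  best <- which.min(a)
  simpler <- which(k < k[best])
  if (length(simpler) && all(a[simpler] - a[best] >= delta)) {
    return(list(chosen = candidates[[best]], rule = "aicc_improvement",
                table = tab))
  }
  # simpler-model rule, with the significant-interaction exception
  has_sig_int <- vapply(candidates, function(f) {
    cc <- f$coefficients
    any(grepl(":", cc$term) & cc$p < p_threshold)
  }, logical(1))
  if (any(has_sig_int)) {
    idx <- which(has_sig_int)
    chosen <- idx[which.min(a[idx])]
    return(list(chosen = candidates[[chosen]],
                rule = "significant_interaction", table = tab))
  }
  list(chosen = candidates[[1]], rule = "simplest", table = tab)
}

#' Fit candidate GLMs of increasing interaction order and select one
#'
#' @inheritParams fit_glm
#' @param orders interaction orders to fit (default 1, 2, 3).
#' @param ... passed to [select_model()].
#' @return As [select_model()], with `candidates` attached.
#' @export
select_glm <- function(table, response,
                       terms = c("temperature", "np_ratio", "nitrate"),
                       family = gaussian(), orders = 1:3, ...) {
  fits <- lapply(orders, function(o)
    fit_glm(table, response, order = o, terms = terms, family = family))
  out <- select_model(fits, ...)
  out$candidates <- fits
  out
}

#' Univariate smoothing-spline additive model with GCV smoothing selection
#'
#' Penalized cubic regression spline of `y` on `x`, the smoothing parameter
#' chosen by generalized cross-validation. When `lambda_grid` is supplied
#' the fit is repeated at each fixed smoothing parameter and the
#' GCV-minimizing one is kept; otherwise the smoothing parameter is
#' optimized directly.
#'
#' @param x,y numeric vectors; `x` must have at least 4 distinct values and
#'   `length(y) >= basis_size`.
#' @param basis_size spline basis dimension (default 10).
#' @param lambda_grid optional vector of fixed smoothing parameters.
#' @return List of class `gam_fit` with `lambda`, `edf` (total, trace of
#'   the hat matrix), `edf_smooth`, `gcv`, `r2_adj`, `deviance_explained`,
#'   `intercept`, `intercept_se`, `p_smooth`, `partial_curve` (data.frame
#'   `x`, `s` of the centered smooth over the observed range) and the
#'   underlying mgcv fit.
#' @export
fit_gam_1d <- function(x, y, basis_size = 10, lambda_grid = NULL) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 4) {
    stop_invalid("`x` must have at least 4 distinct values")
  }
  # the basis cannot exceed the number of distinct covariate values
  basis_size <- min(basis_size, length(unique(x)))
  if (length(y) < basis_size) {
    stop_invalid("need at least `basis_size` observations")
  }
  dat <- data.frame(x = x, y = y)
  fit_at <- function(sp) {
    mgcv::gam(y ~ s(x, k = basis_size, bs = "cr"), data = dat,
              method = "GCV.Cp", sp = sp)
  }
  if (is.null(lambda_grid)) {
    fit <- fit_at(NULL)
  } else {
    fits <- lapply(lambda_grid, fit_at)
    gcvs <- vapply(fits, function(f) f$gcv.ubre, numeric(1))
    if (all(!is.finite(gcvs))) {
      stop_invalid("GCV non-finite over the whole lambda grid")
    }
    fit <- fits[[which.min(gcvs)]]
  }
  sm <- summary(fit)
  grid <- data.frame(x = seq(min(x), max(x), length.out = 200))
  s_curve <- as.numeric(predict(fit, newdata = grid, type = "terms"))
  structure(list(
    lambda = unname(fit$sp), edf = sum(fit$edf),
    edf_smooth = unname(sm$s.table[1, "edf"]),
    gcv = unname(fit$gcv.ubre), r2_adj = sm$r.sq,
    deviance_explained = sm$dev.expl,
    intercept = unname(sm$p.table[1, 1]),
    intercept_se = unname(sm$p.table[1, 2]),
    p_smooth = unname(sm$s.table[1, "p-value"]),
    partial_curve = data.frame(x = grid$x, s = s_curve),
    n = length(y), fit = fit
  ), class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf(
    "Smoothing-spline fit: edf(smooth) = %.3f, GCV = %.4g, r2(adj) = %.3f, deviance explained = %.1f%%\n",
    x$edf_smooth, x$gcv, x$r2_adj, 100 * x$deviance_explained))
  cat(sprintf("  intercept %.4g +/- %.3g, smooth p = %.3g, n = %d\n",
              x$intercept, x$intercept_se, x$p_smooth, x$n))
  invisible(x)
}

#' Amplitude of a fitted partial effect
#'
#' The difference between the fitted smooth at its strongest and weakest
#' effect over the observed range of the covariate (max minus min of the
#' centered partial curve); non-negative, and invariant to adding a
#' constant to the response.
#'
#' @param fit a `gam_fit` from [fit_gam_1d()].
#' @return The response amplitude.
#' @export
response_amplitude <- function(fit) {
  s <- fit$partial_curve$s
  if (!length(s)) stop_invalid("fit carries no partial curve")
  max(s) - min(s)
}

#' Ordinary least-squares regression
#'
#' @param x,y numeric vectors, `n >= 3`.
#' @return List of class `regression_fit` with `slope`, `intercept`, `r2`,
#'   `p` (two-sided, for the slope) and `n`. A response with zero variance
#'   yields slope 0, `r2` 0, `p` 1.
#' @export
ols_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop_insufficient("need n >= 3")
  if (var(x) == 0) stop_invalid("`x` has zero variance")
  if (var(y) == 0) {
    return(structure(list(slope = 0, intercept = mean(y), r2 = 0, p = 1,
                          n = n), class = "regression_fit"))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r2 = sm$r.squared, p = unname(sm$coefficients[2, 4]), n = n
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS: slope = %.4g, intercept = %.4g, r2 = %.3f, p = %.3g, n = %d\n",
              x$slope, x$intercept, x$r2, x$p, x$n))
  invisible(x)
}
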
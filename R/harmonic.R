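#' Harmonic design matrix
#'
#' Builds the regression design `[1, t - t0, cos(2*pi*k*t), sin(2*pi*k*t)
#' (k <= order), tide]`. Time is centered at `t0` (stored with fits) so the
#' intercept is the level at `t0` and the columns are well conditioned for
#' decimal-year inputs.
#'
#' @param time Decimal years.
#' @param tide Water-level heights, or `NULL` when the tide covariate is
#'   disabled.
#' @param order Number of annual harmonic pairs (1 = annual cycle).
#' @param t0 Centering time; defaults to `mean(time)`.
#' @return Numeric matrix with named columns; attribute `t0`.
#' @export
harmonic_design <- function(time, tide = NULL, order = 1, t0 = mean(time)) {
  X <- cbind(a0 = rep(1, length(time)), a1 = time - t0)
  for (k in seq_len(order)) {
    X <- cbind(X, cos(2 * pi * k * time), sin(2 * pi * k * time))
    colnames(X)[ncol(X) - 1:0] <- paste0(c("c", "s"), k)
  }
  if (!is.null(tide)) X <- cbind(X, c_tide = tide)
  attr(X, "t0") <- t0
  X
}

#' Fit a tide-aware harmonic model to one band
#'
#' Ordinary least squares of a band (or index) on the harmonic design. When
#' the tide covariate is enabled but constant over the fitted observations
#' (rank deficient), the tide column is dropped and the fit is annotated.
#'
#' @param series Observation data frame (`time`, band columns, `tide`).
#' @param band Column name of the response.
#' @param order Annual harmonic order.
#' @param tide_enabled Include the water-level covariate.
#' @param t0 Optional centering time.
#' @return Object of class `harmonic_fit`: `coef` (named), `rmse` (root mean
#'   squared residual), `sigma` (df-adjusted residual sd), `se` (coefficient
#'   standard errors), `n`, `order`, `tide_enabled`, `t0`, `tide_dropped`.
#' @export
fit_harmonic <- function(series, band, order = 1, tide_enabled = TRUE,
                         t0 = NULL) {
  y <- series[[band]]
  fit_harmonic_y(series$time, y, if (tide_enabled) series$tide else NULL,
                 order = order, t0 = t0)
}

# core single/multi-response OLS on the harmonic design; y vector or matrix
fit_harmonic_y <- function(time, y, tide = NULL, order = 1, t0 = NULL) {
  y <- as.matrix(y)
  tide_dropped <- FALSE
  if (!is.null(tide) && stats::sd(tide) < 1e-10) {
    tide <- NULL
    tide_dropped <- TRUE
  }
  X <- harmonic_design(time, tide, order = order, t0 = t0 %||% mean(time))
  n <- nrow(X); p <- ncol(X)
  if (n < p) stopf("need at least %d observations to fit %d coefficients", p, p)
  qrx <- qr(X)
  if (qrx$rank < p) stopf("rank-deficient harmonic design")
  coef <- qr.coef(qrx, y)
  res <- y - X %*% coef
  rmse <- sqrt(colMeans(res^2))
  sigma <- if (n > p) sqrt(colSums(res^2) / (n - p)) else rmse
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(outer(diag(xtx_inv), sigma^2))
  rownames(se) <- colnames(X)
  if (ncol(y) == 1) {
    structure(list(coef = stats::setNames(coef[, 1], colnames(X)),
                   rmse = unname(rmse), sigma = unname(sigma),
                   se = stats::setNames(se[, 1], colnames(X)),
                   n = n, order = order, tide_enabled = !is.null(tide),
                   tide_dropped = tide_dropped, t0 = attr(X, "t0")),
              class = "harmonic_fit")
  } else {
    structure(list(coef = coef, rmse = rmse, sigma = sigma, se = se,
                   xtx_inv = xtx_inv,
                   n = n, order = order, tide_enabled = !is.null(tide),
                   tide_dropped = tide_dropped, t0 = attr(X, "t0"),
                   colnames = colnames(X)),
              class = "harmonic_fit_multi")
  }
}

#' Predict from a harmonic fit
#'
#' Evaluates the design row at the requested times (and tide heights, if the
#' fit carries a tide coefficient) against the fitted coefficients.
#'
#' @param object A `harmonic_fit`.
#' @param time Decimal years.
#' @param tide Water-level heights (recycled); ignored when the fit has no
#'   tide term.
#' @param ... Unused.
#' @return Predicted band values.
#' @export
predict.harmonic_fit <- function(object, time, tide = 0, ...) {
  tide <- rep_len(tide, length(time))
  X <- harmonic_design(time, if (object$tide_enabled) tide else NULL,
                       order = object$order, t0 = object$t0)
  drop(X %*% object$coef)
}
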
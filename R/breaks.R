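#' Break-detection parameters
#'
#' Tuning knobs of the sequential spectral-break test. A break is declared
#' when `consecutive_required` consecutive observations have a multi-band
#' normalized residual score above the chi-square quantile
#' `qchisq(chisq_prob, df = length(detect_bands))`.
#'
#' @param detect_bands Bands screened for change (defaults to the
#'   vegetation/moisture-sensitive set: green, red, NIR, SWIR1, SWIR2).
#' @param consecutive_required Consecutive exceedances needed (>= 1).
#' @param chisq_prob Chi-square probability of the exceedance threshold.
#' @param min_obs_init Observations used to initialize each segment model.
#' @param tide_enabled Carry the water-level covariate in the fits.
#' @param order Annual harmonic order.
#' @param sigma_floor Lower bound on the residual sd used to normalize
#'   residuals (guards noiseless inputs).
#' @return A `break_params` list.
#' @export
break_params <- function(detect_bands = c("green", "red", "nir", "swir1", "swir2"),
                         consecutive_required = 6, chisq_prob = 0.99,
                         min_obs_init = 12, tide_enabled = TRUE, order = 1,
                         sigma_floor = 1e-4) {
  stopifnot(consecutive_required >= 1, chisq_prob > 0, chisq_prob < 1,
            min_obs_init >= 1)
  structure(list(detect_bands = detect_bands,
                 consecutive_required = consecutive_required,
                 chisq_prob = chisq_prob, min_obs_init = min_obs_init,
                 tide_enabled = tide_enabled, order = order,
                 sigma_floor = sigma_floor),
            class = "break_params")
}

#' Detect spectral breaks and segment a pixel's record
#'
#' Sequential change detection in the CCDC/COLD lineage, with the water-level
#' covariate in the per-band models so that inundation-driven reflectance
#' swings are explained rather than flagged. A model is initialized on the
#' first `min_obs_init` observations of each segment; each subsequent
#' observation is scored as `sum_b (residual_b / se_pred_b)^2` over the
#' detection bands, where `se_pred = sigma * sqrt(1 + leverage)` is the
#' prediction standard error; when
#' `consecutive_required` consecutive scores exceed the
#' chi-square quantile a break is declared at the first of them, the segment
#' is closed, and monitoring re-initializes at the break. The model is
#' refitted whenever the accepted span grows by a third. A trailing stretch
#' too short to initialize becomes an open segment flagged provisional.
#'
#' @param series Prepped observation data frame (clear, time-ordered, tide
#'   attached; see [composite_32day()] / [attach_tide()]).
#' @param params A [break_params()].
#' @return List of segments; each has `start`, `end` (decimal years),
#'   `first_idx`, `last_idx`, `n_obs`, `ended_by_break`, `break_time`
#'   (`NA` if none), `provisional`, and `fits` (multi-band `harmonic_fit` for
#'   the seven bands, `NULL` when too short to fit).
#' @export
detect_breaks <- function(series, params = break_params()) {
  n <- nrow(series)
  bands <- params$detect_bands
  thresh <- stats::qchisq(params$chisq_prob, df = length(bands))
  t0 <- if (n) mean(series$time) else 0
  tide <- if (params$tide_enabled) series$tide else NULL
  p_coef <- 2 + 2 * params$order + as.integer(params$tide_enabled)
  M <- as.matrix(series[band_names()])
  Yd <- M[, bands, drop = FALSE]
  segs <- list()
  close_segment <- function(i1, i2, ended, break_time, provisional) {
    fits <- NULL
    idx <- i1:i2
    if (length(idx) >= p_coef) {
      fits <- fit_harmonic_y(series$time[idx], M[idx, , drop = FALSE],
                             if (!is.null(tide)) tide[idx], order = params$order,
                             t0 = t0)
    }
    list(start = series$time[i1], end = series$time[i2],
         first_idx = i1, last_idx = i2, n_obs = length(idx),
         ended_by_break = ended, break_time = break_time,
         provisional = provisional, fits = fits)
  }
  if (n == 0) return(segs)

  i1 <- 1L
  while (i1 <= n) {
    remaining <- n - i1 + 1L
    if (remaining < max(params$min_obs_init, p_coef)) {
      segs[[length(segs) + 1L]] <- close_segment(i1, n, FALSE, NA_real_, TRUE)
      break
    }
    i2 <- i1 + params$min_obs_init - 1L
    idx <- i1:i2
    fit <- fit_harmonic_y(series$time[idx], Yd[idx, , drop = FALSE],
                          if (!is.null(tide)) tide[idx],
                          order = params$order, t0 = t0)
    n_fit <- length(idx)
    sig <- pmax(fit$sigma, params$sigma_floor)
    X <- harmonic_design(series$time, if (fit$tide_enabled) tide,
                         order = params$order, t0 = t0)
    run <- 0L; run_start <- NA_integer_; broke <- FALSE
    j <- i2 + 1L
    while (j <= n) {
      r <- Yd[j, ] - drop(X[j, ] %*% fit$coef)
      # prediction-interval normalization: leverage tames early extrapolation
      h <- drop(X[j, ] %*% fit$xtx_inv %*% X[j, ])
      score <- sum((r / (sig * sqrt(1 + h)))^2)
      if (score > thresh) {
        run <- run + 1L
        if (run == 1L) run_start <- j
        if (run >= params$consecutive_required) { broke <- TRUE; break }
      } else {
        run <- 0L; run_start <- NA_integer_
        i2 <- j
        if ((i2 - i1 + 1L) >= ceiling(4 / 3 * n_fit)) {
          idx <- i1:i2
          fit <- fit_harmonic_y(series$time[idx], Yd[idx, , drop = FALSE],
                                if (!is.null(tide)) tide[idx],
                                order = params$order, t0 = t0)
          n_fit <- length(idx)
          sig <- pmax(fit$sigma, params$sigma_floor)
          X <- harmonic_design(series$time, if (fit$tide_enabled) tide,
                               order = params$order, t0 = t0)
        }
      }
      j <- j + 1L
    }
    if (broke) {
      segs[[length(segs) + 1L]] <-
        close_segment(i1, run_start - 1L, TRUE, series$time[run_start], FALSE)
      i1 <- run_start
    } else {
      segs[[length(segs) + 1L]] <- close_segment(i1, n, FALSE, NA_real_, FALSE)
      break
    }
  }
  segs
}
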
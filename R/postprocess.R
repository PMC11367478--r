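#' Polynomial detrending of node time courses
#'
#' Removes, per node, the least-squares fit of a polynomial in time up to the
#' given degree (order 3 removes linear, quadratic and cubic trends along with
#' the mean). Residuals are orthogonal to the polynomial basis.
#'
#' @param tc a \code{\link{timecourse_set}}.
#' @param order polynomial degree >= 0 (0 removes only the mean).
#' @return a \code{timecourse_set} of identical shape.
#' @examples
#' tc <- timecourse_set(cbind(a = 1:20 + rnorm(20), b = rnorm(20)), TR = 2,
#'                      membership = c(a = "DMN", b = "SAN"))
#' out <- detrend_polynomial(tc, 3)
#' @export
detrend_polynomial <- function(tc, order = 3L) {
  stopifnot(inherits(tc, "timecourse_set"))
  if (!is_count(order, min = 0L)) stopf("'order' must be an integer >= 0")
  T_len <- nrow(tc$data)
  if (T_len <= order + 1L) {
    stopf("need more than order + 1 = %d time points, got %d", order + 1L, T_len)
  }
  x <- if (order == 0L) {
    matrix(1, T_len, 1L)
  } else {
    cbind(1, stats::poly(seq_len(T_len), degree = order))
  }
  res <- stats::lm.fit(x, tc$data)$residuals
  replace_data(tc, as.matrix(res))
}

#' Nuisance regression with temporal derivatives
#'
#' Regresses an intercept plus the nuisance regressors (e.g. six realignment
#' parameters) — and, by default, their temporal derivatives — out of every
#' node time course. The temporal derivative is the backward first difference
#' with the first sample set to 0.
#'
#' @param tc a \code{\link{timecourse_set}}.
#' @param regressors T x M numeric matrix of nuisance time series.
#' @param include_derivatives append backward first differences of each
#'   regressor (default TRUE).
#' @return a \code{timecourse_set} of identical shape whose columns are
#'   orthogonal to the expanded regressor set.
#' @export
regress_nuisance <- function(tc, regressors, include_derivatives = TRUE) {
  stopifnot(inherits(tc, "timecourse_set"))
  regressors <- as.matrix(regressors)
  T_len <- nrow(tc$data)
  if (nrow(regressors) != T_len) {
    stopf("regressors have %d rows but time courses have %d", nrow(regressors), T_len)
  }
  if (is.null(colnames(regressors))) {
    colnames(regressors) <- paste0("reg", seq_len(ncol(regressors)))
  }
  x <- regressors
  if (isTRUE(include_derivatives)) {
    d <- apply(regressors, 2L, function(col) c(0, diff(col)))
    colnames(d) <- paste0(colnames(regressors), "_deriv")
    x <- cbind(x, d)
  }
  design <- cbind(intercept = 1, x)
  qrx <- qr(design)
  if (qrx$rank < ncol(design)) {
    bad <- colnames(design)[qrx$pivot[(qrx$rank + 1L):ncol(design)]]
    stopf("nuisance design is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  res <- stats::lm.fit(design, tc$data)$residuals
  replace_data(tc, as.matrix(res))
}

#' Zero-phase low-pass filtering
#'
#' Applies a 5th-order Butterworth low-pass filter forward and backward
#' (\code{signal::filtfilt}), giving zero phase distortion, to every node
#' time course.
#'
#' @param tc a \code{\link{timecourse_set}} (its \code{TR} sets the sampling
#'   rate).
#' @param cutoff_hz cutoff frequency in Hz; must be below the Nyquist
#'   frequency \code{1 / (2 * TR)}.
#' @return a \code{timecourse_set} of identical shape.
#' @examples
#' tc <- timecourse_set(cbind(a = rnorm(100), b = rnorm(100)), TR = 2,
#'                      membership = c(a = "DMN", b = "SAN"))
#' out <- lowpass_filter(tc, 0.15)
#' @export
lowpass_filter <- function(tc, cutoff_hz = 0.15) {
  stopifnot(inherits(tc, "timecourse_set"))
  nyquist <- 1 / (2 * tc$TR)
  if (!is_number(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyquist) {
    stopf("cutoff (%g Hz) must lie in (0, Nyquist = %g Hz)", cutoff_hz, nyquist)
  }
  w_norm <- cutoff_hz / nyquist
  bf <- signal::butter(5, w_norm, type = "low")
  T_len <- nrow(tc$data)
  # odd-reflection padding absorbs the zero-initial-condition transients of
  # the forward-backward pass, so even a constant series is preserved
  pad <- min(T_len - 1L, max(60L, ceiling(24 / w_norm)))
  filtered <- apply(tc$data, 2L, function(col) {
    ext <- c(2 * col[1L] - col[(pad + 1L):2L],
             col,
             2 * col[T_len] - col[(T_len - 1L):(T_len - pad)])
    signal::filtfilt(bf, ext)[(pad + 1L):(pad + T_len)]
  })
  replace_data(tc, as.matrix(filtered))
}

#' Spike removal by robust detection and interpolation
#'
#' Flags, per node, samples whose deviation from the column median exceeds
#' \code{z_thresh} robust standard deviations (1.4826 x the median absolute
#' deviation) and replaces them by linear interpolation between the nearest
#' non-spike neighbours; spikes at the series edges take the nearest
#' non-spike value. Non-spike samples are returned unchanged, so the
#' operation is idempotent on clean data.
#'
#' @param tc a \code{\link{timecourse_set}} with at least 5 time points.
#' @param z_thresh robust z threshold (default 3).
#' @return a \code{timecourse_set} of identical shape.
#' @export
despike <- function(tc, z_thresh = 3) {
  stopifnot(inherits(tc, "timecourse_set"))
  if (nrow(tc$data) < 5L) stopf("despiking needs at least 5 time points")
  if (!is_number(z_thresh) || z_thresh <= 0) stopf("'z_thresh' must be > 0")
  out <- tc$data
  for (j in seq_len(ncol(out))) {
    x <- out[, j]
    med <- stats::median(x)
    robust_sd <- stats::mad(x, constant = 1.4826)
    if (robust_sd == 0) next  # flat or half-constant column: nothing detectable
    spike <- abs(x - med) > z_thresh * robust_sd
    if (!any(spike)) next
    if (mean(spike) > 0.5) {
      stopf("node '%s': more than 50%% of samples flagged as spikes; signal unusable",
            colnames(out)[j])
    }
    good <- which(!spike)
    x[spike] <- stats::approx(good, x[good], xout = which(spike), rule = 2)$y
    out[, j] <- x
  }
  replace_data(tc, out)
}

#' Full time-course post-processing pipeline
#'
#' Applies the four post-processing stages in fixed order: polynomial
#' detrending, nuisance regression (skipped when no regressors are given),
#' zero-phase low-pass filtering, then despiking.
#'
#' @param tc a \code{\link{timecourse_set}}.
#' @param nuisance optional T x M regressor matrix for
#'   \code{\link{regress_nuisance}}.
#' @param detrend_order polynomial degree for detrending (default 3).
#' @param cutoff_hz low-pass cutoff in Hz (default 0.15).
#' @param z_thresh despiking threshold (default 3).
#' @param include_derivatives passed to \code{\link{regress_nuisance}}.
#' @return the post-processed \code{timecourse_set}, same shape as the input.
#' @export
postprocess_timecourses <- function(tc, nuisance = NULL, detrend_order = 3L,
                                    cutoff_hz = 0.15, z_thresh = 3,
                                    include_derivatives = TRUE) {
  out <- detrend_polynomial(tc, detrend_order)
  if (!is.null(nuisance)) {
    out <- regress_nuisance(out, nuisance, include_derivatives = include_derivatives)
  }
  out <- lowpass_filter(out, cutoff_hz)
  despike(out, z_thresh)
}
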
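#' Fisher r-to-z transform
#'
#' \code{atanh} of a correlation, after clipping values with magnitude at or
#' above \code{1 - 1e-7} to that bound so perfect correlations stay finite.
#'
#' @param r numeric vector of correlations in [-1, 1].
#' @return numeric vector of z values.
#' @examples
#' fisher_z(c(0, 0.5, -0.5))
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r))) stopf("'r' must be finite numeric")
  clip <- 1 - 1e-7
  atanh(pmin(pmax(r, -clip), clip))
}

#' Static functional network connectivity
#'
#' Pairwise Pearson correlation between node time courses over the full
#' scan, Fisher r-to-z transformed. The diagonal is set to 0 by convention.
#'
#' @param tc a \code{\link{timecourse_set}} (post-processed), T >= 3.
#' @return N x N symmetric numeric matrix of z values with zero diagonal and
#'   node labels as dimnames.
#' @examples
#' tcs <- simulate_timecourses(1, T_len = 100, TR = 2,
#'   states = make_state_covariances(7, triple_network_membership()), seed = 1)
#' z <- compute_sfnc(tcs[[1]])
#' @export
compute_sfnc <- function(tc) {
  stopifnot(inherits(tc, "timecourse_set"))
  if (nrow(tc$data) < 3L) stopf("need at least 3 time points for correlation")
  sds <- apply(tc$data, 2L, stats::sd)
  if (any(sds == 0)) {
    stopf("zero-variance node(s): %s", paste(colnames(tc$data)[sds == 0], collapse = ", "))
  }
  z <- fisher_z(stats::cor(tc$data))
  diag(z) <- 0
  z
}

#' Tapered sliding-window weights
#'
#' The window taper: a rectangle of the window length convolved with a
#' discrete Gaussian kernel (standard deviation \code{sigma} TRs, truncated
#' at +/- 4 sigma), cut back to the window length and normalized to sum 1.
#' As \code{sigma} tends to 0 the taper tends to the uniform window.
#'
#' @param window_length window length in TRs (>= 2).
#' @param sigma Gaussian standard deviation in TRs (> 0).
#' @return numeric weight vector of length \code{window_length}: symmetric,
#'   strictly positive, summing to 1.
#' @examples
#' w <- make_taper(22, 3)
#' plot(w, type = "h")
#' @export
make_taper <- function(window_length, sigma = 3) {
  if (!is_count(window_length, min = 2L)) stopf("'window_length' must be an integer >= 2")
  if (!is_number(sigma) || sigma <= 0) stopf("'sigma' must be > 0")
  radius <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(seq(-radius, radius), sd = sigma)
  kern <- kern / sum(kern)
  rect <- rep(1, window_length)
  full <- stats::convolve(rect, rev(kern), type = "open")  # length L + 2*radius
  taper <- full[(radius + 1L):(radius + window_length)]    # central L samples
  taper <- (taper + rev(taper)) / 2   # enforce exact symmetry against fft roundoff
  taper / sum(taper)
}

# Taper-weighted Pearson correlation of the columns of x (weights sum to 1).
weighted_correlation <- function(x, w) {
  mu <- colSums(w * x)
  xc <- sweep(x, 2L, mu)
  cv <- crossprod(xc, w * xc)
  d <- sqrt(diag(cv))
  if (any(d == 0)) stopf("zero weighted variance inside a window")
  cv / tcrossprod(d)
}

#' Tapered sliding-window dynamic connectivity
#'
#' Slides a tapered window along the time courses and computes, per window,
#' the taper-weighted Pearson correlation matrix between all node pairs,
#' Fisher r-to-z transformed. Windows start at offsets 0, step, 2*step, ...,
#' giving \code{floor((T - window_length) / step) + 1} windows.
#'
#' @param tc a \code{\link{timecourse_set}}.
#' @param window_length window length in TRs (default 22).
#' @param step window step in TRs (default 1).
#' @param sigma taper Gaussian standard deviation in TRs (default 3).
#' @return object of class \code{windowed_connectivity}: list with
#'   \code{layers} (N x N x W array of z matrices, zero diagonal),
#'   \code{window_length}, \code{step}, \code{sigma}, \code{taper},
#'   \code{node_labels}, \code{membership}, \code{subject_id}.
#' @examples
#' tcs <- simulate_timecourses(1, T_len = 169, TR = 2,
#'   states = make_state_covariances(7, triple_network_membership()), seed = 1)
#' wc <- sliding_window_connectivity(tcs[[1]])
#' wc$layers |> dim()   # 7 x 7 x 148
#' @export
sliding_window_connectivity <- function(tc, window_length = 22L, step = 1L,
                                        sigma = 3) {
  stopifnot(inherits(tc, "timecourse_set"))
  T_len <- nrow(tc$data)
  if (T_len < window_length) {
    stopf("time course length %d is shorter than the window length %d",
          T_len, window_length)
  }
  if (!is_count(step)) stopf("'step' must be a positive integer")
  taper <- make_taper(window_length, sigma)
  n_windows <- floor((T_len - window_length) / step) + 1L
  n <- ncol(tc$data)
  layers <- array(0, dim = c(n, n, n_windows),
                  dimnames = list(tc$node_labels, tc$node_labels, NULL))
  for (w in seq_len(n_windows)) {
    start <- (w - 1L) * step + 1L
    seg <- tc$data[start:(start + window_length - 1L), , drop = FALSE]
    z <- fisher_z(weighted_correlation(seg, taper))
    diag(z) <- 0
    layers[, , w] <- z
  }
  structure(list(layers = layers, window_length = as.integer(window_length),
                 step = as.integer(step), sigma = sigma, taper = taper,
                 node_labels = tc$node_labels, membership = tc$membership,
                 subject_id = tc$subject_id),
            class = "windowed_connectivity")
}

#' @export
print.windowed_connectivity <- function(x, ...) {
  cat(sprintf(
    "<windowed_connectivity> subject '%s': %d windows of %d TRs (step %d, sigma %g), %d nodes\n",
    x$subject_id, dim(x$layers)[3L], x$window_length, x$step, x$sigma,
    dim(x$layers)[1L]))
  invisible(x)
}

#' Vectorize windowed connectivity for clustering
#'
#' @param wc a \code{windowed_connectivity} object.
#' @return W x N(N-1)/2 matrix; each row is the upper triangle of one
#'   window's z matrix, columns named by node pair.
#' @export
window_vectors <- function(wc) {
  stopifnot(inherits(wc, "windowed_connectivity"))
  n_windows <- dim(wc$layers)[3L]
  ut <- upper.tri(wc$layers[, , 1L])
  out <- t(apply(wc$layers, 3L, function(m) m[ut]))
  colnames(out) <- edge_labels(wc$node_labels)
  out
}
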
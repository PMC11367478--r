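# Greedy k-means++ initialization: candidates are drawn from the squared-
# distance distribution and the one minimizing the total potential is kept.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  n_cand <- 2L + floor(log(max(k, 2L)))
  centers <- matrix(0, k, ncol(x))
  first <- sample.int(n, 1L)
  centers[1L, ] <- x[first, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  if (k == 1L) return(centers)
  for (j in 2L:k) {
    if (all(d2 == 0)) {
      cand <- sample.int(n, 1L)
      centers[j, ] <- x[cand, ]
      next
    }
    cands <- sample.int(n, min(n_cand, n), prob = pmax(d2, 0), replace = TRUE)
    best_pot <- Inf
    best_d2 <- d2
    for (cnd in cands) {
      d2_new <- pmin(d2, rowSums(sweep(x, 2L, x[cnd, ])^2))
      pot <- sum(d2_new)
      if (pot < best_pot) {
        best_pot <- pot
        best_d2 <- d2_new
        centers[j, ] <- x[cnd, ]
      }
    }
    d2 <- best_d2
  }
  centers
}

# Pool window vectors from a list of windowed_connectivity objects, keeping
# track of which rows belong to which subject.
pool_windows <- function(windows) {
  if (is.matrix(windows)) {
    return(list(x = windows, subject = rep("all", nrow(windows)),
                ids = "all", per_subject = FALSE))
  }
  if (inherits(windows, "windowed_connectivity")) windows <- list(windows)
  mats <- lapply(windows, window_vectors)
  ids <- vapply(windows, function(w) w$subject_id, character(1L))
  list(x = do.call(rbind, mats),
       subject = rep(ids, vapply(mats, nrow, integer(1L))),
       ids = ids, per_subject = TRUE)
}

#' Cluster windowed connectivity into recurring states
#'
#' K-means with squared Euclidean distance on vectorized window
#' connectivity: each replicate starts from a greedy k-means++
#' initialization and runs Lloyd iterations; the replicate with the lowest
#' total within-cluster sum of squares is kept. Deterministic given
#' \code{seed}. When a list of per-subject windowed connectivity objects is
#' given, windows are pooled across subjects for clustering and the
#' assignments are split back per subject.
#'
#' @param windows either a numeric matrix (rows = windows, columns =
#'   vectorized upper-triangle edges) or a (list of)
#'   \code{windowed_connectivity} object(s).
#' @param k number of states.
#' @param max_iter maximum Lloyd iterations per replicate (default 500).
#' @param n_replicates number of restarts (default 150).
#' @param seed integer seed.
#' @return object of class \code{state_model}: list with \code{k},
#'   \code{centroids} (k x D), \code{assignments} (integer vector, or named
#'   list per subject), \code{inertia}, \code{sizes}.
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 5), 20))
#' m <- cluster_states(x, k = 2, n_replicates = 5, seed = 1)
#' m$sizes
#' @export
cluster_states <- function(windows, k, max_iter = 500L, n_replicates = 150L,
                           seed = 1L) {
  pooled <- pool_windows(windows)
  x <- pooled$x
  if (!is_count(k)) stopf("'k' must be a positive integer")
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stopf("k = %d exceeds the number of distinct windows (%d)", k, n_distinct)
  }
  best <- NULL
  for (rep_i in seq_len(n_replicates)) {
    fit <- with_seed(derive_seed(seed, rep_i), {
      init <- kmeanspp_init(x, k)
      suppressWarnings(stats::kmeans(x, centers = init, iter.max = max_iter,
                                     algorithm = "Lloyd"))
    })
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  assignments <- as.integer(best$cluster)
  if (pooled$per_subject) {
    assignments <- split(assignments, factor(pooled$subject, levels = pooled$ids))
  }
  structure(list(k = as.integer(k), centroids = best$centers,
                 assignments = assignments, inertia = best$tot.withinss,
                 sizes = as.integer(best$size)),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d states, inertia = %.4g\n", x$k, x$inertia))
  cat("  windows per state:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.state_model <- function(object, ...) {
  total <- sum(object$sizes)
  cat(sprintf("State model with %d states over %d windows\n", object$k, total))
  frac <- object$sizes / total
  for (s in seq_len(object$k)) {
    cat(sprintf("  state %d: %5d windows (%.1f%%)\n", s, object$sizes[s], 100 * frac[s]))
  }
  invisible(object)
}

#' Plot state centroids as connectivity matrices
#'
#' @param x a \code{state_model} whose centroid vectors are upper triangles
#'   of N x N matrices.
#' @param node_labels optional node labels (length N).
#' @param ... passed to \code{graphics::image}.
#' @export
plot.state_model <- function(x, node_labels = NULL, ...) {
  d <- ncol(x$centroids)
  n <- (1 + sqrt(1 + 8 * d)) / 2
  if (n != round(n)) stopf("centroid length %d is not an upper-triangle size", d)
  old <- graphics::par(mfrow = c(1, x$k), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(old))
  lim <- max(abs(x$centroids))
  for (s in seq_len(x$k)) {
    m <- unvec_upper(x$centroids[s, ], n, diag_value = NA, labels = node_labels)
    graphics::image(seq_len(n), seq_len(n), t(m[n:1, ]), zlim = c(-lim, lim),
                    col = grDevices::hcl.colors(51, "Blue-Red 3"),
                    axes = FALSE, xlab = "", ylab = "",
                    main = sprintf("state %d", s), ...)
  }
  invisible(x)
}

#' Elbow selection rule on a cluster-quality ratio curve
#'
#' Given the within/between distance ratio R(k) over a k grid, selects the
#' k maximizing the discrete curvature
#' \code{R(k-1) - 2 R(k) + R(k+1)} — the sharpest bend of the curve. At the
#' two endpoints of the grid the missing neighbour is treated as continuing
#' the curve flat, which reduces the curvature to the one-sided difference
#' (so the smallest candidate wins when the curve only rises after it).
#'
#' @param k_values integer grid of k values (consecutive).
#' @param ratios R(k) values, same length.
#' @return selected k (integer).
#' @examples
#' elbow_from_curve(2:5, c(1.0, 0.4, 0.35, 0.33))  # -> 3
#' @export
elbow_from_curve <- function(k_values, ratios) {
  stopifnot(length(k_values) == length(ratios), length(ratios) >= 3L)
  ext <- c(ratios[1L], ratios, ratios[length(ratios)])
  idx <- seq_along(ratios) + 1L
  curvature <- ext[idx - 1L] - 2 * ext[idx] + ext[idx + 1L]
  as.integer(k_values[which.max(curvature)])
}

#' Select the number of states by the elbow criterion
#'
#' For each candidate k, clusters the pooled windows and computes the ratio
#' R(k) between the mean distance of windows to their assigned centroid and
#' the mean pairwise distance between centroids; the selected k maximizes
#' the discrete curvature of the R(k) curve (\code{\link{elbow_from_curve}}).
#'
#' @param windows pooled window matrix or (list of)
#'   \code{windowed_connectivity}.
#' @param k_range candidate k values (default 2:10, consecutive).
#' @param n_replicates k-means restarts per candidate (default 20).
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap per replicate.
#' @return list of class \code{elbow_selection}: \code{k} (selected),
#'   \code{k_range}, \code{ratio} (R(k) curve), \code{models} omitted for
#'   size; plus \code{curvature}.
#' @export
select_k_elbow <- function(windows, k_range = 2:10, n_replicates = 20L,
                           seed = 1L, max_iter = 500L) {
  pooled <- pool_windows(windows)
  x <- pooled$x
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L) stopf("'k_range' needs at least 3 candidate values")
  n_distinct <- nrow(unique(x))
  ratios <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k > n_distinct) {
      warnf("skipping k = %d: only %d distinct windows", k, n_distinct)
      next
    }
    sm <- cluster_states(x, k, max_iter = max_iter, n_replicates = n_replicates,
                         seed = derive_seed(seed, 100L + k))
    d_within <- sqrt(rowSums((x - sm$centroids[sm$assignments, , drop = FALSE])^2))
    d_between <- stats::dist(sm$centroids)
    ratios[i] <- mean(d_within) / mean(d_between)
  }
  keep <- !is.na(ratios)
  sel <- elbow_from_curve(k_range[keep], ratios[keep])
  rr <- ratios[keep]
  ext <- c(rr[1L], rr, rr[length(rr)])
  idx <- seq_along(rr) + 1L
  curvature <- ext[idx - 1L] - 2 * ext[idx] + ext[idx + 1L]
  structure(list(k = sel, k_range = k_range, ratio = ratios,
                 curvature = stats::setNames(curvature, k_range[keep])),
            class = "elbow_selection")
}

#' @export
print.elbow_selection <- function(x, ...) {
  cat(sprintf("<elbow_selection> selected k = %d\n", x$k))
  cat("  k:     ", paste(format(x$k_range), collapse = " "), "\n")
  cat("  R(k):  ", paste(format(round(x$ratio, 3)), collapse = " "), "\n")
  invisible(x)
}

#' Temporal statistics of a state sequence
#'
#' Computes, for a window-to-state assignment sequence, the reoccurrence
#' fraction (RF: fraction of windows spent in each state), the mean dwell
#' time (DT: mean length of maximal runs of each state, in windows; 0 for
#' unvisited states) and the total number of transitions (TTN: count of
#' adjacent window pairs with different states).
#'
#' @param assignments integer state sequence with labels in 1..k.
#' @param k number of states.
#' @param TR optional repetition time in seconds; when given, dwell times in
#'   seconds are also returned (\code{DT_seconds = DT * TR}).
#' @return list of class \code{temporal_properties}: \code{RF} (sums to 1),
#'   \code{DT}, \code{TTN}, and optionally \code{DT_seconds}.
#' @examples
#' temporal_properties(c(1, 1, 1, 2, 1, 1), k = 2)
#' @export
temporal_properties <- function(assignments, k, TR = NULL) {
  if (!length(assignments)) stopf("'assignments' must be a nonempty sequence")
  assignments <- as.integer(assignments)
  if (!is_count(k)) stopf("'k' must be a positive integer")
  if (any(assignments < 1L | assignments > k)) {
    stopf("state label outside 1..%d found", k)
  }
  n_windows <- length(assignments)
  rf <- tabulate(assignments, nbins = k) / n_windows
  runs <- rle(assignments)
  dt <- vapply(seq_len(k), function(s) {
    len <- runs$lengths[runs$values == s]
    if (length(len)) mean(len) else 0
  }, numeric(1L))
  ttn <- length(runs$lengths) - 1L
  out <- list(RF = rf, DT = dt, TTN = as.integer(ttn))
  if (!is.null(TR)) out$DT_seconds <- dt * TR
  structure(out, class = "temporal_properties")
}

#' @export
print.temporal_properties <- function(x, ...) {
  cat("<temporal_properties>\n")
  cat("  RF: ", paste(sprintf("%.3f", x$RF), collapse = " "), "\n")
  cat("  DT: ", paste(sprintf("%.2f", x$DT), collapse = " "), "(windows)\n")
  cat("  TTN:", x$TTN, "\n")
  invisible(x)
}
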
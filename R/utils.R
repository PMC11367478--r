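#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so seeded package functions do not perturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed; keeps values well inside 32-bit range.
derive_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(index) * 7L
}

#' Vectorize the upper triangle of a square matrix
#'
#' @param m square matrix.
#' @return numeric vector of the strictly-upper-triangular entries, in
#'   column-major order; names are "row-col" node-label pairs when
#'   \code{m} has dimnames.
#' @keywords internal
#' @noRd
upper_vec <- function(m) {
  v <- m[upper.tri(m)]
  if (!is.null(rownames(m))) {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    names(v) <- paste(rownames(m)[idx[, 1L]], colnames(m)[idx[, 2L]], sep = "-")
  }
  v
}

# Inverse of upper_vec for an n x n symmetric matrix with given diagonal.
unvec_upper <- function(v, n, diag_value = 0, labels = NULL) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

# Edge labels for the upper triangle of an N-node matrix.
edge_labels <- function(labels) {
  n <- length(labels)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  paste(labels[idx[, 1L]], labels[idx[, 2L]], sep = "-")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
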
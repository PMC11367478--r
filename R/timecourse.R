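#' Node time-course container
#'
#' Bundles a subject's node (independent-component) time courses with the
#' repetition time and the node-to-network membership map used throughout
#' the pipeline.
#'
#' @param data numeric T x N matrix, one column per node, one row per time
#'   point. Column names are taken as node labels when present.
#' @param TR repetition time in seconds (sampling interval).
#' @param membership named character vector mapping every node label to a
#'   network label (e.g. DMN / ECN / SAN).
#' @param subject_id subject identifier string.
#' @return An object of class \code{timecourse_set}: a list with elements
#'   \code{data}, \code{TR}, \code{node_labels}, \code{membership},
#'   \code{subject_id}.
#' @examples
#' tc <- timecourse_set(matrix(rnorm(40), 20, 2,
#'                             dimnames = list(NULL, c("PCC", "MPFC"))),
#'                      TR = 2, membership = c(PCC = "DMN", MPFC = "DMN"))
#' print(tc)
#' @export
timecourse_set <- function(data, TR, membership, subject_id = "subject") {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 2L) {
    stopf("'data' must be a numeric matrix with at least 2 time points")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stopf("time courses contain missing or non-finite values")
  }
  if (!is_number(TR) || TR <= 0) stopf("'TR' must be a positive number (seconds)")
  if (is.null(colnames(data))) {
    colnames(data) <- paste0("node", seq_len(ncol(data)))
  }
  labels <- colnames(data)
  if (is.null(names(membership)) || !all(labels %in% names(membership))) {
    missing_nodes <- if (is.null(names(membership))) labels else setdiff(labels, names(membership))
    stopf("membership map does not cover node(s): %s",
          paste(missing_nodes, collapse = ", "))
  }
  structure(
    list(data = data, TR = TR, node_labels = labels,
         membership = membership[labels], subject_id = as.character(subject_id)),
    class = "timecourse_set"
  )
}

#' @export
print.timecourse_set <- function(x, ...) {
  cat(sprintf("<timecourse_set> subject '%s': %d time points x %d nodes, TR = %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$TR))
  nets <- split(x$node_labels, x$membership[x$node_labels])
  for (nm in names(nets)) {
    cat(sprintf("  %s: %s\n", nm, paste(nets[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.timecourse_set <- function(x) dim(x$data)

# Replace the data matrix, preserving metadata; internal helper used by the
# post-processing stages (which must preserve shape).
replace_data <- function(tc, new_data) {
  stopifnot(all(dim(new_data) == dim(tc$data)))
  dimnames(new_data) <- dimnames(tc$data)
  tc$data <- new_data
  tc
}

#' Default triple-network node membership
#'
#' The seven-node layout used as the package default: three default-mode
#' nodes (PCC, MPFC, IPL), left/right executive-control nodes (LECN, RECN)
#' and two salience nodes (insula, dACC).
#'
#' @return named character vector mapping node labels to network labels.
#' @examples
#' triple_network_membership()
#' @export
triple_network_membership <- function() {
  c(PCC = "DMN", MPFC = "DMN", IPL = "DMN",
    LECN = "ECN", RECN = "ECN",
    insula = "SAN", dACC = "SAN")
}
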
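# --- plain-text I/O: time courses and cohort tables as CSV, ground truth
# --- and provenance as JSON sidecars.

#' Write time courses to CSV files
#'
#' One comma-separated file per subject (\code{<subject_id>.csv}, header row
#' of node labels, one row per time point), plus a JSON sidecar
#' (\code{ground_truth.json}) recording TR, the membership map and — when
#' present — each subject's ground-truth state sequence.
#'
#' @param tcs list of \code{\link{timecourse_set}} objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_timecourses <- function(tcs, dir) {
  if (inherits(tcs, "timecourse_set")) tcs <- list(tcs)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(tcs, function(tc) {
    path <- file.path(dir, paste0(tc$subject_id, ".csv"))
    utils::write.csv(as.data.frame(tc$data), path, row.names = FALSE)
    path
  }, character(1L))
  sidecar <- list(
    TR = tcs[[1L]]$TR,
    membership = as.list(tcs[[1L]]$membership),
    state_sequences = stats::setNames(
      lapply(tcs, function(tc) attr(tc, "state_sequence")),
      vapply(tcs, function(tc) tc$subject_id, character(1L)))
  )
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(c(paths, file.path(dir, "ground_truth.json")))
}

#' Read time courses from CSV files
#'
#' @param dir directory holding per-subject CSV files as written by
#'   \code{\link{write_timecourses}}; TR and membership are taken from the
#'   sidecar unless supplied.
#' @param TR,membership override the sidecar values.
#' @return list of \code{\link{timecourse_set}} objects.
#' @export
read_timecourses <- function(dir, TR = NULL, membership = NULL) {
  sidecar_path <- file.path(dir, "ground_truth.json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (is.null(TR)) TR <- sc$TR
    if (is.null(membership)) membership <- unlist(sc$membership)
  }
  if (is.null(TR) || is.null(membership)) {
    stopf("no sidecar found in '%s': supply TR and membership", dir)
  }
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "cohort.csv"]  # cohort table is not a subject
  lapply(files, function(f) {
    x <- as.matrix(utils::read.csv(f, check.names = FALSE))
    timecourse_set(x, TR = TR, membership = membership,
                   subject_id = sub("\\.csv$", "", basename(f)))
  })
}

#' Write / read a cohort table
#'
#' The cohort table is one comma-separated file: one row per subject with
#' columns \code{subject_id}, \code{group}, the covariates, derived measures
#' and behavior scores.
#'
#' @param cohort data.frame as produced by \code{\link{simulate_cohort}}.
#' @param path CSV file path.
#' @return \code{write_cohort}: invisibly, the path. \code{read_cohort}: the
#'   data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a node-to-network membership map
#'
#' Two-column comma-separated text (\code{node,network}), no header needed
#' (a \code{node,network} header row is tolerated).
#'
#' @param path file path.
#' @return named character vector node -> network.
#' @export
read_membership <- function(path) {
  x <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (tolower(x[1L, 1L]) == "node") x <- x[-1L, , drop = FALSE]
  stats::setNames(as.character(x[[2L]]), as.character(x[[1L]]))
}
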
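#' Construct a single imaging run
#'
#' A run record bundles one run's ROI-by-time signal matrix with its place in
#' the experimental hierarchy (animal, session, run), the acquisition
#' condition, the sampling rate, and an optional per-frame head-motion trace
#' used for frame censoring.
#'
#' @param signal Numeric matrix, regions (rows) by time points (columns).
#' @param fs Sampling rate in Hz.
#' @param animal_id,session_id,run_id Identifiers placing the run in the
#'   animal -> session -> run hierarchy.
#' @param condition Acquisition condition label, one of `"bold"`, `"ca_slow"`,
#'   `"ca_fast"`.
#' @param motion Optional numeric vector of per-frame framewise displacement
#'   (mm); must match the number of time points.
#' @return An object of class `"run_record"`.
#' @examples
#' r <- run_record(matrix(rnorm(40), 4, 10), fs = 1)
#' r
#' @export
run_record <- function(signal, fs, animal_id = "a01", session_id = "s01",
                       run_id = "r01", condition = c("bold", "ca_slow", "ca_fast"),
                       motion = NULL) {
  condition <- match.arg(condition)
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("signal must be a numeric ROI x time matrix", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive sampling rate in Hz", call. = FALSE)
  }
  if (!is.null(motion) && length(motion) != ncol(signal)) {
    stop("motion trace length must equal the number of time points", call. = FALSE)
  }
  structure(
    list(signal = signal, fs = fs, animal_id = animal_id,
         session_id = session_id, run_id = run_id, condition = condition,
         motion = motion),
    class = "run_record"
  )
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> %s/%s/%s [%s] %d ROIs x %d frames @ %g Hz%s\n",
              x$animal_id, x$session_id, x$run_id, x$condition,
              nrow(x$signal), ncol(x$signal), x$fs,
              if (is.null(x$motion)) "" else ", motion trace"))
  invisible(x)
}

#' Construct a hierarchical dataset of runs
#'
#' @param runs List of [run_record()] objects sharing one ROI count.
#' @param truth Optional planted node-by-community membership matrix.
#' @param seed Optional generator seed recorded for provenance.
#' @return An object of class `"fc_dataset"` (a list of runs with metadata).
#' @export
fc_dataset <- function(runs, truth = NULL, seed = NULL) {
  if (length(runs) == 0L) stop("dataset must contain at least one run", call. = FALSE)
  n_rois <- vapply(runs, function(r) nrow(r$signal), integer(1))
  if (length(unique(n_rois)) != 1L) {
    stop("all runs in a dataset must share the ROI count", call. = FALSE)
  }
  structure(list(runs = runs, truth = truth, seed = seed),
            class = "fc_dataset")
}

#' Index table of a dataset's hierarchy
#'
#' @param dataset An [fc_dataset()].
#' @return A data.frame with one row per run (animal, session, run, condition).
#' @export
dataset_index <- function(dataset) {
  stopifnot(inherits(dataset, "fc_dataset"))
  do.call(rbind, lapply(dataset$runs, function(r) {
    data.frame(animal = r$animal_id, session = r$session_id, run = r$run_id,
               condition = r$condition, stringsAsFactors = FALSE)
  }))
}

#' @export
print.fc_dataset <- function(x, ...) {
  idx <- dataset_index(x)
  cat(sprintf("<fc_dataset> %d runs, %d animals, %d ROIs%s\n",
              nrow(idx), length(unique(idx$animal)),
              nrow(x$runs[[1]]$signal),
              if (is.null(x$truth)) "" else ", planted truth"))
  invisible(x)
}
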
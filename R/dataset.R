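#' Multi-run fMRI dataset
#'
#' Bundles a collection of (voxels x time) run matrices, grouped by subject,
#' with a common voxel count and repetition time. This is the input container
#' for \code{\link{pfm_fit}}.
#'
#' @param runs A named list of V x T numeric matrices. Names must be
#'   \code{"<subject>/<run>"}; alternatively supply \code{subject} and
#'   \code{run} vectors of the same length as \code{runs}.
#' @param tr Repetition time in seconds.
#' @param subject,run Optional character vectors giving the subject and run id
#'   of each element of \code{runs}.
#' @return An object of class \code{pfm_dataset}: list with \code{runs} (named
#'   \code{"s/r"}), \code{tr}, \code{V}, \code{subjects} (character vector),
#'   \code{run_subject} (subject id per run).
#' @export
multi_run_dataset <- function(runs, tr, subject = NULL, run = NULL) {
  if (!is.list(runs) || length(runs) == 0)
    stop("'runs' must be a non-empty list of matrices", call. = FALSE)
  if (is.null(subject)) {
    if (is.null(names(runs)) || any(!grepl("/", names(runs))))
      stop("'runs' must be named \"<subject>/<run>\" or subject/run given",
           call. = FALSE)
    parts <- strsplit(names(runs), "/", fixed = TRUE)
    subject <- vapply(parts, `[`, "", 1L)
    run <- vapply(parts, function(p) paste(p[-1], collapse = "/"), "")
  }
  if (is.null(run)) run <- as.character(seq_along(runs))
  subject <- as.character(subject)
  run <- as.character(run)
  names(runs) <- paste(subject, run, sep = "/")
  if (anyDuplicated(names(runs)))
    stop("duplicated (subject, run) pairs", call. = FALSE)
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a single positive number", call. = FALSE)
  V <- nrow(runs[[1]])
  for (k in names(runs)) {
    m <- runs[[k]]
    if (!is.matrix(m) || !is.numeric(m))
      stop(sprintf("run '%s' is not a numeric matrix", k), call. = FALSE)
    if (nrow(m) != V)
      stop(sprintf("run '%s' has %d voxels; expected %d", k, nrow(m), V),
           call. = FALSE)
    if (ncol(m) < 2)
      stop(sprintf("run '%s' has fewer than 2 time points", k), call. = FALSE)
    if (!all(is.finite(m)))
      stop(sprintf("run '%s' contains non-finite values", k), call. = FALSE)
  }
  structure(list(runs = runs, tr = tr, V = V,
                 subjects = unique(subject), run_subject = subject),
            class = "pfm_dataset")
}

#' @export
print.pfm_dataset <- function(x, ...) {
  Ts <- vapply(x$runs, ncol, 0L)
  cat(sprintf(
    "Multi-run fMRI dataset: %d voxels, %d subjects, %d runs (T %s), tr = %g s\n",
    x$V, length(x$subjects), length(x$runs),
    if (length(unique(Ts)) == 1) sprintf("= %d", Ts[1])
    else sprintf("in [%d, %d]", min(Ts), max(Ts)),
    x$tr))
  invisible(x)
}

# run keys belonging to one subject
subject_runs <- function(data, s) names(data$runs)[data$run_subject == s]
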
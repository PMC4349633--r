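# Readers and writers: JSON run manifests, NIfTI-1 volume series (through a
# recorded voxel mask, raster order, 0-based grid indices in all metadata),
# RDS model states with JSON sidecars, JSON/CSV reports.

#' Read a multi-run dataset from a JSON manifest
#'
#' The manifest lists runs with subject/run ids and file paths. Supported run
#' formats: NIfTI-1 4-D volumes (reshaped to voxels x time through the
#' manifest's \code{mask} volume if given, otherwise all voxels; raster
#' order), or RDS matrices. All runs must share the voxel count.
#'
#' @param manifest Path to a JSON file with fields \code{tr}, optional
#'   \code{mask}, and \code{runs}: a list of \code{{subject, run, path}}.
#'   Relative paths resolve against the manifest's directory.
#' @return A \code{pfm_dataset}; the mask's voxel-to-grid mapping (if any) is
#'   attached as attribute \code{"grid"}.
#' @export
read_dataset <- function(manifest) {
  if (!file.exists(manifest))
    stop("manifest not found: ", manifest, call. = FALSE)
  mf <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  base <- dirname(manifest)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  mask_idx <- NULL; grid <- NULL
  if (!is.null(mf$mask)) {
    mk <- RNifti::readNifti(resolve(mf$mask))
    mask_idx <- which(as.array(mk) != 0)    # raster (column-major) order
    grid <- which(as.array(mk) != 0, arr.ind = TRUE) - 1L
  }
  runs <- list()
  rs <- mf$runs
  for (i in seq_len(nrow(rs))) {
    path <- resolve(rs$path[i])
    key <- paste(rs$subject[i], rs$run[i], sep = "/")
    if (!file.exists(path))
      stop(sprintf("run '%s': file not found: %s", key, path),
           call. = FALSE)
    m <- if (grepl("\\.rds$", path, ignore.case = TRUE)) {
      readRDS(path)
    } else {
      img <- as.array(RNifti::readNifti(path))
      if (length(dim(img)) != 4)
        stop(sprintf("run '%s': expected a 4-D volume", key), call. = FALSE)
      T_ <- dim(img)[4]
      flat <- matrix(img, ncol = T_)
      if (is.null(mask_idx)) flat else flat[mask_idx, , drop = FALSE]
    }
    if (length(runs) > 0 && nrow(m) != nrow(runs[[1]]))
      stop(sprintf(
        "voxel count mismatch: run '%s' has %d voxels but run '%s' has %d",
        key, nrow(m), names(runs)[1], nrow(runs[[1]])), call. = FALSE)
    runs[[key]] <- m
  }
  out <- multi_run_dataset(runs, tr = mf$tr)
  attr(out, "grid") <- grid
  out
}

#' Write a multi-run dataset
#'
#' Writes one NIfTI-1 file per run (a synthetic V x 1 x 1 x T grid unless a
#' grid mapping is supplied) plus \code{manifest.json} with the repetition
#' time, run table and an md5 checksum manifest.
#'
#' @param data A \code{pfm_dataset}.
#' @param dir Output directory (created if needed).
#' @param config Optional configuration echoed into the manifest.
#' @return Path of the manifest, invisibly.
#' @export
write_dataset <- function(data, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(subject = data$run_subject,
                    run = sub("^[^/]*/", "", names(data$runs)),
                    path = paste0(gsub("/", "_", names(data$runs)),
                                  ".nii.gz"))
  for (i in seq_along(data$runs)) {
    m <- data$runs[[i]]
    arr <- array(m, dim = c(nrow(m), 1, 1, ncol(m)))
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(1, 1, 1, data$tr)),
                       file.path(dir, tab$path[i]))
  }
  sums <- tools::md5sum(file.path(dir, tab$path))
  manifest <- list(tr = data$tr, runs = tab,
                   md5 = as.list(stats::setNames(unname(sums), tab$path)))
  if (!is.null(config)) manifest$config <- config
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Save / load a model state
#'
#' The state is stored as RDS with a JSON sidecar (\code{<path>.json})
#' carrying the configuration echo, the RNG seed and the ELBO trace for
#' inspection without loading the full state.
#'
#' @param state A \code{pfm_state}.
#' @param path Output path (.rds).
#' @return \code{write_state}: the path, invisibly; \code{read_state}: the
#'   \code{pfm_state}.
#' @export
write_state <- function(state, path) {
  stopifnot(inherits(state, "pfm_state"))
  saveRDS(state, path)
  jsonlite::write_json(
    list(modes = state$M, voxels = state$V, tr = state$tr,
         subjects = names(state$subjects), runs = names(state$tc),
         seed = state$rng_seed, scheme = state$scheme,
         config = state$config, elbo_trace = state$elbo_trace),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  st <- readRDS(path)
  stopifnot(inherits(st, "pfm_state"))
  st
}

#' Export spatial maps as a NIfTI volume series
#'
#' One 3-D volume per mode. Without a grid mapping a synthetic V x 1 x 1
#' grid is used; with one (a V x 3 matrix of 0-based grid coordinates plus
#' attribute-style dims), voxels are scattered back into the grid.
#'
#' @param maps V x M matrix.
#' @param path Output NIfTI path.
#' @param grid Optional list with \code{coords} (V x 3, 0-based) and
#'   \code{dim} (length-3 grid size).
#' @return The path, invisibly.
#' @export
write_mode_maps <- function(maps, path, grid = NULL) {
  M <- ncol(maps)
  if (is.null(grid)) {
    arr <- array(maps, dim = c(nrow(maps), 1, 1, M))
  } else {
    arr <- array(0, dim = c(grid$dim, M))
    for (m in seq_len(M))
      arr[cbind(grid$coords + 1L, m)] <- maps[, m]
  }
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Write a score report
#'
#' JSON (\code{.json}) or CSV (anything else) serialisation of a scoring
#' result.
#'
#' @param report A list or data frame (e.g. \code{pfm_scores} fields,
#'   \code{test_retest} output).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (inherits(report, "pfm_scores"))
      report <- list(spatial = report$spatial, temporal = report$temporal,
                     permutation = report$match$permutation,
                     sign_flips = report$match$sign_flips)
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}
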
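#' Write / read a motion-energy series as CSV with a JSON sidecar
#'
#' The CSV holds `time_s` and `value`; the sidecar (`<path>.json`) records
#' the sampling rate and detrending state so a round trip preserves them.
#'
#' @param series An [me_series()].
#' @param path CSV file path.
#' @return `path`, invisibly (writer); an [me_series()] (reader).
#' @export
write_me_series <- function(series, path) {
  readr::write_csv(series[, c("time_s", "value")], path)
  jsonlite::write_json(
    list(fs = me_fs(series), detrended = isTRUE(attr(series, "detrended"))),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_me_series
#' @export
read_me_series <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  me_series(tab$time_s, tab$value, fs = side$fs, detrended = isTRUE(side$detrended))
}

#' Write / read a block schedule as CSV
#'
#' Columns `run`, `block`, `condition`, `onset_s`, `duration_s`, `initial`;
#' the run length is stored in a JSON sidecar.
#'
#' @param schedule A [make_block_schedule()] tibble.
#' @param path CSV file path.
#' @return `path`, invisibly (writer); a `block_schedule` tibble (reader).
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(as.data.frame(schedule), path)
  jsonlite::write_json(
    list(
      run_length_s = schedule_run_length(schedule),
      n_runs = attr(schedule, "n_runs")
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(tibble::as_tibble(tab),
    run_length_s = side$run_length_s,
    n_runs = as.integer(side$n_runs),
    class = c("block_schedule", class(tibble::tibble()))
  )
}

#' Write / read a frame stack as a directory of PNG frames
#'
#' Frames are written as `frame_000001.png` etc. (intensities scaled from
#' 0--255 to 0--1), with a JSON sidecar recording the frame rate. Requires
#' the `png` package.
#'
#' @param stack A [frame_stack()].
#' @param dir Directory path.
#' @return `dir`, invisibly (writer); a [frame_stack()] (reader).
#' @export
write_frames_png <- function(stack, dir) {
  if (!requireNamespace("png", quietly = TRUE)) abort("the `png` package is required.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(stack$frames)[1]
  for (k in seq_len(n)) {
    png::writePNG(
      pmin(pmax(stack$frames[k, , ] / 255, 0), 1),
      file.path(dir, sprintf("frame_%06d.png", k))
    )
  }
  jsonlite::write_json(
    list(fs = stack$fs, origin_time = stack$origin_time, n_frames = n),
    file.path(dir, "stack.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_frames_png
#' @export
read_frames_png <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE)) abort("the `png` package is required.")
  side <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  frames_list <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1] # luma: first channel of gray PNG
    img * 255
  })
  arr <- array(0, dim = c(length(files), nrow(frames_list[[1]]), ncol(frames_list[[1]])))
  for (k in seq_along(frames_list)) arr[k, , ] <- frames_list[[k]]
  frame_stack(arr, fs = side$fs, origin_time = side$origin_time %||% 0)
}

#' Write a voxel series set as NIfTI
#'
#' Stores the volumes-by-voxels matrix as a 4-D NIfTI image (voxels along
#' the first axis, time along the fourth) with a JSON sidecar holding run
#' boundaries and voxel ids. Requires the `RNifti` package.
#'
#' @param vset A [voxel_series_set()].
#' @param path File path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly (writer); a `voxel_series_set` (reader).
#' @export
write_voxels_nifti <- function(vset, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) abort("the `RNifti` package is required.")
  arr <- array(t(vset$data), dim = c(ncol(vset$data), 1, 1, nrow(vset$data)))
  img <- RNifti::asNifti(arr)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(tr = vset$tr, run = vset$run, time_s = vset$time_s, voxel_ids = vset$voxel_ids),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_voxels_nifti
#' @export
read_voxels_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) abort("the `RNifti` package is required.")
  arr <- RNifti::readNifti(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- t(matrix(arr, nrow = dim(arr)[1], ncol = dim(arr)[4]))
  voxel_series_set(data,
    tr = side$tr, run = as.integer(side$run),
    time_s = side$time_s, voxel_ids = side$voxel_ids
  )
}

#' Write blink events as CSV
#'
#' @param events A [detect_blinks()] tibble (optionally with extra columns
#'   such as `run` or `participant`).
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_blink_events <- function(events, path) {
  readr::write_csv(as.data.frame(events), path)
  invisible(path)
}
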
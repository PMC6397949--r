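#' Grayscale frame stack
#'
#' Container for an ordered stack of grayscale frames sampled at a fixed
#' frame rate: a `T x H x W` numeric array plus the sampling rate and the
#' time of the first frame.
#'
#' @param frames Numeric `T x H x W` array of pixel intensities.
#' @param fs Frame rate (Hz).
#' @param origin_time Acquisition time of the first frame (s).
#' @return A list of class `frame_stack`.
#' @export
frame_stack <- function(frames, fs, origin_time = 0) {
  if (!is.array(frames) || length(dim(frames)) != 3) {
    abort("`frames` must be a T x H x W array.")
  }
  if (!all(is.finite(frames))) abort("`frames` contains non-finite intensities.")
  check_number(fs, "fs", min = 0, strict = TRUE)
  structure(list(frames = frames, fs = fs, origin_time = origin_time),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px at %g Hz (t0 = %g s)\n",
    d[1], d[2], d[3], x$fs, x$origin_time
  ))
  invisible(x)
}

#' Rectangular region of interest
#'
#' 0-based, half-open pixel window (rows `top .. top+height-1`, columns
#' `left .. left+width-1` in 0-based indexing).
#'
#' @param top,left 0-based offsets of the window's top-left corner.
#' @param height,width Window extent in pixels (>= 1).
#' @return A list of class `roi_window`.
#' @export
roi_window <- function(top, left, height, width) {
  check_number(top, "top", min = 0)
  check_number(left, "left", min = 0)
  check_number(height, "height", min = 1)
  check_number(width, "width", min = 1)
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_window")
}

#' Automatic maximum-variance ROI
#'
#' Convenience for synthetic clips: finds the bounding box of pixels whose
#' temporal variance exceeds half the maximum pixel variance. Falls back to
#' the whole frame when the stack is static. Real recordings should use a
#' manually placed [roi_window()] over the eye area.
#'
#' @param stack A [frame_stack()].
#' @return An [roi_window()].
#' @export
auto_roi <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  pv <- apply(stack$frames, c(2, 3), var)
  if (max(pv) <= 0) return(roi_window(0, 0, d[2], d[3]))
  hit <- which(pv > max(pv) / 2, arr.ind = TRUE)
  roi_window(
    top = min(hit[, 1]) - 1L, left = min(hit[, 2]) - 1L,
    height = diff(range(hit[, 1])) + 1L, width = diff(range(hit[, 2])) + 1L
  )
}

#' Motion-energy series constructor
#'
#' A uniformly sampled scalar series stored as a tibble with `time_s` and
#' `value` columns; the sampling rate and detrending state travel as
#' attributes.
#'
#' @param time_s Sample times (s).
#' @param value Motion-energy values (non-negative unless detrended).
#' @param fs Sampling rate (Hz).
#' @param detrended Logical flag.
#' @return A tibble of class `me_series`.
#' @export
me_series <- function(time_s, value, fs, detrended = FALSE) {
  stopifnot(length(time_s) == length(value))
  if (!all(is.finite(value))) abort("motion-energy values must be finite.")
  out <- tibble::tibble(time_s = as.numeric(time_s), value = as.numeric(value))
  structure(out,
    fs = fs, detrended = detrended,
    class = c("me_series", class(out))
  )
}

# Sampling rate of a series; falls back to the median time step.
me_fs <- function(series, fs = NULL) {
  fs %||% attr(series, "fs") %||% (1 / median(diff(series$time_s)))
}

#' Motion energy of a frame stack
#'
#' The first-order frame difference statistic used to track eye-blinks: for
#' each consecutive frame pair, the mean over ROI pixels of the absolute
#' intensity difference. The value for frames `k`/`k+1` is timestamped at
#' frame `k+1` (the instant the motion becomes observable), so the output
#' has `T - 1` samples.
#'
#' @param stack A [frame_stack()] with at least two frames.
#' @param roi An [roi_window()]; `NULL` uses the whole frame.
#' @return An [me_series()] of length `T - 1`.
#' @examples
#' st <- render_blink_video(events = 1, duration = 3)
#' me <- compute_motion_energy(st)
#' @export
compute_motion_energy <- function(stack, roi = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (d[1] < 2) abort("need at least two frames.")
  if (is.null(roi)) roi <- roi_window(0, 0, d[2], d[3])
  if (roi$top + roi$height > d[2] || roi$left + roi$width > d[3]) {
    abort("ROI extends outside the frame bounds.")
  }
  rows <- roi$top + seq_len(roi$height)
  cols <- roi$left + seq_len(roi$width)
  sub <- stack$frames[, rows, cols, drop = FALSE]
  dif <- abs(sub[-1, , , drop = FALSE] - sub[-d[1], , , drop = FALSE])
  vals <- rowMeans(matrix(dif, nrow = d[1] - 1))
  me_series(
    time_s = stack$origin_time + seq_len(d[1] - 1) / stack$fs,
    value = vals, fs = stack$fs, detrended = FALSE
  )
}

#' Shift a series in time
#'
#' Adds a constant to every timestamp. Used to build the REPLAY "screen"
#' series: what is on the screen at time `t` is the partner's face from
#' `t - delay`, so the screen series is the partner's series shifted
#' forward by `delay` seconds.
#'
#' @param series An [me_series()].
#' @param shift_s Shift in seconds (positive = later).
#' @return The shifted series.
#' @export
shift_series <- function(series, shift_s) {
  out <- series
  out$time_s <- out$time_s + shift_s
  out
}

#' Segment a series into per-block analysis windows
#'
#' For every block of the requested condition, extracts the final
#' `analysis_window_s` seconds (the leading seconds of each block are
#' discarded to avoid the brightness instability around condition switches).
#' At 30 Hz and the default 15 s window each block yields 450 samples; the
#' canonical 4-run schedule yields 32 sub-series per condition.
#'
#' @param series An [me_series()]; may carry a `run` column, in which case
#'   blocks are matched within runs. Without a `run` column a multi-run
#'   schedule is interpreted on a global clock (run `r` offset by
#'   `(r - 1) * run_length`).
#' @param schedule A [make_block_schedule()] tibble.
#' @param condition `"LIVE"`, `"REPLAY"`, or `"REST"`.
#' @param analysis_window_s Window length (s); blocks shorter than this are
#'   an error.
#' @param include_initial Include the initial settling REST block?
#' @return A tibble with columns `run`, `block`, `condition`,
#'   `block_onset_s`, `time_s`, `value`, ordered by block onset; attributes
#'   `fs` and `analysis_window_s`. Zero matching blocks give a zero-row
#'   tibble.
#' @export
segment_blocks <- function(series, schedule, condition,
                           analysis_window_s = 15, include_initial = FALSE) {
  fs <- me_fs(series)
  blocks <- schedule_condition_blocks(schedule, condition, include_initial)
  out_proto <- tibble::tibble(
    run = integer(), block = integer(), condition = character(),
    block_onset_s = numeric(), time_s = numeric(), value = numeric()
  )
  if (nrow(blocks) == 0) {
    return(structure(out_proto, fs = fs, analysis_window_s = analysis_window_s,
                     class = c("me_blocks", class(out_proto))))
  }
  if (any(blocks$duration_s < analysis_window_s)) {
    abort("a matching block is shorter than `analysis_window_s`.")
  }
  per_run <- "run" %in% names(series)
  run_len <- schedule_run_length(schedule)
  n_expected <- round(analysis_window_s * fs)
  pieces <- purrr::map(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    lo <- b$onset_s + b$duration_s - analysis_window_s
    hi <- b$onset_s + b$duration_s
    if (per_run) {
      sub <- series[series$run == b$run & series$time_s >= lo & series$time_s < hi, ]
    } else {
      off <- (b$run - 1) * run_len
      sub <- series[series$time_s >= lo + off & series$time_s < hi + off, ]
    }
    if (nrow(sub) != n_expected) {
      abort(sprintf(
        "block %d of run %d: expected %d samples in its analysis window, found %d (schedule outside the series time span?).",
        b$block, b$run, n_expected, nrow(sub)
      ))
    }
    tibble::tibble(
      run = as.integer(b$run), block = as.integer(b$block),
      condition = b$condition, block_onset_s = b$onset_s,
      time_s = sub$time_s, value = sub$value
    )
  })
  out <- dplyr::bind_rows(pieces)
  structure(out, fs = fs, analysis_window_s = analysis_window_s,
            class = c("me_blocks", class(out)))
}

# Least-squares line removal from a bare numeric vector.
detrend_vector <- function(v) {
  n <- length(v)
  if (n < 2) abort("need at least 2 samples to detrend.")
  k <- seq_len(n)
  kc <- k - mean(k)
  denom <- sum(kc^2)
  slope <- if (denom > 0) sum(kc * v) / denom else 0
  v - mean(v) - slope * kc
}

#' Remove a linear trend
#'
#' Subtracts the least-squares straight line (fit against the sample index),
#' leaving a zero-mean series. Applied per block when given a segmented
#' [segment_blocks()] tibble; idempotent to numerical precision. A constant
#' series detrends to exact zeros.
#'
#' @param series An [me_series()], a [segment_blocks()] tibble, or a bare
#'   numeric vector.
#' @return The same shape with `value` detrended and (for series input) the
#'   `detrended` attribute set.
#' @export
detrend_linear <- function(series) {
  if (is.numeric(series)) return(detrend_vector(series))
  if (inherits(series, "me_blocks") ||
      all(c("run", "block", "value") %in% names(series))) {
    out <- series
    grp <- interaction(series$run, series$block, drop = TRUE)
    out$value <- stats::ave(series$value, grp, FUN = detrend_vector)
    attr(out, "detrended") <- TRUE
    return(out)
  }
  fs <- me_fs(series)
  me_series(series$time_s, detrend_vector(series$value), fs = fs, detrended = TRUE)
}
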
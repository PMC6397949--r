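#' Detect blink events as prominent motion-energy peaks
#'
#' Finds local maxima of the (non-detrended) motion-energy series whose
#' topographic prominence exceeds `min_prominence`, then greedily enforces a
#' minimum separation: peaks are visited from highest to lowest (earlier
#' first on exact height ties) and a peak is kept only if it lies at least
#' `min_separation_s` from every already-kept peak.
#'
#' The default prominence threshold is five times the raw median absolute
#' deviation of the series -- an automatic stand-in for visual verification
#' of detected peaks. The default separation, 0.2 s, is the lower bound of
#' the typical 200--400 ms blink duration.
#'
#' @param series An [me_series()] (not detrended) of length >= 3.
#' @param min_separation_s Minimum gap between events (s).
#' @param min_prominence Prominence threshold; `NULL` for the MAD rule.
#' @return A tibble of class `blink_events`: columns `time_s` (strictly
#'   increasing), `height`, `prominence`.
#' @export
detect_blinks <- function(series, min_separation_s = 0.2, min_prominence = NULL) {
  check_number(min_separation_s, "min_separation_s", min = 0, strict = TRUE)
  if (!is.null(min_prominence)) {
    check_number(min_prominence, "min_prominence", min = 0, strict = TRUE)
  }
  v <- series$value
  tt <- series$time_s
  if (length(v) < 3) abort("series too short for peak detection.")
  if (isTRUE(attr(series, "detrended"))) {
    warn("detecting blinks on a detrended series; counts assume positive excursions.")
  }
  if (is.null(min_prominence)) min_prominence <- 5 * mad(v, constant = 1)

  n <- length(v)
  is_peak <- which(v[-c(1, n)] > v[-c(n - 1, n)] & v[-c(1, n)] >= v[-c(1, 2)]) + 1L
  if (!length(is_peak)) {
    out <- tibble::tibble(time_s = numeric(), height = numeric(), prominence = numeric())
    return(structure(out, class = c("blink_events", class(out))))
  }
  prom <- vapply(is_peak, function(i) peak_prominence(v, i), numeric(1))
  keep <- prom > min_prominence
  is_peak <- is_peak[keep]
  prom <- prom[keep]
  # greedy separation pruning: tallest first, earlier on ties
  ord <- order(-v[is_peak], tt[is_peak])
  acc_t <- numeric(0)
  acc <- logical(length(is_peak))
  for (j in ord) {
    t_j <- tt[is_peak[j]]
    if (!length(acc_t) || all(abs(acc_t - t_j) >= min_separation_s)) {
      acc[j] <- TRUE
      acc_t <- c(acc_t, t_j)
    }
  }
  sel <- is_peak[acc]
  o <- order(tt[sel])
  out <- tibble::tibble(
    time_s = tt[sel][o], height = v[sel][o], prominence = prom[acc][o]
  )
  structure(out, class = c("blink_events", class(out)))
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two key saddles (minimum between the peak and the nearest
# sample at least as high, walked outward on each side; series edge if none).
peak_prominence <- function(v, i) {
  h <- v[i]
  left_min <- h
  j <- i - 1
  while (j >= 1 && v[j] <= h) { # equal height does not terminate the walk
    left_min <- min(left_min, v[j])
    j <- j - 1
  }
  right_min <- h
  j <- i + 1
  n <- length(v)
  while (j <= n && v[j] <= h) {
    right_min <- min(right_min, v[j])
    j <- j + 1
  }
  h - max(left_min, right_min)
}

#' Blink counts per block and the per-participant mean
#'
#' Counts detected blink events whose time falls inside each block's final
#' `window_s` seconds (the same analysis window used for segmentation) and
#' averages the counts across blocks -- the "blinks per block" behavioral
#' measure.
#'
#' @param events A [detect_blinks()] tibble; may carry a `run` column for
#'   per-run clocks (otherwise a multi-run schedule is read on a global
#'   clock).
#' @param schedule A [make_block_schedule()] tibble.
#' @param condition Condition label to count within.
#' @param window_s Analysis window (s).
#' @param include_initial Include the initial settling REST block?
#' @return A list: `blocks`, a tibble (`run`, `block`, `condition`,
#'   `n_blinks`); `mean`, the mean count per block.
#' @export
blinks_per_block <- function(events, schedule, condition, window_s = 15,
                             include_initial = FALSE) {
  blocks <- schedule_condition_blocks(schedule, condition, include_initial)
  per_run <- "run" %in% names(events)
  run_len <- schedule_run_length(schedule)
  counts <- purrr::map_int(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    lo <- b$onset_s + b$duration_s - window_s
    hi <- b$onset_s + b$duration_s
    if (per_run) {
      sum(events$run == b$run & events$time_s >= lo & events$time_s < hi)
    } else {
      off <- (b$run - 1) * run_len
      sum(events$time_s >= lo + off & events$time_s < hi + off)
    }
  })
  blocks_out <- tibble::tibble(
    run = as.integer(blocks$run), block = as.integer(blocks$block),
    condition = blocks$condition, n_blinks = counts
  )
  list(blocks = blocks_out, mean = if (length(counts)) mean(counts) else 0)
}
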
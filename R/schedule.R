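#' Build a blocked LIVE/REPLAY/REST condition schedule
#'
#' Constructs the blocked design used for dyadic eye-contact runs: each run
#' opens with an initial REST settling block, followed by a pseudorandomized
#' sequence of equal-length LIVE, REPLAY, and REST blocks (the same number of
#' each per run). The canonical defaults -- 4 runs, 8 blocks per condition,
#' 20 s blocks, 30 s initial REST -- give a 510 s run (510 volumes at TR 1 s).
#' The brief screen-off blank between blocks (`gap_s`, 1 s by default) is
#' counted inside the preceding block's final second, so blocks tile the run
#' contiguously; set `gap_in_block = FALSE` to insert explicit gaps instead.
#'
#' @param n_runs Number of runs.
#' @param blocks_per_condition Number of LIVE blocks per run (REPLAY and REST
#'   get the same count).
#' @param block_s Block duration in seconds.
#' @param initial_rest_s Duration of the initial REST settling block (s).
#' @param gap_s Screen-off blank between blocks (s).
#' @param gap_in_block If `TRUE` (default) the blank is part of the block's
#'   final `gap_s` seconds; if `FALSE` it is appended after each block and
#'   lengthens the run.
#' @param seed Integer seed controlling the pseudorandom block order.
#' @param expected_run_length_s Optional check: error if the computed run
#'   length differs from this value.
#'
#' @return A tibble of class `block_schedule` with columns `run`, `block`
#'   (0 = initial settling block), `condition`, `onset_s` (within-run onset),
#'   `duration_s`, and `initial`. Attributes `run_length_s`, `n_runs`,
#'   `block_s`, and `gap_s` record the design geometry.
#' @examples
#' sched <- make_block_schedule(seed = 1)
#' attr(sched, "run_length_s")  # 510
#' @export
make_block_schedule <- function(n_runs = 4, blocks_per_condition = 8, block_s = 20,
                                initial_rest_s = 30, gap_s = 1, gap_in_block = TRUE,
                                seed = 1, expected_run_length_s = NULL) {
  check_number(n_runs, "n_runs", min = 1)
  check_number(blocks_per_condition, "blocks_per_condition", min = 0)
  check_number(block_s, "block_s", min = 0, strict = TRUE)
  check_number(initial_rest_s, "initial_rest_s", min = 0)
  check_number(gap_s, "gap_s", min = 0)
  if (!gap_in_block && gap_s >= block_s) abort("`gap_s` must be smaller than `block_s`.")
  if (gap_in_block && gap_s >= block_s) abort("in-block blank cannot cover the whole block.")

  n_block <- 3L * as.integer(blocks_per_condition)
  step <- block_s + if (gap_in_block) 0 else gap_s
  run_length <- initial_rest_s + n_block * step
  if (!is.null(expected_run_length_s) && abs(run_length - expected_run_length_s) > 1e-9) {
    abort(sprintf(
      "computed run length %g s disagrees with expected_run_length_s = %g s.",
      run_length, expected_run_length_s
    ))
  }

  runs <- purrr::map(seq_len(n_runs), function(r) {
    conds <- rep(c("LIVE", "REPLAY", "REST"), blocks_per_condition)
    if (n_block > 0) {
      conds <- with_seed(derive_seed(seed, "schedule", r), sample(conds))
    }
    init <- tibble::tibble(
      run = r, block = 0L, condition = "REST",
      onset_s = 0, duration_s = initial_rest_s, initial = TRUE
    )
    if (initial_rest_s == 0) init <- init[0, ]
    blocks <- tibble::tibble(
      run = r, block = seq_len(n_block), condition = conds,
      onset_s = initial_rest_s + (seq_len(n_block) - 1) * step,
      duration_s = block_s, initial = FALSE
    )
    if (n_block == 0) blocks <- blocks[0, ]
    dplyr::bind_rows(init, blocks)
  })
  out <- dplyr::bind_rows(runs)
  structure(out,
    run_length_s = run_length, n_runs = as.integer(n_runs),
    block_s = block_s, gap_s = gap_s,
    class = c("block_schedule", class(out))
  )
}

#' Run length of a block schedule
#'
#' @param schedule A [make_block_schedule()] tibble.
#' @return Run length in seconds (scalar).
#' @export
schedule_run_length <- function(schedule) {
  rl <- attr(schedule, "run_length_s")
  if (is.null(rl)) rl <- max(schedule$onset_s + schedule$duration_s)
  rl
}

# Blocks of one condition, optionally dropping the initial settling block.
schedule_condition_blocks <- function(schedule, condition, include_initial = FALSE) {
  out <- dplyr::filter(schedule, .data$condition == !!condition)
  if (!include_initial && "initial" %in% names(out)) {
    out <- dplyr::filter(out, !.data$initial)
  }
  dplyr::arrange(out, .data$run, .data$onset_s)
}
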
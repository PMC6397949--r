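#' Configuration for a simulated dyad
#'
#' Bundles the ground-truth parameters of the synthetic dyad generator: two
#' participants blink as point processes with a baseline rate, a refractory
#' period, and directional cross-excitation -- after a partner blink, a
#' participant's blink hazard is transiently multiplied, with a raised-cosine
#' kernel starting `coupling_latency` seconds after the partner event. The
#' defaults emulate spontaneous blinking during mutual gaze: 15 blinks/min
#' baseline, blink durations drawn uniformly from 200--400 ms, and a 0.25 s
#' reaction latency with a 0.5 s kernel width -- a reactive-blink timescale
#' that the lag horizon of the downstream autoregressive analysis (orders
#' 1--10 at 30 Hz) can resolve.
#'
#' @param seed Master integer seed; per-participant and per-stage substreams
#'   are derived from it.
#' @param fs Sampling rate in Hz (video frame rate; default 30).
#' @param duration Simulated duration in seconds.
#' @param baseline_blink_rate Baseline blink rate, events per minute.
#' @param coupling_gain_12,coupling_gain_21 Dimensionless gains (>= 0):
#'   the multiplicative hazard increase of participant 2 (resp. 1) at the
#'   peak of the kernel following a blink of participant 1 (resp. 2).
#' @param coupling_latency Seconds from a partner blink to the start of the
#'   excitation kernel.
#' @param coupling_kernel_width Kernel support width in seconds.
#' @param blink_duration_range Range (s) from which per-event blink durations
#'   are drawn uniformly.
#' @param refractory Minimum gap between consecutive blinks of the same
#'   participant (s); must be at least the longest blink duration.
#' @param replay_delay_s Video delay of the REPLAY condition (s); used when a
#'   schedule gates the coupling (see [simulate_coupled_blinks()]).
#'
#' @return A list of class `dyad_sim_config`.
#' @export
dyad_sim_config <- function(seed = 1, fs = 30, duration = 510,
                            baseline_blink_rate = 15,
                            coupling_gain_12 = 1, coupling_gain_21 = 1,
                            coupling_latency = 0.25, coupling_kernel_width = 0.5,
                            blink_duration_range = c(0.2, 0.4),
                            refractory = 0.4, replay_delay_s = 20) {
  check_number(fs, "fs", min = 0, strict = TRUE)
  check_number(duration, "duration", min = 0, strict = TRUE)
  check_number(baseline_blink_rate, "baseline_blink_rate", min = 0)
  check_number(coupling_gain_12, "coupling_gain_12", min = 0)
  check_number(coupling_gain_21, "coupling_gain_21", min = 0)
  check_number(coupling_latency, "coupling_latency", min = 0)
  check_number(coupling_kernel_width, "coupling_kernel_width", min = 0, strict = TRUE)
  check_number(refractory, "refractory", min = 0)
  stopifnot(length(blink_duration_range) == 2, diff(blink_duration_range) >= 0)
  if (refractory < max(blink_duration_range)) {
    abort("`refractory` must be >= the maximum blink duration.")
  }
  structure(
    list(
      seed = as.integer(seed), fs = fs, duration = duration,
      baseline_blink_rate = baseline_blink_rate,
      coupling_gain_12 = coupling_gain_12, coupling_gain_21 = coupling_gain_21,
      coupling_latency = coupling_latency,
      coupling_kernel_width = coupling_kernel_width,
      blink_duration_range = blink_duration_range,
      refractory = refractory, replay_delay_s = replay_delay_s
    ),
    class = "dyad_sim_config"
  )
}

# Raised-cosine excitation kernel on [0, width], normalized to unit time
# integral (units 1/s), so the expected number of reactive blinks added per
# observed partner blink is gain * baseline hazard * 1 s.
raised_cosine <- function(u, width) {
  k <- numeric(length(u))
  inside <- u >= 0 & u <= width
  k[inside] <- (1 - cos(2 * pi * u[inside] / width)) / width
  k
}

#' Simulate a dyad of cross-excited blink trains
#'
#' Discrete-time thinning of a mutually exciting point-process pair: each
#' participant blinks at their baseline hazard, multiplied by
#' `1 + gain * K(t - t_partner - latency)` for every recent partner blink,
#' where `K` is a raised-cosine kernel normalized to unit time integral --
#' so each partner blink adds, in expectation, `gain * baseline_hazard`
#' reactive blinks (e.g. 0.25 per partner blink at 15 blinks/min and
#' gain 1). A refractory period is enforced.
#' With `schedule = NULL` the coupling is active throughout. With a [make_block_schedule()] schedule the
#' coupling is condition-gated, mirroring what each participant can actually
#' see: during LIVE blocks excitation comes from the partner's live blinks,
#' during REPLAY blocks from the partner's blinks delayed by
#' `config$replay_delay_s` (the on-screen video), and during REST there is
#' no excitation. The response gain is identical in LIVE and REPLAY -- the
#' conditions differ only in loop timing, not in reactivity.
#'
#' @param config A [dyad_sim_config()].
#' @param schedule Optional single-run [make_block_schedule()] tibble whose
#'   onsets lie within `[0, config$duration]`.
#' @param dt Simulation time step (s); defaults to one video frame, `1/fs`.
#'
#' @return A list of class `simulated_dyad` with elements `events_1`,
#'   `events_2` (strictly increasing blink onset times, s), `durations_1`,
#'   `durations_2` (per-event blink durations, s), and `truth` (the config).
#' @export
simulate_coupled_blinks <- function(config, schedule = NULL, dt = 1 / config$fs) {
  stopifnot(inherits(config, "dyad_sim_config"))
  base_hz <- config$baseline_blink_rate / 60
  if (base_hz * config$refractory >= 1) {
    abort("baseline blink rate too high: more than one expected event per refractory period.")
  }
  n_steps <- floor(config$duration / dt)
  times <- (seq_len(n_steps) - 0.5) * dt

  cond_at <- rep("LIVE", n_steps) # schedule-free: coupling always on
  if (!is.null(schedule)) {
    cond_at <- rep("REST", n_steps)
    for (i in seq_len(nrow(schedule))) {
      sel <- times >= schedule$onset_s[i] & times < schedule$onset_s[i] + schedule$duration_s[i]
      cond_at[sel] <- schedule$condition[i]
    }
  }

  u1 <- with_seed(derive_seed(config$seed, "blinks", 1), runif(n_steps))
  u2 <- with_seed(derive_seed(config$seed, "blinks", 2), runif(n_steps))
  gains <- c(config$coupling_gain_21, config$coupling_gain_12) # onto participant 1, 2
  lat <- config$coupling_latency
  w <- config$coupling_kernel_width
  delay <- config$replay_delay_s

  ev <- list(numeric(0), numeric(0))
  last <- c(-Inf, -Inf)
  u <- list(u1, u2)
  for (k in seq_len(n_steps)) {
    t <- times[k]
    cond <- cond_at[k]
    for (p in 1:2) {
      if (t - last[p] < config$refractory) next
      haz <- base_hz
      if (cond != "REST" && gains[p] > 0) {
        src <- ev[[3 - p]]
        if (cond == "REPLAY") src <- src + delay
        if (length(src)) {
          lag <- t - src - lat
          rec <- lag >= 0 & lag <= w
          if (any(rec)) haz <- base_hz * (1 + gains[p] * sum(raised_cosine(lag[rec], w)))
        }
      }
      if (u[[p]][k] < haz * dt) {
        ev[[p]] <- c(ev[[p]], t)
        last[p] <- t
      }
    }
  }

  rng <- config$blink_duration_range
  dur1 <- with_seed(
    derive_seed(config$seed, "durations", 1),
    runif(length(ev[[1]]), rng[1], rng[2])
  )
  dur2 <- with_seed(
    derive_seed(config$seed, "durations", 2),
    runif(length(ev[[2]]), rng[1], rng[2])
  )
  structure(
    list(
      events_1 = ev[[1]], events_2 = ev[[2]],
      durations_1 = dur1, durations_2 = dur2, truth = config
    ),
    class = "simulated_dyad"
  )
}

#' Synthesize a motion-energy trace directly from blink events
#'
#' Renders each blink as a raised-cosine motion-energy pulse of the event's
#' duration, on top of a half-normal sensor-noise floor. This is the cheap
#' scalar counterpart of [render_blink_video()] followed by
#' [compute_motion_energy()], used by the pipeline where rendering full frame
#' stacks would be wasteful.
#'
#' @param events Blink onset times (s).
#' @param durations Per-event blink durations (s); recycled if length 1.
#' @param fs Sampling rate (Hz).
#' @param duration Total trace duration (s).
#' @param pulse_height Peak motion-energy amplitude of a blink (intensity
#'   units).
#' @param noise_sd Scale of the half-normal noise floor; 0 for a clean trace.
#' @param seed Integer seed for the noise stream (required if `noise_sd > 0`).
#'
#' @return A motion-energy tibble (`me_series`): columns `time_s`, `value`.
#' @export
events_to_motion_energy <- function(events, durations = 0.3, fs = 30, duration,
                                    pulse_height = 10, noise_sd = 0.5, seed = NULL) {
  check_number(duration, "duration", min = 0, strict = TRUE)
  n <- round(duration * fs)
  tt <- seq_len(n) / fs
  val <- numeric(n)
  durations <- rep_len(durations, length(events))
  for (i in seq_along(events)) {
    e <- events[i]
    d <- durations[i]
    sel <- which(tt >= e & tt <= e + d)
    val[sel] <- val[sel] + pulse_height * 0.5 * (1 - cos(2 * pi * (tt[sel] - e) / d))
  }
  if (noise_sd > 0) {
    if (is.null(seed)) abort("`seed` is required when `noise_sd > 0`.")
    val <- val + abs(with_seed(seed, rnorm(n, 0, noise_sd)))
  }
  me_series(tt, val, fs = fs, detrended = FALSE)
}

#' Render blink events as a synthetic eye-region frame stack
#'
#' Produces grayscale frames with a constant background; during each blink an
#' eyelid, modeled as a darkening band, sweeps down and back up over the ROI
#' following a sinusoidal closure profile lasting the blink's duration. The
#' motion energy of the result is exactly zero on frames with no blink
#' activity, and each blink produces the double-humped pulse characteristic
#' of real eyelid closure/opening.
#'
#' @param events Blink onset times (s), within `[0, duration]`.
#' @param fs Frame rate (Hz).
#' @param duration Clip duration (s); frame count is `round(duration * fs)`.
#' @param frame_shape `c(height, width)` in pixels.
#' @param roi Optional [roi_window()] over which the eyelid sweeps; defaults
#'   to a central band spanning the middle half of the frame.
#' @param blink_durations Per-event durations (s); recycled.
#' @param contrast Eyelid darkening in intensity units (0--255 scale).
#' @param background Background intensity.
#'
#' @return A [frame_stack()].
#' @export
render_blink_video <- function(events, fs = 30, duration,
                               frame_shape = c(48, 64), roi = NULL,
                               blink_durations = 0.3, contrast = 30,
                               background = 128) {
  check_number(duration, "duration", min = 0, strict = TRUE)
  blink_durations <- rep_len(blink_durations, length(events))
  if (length(events)) {
    if (any(events < 0) || any(events + blink_durations > duration)) {
      abort("blink events must lie within [0, duration].")
    }
    o <- order(events)
    events <- events[o]
    blink_durations <- blink_durations[o]
    if (length(events) > 1 &&
      any(events[-1] < (events + blink_durations)[-length(events)])) {
      abort("overlapping blinks: consecutive events closer than their durations.")
    }
  }
  h <- frame_shape[1]
  w <- frame_shape[2]
  if (is.null(roi)) {
    roi <- roi_window(
      top = floor(h / 4), left = floor(w / 4),
      height = max(1, floor(h / 2)), width = max(1, floor(w / 2))
    )
  }
  n <- round(duration * fs)
  frames <- array(background, dim = c(n, h, w))
  f_times <- (seq_len(n) - 1) / fs
  rows <- roi$top + seq_len(roi$height) # 1-based rows of the ROI
  cols <- roi$left + seq_len(roi$width)
  for (i in seq_along(events)) {
    e <- events[i]
    d <- blink_durations[i]
    sel <- which(f_times >= e & f_times <= e + d)
    for (k in sel) {
      closure <- sin(pi * (f_times[k] - e) / d)^6 # 0 -> 1 -> 0, velocity concentrated mid-blink
      n_rows <- round(closure * roi$height)
      if (n_rows > 0) {
        frames[k, rows[seq_len(n_rows)], cols] <-
          frames[k, rows[seq_len(n_rows)], cols] - contrast
      }
    }
  }
  frame_stack(frames, fs = fs)
}

#' Simulate paired voxel time series with a shared latent signal
#'
#' Generates two BOLD-like volumes-by-voxels arrays for a participant pair:
#' per voxel, `series = task_amp * (condition boxcars convolved with a
#' canonical HRF) + sqrt(rho) * latent + sqrt(1 - rho) * noise`, where the
#' latent standard-normal series is shared within the pair, so the
#' task-free cross-correlation equals `shared_rho` in expectation (unit
#' marginal variance around the task component). The task component is
#' identical for both participants, emulating task-locked coactivation that
#' residualization must remove. Optionally, a subset of voxels can carry
#' extra coupling restricted to LIVE volumes (`live_rho`, `live_voxels`),
#' planting condition-specific synchronization.
#'
#' @param n_voxels Number of voxels.
#' @param n_volumes Volumes per run when `schedule` is `NULL`; ignored
#'   otherwise (the run length / TR determines it).
#' @param shared_rho Target latent correlation per voxel (recycled);
#'   strictly inside (-1, 1).
#' @param task_amp Amplitude of the task-locked component.
#' @param schedule Optional [make_block_schedule()]; when supplied, each of
#'   its runs is simulated at `n_volumes_per_run = run_length / tr`.
#' @param tr Repetition time (s).
#' @param seed Integer seed.
#' @param live_rho,live_voxels Optional LIVE-specific latent correlation and
#'   the voxel indices that carry it.
#'
#' @return A list of class `voxel_pair_sim`: [voxel_series_set()]s `a` and
#'   `b`, plus `truth`.
#' @export
simulate_voxel_pair <- function(n_voxels, n_volumes = NULL, shared_rho = 0.3,
                                task_amp = 0, schedule = NULL, tr = 1, seed = 1,
                                live_rho = NULL, live_voxels = integer(0)) {
  rho <- rep_len(shared_rho, n_voxels)
  if (any(rho <= -1 | rho >= 1)) abort("`shared_rho` must be strictly inside (-1, 1).")
  if (!is.null(live_rho) && (live_rho <= -1 || live_rho >= 1)) {
    abort("`live_rho` must be strictly inside (-1, 1).")
  }
  if (is.null(schedule)) {
    if (is.null(n_volumes)) abort("supply `n_volumes` or a `schedule`.")
    n_runs <- 1L
    vols_per_run <- as.integer(n_volumes)
    run_len <- vols_per_run * tr
    sched1 <- NULL
  } else {
    n_runs <- attr(schedule, "n_runs") %||% max(schedule$run)
    run_len <- schedule_run_length(schedule)
    vols_per_run <- as.integer(round(run_len / tr))
  }
  n_total <- n_runs * vols_per_run
  run_id <- rep(seq_len(n_runs), each = vols_per_run)
  t_in_run <- rep((seq_len(vols_per_run) - 1) * tr, n_runs)

  # Task regressor: all non-REST boxcars convolved with the canonical HRF.
  task <- numeric(n_total)
  live_vol <- rep(FALSE, n_total)
  if (!is.null(schedule)) {
    for (r in seq_len(n_runs)) {
      blocks <- schedule[schedule$run == r, ]
      idx <- which(run_id == r)
      box <- numeric(vols_per_run)
      tt <- t_in_run[idx]
      for (i in seq_len(nrow(blocks))) {
        on <- tt >= blocks$onset_s[i] & tt < blocks$onset_s[i] + blocks$duration_s[i]
        if (blocks$condition[i] != "REST") box[on] <- 1
        if (blocks$condition[i] == "LIVE") live_vol[idx[on]] <- TRUE
      }
      task[idx] <- convolve_hrf(box, tr)
    }
  }

  # Per-volume, per-voxel latent loading (sqrt of the target correlation,
  # with sign), optionally boosted on LIVE volumes for planted voxels.
  rho_mat <- matrix(rho, nrow = n_total, ncol = n_voxels, byrow = TRUE)
  if (!is.null(live_rho) && length(live_voxels)) {
    rho_mat[live_vol, live_voxels] <- live_rho
  }
  lam <- sign(rho_mat) * sqrt(abs(rho_mat))
  sig <- sqrt(1 - abs(rho_mat))

  latent <- with_seed(derive_seed(seed, "latent"), matrix(rnorm(n_total * n_voxels), n_total))
  e_a <- with_seed(derive_seed(seed, "noise", "a"), matrix(rnorm(n_total * n_voxels), n_total))
  e_b <- with_seed(derive_seed(seed, "noise", "b"), matrix(rnorm(n_total * n_voxels), n_total))
  a <- task_amp * task + lam * latent + sig * e_a
  b <- task_amp * task + lam * latent + sig * e_b
  ids <- paste0("v", seq_len(n_voxels))
  structure(
    list(
      a = voxel_series_set(a, tr = tr, run = run_id, time_s = t_in_run, voxel_ids = ids),
      b = voxel_series_set(b, tr = tr, run = run_id, time_s = t_in_run, voxel_ids = ids),
      truth = list(
        shared_rho = rho, task_amp = task_amp, seed = seed,
        live_rho = live_rho, live_voxels = live_voxels
      )
    ),
    class = "voxel_pair_sim"
  )
}
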
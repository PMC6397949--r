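#' Configuration for an end-to-end synthetic run
#'
#' Collects every tunable of the synthetic pipeline in one validated list:
#' design geometry, generator ground truth, blink-detection and NCR
#' settings, and the voxel-synchronization stage. Any field can be
#' overridden; the defaults are the canonical study conditions (4 runs of
#' 510 s, 8 blocks per condition, 30 Hz video, 15 blinks/min baseline,
#' coupling gain 1 at 0.25 s latency, AR orders 1--10, 513-point NCR grid,
#' TR 1 s, 128 s high-pass, 10 discarded volumes per run).
#'
#' @param seed Master integer seed (mandatory; every stage derives its own
#'   substream from it).
#' @param n_pairs Number of simulated dyads.
#' @param n_runs,blocks_per_condition,block_s,initial_rest_s Design geometry
#'   passed to [make_block_schedule()].
#' @param fs Video sampling rate (Hz).
#' @param baseline_blink_rate Blinks/min baseline of the generator.
#' @param coupling_gain_12,coupling_gain_21 Ground-truth coupling gains.
#' @param coupling_latency,coupling_kernel_width,refractory,replay_delay_s
#'   Remaining generator parameters (see [dyad_sim_config()]).
#' @param pulse_height,noise_sd Motion-energy rendering of blinks (see
#'   [events_to_motion_energy()]).
#' @param analysis_window_s Final-seconds analysis window per block.
#' @param min_separation_s Blink-detection separation.
#' @param max_order,n_freqs NCR settings.
#' @param n_voxels,tr,shared_rho,task_amp,live_rho,live_voxels,highpass_s,drop_initial
#'   Voxel-synchronization stage settings (see [simulate_voxel_pair()] and
#'   [glm_residualize()]).
#' @param out_dir Optional output directory; when set, result tables are
#'   written as CSV plus a JSON manifest sufficient to replay the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed, n_pairs = 14,
                       n_runs = 4, blocks_per_condition = 8, block_s = 20,
                       initial_rest_s = 30, fs = 30,
                       baseline_blink_rate = 15,
                       coupling_gain_12 = 1, coupling_gain_21 = 1,
                       coupling_latency = 0.25, coupling_kernel_width = 0.5,
                       refractory = 0.4, replay_delay_s = 20,
                       pulse_height = 10, noise_sd = 0.5,
                       analysis_window_s = 15, min_separation_s = 0.2,
                       max_order = 10, n_freqs = 513,
                       n_voxels = 200, tr = 1, shared_rho = 0.1, task_amp = 1,
                       live_rho = NULL, live_voxels = integer(0),
                       highpass_s = 128, drop_initial = 10,
                       out_dir = NULL) {
  check_number(seed, "seed")
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

# Simulate one dyad's motion-energy series for all runs. Returns per-
# participant series tibbles (with a `run` column) and the schedule.
simulate_dyad_series <- function(cfg, pair) {
  schedule <- make_block_schedule(
    n_runs = cfg$n_runs, blocks_per_condition = cfg$blocks_per_condition,
    block_s = cfg$block_s, initial_rest_s = cfg$initial_rest_s,
    seed = derive_seed(cfg$seed, "schedule", pair)
  )
  run_len <- schedule_run_length(schedule)
  per_run <- purrr::map(seq_len(cfg$n_runs), function(r) {
    sim_cfg <- dyad_sim_config(
      seed = derive_seed(cfg$seed, "dyad", pair, r),
      fs = cfg$fs, duration = run_len,
      baseline_blink_rate = cfg$baseline_blink_rate,
      coupling_gain_12 = cfg$coupling_gain_12,
      coupling_gain_21 = cfg$coupling_gain_21,
      coupling_latency = cfg$coupling_latency,
      coupling_kernel_width = cfg$coupling_kernel_width,
      refractory = cfg$refractory, replay_delay_s = cfg$replay_delay_s
    )
    sim <- simulate_coupled_blinks(sim_cfg, schedule = schedule[schedule$run == r, ])
    series <- purrr::map(1:2, function(i) {
      ev <- if (i == 1) sim$events_1 else sim$events_2
      du <- if (i == 1) sim$durations_1 else sim$durations_2
      me <- events_to_motion_energy(
        ev, du, fs = cfg$fs, duration = run_len,
        pulse_height = cfg$pulse_height, noise_sd = cfg$noise_sd,
        seed = derive_seed(cfg$seed, "me", pair, r, i)
      )
      me$run <- r
      me
    })
    list(series = series, events = list(sim$events_1, sim$events_2))
  })
  series <- purrr::map(1:2, function(i) {
    out <- dplyr::bind_rows(purrr::map(per_run, ~ .x$series[[i]]))
    structure(out, fs = cfg$fs, class = c("me_series", class(out)))
  })
  list(schedule = schedule, series = series)
}

# The four directional quantities for one participant: influence of the
# partner's face (LIVE, REPLAY, REST) and of the REPLAY screen on the
# participant's own blink series.
participant_quantities <- function(own, partner, schedule, cfg) {
  seg_own <- function(cond) {
    segment_blocks(own, schedule, cond, analysis_window_s = cfg$analysis_window_s)
  }
  quantify <- function(cond, influencer) {
    paired <- pair_block_series(
      seg_own(cond),
      segment_blocks(influencer, schedule, cond,
        analysis_window_s = cfg$analysis_window_s
      )
    )
    participant_sigma_ncr(paired,
      direction = "y_to_x",
      max_order = cfg$max_order, n_freqs = cfg$n_freqs, fs = cfg$fs
    )
  }
  screen <- shift_series(partner, cfg$replay_delay_s)
  list(
    FF_LIVE = quantify("LIVE", partner),
    FF_REPLAY = quantify("REPLAY", partner),
    SF_REPLAY = quantify("REPLAY", screen),
    FF_REST = quantify("REST", partner)
  )
}

#' Run the behavioral analysis end to end on synthetic dyads
#'
#' For every simulated pair: generates the blocked schedule and the coupled
#' blink trains, renders motion-energy series, detects blinks and counts
#' them per block, computes the four participant-level integrated NCR
#' quantities (face-to-face LIVE / REPLAY / REST and screen-to-face
#' REPLAY), forms REST-baseline enhancements, and runs the inferential
#' layer (repeated-measures ANOVAs with generalized eta-squared, Bonferroni
#' paired t tests, the 2-SD outlier re-run, and a session-by-condition
#' ANOVA when there are multiple runs). With `out_dir` set, tidy CSVs and a
#' reproducibility manifest are written; identical configs and seeds yield
#' byte-identical files.
#'
#' @param config A [run_config()].
#' @return A list of class `behavioral_run`: `blinks`, `sigma_ncr`,
#'   `sigma_ncr_blocks`, `enhancement` tibbles, the `stats` list, and
#'   `manifest`.
#' @export
run_behavioral <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  rows_blinks <- list()
  rows_sigma <- list()
  rows_blocks <- list()
  for (p in seq_len(cfg$n_pairs)) {
    dyad <- tryCatch(simulate_dyad_series(cfg, p), error = function(e) {
      warn(sprintf("pair %d failed to simulate: %s", p, conditionMessage(e)))
      NULL
    })
    if (is.null(dyad)) next
    for (i in 1:2) {
      pid <- sprintf("P%02d_%d", p, i)
      own <- dyad$series[[i]]
      partner <- dyad$series[[3 - i]]
      # blink counts from detected events, per run
      ev <- dplyr::bind_rows(purrr::map(unique(own$run), function(r) {
        sub <- own[own$run == r, ]
        sub <- structure(sub, fs = cfg$fs, class = c("me_series", class(sub)))
        det <- detect_blinks(sub, min_separation_s = cfg$min_separation_s)
        if (nrow(det)) det$run <- r
        det
      }))
      for (cond in c("LIVE", "REPLAY", "REST")) {
        bb <- blinks_per_block(ev, dyad$schedule, cond,
          window_s = cfg$analysis_window_s
        )
        rows_blinks[[length(rows_blinks) + 1]] <- tibble::tibble(
          pair = p, participant = pid, condition = cond, mean_blinks = bb$mean
        )
      }
      qs <- tryCatch(
        participant_quantities(own, partner, dyad$schedule, cfg),
        error = function(e) {
          warn(sprintf("participant %s NCR failed: %s", pid, conditionMessage(e)))
          NULL
        }
      )
      if (is.null(qs)) next
      for (qn in names(qs)) {
        rows_sigma[[length(rows_sigma) + 1]] <- tibble::tibble(
          pair = p, participant = pid, quantity = qn, sigma_ncr = qs[[qn]]$mean
        )
        blk <- qs[[qn]]$blocks
        blk$pair <- p
        blk$participant <- pid
        blk$quantity <- qn
        rows_blocks[[length(rows_blocks) + 1]] <- blk
      }
    }
  }
  blinks <- dplyr::bind_rows(rows_blinks)
  sigma <- dplyr::bind_rows(rows_sigma)
  blocks <- dplyr::bind_rows(rows_blocks)

  enh <- sigma |>
    tidyr::pivot_wider(names_from = "quantity", values_from = "sigma_ncr") |>
    dplyr::transmute(
      pair = .data$pair, participant = .data$participant,
      FF_LIVE = enhanced_sigma_ncr(.data$FF_LIVE, .data$FF_REST),
      FF_REPLAY = enhanced_sigma_ncr(.data$FF_REPLAY, .data$FF_REST),
      SF_REPLAY = enhanced_sigma_ncr(.data$SF_REPLAY, .data$FF_REST)
    ) |>
    tidyr::pivot_longer(c("FF_LIVE", "FF_REPLAY", "SF_REPLAY"),
      names_to = "quantity", values_to = "enhancement"
    )

  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  stats_out <- list(
    anova_blinks = safe(rm_anova(blinks, dv = "mean_blinks", subject = "participant")),
    anova_sigma = safe(rm_anova(sigma,
      dv = "sigma_ncr", within = "quantity", subject = "participant"
    )),
    posthoc_sigma = safe(paired_t_bonferroni(sigma,
      dv = "sigma_ncr", within = "quantity", subject = "participant"
    )),
    anova_enhancement = safe(rm_anova(enh,
      dv = "enhancement", within = "quantity", subject = "participant"
    ))
  )
  scr <- safe(remove_outliers_2sd(sigma,
    dv = "sigma_ncr", within = "quantity", subject = "participant"
  ))
  if (!is.null(scr)) {
    stats_out$outliers_removed <- scr$removed
    stats_out$anova_sigma_screened <- safe(rm_anova(scr$table,
      dv = "sigma_ncr", within = "quantity", subject = "participant"
    ))
  }
  if (cfg$n_runs >= 2 && nrow(blocks)) {
    per_session <- blocks |>
      dplyr::filter(!.data$skipped) |>
      dplyr::group_by(.data$participant, .data$quantity, session = .data$run) |>
      dplyr::summarise(sigma_ncr = mean(.data$sigma_ncr), .groups = "drop")
    stats_out$anova_session <- safe(rm_anova(per_session,
      dv = "sigma_ncr", within = c("quantity", "session"), subject = "participant"
    ))
  }

  out <- structure(
    list(
      blinks = blinks, sigma_ncr = sigma, sigma_ncr_blocks = blocks,
      enhancement = enh, stats = stats_out,
      manifest = run_manifest(cfg, "behavioral")
    ),
    class = "behavioral_run"
  )
  if (!is.null(cfg$out_dir)) write_behavioral_run(out, cfg$out_dir)
  out
}

#' Run the interbrain-synchronization analysis on synthetic pairs
#'
#' For every simulated pair: generates paired voxel series sharing a latent
#' signal (plus task-locked components), residualizes task and drift per
#' run, splits and concatenates the LIVE and REPLAY volumes, computes the
#' homologous-voxel Fisher-z synchronization maps, and contrasts LIVE
#' against REPLAY with a per-voxel paired t test across pairs.
#'
#' @param config A [run_config()].
#' @return A list of class `sync_run`: `z_maps` (long tibble: pair,
#'   condition, voxel, r, z), `contrast` (per-voxel paired t), `manifest`.
#' @export
run_sync <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  schedule <- make_block_schedule(
    n_runs = cfg$n_runs, blocks_per_condition = cfg$blocks_per_condition,
    block_s = cfg$block_s, initial_rest_s = cfg$initial_rest_s,
    seed = derive_seed(cfg$seed, "sync-schedule")
  )
  maps <- list(LIVE = list(), REPLAY = list())
  rows <- list()
  for (p in seq_len(cfg$n_pairs)) {
    sim <- simulate_voxel_pair(
      n_voxels = cfg$n_voxels, shared_rho = cfg$shared_rho,
      task_amp = cfg$task_amp, schedule = schedule, tr = cfg$tr,
      seed = derive_seed(cfg$seed, "voxels", p),
      live_rho = cfg$live_rho, live_voxels = cfg$live_voxels
    )
    ra <- glm_residualize(sim$a, schedule,
      highpass_s = cfg$highpass_s, drop_initial = cfg$drop_initial
    )
    rb <- glm_residualize(sim$b, schedule,
      highpass_s = cfg$highpass_s, drop_initial = cfg$drop_initial
    )
    for (cond in c("LIVE", "REPLAY")) {
      sm <- voxelwise_sync(
        split_concat_condition(ra, schedule, cond),
        split_concat_condition(rb, schedule, cond)
      )
      maps[[cond]][[p]] <- sm
      rows[[length(rows) + 1]] <- tibble::tibble(
        pair = p, condition = cond, voxel = sm$voxel, r = sm$r, z = sm$z
      )
    }
  }
  contrast <- paired_sync_contrast(maps$LIVE, maps$REPLAY)
  out <- structure(
    list(
      z_maps = dplyr::bind_rows(rows), contrast = contrast,
      live_maps = maps$LIVE, replay_maps = maps$REPLAY,
      manifest = run_manifest(cfg, "sync")
    ),
    class = "sync_run"
  )
  if (!is.null(cfg$out_dir)) write_sync_run(out, cfg$out_dir)
  out
}

# Reproducibility manifest: everything needed to replay the run.
run_manifest <- function(cfg, stage) {
  plain <- unclass(cfg)
  plain$out_dir <- NULL
  list(
    stage = stage,
    package = "blinksync",
    package_version = as.character(utils::packageVersion("blinksync")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = plain,
    config_hash = rlang::hash(plain)
  )
}

write_behavioral_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$blinks, file.path(dir, "blinks.csv"))
  readr::write_csv(run$sigma_ncr, file.path(dir, "sigma_ncr.csv"))
  readr::write_csv(run$sigma_ncr_blocks, file.path(dir, "sigma_ncr_blocks.csv"))
  readr::write_csv(run$enhancement, file.path(dir, "enhancement.csv"))
  anovas <- dplyr::bind_rows(purrr::imap(
    purrr::keep(
      run$stats[c("anova_blinks", "anova_sigma", "anova_enhancement",
                  "anova_sigma_screened", "anova_session")],
      ~ !is.null(.x)
    ),
    ~ dplyr::mutate(.x, analysis = .y, .before = 1)
  ))
  if (nrow(anovas)) readr::write_csv(anovas, file.path(dir, "stats_anova.csv"))
  if (!is.null(run$stats$posthoc_sigma)) {
    readr::write_csv(run$stats$posthoc_sigma, file.path(dir, "stats_posthoc.csv"))
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}

write_sync_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$z_maps, file.path(dir, "sync_z.csv"))
  readr::write_csv(run$contrast, file.path(dir, "sync_contrast.csv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}

#' @export
print.behavioral_run <- function(x, ...) {
  cat(sprintf(
    "<behavioral_run> %d participants | %d sigma-NCR values | %d block fits\n",
    length(unique(x$sigma_ncr$participant)), nrow(x$sigma_ncr),
    nrow(x$sigma_ncr_blocks)
  ))
  if (!is.null(x$stats$anova_sigma)) {
    a <- x$stats$anova_sigma
    cat(sprintf(
      "  sigma-NCR condition effect: F(%d, %d) = %.3f, p = %.4f, ges = %.4f\n",
      a$df_num, a$df_den, a$statistic, a$p_value, a$ges
    ))
  }
  invisible(x)
}

#' @export
print.sync_run <- function(x, ...) {
  cat(sprintf(
    "<sync_run> %d pairs x %d voxels | top contrast |t| = %.2f\n",
    length(x$live_maps), length(unique(x$contrast$voxel)),
    max(abs(x$contrast$statistic))
  ))
  invisible(x)
}
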
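test_that("with no task the residuals equal the high-pass projection", {
  sched <- make_block_schedule(n_runs = 1, seed = 1)
  set.seed(90)
  Y <- matrix(rnorm(510 * 4), 510, 4)
  vset <- voxel_series_set(Y, tr = 1)
  res <- glm_residualize(vset, sched, drop_initial = 10)
  # oracle: project the kept volumes on intercept + DCT only, then compare
  # (the HRF-convolved condition regressors are in the span regardless, so
  # instead build the full design independently with lm)
  keep <- 11:510
  n <- length(keep)
  K <- floor(2 * n * 1 / 128)
  dct <- outer(seq_len(n) - 1, seq_len(K), function(i, k) cos(pi * (2 * i + 1) * k / (2 * n)))
  # no-task input: the task betas just absorb noise; compare against lm with
  # the same full design
  tt <- (keep - 1) * 1
  hrf <- canonical_hrf(seq(0, 32, by = 1))
  regs <- sapply(c("LIVE", "REPLAY"), function(cc) {
    bb <- sched[sched$condition == cc, ]
    box <- numeric(510)
    t_all <- 0:509
    for (i in seq_len(nrow(bb))) {
      box[t_all >= bb$onset_s[i] & t_all < bb$onset_s[i] + bb$duration_s[i]] <- 1
    }
    as.numeric(stats::convolve(box, rev(hrf), type = "open"))[1:510][keep]
  })
  X <- cbind(1, regs, dct)
  ora <- Y[keep, ] - X %*% solve(t(X) %*% X, t(X) %*% Y[keep, ])
  expect_equal(res$data, unname(ora), tolerance = 1e-8)
})

test_that("pure task signal is annihilated by residualization", {
  sched <- make_block_schedule(n_runs = 2, seed = 2)
  hrf <- canonical_hrf(seq(0, 32, by = 1))
  task_col <- function(cond, amp) {
    unlist(lapply(1:2, function(r) {
      bb <- sched[sched$run == r & sched$condition == cond, ]
      box <- numeric(510)
      t_all <- 0:509
      for (i in seq_len(nrow(bb))) {
        box[t_all >= bb$onset_s[i] & t_all < bb$onset_s[i] + bb$duration_s[i]] <- 1
      }
      amp * as.numeric(stats::convolve(box, rev(hrf), type = "open"))[1:510]
    }))
  }
  Y <- cbind(
    task_col("LIVE", 3), task_col("REPLAY", -2),
    task_col("LIVE", 1) + task_col("REPLAY", 4)
  )
  vset <- voxel_series_set(Y, tr = 1, run = rep(1:2, each = 510))
  res <- glm_residualize(vset, sched)
  ratio <- sqrt(sum(res$data^2)) / sqrt(sum(Y[c(11:510, 521:1020), ]^2))
  expect_lt(ratio, 1e-6)
})

test_that("volume bookkeeping: 4 runs drop to 2000 analyzed volumes", {
  sched <- make_block_schedule(seed = 3)
  Y <- matrix(rnorm(4 * 510 * 2), 4 * 510, 2)
  vset <- voxel_series_set(Y, tr = 1, run = rep(1:4, each = 510))
  res <- glm_residualize(vset, sched, drop_initial = 10)
  expect_equal(nrow(res$data), 4 * 500)
  expect_equal(attr(res, "n_dropped"), 40)
})

test_that("condition concatenation: canonical LIVE has 640 volumes", {
  sched <- make_block_schedule(seed = 4)
  Y <- matrix(rnorm(4 * 510), 4 * 510, 1)
  vset <- voxel_series_set(Y, tr = 1, run = rep(1:4, each = 510))
  res <- glm_residualize(vset, sched, drop_initial = 10)
  expect_equal(nrow(split_concat_condition(res, sched, "LIVE")$data), 640)
  expect_equal(nrow(split_concat_condition(res, sched, "REPLAY")$data), 640)
})

test_that("a single 20 s block at TR 1 contributes 20 volumes (half-open)", {
  sched <- make_block_schedule(
    n_runs = 1, blocks_per_condition = 1, block_s = 20, initial_rest_s = 30, seed = 5
  )
  vset <- voxel_series_set(matrix(rnorm(90), 90, 1), tr = 1)
  out <- split_concat_condition(vset, sched, "LIVE")
  expect_equal(nrow(out$data), 20)
  blk <- sched[sched$condition == "LIVE", ]
  # hand enumeration of the half-open [onset, onset + 20) rule
  expect_equal(out$time_s, seq(blk$onset_s, blk$onset_s + 19))
})

test_that("identical participants give r = 1 up to the clamp guard", {
  vset <- voxel_series_set(matrix(rnorm(200), 100, 2), tr = 1)
  sm <- voxelwise_sync(vset, vset)
  expect_true(all(sm$r == 1 - 1e-12))
  expect_true(all(sm$z == atanh(1 - 1e-12)))
})

test_that("sync is invariant to per-voxel affine rescaling", {
  set.seed(91)
  a <- voxel_series_set(matrix(rnorm(300), 100, 3), tr = 1)
  b <- voxel_series_set(matrix(rnorm(300), 100, 3), tr = 1)
  base <- voxelwise_sync(a, b)
  a2 <- voxel_series_set(sweep(a$data %*% diag(c(2, 5, 0.1)), 2, c(-3, 7, 100), "+"), tr = 1)
  expect_equal(voxelwise_sync(a2, b)$r, base$r, tolerance = 1e-12)
})

test_that("zero-variance voxels get z = 0 with a warning", {
  a <- voxel_series_set(cbind(rnorm(50), rep(1, 50)), tr = 1)
  b <- voxel_series_set(matrix(rnorm(100), 50, 2), tr = 1)
  expect_warning(sm <- voxelwise_sync(a, b), "zero-variance")
  expect_equal(sm$z[2], 0)
})

test_that("null Fisher z spread matches 1/sqrt(n - 3)", {
  sim <- simulate_voxel_pair(n_voxels = 3000, n_volumes = 640, shared_rho = 0, seed = 92)
  sm <- voxelwise_sync(sim$a, sim$b)
  expect_lt(abs(sd(sm$z) * sqrt(637) - 1), 0.1)
})

test_that("paired contrast: identical map sets give t = 0 everywhere", {
  set.seed(93)
  maps <- lapply(1:4, function(i) {
    v <- voxel_series_set(matrix(rnorm(200), 50, 4), tr = 1)
    w <- voxel_series_set(matrix(rnorm(200), 50, 4), tr = 1)
    voxelwise_sync(v, w)
  })
  res <- paired_sync_contrast(maps, maps)
  expect_true(all(res$statistic == 0))
  expect_error(paired_sync_contrast(maps[1:2], maps[1:2]), "3 pairs")
})

test_that("paired contrast matches hand arithmetic on 3 pairs x 2 voxels", {
  mk <- function(z) {
    out <- tibble::tibble(voxel = c("v1", "v2"), r = tanh(z), z = z)
    structure(out, class = c("sync_map", class(out)))
  }
  a <- list(mk(c(0.5, 0.1)), mk(c(0.7, 0.0)), mk(c(0.6, 0.2)))
  b <- list(mk(c(0.1, 0.1)), mk(c(0.2, 0.1)), mk(c(0.3, 0.0)))
  res <- paired_sync_contrast(a, b)
  d1 <- c(0.4, 0.5, 0.3) # voxel 1 differences
  d2 <- c(0.0, -0.1, 0.2)
  expect_equal(res$mean_dz, c(mean(d1), mean(d2)))
  expect_equal(
    res$statistic,
    c(
      mean(d1) / (sd(d1) / sqrt(3)),
      mean(d2) / (sd(d2) / sqrt(3))
    ),
    tolerance = 1e-12
  )
  expect_equal(res$df, c(2, 2))
})

test_that("LIVE-specific planted synchronization is localized by the contrast", {
  sched <- make_block_schedule(n_runs = 2, seed = 6)
  live_maps <- list()
  replay_maps <- list()
  for (p in 1:6) {
    sim <- simulate_voxel_pair(
      n_voxels = 60, shared_rho = 0.05, task_amp = 1, schedule = sched,
      seed = 900 + p, live_rho = 0.6, live_voxels = 1:10
    )
    ra <- glm_residualize(sim$a, sched)
    rb <- glm_residualize(sim$b, sched)
    live_maps[[p]] <- voxelwise_sync(
      split_concat_condition(ra, sched, "LIVE"),
      split_concat_condition(rb, sched, "LIVE")
    )
    replay_maps[[p]] <- voxelwise_sync(
      split_concat_condition(ra, sched, "REPLAY"),
      split_concat_condition(rb, sched, "REPLAY")
    )
  }
  res <- paired_sync_contrast(live_maps, replay_maps)
  top10 <- order(-res$statistic)[1:10]
  expect_gte(length(intersect(top10, 1:10)), 8)
})
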
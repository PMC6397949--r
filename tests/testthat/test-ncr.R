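test_that("zero coefficients give the identity transfer function", {
  fit <- fake_mvar_fit(a = 0, b = 0, c = 0, d = 0)
  spec <- transfer_functions(fit, n_freqs = 65)
  expect_true(all(abs(spec$alpha_sq - 1) < 1e-12))
  expect_true(all(spec$beta_sq == 0))
  expect_true(all(spec$gamma_sq == 0))
  expect_true(all(abs(spec$delta_sq - 1) < 1e-12))
  expect_equal(range(spec$freq_hz), c(0, 15))
})

test_that("scalar AR(1) with a1 = 0.5 has |alpha(0)|^2 = 4", {
  fit <- fake_mvar_fit(a = 0.5, b = 0, c = 0, d = 0)
  spec <- transfer_functions(fit, n_freqs = 33)
  expect_equal(spec$alpha_sq[1], 1 / (1 - 0.5)^2, tolerance = 1e-12)
})

test_that("direct inversion matches the truncated impulse-response FFT oracle", {
  set.seed(41)
  fit <- fake_mvar_fit(
    a = c(0.4, -0.3), b = c(0.2, 0.1), c = c(-0.1, 0.05), d = c(0.3, -0.2)
  )
  spec <- transfer_functions(fit, n_freqs = 17)
  ora <- oracle_transfer_fft(fit, spec$freq_hz, fs = 30, len = 2048)
  expect_equal(spec$alpha_sq, ora[, 1], tolerance = 1e-6)
  expect_equal(spec$beta_sq, ora[, 2], tolerance = 1e-6)
  expect_equal(spec$gamma_sq, ora[, 3], tolerance = 1e-6)
  expect_equal(spec$delta_sq, ora[, 4], tolerance = 1e-6)
})

test_that("unstable fits are rejected with the spectral radius named", {
  fit <- fake_mvar_fit(a = 1.05, b = 0, c = 0, d = 0)
  expect_error(transfer_functions(fit), "1.05")
})

test_that("NCR is zero without cross-coefficients and bounded always", {
  fit0 <- fake_mvar_fit(a = 0.6, b = 0, c = 0.2, d = 0.3)
  spec0 <- compute_ncr(fit0)
  expect_true(all(spec0$ncr_y_to_x == 0)) # b == 0: y contributes nothing to x
  expect_true(all(spec0$ncr_x_to_y > 0))

  set.seed(42)
  for (i in 1:20) {
    repeat {
      cf <- runif(8, -0.45, 0.45)
      fit <- fake_mvar_fit(
        a = cf[1:2], b = cf[3:4], c = cf[5:6], d = cf[7:8],
        sigma2_ux = runif(1, 0.5, 2), sigma2_uy = runif(1, 0.5, 2)
      )
      if (blinksync:::mvar_spectral_radius(fit) < 1) break
    }
    spec <- compute_ncr(fit, n_freqs = 129)
    expect_true(all(spec$ncr_y_to_x >= 0 & spec$ncr_y_to_x <= 1))
    expect_true(all(spec$ncr_x_to_y >= 0 & spec$ncr_x_to_y <= 1))
  }
})

test_that("a fully symmetric fit has symmetric NCR", {
  fit <- fake_mvar_fit(a = c(0.3, 0.1), b = c(0.2, -0.1), c = c(0.2, -0.1), d = c(0.3, 0.1))
  spec <- compute_ncr(fit)
  expect_equal(spec$ncr_y_to_x, spec$ncr_x_to_y, tolerance = 1e-12)
})

test_that("NCR matches the noise-silencing simulation oracle", {
  # ground-truth coupled AR(1): y drives x
  a1 <- 0.5; b1 <- 0.4; d1 <- 0.5
  A <- list(matrix(c(a1, 0, b1, d1), 2, 2))
  n <- 200000
  both <- simulate_var(A, n = n, seed = 43)
  # silence x's own innovations: x is then driven purely by y's noise
  set.seed(43) # same innovations as simulate_var's internals
  e <- cbind(rnorm(n + 200), rnorm(n + 200))
  xs <- matrix(0, n + 200, 2)
  for (t in 2:(n + 200)) {
    xs[t, 2] <- d1 * xs[t - 1, 2] + e[t, 2]
    xs[t, 1] <- a1 * xs[t - 1, 1] + b1 * xs[t - 1, 2] # u_x silenced
  }
  x_sil <- xs[201:(n + 200), 1]

  welch <- function(v) {
    sp <- stats::spec.pgram(v, spans = c(101, 101), taper = 0, detrend = FALSE, plot = FALSE)
    sp
  }
  sp_tot <- welch(both[, 1])
  sp_sil <- welch(x_sil)

  fit <- fake_mvar_fit(a = a1, b = b1, c = 0, d = d1, fs = 1)
  spec <- compute_ncr(fit, n_freqs = 513, fs = 1)
  model_tot <- spec$alpha_sq * 1 + spec$beta_sq * 1
  model_at <- function(fr, vals) approx(spec$freq_hz, vals, xout = fr)$y

  bands <- cut(sp_tot$freq, breaks = seq(0, 0.5, length.out = 9))
  # band-averaged model-implied spectrum vs Welch periodogram of x
  for (bd in levels(bands)) {
    sel <- bands == bd
    est <- mean(sp_tot$spec[sel])
    mod <- mean(model_at(sp_tot$freq[sel], model_tot))
    expect_lt(abs(est - mod) / mod, 0.10)
  }
  # band-averaged empirical NCR (silenced / total power) vs analytic NCR
  ncr_emp <- sp_sil$spec / sp_tot$spec
  for (bd in levels(bands)) {
    sel <- bands == bd
    est <- mean(ncr_emp[sel])
    mod <- mean(model_at(sp_tot$freq[sel], spec$ncr_y_to_x))
    expect_lt(abs(est - mod), 0.05)
  }
})

test_that("trapezoidal integration of the NCR spectrum is exact on knowns", {
  fit <- fake_mvar_fit(a = 0.3, b = 0.2, c = 0.1, d = 0.2)
  spec <- compute_ncr(fit, n_freqs = 201)
  # constant spectrum: overwrite with c = 0.25 -> integral 15 * 0.25
  spec$ncr_y_to_x <- rep(0.25, nrow(spec))
  expect_equal(integrate_ncr(spec), 0.25 * 15)
  spec$ncr_y_to_x <- rep(0, nrow(spec))
  expect_equal(integrate_ncr(spec), 0)
})

test_that("trapezoid matches hand arithmetic on a 5-point toy", {
  toy <- tibble::tibble(
    freq_hz = c(0, 2, 5, 10, 15),
    ncr_y_to_x = c(0, 0.2, 0.4, 0.1, 0)
  )
  # hand: 0.2 + 0.9 + 1.25 + 0.25 = 2.6
  expect_equal(integrate_ncr(toy), 2.6)
})

test_that("participant-level summary averages the per-block values", {
  set.seed(44)
  x <- rnorm(450)
  y <- 0.5 * dplyr::lag(x, 2, default = 0) + rnorm(450)
  one <- blinksync:::sigma_ncr_block(x, y, fs = 30)

  blocks <- dplyr::bind_rows(lapply(1:4, function(b) {
    tibble::tibble(run = 1L, block = b, x = x, y = y)
  }))
  res <- participant_sigma_ncr(blocks, fs = 30)
  expect_equal(nrow(res$blocks), 4)
  expect_equal(res$mean, one$sigma_ncr_y_to_x, tolerance = 1e-10)
  expect_equal(res$mean, mean(res$blocks$sigma_ncr), tolerance = 1e-12)
})

test_that("degenerate blocks are skipped with a warning, not fatal", {
  set.seed(45)
  good <- tibble::tibble(run = 1L, block = 1L, x = rnorm(450), y = rnorm(450))
  bad <- tibble::tibble(run = 1L, block = 2L, x = rep(1, 450), y = rnorm(450))
  expect_warning(
    res <- participant_sigma_ncr(dplyr::bind_rows(good, bad), fs = 30),
    "skipped"
  )
  expect_equal(sum(res$blocks$skipped), 1)
  expect_false(is.na(res$mean))
})

test_that("enhancement is the difference from the REST baseline", {
  expect_equal(enhanced_sigma_ncr(1.2, 0.4), 0.8)
  expect_equal(enhanced_sigma_ncr(0.7, 0.7), 0)
  expect_equal(enhanced_sigma_ncr(c(1, 2), c(0.5, 0.5)), c(0.5, 1.5))
})
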
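#' Frequency-response (transfer) functions of a bivariate AR fit
#'
#' For lag matrices `A_k = [[a_k, b_k], [c_k, d_k]]`, the transfer matrix at
#' frequency `f` is `H(f) = [I - sum_k A_k exp(-2 pi i f k / fs)]^{-1}`,
#' evaluated by direct inversion of the 2 x 2 lag polynomial (mathematically
#' identical to Fourier-transforming the impulse response, without
#' truncation error). `alpha(f)` and `beta(f)` are the first row of `H`
#' (the response of `x` to its own and to the partner's innovations);
#' `gamma`, `delta` the second row. The grid is `n_freqs` uniform points on
#' `[0, fs/2]`. The fit must be stable (companion-matrix spectral
#' radius < 1).
#'
#' @param fit An [fit_mvar()] object.
#' @param n_freqs Number of frequency-grid points (>= 2).
#' @param fs Sampling rate (Hz); defaults to the fit's.
#' @return An `ncr_spectrum` tibble: `freq_hz`, `alpha_sq`, `beta_sq`,
#'   `gamma_sq`, `delta_sq` (squared moduli), with the fit's noise variances
#'   attached as attributes.
#' @export
transfer_functions <- function(fit, n_freqs = 513, fs = NULL) {
  stopifnot(inherits(fit, "mvar_fit"))
  fs <- fs %||% fit$fs
  if (is.null(fs)) abort("sampling rate unknown: supply `fs`.")
  if (n_freqs < 2) abort("`n_freqs` must be >= 2.")
  rad <- mvar_spectral_radius(fit)
  if (rad >= 1) {
    abort(sprintf("unstable AR fit: companion spectral radius %.4f >= 1.", rad))
  }
  freqs <- seq(0, fs / 2, length.out = n_freqs)
  E <- exp(-2i * pi * outer(freqs, seq_len(fit$order)) / fs) # n_freqs x N
  s11 <- 1 - as.vector(E %*% fit$a)
  s12 <- -as.vector(E %*% fit$b)
  s21 <- -as.vector(E %*% fit$c)
  s22 <- 1 - as.vector(E %*% fit$d)
  det <- s11 * s22 - s12 * s21
  out <- tibble::tibble(
    freq_hz = freqs,
    alpha_sq = Mod(s22 / det)^2,
    beta_sq = Mod(-s12 / det)^2,
    gamma_sq = Mod(-s21 / det)^2,
    delta_sq = Mod(s11 / det)^2
  )
  structure(out,
    fs = fs, order = fit$order,
    sigma2_ux = fit$sigma2_ux, sigma2_uy = fit$sigma2_uy,
    spectral_radius = rad,
    class = c("ncr_spectrum", class(out))
  )
}

# Spectral radius of the 2N x 2N companion matrix of the fitted lag
# polynomial; < 1 iff the AR process is stable.
mvar_spectral_radius <- function(fit) {
  N <- fit$order
  A_top <- matrix(0, 2, 2 * N)
  for (k in seq_len(N)) {
    A_top[, (2 * k - 1):(2 * k)] <- matrix(
      c(fit$a[k], fit$c[k], fit$b[k], fit$d[k]), 2, 2
    )
  }
  comp <- rbind(A_top, cbind(diag(2 * (N - 1) + 2)[seq_len(2 * N - 2), , drop = FALSE]))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Noise contribution ratio spectrum
#'
#' Decomposes the model-implied power spectrum of each series into the parts
#' driven by its own and by the partner's innovation noise, and forms the
#' noise contribution ratio
#' \deqn{NCR_{y \to x}(f) = \frac{|\beta(f)|^2 \sigma^2_{uy}}
#'   {|\alpha(f)|^2 \sigma^2_{ux} + |\beta(f)|^2 \sigma^2_{uy}}}
#' (and symmetrically for `x -> y`). The ratio lies in `[0, 1]` at every
#' frequency and is identically 0 when the corresponding cross-coefficients
#' vanish.
#'
#' @inheritParams transfer_functions
#' @return The [transfer_functions()] tibble with `ncr_y_to_x` and
#'   `ncr_x_to_y` columns added.
#' @export
compute_ncr <- function(fit, n_freqs = 513, fs = NULL) {
  spec <- transfer_functions(fit, n_freqs = n_freqs, fs = fs)
  s2x <- attr(spec, "sigma2_ux")
  s2y <- attr(spec, "sigma2_uy")
  den_x <- spec$alpha_sq * s2x + spec$beta_sq * s2y
  den_y <- spec$gamma_sq * s2x + spec$delta_sq * s2y
  if (any(den_x <= 0) || any(den_y <= 0)) {
    abort("zero spectral density encountered; NCR undefined.")
  }
  spec$ncr_y_to_x <- spec$beta_sq * s2y / den_x
  spec$ncr_x_to_y <- spec$gamma_sq * s2x / den_y
  stopifnot(
    all(spec$ncr_y_to_x >= 0 & spec$ncr_y_to_x <= 1),
    all(spec$ncr_x_to_y >= 0 & spec$ncr_x_to_y <= 1)
  )
  spec
}

#' Integrate an NCR spectrum over frequency
#'
#' Trapezoidal integration of the noise contribution ratio over
#' `[0, fs/2]`, giving the scalar directional-influence index (units Hz).
#'
#' @param spectrum A [compute_ncr()] tibble.
#' @param direction `"y_to_x"` (default) or `"x_to_y"`.
#' @return The integral (scalar, Hz), between 0 and `fs/2`.
#' @export
integrate_ncr <- function(spectrum, direction = c("y_to_x", "x_to_y")) {
  direction <- match.arg(direction)
  col <- paste0("ncr_", direction)
  if (!col %in% names(spectrum)) abort("spectrum lacks NCR columns; run compute_ncr().")
  trapezoid(spectrum$freq_hz, spectrum[[col]])
}

# One block: detrend both series, select the order by AIC, fit, and
# integrate the NCR in both directions. Returns a one-row tibble.
sigma_ncr_block <- function(x, y, max_order = 10, n_freqs = 513, fs) {
  xd <- detrend_vector(x)
  yd <- detrend_vector(y)
  sel <- select_order(xd, yd, max_order = max_order, fs = fs)
  spec <- compute_ncr(sel$fit, n_freqs = n_freqs, fs = fs)
  tibble::tibble(
    order = sel$order,
    sigma_ncr_y_to_x = integrate_ncr(spec, "y_to_x"),
    sigma_ncr_x_to_y = integrate_ncr(spec, "x_to_y"),
    residual_corr = sel$fit$residual_corr
  )
}

#' Pair two segmented series block by block
#'
#' Joins two [segment_blocks()] tibbles (the participant's own series `x`
#' and the influencing series `y` -- the partner's face or the screen) on
#' run, block, and sample index, producing the per-block paired input of
#' [participant_sigma_ncr()].
#'
#' @param blocks_x,blocks_y Segmented tibbles with identical block structure
#'   and per-block sample counts.
#' @return A tibble: `run`, `block`, `condition`, `time_s` (from `x`), `x`,
#'   `y`; attribute `fs`.
#' @export
pair_block_series <- function(blocks_x, blocks_y) {
  kx <- dplyr::count(blocks_x, .data$run, .data$block)
  ky <- dplyr::count(blocks_y, .data$run, .data$block)
  if (!identical(kx$n, ky$n) || !identical(kx$run, ky$run) ||
      !identical(kx$block, ky$block)) {
    abort("the two segmented series have different block structures.")
  }
  out <- tibble::tibble(
    run = blocks_x$run, block = blocks_x$block, condition = blocks_x$condition,
    time_s = blocks_x$time_s, x = blocks_x$value, y = blocks_y$value
  )
  structure(out, fs = attr(blocks_x, "fs"), class = class(out))
}

#' Per-participant integrated NCR across blocks
#'
#' Runs the full per-block chain -- linear detrend, AIC order selection
#' (orders `1 .. max_order`), bivariate AR fit, NCR spectrum, trapezoidal
#' integration -- for every block of a paired tibble, then averages the
#' per-block values into the participant-level summary. Blocks whose fit is
#' unstable (or singular) are skipped with a warning and excluded from the
#' mean.
#'
#' @param blocks A [pair_block_series()] tibble (columns `run`, `block`,
#'   `x`, `y`).
#' @param direction Which integral to summarize: `"y_to_x"` (influence of
#'   the partner/screen on the participant; default) or `"x_to_y"`.
#' @param max_order,n_freqs,fs Passed to the per-block chain.
#' @return A list: `mean`, the across-block mean; `blocks`, a tibble
#'   (`run`, `block`, `order`, `sigma_ncr`, `residual_corr`, `skipped`).
#' @export
participant_sigma_ncr <- function(blocks, direction = c("y_to_x", "x_to_y"),
                                  max_order = 10, n_freqs = 513, fs = NULL) {
  direction <- match.arg(direction)
  fs <- fs %||% attr(blocks, "fs")
  if (is.null(fs)) abort("sampling rate unknown: supply `fs`.")
  if (nrow(blocks) == 0) abort("no blocks supplied.")
  keys <- dplyr::distinct(blocks, .data$run, .data$block)
  rows <- purrr::map(seq_len(nrow(keys)), function(i) {
    sub <- blocks[blocks$run == keys$run[i] & blocks$block == keys$block[i], ]
    res <- tryCatch(
      withCallingHandlers(
        sigma_ncr_block(sub$x, sub$y, max_order = max_order, n_freqs = n_freqs, fs = fs),
        warning = function(w) invokeRestart("muffleWarning")
      ),
      error = function(e) {
        warn(sprintf(
          "block %d of run %d skipped: %s", keys$block[i], keys$run[i],
          conditionMessage(e)
        ))
        NULL
      }
    )
    if (is.null(res)) {
      tibble::tibble(
        run = keys$run[i], block = keys$block[i], order = NA_integer_,
        sigma_ncr = NA_real_, residual_corr = NA_real_, skipped = TRUE
      )
    } else {
      tibble::tibble(
        run = keys$run[i], block = keys$block[i], order = res$order,
        sigma_ncr = res[[paste0("sigma_ncr_", direction)]],
        residual_corr = res$residual_corr, skipped = FALSE
      )
    }
  })
  tab <- dplyr::bind_rows(rows)
  list(mean = mean(tab$sigma_ncr[!tab$skipped]), blocks = tab)
}

#' Enhancement of integrated NCR over the REST baseline
#'
#' The condition-specific increase in directional influence: the
#' participant's condition value minus their REST value.
#'
#' @param condition_value,rest_value Participant-level integrated NCR values
#'   (vectorized).
#' @return `condition_value - rest_value`.
#' @export
enhanced_sigma_ncr <- function(condition_value, rest_value) {
  condition_value - rest_value
}
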
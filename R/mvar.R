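#' Fit a bivariate autoregressive model by least squares
#'
#' Models each of two series as a lagged linear combination of both:
#' \deqn{x_t = \sum_{i=1}^N a_i x_{t-i} + \sum_{i=1}^N b_i y_{t-i} + u_{x,t}}
#' \deqn{y_t = \sum_{i=1}^N c_i x_{t-i} + \sum_{i=1}^N d_i y_{t-i} + u_{y,t}}
#' estimated by ordinary least squares on the joint regression over
#' `t = N+1, ..., T` (equivalently per-equation OLS; no intercept -- series
#' are expected to be detrended). Residual variances use denominator
#' `T - N`, and the residual cross-correlation is reported: the noise
#' contribution ratio presumes near-independent innovations, so a warning is
#' issued when it exceeds 0.2 in magnitude.
#'
#' @param x,y Numeric vectors or [me_series()] tibbles of equal length `T`
#'   with `T > 10 * order`.
#' @param order Model order `N` (number of lags).
#' @param fs Sampling rate (Hz); taken from `x` when it is an `me_series`.
#' @param start First predicted index (default `order + 1`); raising it lets
#'   candidate orders share an estimation sample (see [select_order()]).
#' @return An object of class `mvar_fit`: `order`, coefficient vectors `a`,
#'   `b`, `c`, `d`, residual variances `sigma2_ux`, `sigma2_uy`,
#'   `residual_corr`, `aic`, `n_samples`, `n_used`, `fs`.
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = 0.5), 500))
#' y <- rnorm(500)
#' fit_mvar(x, y, order = 2)
#' @export
fit_mvar <- function(x, y, order, fs = NULL, start = order + 1) {
  if (inherits(x, "me_series") || is.data.frame(x)) {
    fs <- fs %||% attr(x, "fs")
    x <- x$value
  }
  if (inherits(y, "me_series") || is.data.frame(y)) y <- y$value
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  order <- as.integer(order)
  if (order < 1) abort("`order` must be >= 1.")
  if (n <= 10 * order) abort("need more than 10 * order samples.")
  if (start < order + 1) abort("`start` must be at least order + 1.")

  if (var(x) == 0 || var(y) == 0) {
    abort("singular lag design (constant or collinear series); cannot fit.")
  }
  idx <- start:n
  lagmat <- function(v) {
    vapply(seq_len(order), function(i) v[idx - i], numeric(length(idx)))
  }
  Z <- cbind(lagmat(x), lagmat(y)) # [x lags 1..N | y lags 1..N]
  Y <- cbind(x[idx], y[idx])
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    abort("singular lag design (constant or collinear series); cannot fit.")
  }
  B <- qr.coef(qz, Y)
  resid <- Y - Z %*% B
  n_used <- length(idx)
  sigma2 <- colSums(resid^2) / (n - order)
  if (any(sigma2 <= 0)) abort("degenerate fit: zero residual variance.")
  rcorr <- suppressWarnings(cor(resid[, 1], resid[, 2]))
  if (!is.finite(rcorr)) rcorr <- 0
  if (abs(rcorr) > 0.2) {
    warn(sprintf(
      "residual cross-correlation %.3f exceeds 0.2; the NCR independence assumption is strained.",
      rcorr
    ))
  }
  sig_ml <- crossprod(resid) / n_used
  aic <- n_used * log(det(sig_ml)) + 2 * (4 * order + 2)

  structure(
    list(
      order = order,
      a = unname(B[seq_len(order), 1]), b = unname(B[order + seq_len(order), 1]),
      c = unname(B[seq_len(order), 2]), d = unname(B[order + seq_len(order), 2]),
      sigma2_ux = unname(sigma2[1]), sigma2_uy = unname(sigma2[2]),
      residual_corr = rcorr, aic = aic,
      n_samples = n, n_used = n_used, fs = fs
    ),
    class = "mvar_fit"
  )
}

#' @export
print.mvar_fit <- function(x, ...) {
  cat(sprintf(
    "<mvar_fit> order %d on %d samples | AIC %.2f | sigma2 (%.4g, %.4g) | resid corr %.3f\n",
    x$order, x$n_samples, x$aic, x$sigma2_ux, x$sigma2_uy, x$residual_corr
  ))
  invisible(x)
}

#' @describeIn fit_mvar Coefficients in long form: one row per
#'   (equation term, lag).
#' @param x An `mvar_fit`.
#' @param ... Unused.
#' @method tidy mvar_fit
#' @export
tidy.mvar_fit <- function(x, ...) {
  tibble::tibble(
    term = rep(c("a", "b", "c", "d"), each = x$order),
    lag = rep(seq_len(x$order), 4),
    estimate = c(x$a, x$b, x$c, x$d)
  )
}

#' @describeIn fit_mvar One-row model summary.
#' @method glance mvar_fit
#' @export
glance.mvar_fit <- function(x, ...) {
  tibble::tibble(
    order = x$order, aic = x$aic,
    sigma2_ux = x$sigma2_ux, sigma2_uy = x$sigma2_uy,
    residual_corr = x$residual_corr, n_samples = x$n_samples
  )
}

#' Select the autoregressive order by AIC
#'
#' Fits candidate orders `1 .. max_order` on a common estimation sample
#' (`t = max_order + 1, ..., T`, so every candidate predicts the same
#' observations) and picks the order minimizing the multivariate Gaussian
#' AIC, `n log det(Sigma_hat) + 2 (4N + 2)`; ties go to the smallest order.
#'
#' @inheritParams fit_mvar
#' @param max_order Largest candidate order (default 10).
#' @return A list: `order` (the minimizer), `aic` (tibble `order`, `aic`
#'   with `max_order` rows), and `fit`, the model refit at the selected
#'   order on the full sample.
#' @export
select_order <- function(x, y, max_order = 10, fs = NULL) {
  if (inherits(x, "me_series") || is.data.frame(x)) {
    fs <- fs %||% attr(x, "fs")
  }
  max_order <- as.integer(max_order)
  if (max_order < 1) abort("`max_order` must be >= 1.")
  aics <- vapply(seq_len(max_order), function(N) {
    withCallingHandlers(
      fit_mvar(x, y, order = N, fs = fs, start = max_order + 1)$aic,
      warning = function(w) invokeRestart("muffleWarning")
    )
  }, numeric(1))
  best <- which.min(aics) # which.min returns the first (smallest N) on ties
  list(
    order = best,
    aic = tibble::tibble(order = seq_len(max_order), aic = aics),
    fit = fit_mvar(x, y, order = best, fs = fs)
  )
}
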
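# Independent oracles used across tests. Each is deliberately written the
# dumb, direct way (explicit loops, explicit normal equations, stock base-R
# model fitters) so it shares no code path with the package implementation.

# Mean absolute frame difference by explicit double loop over ROI pixels.
oracle_motion_energy <- function(frames, rows, cols) {
  n <- dim(frames)[1]
  out <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    acc <- 0
    for (i in rows) {
      for (j in cols) {
        acc <- acc + abs(frames[k + 1, i, j] - frames[k, i, j])
      }
    }
    out[k] <- acc / (length(rows) * length(cols))
  }
  out
}

# Joint bivariate AR(N) least squares via explicitly assembled normal
# equations solve(Z'Z, Z'y), one equation at a time.
oracle_mvar <- function(x, y, N) {
  T <- length(x)
  idx <- (N + 1):T
  Z <- matrix(0, length(idx), 2 * N)
  for (i in seq_len(N)) {
    Z[, i] <- x[idx - i]
    Z[, N + i] <- y[idx - i]
  }
  bx <- solve(t(Z) %*% Z, t(Z) %*% x[idx])
  by <- solve(t(Z) %*% Z, t(Z) %*% y[idx])
  rx <- x[idx] - Z %*% bx
  ry <- y[idx] - Z %*% by
  list(
    a = bx[1:N], b = bx[N + 1:N], c = by[1:N], d = by[N + 1:N],
    sigma2_ux = sum(rx^2) / (T - N), sigma2_uy = sum(ry^2) / (T - N)
  )
}

# Transfer functions via the literal route: simulate the bivariate impulse
# response by recursion, truncate, and FFT it.
oracle_transfer_fft <- function(fit, freqs, fs, len = 2048) {
  N <- fit$order
  A <- lapply(seq_len(N), function(k) {
    matrix(c(fit$a[k], fit$c[k], fit$b[k], fit$d[k]), 2, 2)
  })
  # impulse response h[k] (2x2): response at lag k to unit innovations
  h <- vector("list", len)
  for (k in seq_len(len)) {
    hk <- if (k == 1) diag(2) else matrix(0, 2, 2)
    for (j in seq_len(min(N, k - 1))) {
      hk <- hk + A[[j]] %*% h[[k - j]]
    }
    h[[k]] <- hk
  }
  t(vapply(freqs, function(f) {
    zk <- exp(-2i * pi * f * (0:(len - 1)) / fs)
    H <- Reduce(`+`, Map(function(hk, z) hk * z, h, as.list(zk)))
    c(
      Mod(H[1, 1])^2, Mod(H[1, 2])^2,
      Mod(H[2, 1])^2, Mod(H[2, 2])^2
    )
  }, numeric(4)))
}

# Within-subject ANOVA through base R's aov() + Error() strata.
oracle_rm_anova_F <- function(table, dv, within, subject) {
  table[[subject]] <- factor(table[[subject]])
  for (w in within) table[[w]] <- factor(table[[w]])
  if (length(within) == 1) {
    form <- stats::as.formula(sprintf(
      "%s ~ %s + Error(%s/%s)", dv, within, subject, within
    ))
  } else {
    form <- stats::as.formula(sprintf(
      "%s ~ %s * %s + Error(%s/(%s * %s))",
      dv, within[1], within[2], subject, within[1], within[2]
    ))
  }
  fit <- stats::aov(form, data = table)
  sm <- summary(fit)
  out <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      if (terms[i] != "Residuals" && !is.na(tab[i, "F value"])) {
        out[[terms[i]]] <- c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
      }
    }
  }
  out
}

# Hand-constructable AR fit object for spectrum tests with known truth.
fake_mvar_fit <- function(a, b, c, d, sigma2_ux = 1, sigma2_uy = 1, fs = 30) {
  structure(
    list(
      order = length(a), a = a, b = b, c = c, d = d,
      sigma2_ux = sigma2_ux, sigma2_uy = sigma2_uy,
      residual_corr = 0, aic = NA_real_,
      n_samples = NA_integer_, n_used = NA_integer_, fs = fs
    ),
    class = "mvar_fit"
  )
}

# Simulate a bivariate AR process from lag matrices (list of 2x2) with
# innovation SDs; used for spectrum and order-selection ground truth.
simulate_var <- function(A, n, sd = c(1, 1), burn = 200, seed = 1) {
  set.seed(seed)
  N <- length(A)
  x <- matrix(0, n + burn, 2)
  e <- cbind(rnorm(n + burn, 0, sd[1]), rnorm(n + burn, 0, sd[2]))
  for (t in (N + 1):(n + burn)) {
    acc <- e[t, ]
    for (k in seq_len(N)) acc <- acc + A[[k]] %*% x[t - k, ]
    x[t, ] <- acc
  }
  x[(burn + 1):(burn + n), ]
}
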
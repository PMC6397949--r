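#' Voxel-by-volume time-series set
#'
#' Container for one participant's voxel time series: a volumes-by-voxels
#' matrix, the repetition time, a run identifier and within-run acquisition
#' time per volume, and stable voxel identifiers shared across participants
#' (the stand-in for identical template coordinates).
#'
#' @param data Numeric `volumes x voxels` matrix.
#' @param tr Repetition time (s).
#' @param run Integer run id per volume (default: single run).
#' @param time_s Within-run acquisition time per volume (s); default
#'   `(index within run - 1) * tr`.
#' @param voxel_ids Character identifiers, one per voxel.
#' @return A list of class `voxel_series_set`.
#' @export
voxel_series_set <- function(data, tr = 1, run = NULL, time_s = NULL,
                             voxel_ids = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) abort("voxel data must be finite.")
  n <- nrow(data)
  run <- as.integer(run %||% rep(1L, n))
  if (length(run) != n) abort("`run` must have one entry per volume.")
  if (is.null(time_s)) {
    time_s <- as.numeric(stats::ave(rep(tr, n), run, FUN = function(z) cumsum(z) - tr))
  }
  if (length(time_s) != n) abort("`time_s` must have one entry per volume.")
  voxel_ids <- voxel_ids %||% paste0("v", seq_len(ncol(data)))
  if (length(voxel_ids) != ncol(data)) abort("one voxel id per column required.")
  structure(
    list(data = data, tr = tr, run = run, time_s = time_s,
         voxel_ids = as.character(voxel_ids)),
    class = "voxel_series_set"
  )
}

#' @export
print.voxel_series_set <- function(x, ...) {
  cat(sprintf(
    "<voxel_series_set> %d volumes x %d voxels, TR %g s, %d run(s)%s\n",
    nrow(x$data), ncol(x$data), x$tr, length(unique(x$run)),
    if (isTRUE(attr(x, "residualized"))) ", residualized" else ""
  ))
  invisible(x)
}

#' Canonical double-gamma hemodynamic response
#'
#' The de facto canonical HRF: a gamma density peaking near 5--6 s minus a
#' later gamma undershoot (shape 16) scaled by `ratio`, normalized to unit
#' peak.
#'
#' @param t Time points (s).
#' @param peak_shape,undershoot_shape Gamma shape parameters (rate 1).
#' @param ratio Undershoot amplitude relative to the peak.
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak_shape = 6, undershoot_shape = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_shape, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_shape, rate = 1)
  h / max(stats::dgamma((peak_shape - 1), shape = peak_shape, rate = 1), .Machine$double.eps)
}

# Convolve a boxcar sampled at TR with the canonical HRF (32 s support).
convolve_hrf <- function(box, tr) {
  h <- canonical_hrf(seq(0, 32, by = tr))
  out <- stats::convolve(box, rev(h), type = "open")
  out[seq_along(box)]
}

# Discrete-cosine high-pass basis (SPM-style), K components on n volumes.
dct_basis <- function(n, tr, highpass_s) {
  K <- floor(2 * n * tr / highpass_s)
  if (K < 1) return(matrix(numeric(0), n, 0))
  k <- seq_len(K)
  m <- outer(seq_len(n) - 1, k, function(i, kk) cos(pi * (2 * i + 1) * kk / (2 * n)))
  colnames(m) <- paste0("dct", k)
  m
}

#' Remove task-locked signal and slow drifts from voxel series
#'
#' Per run: discards the first `drop_initial` volumes (magnetization
#' settling), then regresses out (i) each non-REST condition's boxcar
#' convolved with the canonical double-gamma HRF, (ii) a run intercept, and
#' (iii) a discrete-cosine high-pass basis with cutoff `highpass_s`. The
#' residuals -- the spontaneous fluctuations that interbrain synchronization
#' is computed on -- are returned with the original acquisition times, so a
#' schedule still addresses them correctly.
#'
#' @param vset A [voxel_series_set()].
#' @param schedule A [make_block_schedule()] covering every run in `vset`.
#' @param highpass_s High-pass cutoff period (s); 128 s by default.
#' @param drop_initial Volumes discarded at the start of each run.
#' @return A residualized `voxel_series_set` (attribute `residualized`);
#'   attribute `n_dropped` records the discarded volume count.
#' @export
glm_residualize <- function(vset, schedule, highpass_s = 128, drop_initial = 10) {
  stopifnot(inherits(vset, "voxel_series_set"))
  runs <- sort(unique(vset$run))
  if (!all(runs %in% unique(schedule$run))) {
    abort("schedule does not cover every run in the data.")
  }
  conds <- setdiff(unique(schedule$condition), "REST")
  pieces <- lapply(runs, function(r) {
    idx <- which(vset$run == r)
    tt <- vset$time_s[idx]
    keep <- seq_along(idx) > drop_initial
    if (!any(keep)) abort("`drop_initial` removes an entire run.")
    blocks <- schedule[schedule$run == r, ]
    # condition regressors built on the full run grid, then subset
    reg <- matrix(numeric(0), length(idx), 0)
    if (length(conds)) {
      reg <- sapply(conds, function(cc) {
        box <- numeric(length(idx))
        bb <- blocks[blocks$condition == cc, ]
        for (i in seq_len(nrow(bb))) {
          box[tt >= bb$onset_s[i] & tt < bb$onset_s[i] + bb$duration_s[i]] <- 1
        }
        convolve_hrf(box, vset$tr)
      })
    }
    X <- cbind(
      intercept = 1, reg[keep, , drop = FALSE],
      dct_basis(sum(keep), vset$tr, highpass_s)
    )
    colnames(X)[1 + seq_along(conds)] <- conds
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      abort(sprintf("collinear design columns in run %d: %s", r, paste(bad, collapse = ", ")))
    }
    Y <- vset$data[idx[keep], , drop = FALSE]
    list(
      resid = Y - X %*% qr.coef(qx, Y),
      run = vset$run[idx[keep]], time_s = tt[keep], dropped = sum(!keep)
    )
  })
  out <- voxel_series_set(
    do.call(rbind, lapply(pieces, `[[`, "resid")),
    tr = vset$tr,
    run = unlist(lapply(pieces, `[[`, "run")),
    time_s = unlist(lapply(pieces, `[[`, "time_s")),
    voxel_ids = vset$voxel_ids
  )
  attr(out, "residualized") <- TRUE
  attr(out, "n_dropped") <- sum(vapply(pieces, `[[`, numeric(1), "dropped"))
  out
}

#' Extract and concatenate the volumes of one condition
#'
#' Selects the volumes whose acquisition time falls inside a block of the
#' requested condition (half-open `[onset, onset + duration)` rule) and
#' concatenates them across blocks and runs in temporal order. With the
#' canonical schedule at TR 1 s, LIVE and REPLAY each yield 640 volumes.
#'
#' @param vset A (typically residualized) [voxel_series_set()].
#' @param schedule A [make_block_schedule()].
#' @param condition Condition label.
#' @param include_initial Include the initial settling REST block?
#' @return A `voxel_series_set` restricted to the selected volumes;
#'   attribute `condition` records the label.
#' @export
split_concat_condition <- function(vset, schedule, condition,
                                   include_initial = TRUE) {
  stopifnot(inherits(vset, "voxel_series_set"))
  blocks <- schedule_condition_blocks(schedule, condition, include_initial)
  sel <- rep(FALSE, nrow(vset$data))
  for (i in seq_len(nrow(blocks))) {
    sel <- sel | (vset$run == blocks$run[i] &
      vset$time_s >= blocks$onset_s[i] &
      vset$time_s < blocks$onset_s[i] + blocks$duration_s[i])
  }
  if (!any(sel)) abort(sprintf("no volumes fall in %s blocks.", condition))
  ord <- order(vset$run[sel], vset$time_s[sel])
  idx <- which(sel)[ord]
  out <- voxel_series_set(
    vset$data[idx, , drop = FALSE], tr = vset$tr,
    run = vset$run[idx], time_s = vset$time_s[idx], voxel_ids = vset$voxel_ids
  )
  attr(out, "residualized") <- attr(vset, "residualized")
  attr(out, "condition") <- condition
  out
}

#' Homologous-voxel interbrain synchronization map
#'
#' Pearson correlation between the two participants' series at each shared
#' voxel id, Fisher r-to-z transformed (`z = atanh(r)` with `r` clamped to
#' `+/-(1 - 1e-12)`). Zero-variance voxels get `z = 0` with a warning.
#'
#' @param a,b [voxel_series_set()]s with identical voxel ids and volume
#'   counts.
#' @return A tibble of class `sync_map`: `voxel`, `r`, `z`; attributes
#'   `n_volumes` and `condition` (from `a`, if present).
#' @export
voxelwise_sync <- function(a, b) {
  stopifnot(inherits(a, "voxel_series_set"), inherits(b, "voxel_series_set"))
  if (!identical(a$voxel_ids, b$voxel_ids)) abort("voxel ids differ between participants.")
  if (nrow(a$data) != nrow(b$data)) abort("volume counts differ between participants.")
  n <- nrow(a$data)
  ca <- scale(a$data, center = TRUE, scale = FALSE)
  cb <- scale(b$data, center = TRUE, scale = FALSE)
  sa <- sqrt(colSums(ca^2))
  sb <- sqrt(colSums(cb^2))
  r <- colSums(ca * cb) / (sa * sb)
  bad <- !is.finite(r)
  if (any(bad)) {
    warn(sprintf("%d zero-variance voxel(s); their z set to 0.", sum(bad)))
    r[bad] <- 0
  }
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  out <- tibble::tibble(voxel = a$voxel_ids, r = unname(r), z = atanh(unname(r)))
  out$z[bad] <- 0
  structure(out,
    n_volumes = n, condition = attr(a, "condition"),
    class = c("sync_map", class(out))
  )
}

#' Paired contrast of synchronization maps across dyads
#'
#' Per-voxel paired t test of the Fisher-z maps of two conditions across
#' pairs (one LIVE and one REPLAY map per pair). Reports uncorrected p
#' values; cluster-level family-wise inference is out of scope.
#'
#' @param z_a_maps,z_b_maps Lists of [voxelwise_sync()] maps, one per pair,
#'   all sharing the voxel set. The contrast is `a - b`.
#' @return A tibble: `voxel`, `mean_dz`, `statistic` (t), `df`, `p_value`.
#' @export
paired_sync_contrast <- function(z_a_maps, z_b_maps) {
  n <- length(z_a_maps)
  if (n != length(z_b_maps)) abort("need one map per pair in each condition.")
  if (n < 3) abort("need at least 3 pairs.")
  vox <- z_a_maps[[1]]$voxel
  za <- vapply(z_a_maps, function(m) {
    if (!identical(m$voxel, vox)) abort("voxel sets differ across maps.")
    m$z
  }, numeric(length(vox)))
  zb <- vapply(z_b_maps, function(m) {
    if (!identical(m$voxel, vox)) abort("voxel sets differ across maps.")
    m$z
  }, numeric(length(vox)))
  d <- za - zb # voxels x pairs
  md <- rowMeans(d)
  se <- apply(d, 1, sd) / sqrt(n)
  tval <- md / se
  tval[!is.finite(tval)] <- 0
  df <- n - 1
  tibble::tibble(
    voxel = vox, mean_dz = md, statistic = tval, df = df,
    p_value = 2 * pt(-abs(tval), df)
  )
}
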
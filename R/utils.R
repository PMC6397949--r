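# Internal helpers: reproducible substreams and light input checking.

# Deterministic 32-bit sub-seed from a master seed and a tag path, so each
# simulation stage (per pair, per run, per participant) draws from its own
# stream. Plain integer arithmetic; stable across platforms.
derive_seed <- function(seed, ...) {
  tag <- paste(c(...), collapse = ":")
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 1048573
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 1) %% 2147483647)
}

# Evaluate expr under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

check_number <- function(x, name, min = -Inf, strict = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must be supplied.", name))
  }
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict && x <= min) abort(sprintf("`%s` must be > %g.", name, min))
  if (!strict && x < min) abort(sprintf("`%s` must be >= %g.", name, min))
  invisible(x)
}

# Trapezoidal rule on an (x, y) grid.
trapezoid <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}
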
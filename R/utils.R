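# Internal helpers shared across modules.

# Deterministic child seed: every stochastic stage derives its seed from the
# global seed plus a stage label, so independent stages never share streams.
# FNV-1a style string hash folded into [0, 2^31 - 63).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (code in utf8ToInt(stage)) {
    h <- (h * 69069 + code) %% 2147483587  # products stay exact in doubles
  }
  as.integer((abs(seed) %% 2147483587 * 31 + h) %% 2147483587)
}

# Trapezoidal integral and cumulative integral on a (possibly non-uniform) grid.
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

cumtrapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(numeric(n))
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

# Guard: strictly increasing, uniformly spaced time grid.
check_uniform_grid <- function(t, tol = 1e-9, what = "t") {
  if (length(t) < 2L) abort(sprintf("`%s` needs at least 2 samples", what))
  dt <- diff(t)
  if (any(dt <= 0)) abort(sprintf("`%s` must be strictly increasing", what))
  if (max(dt) - min(dt) > tol) {
    abort(sprintf("`%s` must be a uniform grid (spacing varies by more than %g s)", what, tol))
  }
  invisible(mean(dt))
}

check_cols <- function(df, cols, what = "data") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_finite <- function(x, what = "values") {
  if (!all(is.finite(x))) abort(sprintf("non-finite %s encountered", what))
  invisible(x)
}

# Short content hash of a canonicalised R object (used to stamp run outputs).
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 0
  for (code in utf8ToInt(s)) {
    h <- (h * 69069 + code) %% 2147483587
  }
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
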
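#' Resample a time series onto a uniform grid by linear interpolation
#'
#' @param series Data frame with a time column `t` (strictly increasing) and
#'   one or more numeric value columns.
#' @param target_rate Target sampling rate in Hz.
#' @return Tibble on the uniform grid from the first to the last input
#'   timestamp (no extrapolation), same value columns.
#' @export
resample_linear <- function(series, target_rate) {
  series <- as_tibble(series)
  check_cols(series, "t", "series")
  if (nrow(series) < 2L) abort("resampling needs at least 2 samples")
  if (target_rate <= 0) abort("target_rate must be > 0")
  if (any(diff(series$t) <= 0)) abort("input timestamps must be strictly increasing")
  t_new <- seq(series$t[1], series$t[nrow(series)], by = 1 / target_rate)
  out <- tibble(t = t_new)
  for (col in setdiff(names(series), "t")) {
    out[[col]] <- approx(series$t, series[[col]], xout = t_new)$y
  }
  out
}

#' Amplitude and unwrapped phase of an I/Q trajectory
#'
#' Amplitude is `sqrt(I^2 + Q^2)`; phase is the four-quadrant angle of
#' `(I, Q)`, unwrapped along time. Where the amplitude falls below
#' `amp_floor` the angle is undefined, so the previous sample's phase is
#' carried forward before unwrapping.
#'
#' @param i_signal,q_signal Equal-length numeric vectors.
#' @param amp_floor Amplitude below which the phase is carried from the
#'   neighbouring sample.
#' @return List with numeric vectors `amplitude` and `phase` (rad).
#' @export
amplitude_phase <- function(i_signal, q_signal, amp_floor = 1e-12) {
  if (length(i_signal) != length(q_signal)) abort("i and q must have equal length")
  amplitude <- sqrt(i_signal^2 + q_signal^2)
  phase <- atan2(q_signal, i_signal)
  low <- which(amplitude < amp_floor)
  for (k in low) phase[k] <- if (k == 1L) 0 else phase[k - 1L]
  list(amplitude = amplitude, phase = unwrap_phase(phase))
}

unwrap_phase <- function(phase) {
  if (length(phase) < 2L) return(phase)
  d <- diff(phase)
  jumps <- -round(d / (2 * pi))
  phase + c(0, cumsum(jumps)) * 2 * pi
}

#' Zero-phase Butterworth band-pass filter
#'
#' Third-order Butterworth band-pass (0.1-16 Hz by default, the respiratory
#' band used throughout the pipeline), applied forward-backward so the filter
#' is zero-phase: event timing is the headline quantity downstream and a
#' causal pass would delay every onset by the group delay. Set
#' `causal = TRUE` for a single forward pass.
#'
#' @param x Numeric vector on a uniform grid.
#' @param sample_rate Sampling rate in Hz (must exceed `2 * high`).
#' @param low,high Band edges in Hz.
#' @param order Filter order.
#' @param causal Single forward pass instead of forward-backward.
#' @return Filtered numeric vector.
#' @export
bandpass <- function(x, sample_rate, low = 0.1, high = 16, order = 3,
                     causal = FALSE) {
  if (sample_rate <= 2 * high) abort("sample_rate must exceed twice the upper band edge")
  warmup <- 3 * order * sample_rate / low
  if (length(x) < warmup) {
    abort(sprintf("series too short for band-pass warm-up: %d samples < %g (3 x order x rate/low)",
                  length(x), warmup))
  }
  bf <- signal::butter(order, c(low, high) / (sample_rate / 2), type = "pass")
  if (causal) {
    return(as.numeric(signal::filter(bf, x)))
  }
  # odd-reflection padding before the forward-backward pass: the low band edge
  # implies a long settling time, and unpadded transients would swamp the
  # record ends by orders of magnitude
  n <- length(x)
  p <- min(n - 1L, ceiling(3 * sample_rate / low))
  xp <- c(2 * x[1] - rev(x[2:(p + 1L)]), x, 2 * x[n] - rev(x[(n - p):(n - 1L)]))
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(p + 1L):(p + n)]
}

#' Time derivative by central differences
#'
#' Central differences in the interior, one-sided at the ends; units of the
#' input per second.
#'
#' @param x Numeric vector on a uniform grid.
#' @param dt Sample interval in s.
#' @return Numeric vector of the same length.
#' @export
time_derivative <- function(x, dt) {
  n <- length(x)
  if (n < 3L) abort("derivative needs at least 3 samples")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Instantaneous angular rate of the I/Q trajectory
#'
#' The phase-related feature computed from the channel derivatives:
#' `(I dQ/dt - Q dI/dt) / (I^2 + Q^2)`, the exact derivative of the
#' four-quadrant angle, independent of trajectory radius. Where the squared
#' amplitude falls below `floor` the rate is undefined and 0 is returned.
#'
#' @param i,q,di,dq Equal-length numeric vectors (channels and their
#'   derivatives).
#' @param floor Denominator floor (scaled units).
#' @return Numeric vector, rad/s.
#' @export
phase_rate_feature <- function(i, q, di, dq, floor = 1e-12) {
  n <- length(i)
  if (any(c(length(q), length(di), length(dq)) != n)) abort("inputs must have equal length")
  denom <- i^2 + q^2
  out <- numeric(n)
  ok <- denom >= floor
  out[ok] <- (i[ok] * dq[ok] - q[ok] * di[ok]) / denom[ok]
  out
}

#' Fit a Yeo-Johnson + robust-scaling transform state
#'
#' For every feature column, estimates the maximum-likelihood Yeo-Johnson
#' power-transform exponent on the fitting rows, then records the median and
#' interquartile range of the transformed fitting data. The state is fitted
#' once (on training subjects only, when cross-validating: `fitting_mask` is
#' the leakage guard) and applied unchanged elsewhere.
#'
#' @param features Tibble with a `t` column and numeric feature columns.
#' @param fitting_mask Logical vector selecting the fitting rows (default all).
#' @param max_fit_points Cap on the number of rows used for the likelihood
#'   fit (deterministic stride subsample; the exponent is a one-dimensional
#'   ML estimate and does not need every sample).
#' @return An object of class `respiq_transform`: per-column exponent, robust
#'   center (median) and scale (IQR).
#' @export
fit_transform_state <- function(features, fitting_mask = NULL,
                                max_fit_points = 20000) {
  features <- as_tibble(features)
  cols <- setdiff(names(features), "t")
  if (is.null(fitting_mask)) fitting_mask <- rep(TRUE, nrow(features))
  if (length(fitting_mask) != nrow(features)) abort("fitting_mask length must match rows")
  rows <- purrr::map(cols, function(col) {
    x <- features[[col]][fitting_mask]
    check_finite(x, sprintf("feature column '%s'", col))
    xs <- x
    if (length(xs) > max_fit_points) {
      xs <- xs[seq(1, length(xs), length.out = max_fit_points)]
    }
    # optimiser hiccups on degenerate/heavy-tailed columns are tolerable:
    # the exponent is a shape refinement, the robust scaling below does the
    # real normalisation, so fall back to the identity exponent on failure
    lambda <- tryCatch(
      suppressWarnings(as.numeric(car::powerTransform(xs, family = "yjPower")$lambda)),
      error = function(e) 1)
    z <- car::yjPower(x, lambda)
    ctr <- median(z)
    scl <- unname(diff(quantile(z, c(0.25, 0.75), names = FALSE)))
    if (!is.finite(scl) || scl <= 0) {
      abort(sprintf("column '%s' has zero interquartile range on the fitting set", col))
    }
    tibble(column = col, lambda = lambda, center = ctr, scale = scl)
  })
  structure(list(params = dplyr::bind_rows(rows), fit_scope = "fitting-mask"),
            class = "respiq_transform")
}

#' Apply (or invert) a fitted transform state
#'
#' @param features Tibble containing every column named in `state`.
#' @param state A [fit_transform_state()] result; never mutated.
#' @param clip Winsorisation bound in robust-scale units: transformed values
#'   are clamped to `[-clip, clip]` (default `Inf`, no clipping). Regression
#'   inputs use a finite bound so that rare extreme feature excursions (the
#'   phase-rate feature near the trajectory origin) cannot drive the model
#'   outside the range it was trained on.
#' @return Tibble with the named columns transformed (power transform, then
#'   centred by the robust center and divided by the robust scale).
#' @export
apply_transform <- function(features, state, clip = Inf) {
  stopifnot(inherits(state, "respiq_transform"))
  features <- as_tibble(features)
  for (k in seq_len(nrow(state$params))) {
    p <- state$params[k, ]
    if (!p$column %in% names(features)) {
      abort(sprintf("apply_transform: column '%s' missing from features", p$column))
    }
    z <- (car::yjPower(features[[p$column]], p$lambda) - p$center) / p$scale
    features[[p$column]] <- pmin(pmax(z, -clip), clip)
  }
  features
}

#' @rdname apply_transform
#' @param z Numeric vector in transformed (scaled) units.
#' @param column Which column's parameters to invert with.
#' @return `invert_transform()`: numeric vector back in physical units.
#' @export
invert_transform <- function(z, state, column) {
  stopifnot(inherits(state, "respiq_transform"))
  p <- state$params[state$params$column == column, ]
  if (nrow(p) != 1L) abort(sprintf("no transform parameters for column '%s'", column))
  inv_yeo_johnson(z * p$scale + p$center, p$lambda)
}

# Closed-form inverse of the Yeo-Johnson transform.
inv_yeo_johnson <- function(y, lambda) {
  x <- numeric(length(y))
  pos <- y >= 0
  if (abs(lambda) > 1e-12) {
    x[pos] <- pmax(lambda * y[pos] + 1, 1e-12)^(1 / lambda) - 1
  } else {
    x[pos] <- expm1(y[pos])
  }
  if (abs(2 - lambda) > 1e-12) {
    x[!pos] <- 1 - pmax(1 - (2 - lambda) * y[!pos], 1e-12)^(1 / (2 - lambda))
  } else {
    x[!pos] <- -expm1(-y[!pos])
  }
  x
}

#' Build the five-feature matrix from a raw I/Q record
#'
#' Fixed pipeline order: resample both channels to the feature grid by linear
#' interpolation; derive amplitude and unwrapped phase; band-pass each of the
#' four channels (0.1-16 Hz, zero-phase); differentiate each; compute the
#' phase-rate feature from the band-passed channels and their derivatives;
#' finally apply the power transform + robust scaling. Errors raised by a
#' stage are re-signalled with the stage name.
#'
#' @param iq Tibble with columns `t`, `i`, `q`.
#' @param state Either `"fit"` (fit the transform on all rows of this record
#'   and attach it as attribute `"transform_state"`), `"raw"` (return
#'   untransformed features, e.g. so a cross-validation fold can fit its own
#'   state), or a [fit_transform_state()] object to apply.
#' @param sample_rate Feature grid rate in Hz (default 100).
#' @param low,high,order,causal Band-pass settings, see [bandpass()].
#' @return Tibble with columns `t`, `d_i`, `d_q`, `d_amp`, `d_phase`,
#'   `phase_rate`.
#' @export
build_features <- function(iq, state = "fit", sample_rate = 100,
                           low = 0.1, high = 16, order = 3, causal = FALSE) {
  check_cols(iq, c("t", "i", "q"), "iq")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("feature stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  rs <- stage("resample", resample_linear(iq, sample_rate))
  dt <- 1 / sample_rate
  ap <- stage("amplitude_phase", amplitude_phase(rs$i, rs$q))
  bp <- stage("bandpass", list(
    i = bandpass(rs$i, sample_rate, low, high, order, causal),
    q = bandpass(rs$q, sample_rate, low, high, order, causal),
    amp = bandpass(ap$amplitude, sample_rate, low, high, order, causal),
    phase = bandpass(ap$phase, sample_rate, low, high, order, causal)))
  dv <- stage("derivative", purrr::map(bp, time_derivative, dt = dt))
  pr <- stage("phase_rate", phase_rate_feature(bp$i, bp$q, dv$i, dv$q))
  feats <- tibble(t = rs$t, d_i = dv$i, d_q = dv$q, d_amp = dv$amp,
                  d_phase = dv$phase, phase_rate = pr)
  check_finite(as.matrix(feats[-1]), "feature matrix")
  if (identical(state, "raw")) return(feats)
  if (identical(state, "fit")) {
    st <- stage("transform", fit_transform_state(feats))
    out <- stage("transform", apply_transform(feats, st))
    attr(out, "transform_state") <- st
    return(out)
  }
  stage("transform", apply_transform(feats, state))
}
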
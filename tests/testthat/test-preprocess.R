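test_that("linear resampling reproduces and interpolates values", {
  u <- tibble::tibble(t = seq(0, 1, by = 0.01), v = sin(seq(0, 1, by = 0.01)))
  expect_equal(resample_linear(u, 100)$v, u$v)

  two <- tibble::tibble(t = c(0, 1), v = c(0, 2))
  out <- resample_linear(two, 2)
  expect_equal(out$v[out$t == 0.5], 1)

  # brute-force piecewise-linear oracle on an irregular record
  set.seed(8)
  irr <- tibble::tibble(t = cumsum(runif(60, 0.02, 0.04)))
  irr$v <- rnorm(60)
  out <- resample_linear(irr, 100)
  oracle <- vapply(out$t, function(tt) {
    j <- max(which(irr$t <= tt + 1e-12))
    if (j == nrow(irr)) return(irr$v[j])
    w <- (tt - irr$t[j]) / (irr$t[j + 1] - irr$t[j])
    (1 - w) * irr$v[j] + w * irr$v[j + 1]
  }, numeric(1))
  expect_equal(out$v, oracle, tolerance = 1e-12)
  expect_true(max(out$t) <= max(irr$t) + 1e-12)  # no extrapolation
  expect_error(resample_linear(tibble::tibble(t = 1, v = 1), 10), "2 samples")
})

test_that("amplitude and unwrapped phase behave on canonical trajectories", {
  ap <- amplitude_phase(3, 4)
  expect_equal(ap$amplitude, 5)
  expect_equal(ap$phase, atan2(4, 3))
  expect_equal(amplitude_phase(0, 1)$phase, pi / 2)

  k <- 0:100
  circ <- amplitude_phase(cos(2 * pi * k / 100), sin(2 * pi * k / 100))
  expect_true(all(diff(circ$phase) > 0))
  expect_equal(circ$phase[101] - circ$phase[1], 2 * pi)

  # amplitude ~ 0: the phase is carried from the neighbouring sample
  ap0 <- amplitude_phase(c(1, 0, 1), c(1, 0, 1))
  expect_equal(ap0$phase[2], ap0$phase[1])
})

test_that("the band-pass filter rejects DC and shapes tones as designed", {
  fs <- 100
  t <- seq(0, 120, by = 1 / fs)
  trim <- seq(10 * fs, length(t) - 10 * fs)

  dc <- bandpass(rep(2, length(t)), fs)
  expect_lt(max(abs(dc[trim])), 1e-3 * 2)

  # analytic magnitude response of the digital filter (transfer polynomials
  # evaluated on the unit circle), squared by the forward-backward application
  bf <- signal::butter(3, c(0.1, 16) / (fs / 2), type = "pass")
  H <- function(f_hz) {
    z <- exp(-1i * 2 * pi * f_hz / fs * (seq_along(bf$b) - 1))
    Mod(sum(bf$b * z) / sum(bf$a * z))^2
  }

  tone1 <- bandpass(sin(2 * pi * 1 * t), fs)
  amp1 <- max(abs(tone1[trim]))
  expect_equal(amp1, H(1), tolerance = 0.05)
  expect_gt(amp1, 0.95)

  tone30 <- bandpass(sin(2 * pi * 30 * t), fs)
  amp30 <- max(abs(tone30[trim]))
  expect_lt(amp30, amp1 / 10)
  expect_equal(amp30, H(30), tolerance = 0.5)

  expect_error(bandpass(rnorm(100), fs), "warm-up")
  expect_error(bandpass(rnorm(10000), sample_rate = 30), "twice the upper")
})

test_that("central differences reach second-order accuracy", {
  expect_equal(time_derivative(rep(3, 50), 0.1), rep(0, 50))
  tt <- seq(0, 1, by = 0.01)
  expect_equal(time_derivative(5 * tt, 0.01), rep(5, length(tt)))

  f <- 2
  dt <- 0.01
  d <- time_derivative(sin(2 * pi * f * tt), dt)
  interior <- 2:(length(tt) - 1)
  rel_err <- abs(d - 2 * pi * f * cos(2 * pi * f * tt)) / (2 * pi * f)
  expect_lt(max(rel_err[interior]), (2 * pi * f * dt)^2)
  expect_error(time_derivative(c(1, 2), 0.1), "3 samples")
})

test_that("the phase-rate feature equals the angular rate of the trajectory", {
  tt <- seq(0, 2, by = 1e-3)
  for (rho in c(0.5, 2)) {
    Omega <- 3
    i <- rho * cos(Omega * tt); q <- rho * sin(Omega * tt)
    pr <- phase_rate_feature(i, q, -rho * Omega * sin(Omega * tt),
                             rho * Omega * cos(Omega * tt))
    expect_equal(pr, rep(Omega, length(tt)))  # radius-independent
  }
  # purely radial motion has zero angular rate
  expect_equal(phase_rate_feature(1:5, rep(0, 5), rep(1, 5), rep(0, 5)),
               rep(0, 5))
  # degenerate origin: floored to 0
  expect_equal(phase_rate_feature(0, 0, 1, 1), 0)

  # unwrap-then-differentiate oracle on a smooth non-circular trajectory
  dt <- 1e-4
  tt <- seq(0, 1, by = dt)
  i <- 2 + cos(2 * pi * tt); q <- 1 + 0.5 * sin(2 * pi * tt)
  pr <- phase_rate_feature(i, q, time_derivative(i, dt), time_derivative(q, dt))
  oracle <- time_derivative(respiq:::unwrap_phase(atan2(q, i)), dt)
  interior <- 3:(length(tt) - 2)
  expect_lt(max(abs(pr - oracle)[interior]), 1e-6)
})

test_that("the power transform + robust scaler normalises as specified", {
  set.seed(4)
  n <- 4000
  feats <- tibble::tibble(t = seq_len(n),
                          sym = runif(n, -1, 1),
                          skewed = rlnorm(n, 0, 0.8))
  st <- fit_transform_state(feats)
  out <- apply_transform(feats, st)

  # fitted columns: median exactly 0, IQR exactly 1 on the fitting set
  for (col in c("sym", "skewed")) {
    expect_equal(median(out[[col]]), 0, tolerance = 1e-9)
    expect_equal(unname(diff(quantile(out[[col]], c(0.25, 0.75)))), 1,
                 tolerance = 1e-9)
  }
  # symmetric column: identity regime of the transform
  p <- st$params[st$params$column == "sym", ]
  expect_equal(p$lambda, 1, tolerance = 0.15)
  expect_gt(cor(out$sym, feats$sym), 0.999)
  # right-skewed column: skewness magnitude reduced
  expect_lt(abs(sample_skewness(out$skewed)),
            abs(sample_skewness(feats$skewed)))

  # degenerate column is a named error
  bad <- tibble::tibble(t = 1:100, flat = rep(1, 100))
  expect_error(fit_transform_state(bad), "flat")
})

test_that("transform states honour the fitting mask and never mutate", {
  set.seed(5)
  feats <- tibble::tibble(t = 1:2000, v = c(rnorm(1000), rnorm(1000, 5, 3)))
  mask <- c(rep(TRUE, 1000), rep(FALSE, 1000))
  st <- fit_transform_state(feats, fitting_mask = mask)
  out <- apply_transform(feats, st)
  # the fitting half is normalised; the held-out half is not re-fitted
  expect_equal(median(out$v[mask]), 0, tolerance = 1e-9)
  expect_gt(abs(median(out$v[!mask])), 0.5)

  before <- serialize(st, NULL)
  invisible(apply_transform(feats, st))
  invisible(invert_transform(c(-1, 0, 1), st, "v"))
  expect_identical(serialize(st, NULL), before)

  # round trip back to physical units across both transform branches
  z <- apply_transform(feats, st)$v
  expect_equal(invert_transform(z, st, "v"), feats$v, tolerance = 1e-8)
  expect_error(invert_transform(z, st, "nope"), "nope")
})

test_that("winsorisation bounds applied transforms without touching the core", {
  feats <- tibble::tibble(t = 1:1000, v = rnorm(1000))
  st <- fit_transform_state(feats)
  wide <- tibble::tibble(t = 1, v = 1e6)
  expect_equal(apply_transform(wide, st, clip = 8)$v, 8)
  core <- apply_transform(feats, st, clip = 8)$v
  expect_equal(core, apply_transform(feats, st)$v, tolerance = 1e-12)
})

test_that("build_features runs the fixed pipeline and is deterministic", {
  s <- single_subject()
  fe <- build_features(s$iq)
  st <- attr(fe, "transform_state")
  expect_s3_class(st, "respiq_transform")
  expect_named(fe, c("t", "d_i", "d_q", "d_amp", "d_phase", "phase_rate"))
  expect_true(all(is.finite(as.matrix(fe[-1]))))
  expect_equal(nrow(fe), length(seq(s$iq$t[1], max(s$iq$t), by = 0.01)))

  fe2 <- build_features(s$iq, state = st)
  expect_equal(fe2$d_i, fe$d_i, tolerance = 1e-12)
  fe3 <- build_features(s$iq, state = st)
  expect_identical(fe2, fe3)

  # stage errors carry the stage name
  short <- s$iq[1:50, ]
  expect_error(build_features(short), "bandpass")
})

test_that("a sinusoidal permittivity modulation appears at its own frequency", {
  f0 <- 0.3
  flow <- tibble::tibble(t = seq(0, 120, by = 0.01))
  flow$flow <- 0.4 * cos(2 * pi * f0 * flow$t)
  iq <- simulate_iq(flow, dipole_geometry(), medium_model(), carrier_config(),
                    subject_profile(noise_sd = 0, drift_amplitude = 0), seed = 2)
  fe <- build_features(iq, state = "raw")
  sp <- stats::spec.pgram(fe$d_i, taper = 0, plot = FALSE)
  peak_hz <- sp$freq[which.max(sp$spec)] * 100
  expect_equal(peak_hz, f0, tolerance = 0.05)
})

test_that("at least one feature tracks the flow strongly on clean data", {
  s <- single_subject()
  fe <- build_features(s$iq)
  truth <- approx(s$flow$t, s$flow$flow, xout = fe$t, rule = 2)$y
  cors <- vapply(setdiff(names(fe), "t"),
                 function(col) abs(cor(fe[[col]], truth)), numeric(1))
  expect_gt(max(cors), 0.6)
})
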
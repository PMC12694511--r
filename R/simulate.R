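#' Subject-specific sensing profile
#'
#' Collects the subject- and hardware-level non-idealities applied by
#' [simulate_iq()]: a complex coupling gain (posture/position dependent; its
#' magnitude is what makes flow amplitude recovery subject-biased), quadrature
#' gain imbalance and phase skew (the "arc trajectory" imperfection of real
#' I/Q hardware), DC offsets, slow sinusoidal drift, additive white Gaussian
#' receiver noise, and low-signal dropout intervals during which the received
#' carrier is attenuated (e.g. subject misplacement relative to the array).
#'
#' @param subject_id Character id.
#' @param coupling_gain Complex dimensionless gain (|gain| > 0). The default
#'   phase of -0.75 rad aligns the demodulator so the respiratory modulation
#'   splits roughly equally between the I and Q channels, as observed in the
#'   real system; posture shifts rotate and scale it per subject.
#' @param dc_offset_i,dc_offset_q DC offsets in V.
#' @param iq_gain_imbalance Dimensionless Q-channel gain factor.
#' @param iq_phase_skew Quadrature phase skew in rad.
#' @param noise_sd Receiver noise standard deviation in V.
#' @param drift_amplitude Amplitude of the slow sinusoidal baseline drift in V.
#' @param drift_period Drift period in s.
#' @param dropout_intervals Data frame with columns `start`, `end` (s) and
#'   `attenuation` in (0, 1): the received coupled signal is multiplied by
#'   `attenuation` inside each interval.
#' @return An object of class `respiq_profile`.
#' @export
subject_profile <- function(subject_id = "S01",
                            coupling_gain = complex(modulus = 1, argument = -0.75),
                            dc_offset_i = 0.05,
                            dc_offset_q = -0.04,
                            iq_gain_imbalance = 1.05,
                            iq_phase_skew = 2 * pi / 180,
                            noise_sd = 5e-5,
                            drift_amplitude = 0.01,
                            drift_period = 60,
                            dropout_intervals = NULL) {
  if (Mod(coupling_gain) <= 0) abort("|coupling_gain| must be > 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (is.null(dropout_intervals)) {
    dropout_intervals <- tibble(start = numeric(), end = numeric(),
                                attenuation = numeric())
  }
  dropout_intervals <- as_tibble(dropout_intervals)
  if (nrow(dropout_intervals) > 0) {
    check_cols(dropout_intervals, c("start", "end", "attenuation"), "dropout_intervals")
    if (any(dropout_intervals$attenuation <= 0 | dropout_intervals$attenuation >= 1)) {
      abort("dropout attenuation must lie strictly in (0, 1)")
    }
    if (any(dropout_intervals$end <= dropout_intervals$start)) {
      abort("dropout intervals must have end > start")
    }
  }
  structure(list(subject_id = subject_id, coupling_gain = coupling_gain,
                 dc_offset_i = dc_offset_i, dc_offset_q = dc_offset_q,
                 iq_gain_imbalance = iq_gain_imbalance,
                 iq_phase_skew = iq_phase_skew, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude, drift_period = drift_period,
                 dropout_intervals = dropout_intervals),
            class = "respiq_profile")
}

#' Simulate the I/Q sensor output for a flow waveform
#'
#' Forward model: the inhaled volume `V(t)` (cumulative integral of flow)
#' lowers the effective permittivity, which modulates the mutual impedance
#' between the dipoles; the coupled signal is `S(t) = coupling_gain *
#' Z12(eps(t)) * sensor_scale`. Low-signal dropout intervals attenuate `S`
#' itself (the received carrier drops; receiver noise and offsets do not),
#' then the receiver chain applies quadrature skew and gain imbalance
#' (`I = Re S`, `Q = imbalance * Im(S * exp(1i * skew))`), DC offsets, slow
#' sinusoidal drift, and additive white Gaussian noise, all evaluated on the
#' sensor time grid.
#'
#' @param flow Flow tibble (`t`, `flow`) covering the sensor window.
#' @param geom,medium,carrier See [dipole_geometry()], [medium_model()],
#'   [carrier_config()].
#' @param profile A [subject_profile()].
#' @param sensor_rate Sensor sampling rate in Hz (default 33).
#' @param seed Integer seed (required; drives noise, drift phase and jitter).
#' @param sensor_scale Transduction scale from Ohm to V at the digitizer, after
#'   receiver amplification (default 1).
#' @param jitter_sd Uniform timestamp jitter half-width in s (default 0 = off;
#'   the acquisition clock is not synchronous with the reference device).
#' @return Tibble with columns `t` (s), `i`, `q` (V).
#' @export
simulate_iq <- function(flow, geom, medium, carrier, profile,
                        sensor_rate = 33, seed, sensor_scale = 1,
                        jitter_sd = 0) {
  check_cols(flow, c("t", "flow"), "flow")
  if (missing(seed)) abort("`seed` is required for simulate_iq()")
  stopifnot(inherits(profile, "respiq_profile"))
  set.seed(derive_seed(seed, paste0("simulate_iq/", profile$subject_id)))

  ts <- seq(flow$t[1], flow$t[length(flow$t)], by = 1 / sensor_rate)
  if (jitter_sd > 0) {
    ts <- ts + runif(length(ts), -jitter_sd, jitter_sd)
    ts <- sort(ts)
    ts <- pmin(pmax(ts, flow$t[1]), flow$t[length(flow$t)])
  }

  vol <- cumtrapz(flow$t, flow$flow)
  vol_s <- approx(flow$t, vol, xout = ts)$y
  eps_t <- medium$eps_baseline - medium$eps_per_litre * vol_s
  if (any(eps_t <= 0)) {
    abort("simulated volume drives the effective permittivity non-positive; lower eps_per_litre or tidal volumes")
  }
  S <- profile$coupling_gain * sensor_scale *
    mutual_impedance(geom, medium, carrier, eps = eps_t)
  check_finite(c(Re(S), Im(S)), "coupled signal")

  # low-signal intervals: received carrier attenuated, receiver chain untouched
  if (nrow(profile$dropout_intervals) > 0) {
    for (k in seq_len(nrow(profile$dropout_intervals))) {
      di <- profile$dropout_intervals[k, ]
      inside <- ts >= di$start & ts <= di$end
      S[inside] <- S[inside] * di$attenuation
    }
  }

  S_skew <- S * exp(1i * profile$iq_phase_skew)
  i_sig <- Re(S)
  q_sig <- profile$iq_gain_imbalance * Im(S_skew)

  i_sig <- i_sig + profile$dc_offset_i
  q_sig <- q_sig + profile$dc_offset_q

  if (profile$drift_amplitude > 0) {
    ph <- runif(2, 0, 2 * pi)
    i_sig <- i_sig + profile$drift_amplitude * sin(2 * pi * ts / profile$drift_period + ph[1])
    q_sig <- q_sig + profile$drift_amplitude * sin(2 * pi * ts / profile$drift_period + ph[2])
  }
  if (profile$noise_sd > 0) {
    i_sig <- i_sig + rnorm(length(ts), 0, profile$noise_sd)
    q_sig <- q_sig + rnorm(length(ts), 0, profile$noise_sd)
  }
  check_finite(c(i_sig, q_sig), "I/Q output")
  tibble(t = ts, i = i_sig, q = q_sig)
}

#' Write / read a paired flow + I/Q dataset
#'
#' Writes `flow.csv` (`t,flow`), `iq.csv` (`t,i,q`) and a plain-text
#' `meta.yaml` sidecar recording the seed, subject profile and physics
#' configuration, so a dataset can be regenerated or audited.
#' `read_dataset()` round-trips the written values at the printed precision.
#'
#' @param flow Flow tibble (`t`, `flow`).
#' @param iq I/Q tibble (`t`, `i`, `q`).
#' @param path Directory to write into (created if needed).
#' @param meta Named list of metadata (seed, profile fields, geometry, ...).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(flow, iq, path, meta = list()) {
  check_cols(flow, c("t", "flow"), "flow")
  check_cols(iq, c("t", "i", "q"), "iq")
  if (nrow(flow) == 0 || nrow(iq) == 0) abort("flow and iq series must be non-empty")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("cannot create dataset directory '%s'", path))
  readr::write_csv(flow[, c("t", "flow")], file.path(path, "flow.csv"))
  readr::write_csv(iq[, c("t", "i", "q")], file.path(path, "iq.csv"))
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' @rdname write_dataset
#' @return `read_dataset()`: list with elements `flow`, `iq`, `meta`.
#' @export
read_dataset <- function(path) {
  fp <- file.path(path, "flow.csv")
  ip <- file.path(path, "iq.csv")
  mp <- file.path(path, "meta.yaml")
  for (f in c(fp, ip)) if (!file.exists(f)) abort(sprintf("missing dataset file '%s'", f))
  flow <- readr::read_csv(fp, show_col_types = FALSE)
  iq <- readr::read_csv(ip, show_col_types = FALSE)
  check_cols(flow, c("t", "flow"), "flow.csv")
  check_cols(iq, c("t", "i", "q"), "iq.csv")
  meta <- if (file.exists(mp)) yaml::read_yaml(mp) else list()
  list(flow = as_tibble(flow), iq = as_tibble(iq), meta = meta)
}

#' Simulate a multi-subject cohort of paired flow / I/Q recordings
#'
#' Builds one breathing script per subject with the study's cycle mix
#' (roughly 20 % fast, 48 % normal, 20 % slow cycles plus ~12 % apnea time,
#' shuffled per subject), tidal volumes around 0.55 L with 15 % per-cycle
#' jitter and 8 % rate jitter, then simulates the sensor output with
#' subject-specific coupling gains log-spaced over `gain_range` (small random
#' phase scatter), emulating posture/position-dependent amplitude bias.
#' Optionally one subject receives a low-signal dropout interval.
#'
#' @param n_subjects Number of subjects.
#' @param duration_s Recording length per subject in s.
#' @param seed Global integer seed.
#' @param gain_range Length-2 numeric: range of coupling-gain magnitudes.
#' @param dropout_subject Index (1-based) of the subject given a dropout
#'   interval, or `NA` for none.
#' @param dropout_window Length-2 numeric, start/end (s) of that interval.
#' @param dropout_attenuation Attenuation factor in (0, 1).
#' @param geom,medium,carrier Physics configuration (defaults as documented).
#' @param sensor_rate,flow_rate Sampling rates in Hz.
#' @return Nested tibble: one row per subject with `subject_id`, list-columns
#'   `flow` (reference flow tibble), `iq` (sensor tibble), `script`, `profile`.
#' @export
simulate_cohort <- function(n_subjects = 6, duration_s = 180, seed = 1L,
                            gain_range = c(0.5, 2),
                            dropout_subject = NA, dropout_window = c(95, 120),
                            dropout_attenuation = 0.05,
                            geom = dipole_geometry(), medium = medium_model(),
                            carrier = carrier_config(),
                            sensor_rate = 33, flow_rate = 100) {
  gains <- exp(seq(log(gain_range[1]), log(gain_range[2]),
                   length.out = n_subjects))
  rows <- purrr::map(seq_len(n_subjects), function(s) {
    sid <- sprintf("S%02d", s)
    sseed <- derive_seed(seed, paste0("cohort/", sid))
    set.seed(sseed)
    segs <- cohort_segments(duration_s)
    segs <- segs[sample.int(nrow(segs)), ]
    script <- breathing_script(segs, vt_jitter = 0.15, rate_jitter = 0.08,
                               seed = sseed)
    drop_iv <- NULL
    if (!is.na(dropout_subject) && s == dropout_subject) {
      drop_iv <- tibble(start = dropout_window[1], end = dropout_window[2],
                        attenuation = dropout_attenuation)
    }
    profile <- subject_profile(
      subject_id = sid,
      coupling_gain = complex(modulus = gains[s],
                              argument = -0.75 + runif(1, -0.2, 0.2)),
      dropout_intervals = drop_iv)
    flow <- generate_flow(script, sample_rate = flow_rate)
    iq <- simulate_iq(flow, geom, medium, carrier, profile,
                      sensor_rate = sensor_rate, seed = sseed)
    tibble(subject_id = sid, flow = list(flow), iq = list(iq),
           script = list(script), profile = list(profile))
  })
  dplyr::bind_rows(rows)
}

# Segment recipe for one cohort subject: scaled to `duration_s`, targeting the
# study cycle mix (fast/normal/slow ~ 6/14/6 cycles per 3 min + ~12 % apnea).
cohort_segments <- function(duration_s) {
  u <- duration_s / 180
  tibble(
    pattern      = c("fast", "normal", "normal", "slow", "apnea", "apnea"),
    duration     = u * c(18, 36, 36, 64, 16, 10),
    rate         = c(25, 15, 16, 7.5, NA, NA),
    tidal_volume = c(0.45, 0.55, 0.6, 0.6, 0, 0),
    ie           = c(1, 0.8, 0.9, 0.8, 1, 1)
  )
}
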
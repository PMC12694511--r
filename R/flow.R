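#' Breathing-pattern classes and their rate/duration bounds
#'
#' Clinical rate classes used throughout the package: fast breathing is
#' >= 20 breaths/min (cycle duration <= 3 s), normal breathing 10-20 breaths/min
#' (3-6 s), slow breathing <= 10 breaths/min (>= 6 s), and apnea is the absence
#' of breathing. Boundary durations are derived from the rate bounds
#' (60 / 20 = 3 s and 60 / 10 = 6 s).
#'
#' @return A tibble with one row per class: `pattern`, `min_rate`, `max_rate`
#'   (breaths/min, `NA` where unbounded), `min_duration_s`, `max_duration_s`.
#' @export
#' @examples
#' rate_class_bounds()
rate_class_bounds <- function() {
  tibble(
    pattern        = c("fast", "normal", "slow", "apnea"),
    min_rate       = c(20, 10, NA, NA),
    max_rate       = c(NA, 20, 10, NA),
    min_duration_s = c(NA, 60 / 20, 60 / 10, NA),
    max_duration_s = c(60 / 20, 60 / 10, NA, NA)
  )
}

#' Classify a breath-cycle duration into a rate class
#'
#' Boundaries are closed as printed in the class definitions: exactly 3 s is
#' `fast`, exactly 6 s is `slow`.
#'
#' @param duration_s Cycle duration(s) in seconds.
#' @return Character vector in `c("fast", "normal", "slow")`.
#' @export
classify_cycle_duration <- function(duration_s) {
  dplyr::case_when(
    duration_s <= 3 ~ "fast",
    duration_s >= 6 ~ "slow",
    TRUE ~ "normal"
  )
}

validate_segment <- function(pattern, rate) {
  ok <- switch(pattern,
    fast   = is.finite(rate) && rate >= 20,
    normal = is.finite(rate) && rate > 10 && rate < 20,
    slow   = is.finite(rate) && rate <= 10 && rate > 0,
    apnea  = TRUE,
    FALSE
  )
  if (!ok) {
    abort(sprintf(
      "segment class/rate pair violates the class bounds: pattern '%s' with rate %s (fast >= 20, normal in (10, 20), slow in (0, 10])",
      pattern, format(rate)))
  }
  invisible(TRUE)
}

#' Define a breathing script
#'
#' A script is an ordered list of breathing segments, each with a pattern class,
#' duration, target rate, target tidal volume and inspiratory:expiratory (I:E)
#' ratio. Scripts drive [generate_flow()]. Optional per-cycle jitter makes
#' tidal volumes and rates vary cycle-to-cycle (real breathing is never
#' metronomic, and cycle-level variability is what makes within-subject
#' tidal-volume trends measurable).
#'
#' @param segments Data frame with columns `pattern` (one of `"fast"`,
#'   `"normal"`, `"slow"`, `"apnea"`), `duration` (s), `rate` (breaths/min,
#'   ignored for apnea), `tidal_volume` (L, must be 0 for apnea) and optionally
#'   `ie` (I:E ratio, default 1).
#' @param vt_jitter Relative standard deviation of per-cycle tidal-volume
#'   jitter (e.g. 0.15 for 15 %). Default 0 (deterministic cycles).
#' @param rate_jitter Relative standard deviation of per-cycle rate jitter.
#' @param seed Integer seed controlling the per-cycle jitter draws.
#' @return An object of class `respiq_script`.
#' @export
#' @examples
#' breathing_script(tibble::tibble(
#'   pattern = c("normal", "apnea"), duration = c(60, 15),
#'   rate = c(15, NA), tidal_volume = c(0.5, 0)))
breathing_script <- function(segments, vt_jitter = 0, rate_jitter = 0, seed = 1L) {
  segments <- as_tibble(segments)
  check_cols(segments, c("pattern", "duration", "rate", "tidal_volume"), "segments")
  if (!"ie" %in% names(segments)) segments$ie <- 1
  if (any(segments$duration <= 0)) abort("segment durations must be > 0")
  if (any(segments$ie <= 0)) abort("ie_ratio must be > 0")
  if (any(segments$pattern == "apnea" & segments$tidal_volume != 0)) {
    abort("apnea segments must have zero target tidal volume")
  }
  non_apnea <- segments$pattern != "apnea"
  if (any(segments$tidal_volume[non_apnea] <= 0)) {
    abort("non-apnea segments must have positive target tidal volume")
  }
  purrr::walk2(segments$pattern, segments$rate, validate_segment)
  if (vt_jitter < 0 || rate_jitter < 0) abort("jitter sds must be >= 0")
  structure(
    list(segments = segments, vt_jitter = vt_jitter,
         rate_jitter = rate_jitter, seed = as.integer(seed)),
    class = "respiq_script")
}

#' @export
print.respiq_script <- function(x, ...) {
  cat(sprintf("<respiq_script> %d segment(s), %.1f s total, seed %d\n",
              nrow(x$segments), sum(x$segments$duration), x$seed))
  print(x$segments)
  invisible(x)
}

#' Generate a respiratory flow waveform from a breathing script
#'
#' Each breath cycle is a pair of asymmetric half-sine lobes: an inspiratory
#' lobe of duration `T * IE / (1 + IE)` and an expiratory lobe of duration
#' `T / (1 + IE)` (with `T = 60 / rate`), with amplitudes chosen so the
#' inspiratory integral equals the target tidal volume and the expired volume
#' balances it. Apnea segments emit zero flow for their full duration;
#' breathing segments hold as many whole cycles as fit their budget and
#' cycles concatenate continuously (consecutive breaths are back to back,
#' with no silent remainders). Inhalation is positive.
#'
#' @param script A [breathing_script()].
#' @param sample_rate Output sampling rate in Hz (>= 50).
#' @return A tibble with columns `t` (s, uniform grid starting at 0) and `flow`
#'   (L/s). The scripted ground-truth cycle table (onsets, durations, tidal
#'   volumes, pattern) is attached as attribute `"cycles"`; see
#'   [scripted_cycles()].
#' @export
#' @examples
#' ft <- generate_flow(breathing_script(tibble::tibble(
#'   pattern = "normal", duration = 8, rate = 15, tidal_volume = 0.5)))
#' scripted_cycles(ft)
generate_flow <- function(script, sample_rate = 100) {
  stopifnot(inherits(script, "respiq_script"))
  if (sample_rate < 50) abort("sample_rate must be >= 50 Hz")
  segs <- script$segments
  dt <- 1 / sample_rate

  # first pass: lay out cycles continuously. A breathing segment contributes
  # as many whole cycles as fit its budget and ends with its last cycle
  # (no silent remainder — consecutive breaths are back to back); apnea
  # segments advance time by their full duration.
  set.seed(derive_seed(script$seed, "generate_flow"))
  cycles <- list()
  cursor <- 0
  for (s in seq_len(nrow(segs))) {
    seg <- segs[s, ]
    if (seg$pattern == "apnea") {
      cursor <- cursor + seg$duration
      next
    }
    budget <- seg$duration
    repeat {
      rate_c <- seg$rate * max(0.2, 1 + rnorm(1, 0, script$rate_jitter))
      vt_c <- seg$tidal_volume * max(0.05, 1 + rnorm(1, 0, script$vt_jitter))
      T_c <- 60 / rate_c
      if (T_c > budget + 1e-9) break
      Ti <- T_c * seg$ie / (1 + seg$ie)
      cycles[[length(cycles) + 1L]] <- tibble(
        pattern = seg$pattern, insp_onset = cursor, exp_onset = cursor + Ti,
        end = cursor + T_c, duration = T_c, tidal_volume = vt_c)
      cursor <- cursor + T_c
      budget <- budget - T_c
    }
  }
  total <- if (length(cycles)) max(cursor, cycles[[length(cycles)]]$end) else cursor
  t <- seq(0, total - dt / 2, by = dt)
  flow <- numeric(length(t))
  for (cyc in cycles) {
    Ti <- cyc$exp_onset - cyc$insp_onset
    Te <- cyc$end - cyc$exp_onset
    Ai <- pi * cyc$tidal_volume / (2 * Ti)
    Ae <- pi * cyc$tidal_volume / (2 * Te)
    idx <- which(t >= cyc$insp_onset - 1e-12 & t < cyc$end - 1e-12)
    tt <- t[idx] - cyc$insp_onset
    flow[idx] <- ifelse(tt < Ti,
                        Ai * sin(pi * tt / Ti),
                        -Ae * sin(pi * (tt - Ti) / Te))
  }
  cycles <- if (length(cycles)) dplyr::bind_rows(cycles) else
    tibble(pattern = character(), insp_onset = numeric(), exp_onset = numeric(),
           end = numeric(), duration = numeric(), tidal_volume = numeric())
  out <- tibble(t = t, flow = flow)
  attr(out, "cycles") <- cycles
  out
}

#' Scripted ground-truth cycles of a generated flow trace
#'
#' @param flow A flow tibble produced by [generate_flow()].
#' @return Tibble of scripted cycles (pattern, onsets, duration, tidal volume).
#' @export
scripted_cycles <- function(flow) {
  cyc <- attr(flow, "cycles")
  if (is.null(cyc)) abort("`flow` carries no scripted cycle table; was it made by generate_flow()?")
  cyc
}
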
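#' Detect inspiration and expiration onsets by zero-crossings
#'
#' An inspiration onset is an upward zero-crossing (negative to positive) of
#' the flow whose following excursion exceeds `+hysteresis` before the signal
#' returns through zero; expiration onsets are the symmetric downward case.
#' Crossing times are linearly interpolated between the bracketing samples.
#' With `hysteresis = 0` the rule reduces to the literal zero-crossing rule.
#' Onsets strictly alternate: a repeated crossing in the same direction (a
#' noise re-cross whose opposite excursion stayed sub-threshold) is not a new
#' onset.
#'
#' Reconstructed (predicted) flow carries sample-level regression noise whose
#' zero crossings are not breath events; `smooth_hz` optionally low-passes the
#' trace (zero-phase, so timing is unbiased) before crossing detection.
#'
#' @param flow Tibble with columns `t` (uniform grid) and `flow` (L/s).
#' @param hysteresis Excursion threshold in L/s (>= 0; default 0.03).
#' @param smooth_hz Optional zero-phase low-pass cutoff in Hz applied before
#'   detection (`NULL` = none).
#' @return An object of class `respiq_onsets`: list with `insp` and `exp`
#'   onset times (s) plus the raw unvalidated crossing times (`raw_up`,
#'   `raw_down`) used downstream for cycle closure.
#' @export
detect_onsets <- function(flow, hysteresis = 0.03, smooth_hz = NULL) {
  check_cols(flow, c("t", "flow"), "flow")
  if (hysteresis < 0) abort("hysteresis must be >= 0")
  t <- flow$t
  f <- flow$flow
  empty <- structure(list(insp = numeric(), exp = numeric(),
                          raw_up = numeric(), raw_down = numeric()),
                     class = "respiq_onsets")
  if (length(t) < 2L) return(empty)
  dt <- check_uniform_grid(t)
  if (!is.null(smooth_hz)) {
    rate <- 1 / dt
    bf <- signal::butter(3, min(smooth_hz / (rate / 2), 0.99), type = "low")
    f <- as.numeric(signal::filtfilt(bf, f))
  }

  n <- length(f)
  up_i <- which(f[-n] <= 0 & f[-1] > 0)
  dn_i <- which(f[-n] >= 0 & f[-1] < 0)
  cross_time <- function(i) t[i] + dt * (0 - f[i]) / (f[i + 1] - f[i])
  crossings <- dplyr::arrange(dplyr::bind_rows(
    tibble(idx = up_i, dir = 1),
    tibble(idx = dn_i, dir = -1)), .data$idx)
  if (nrow(crossings) == 0) return(empty)
  crossings$time <- purrr::map2_dbl(crossings$idx, crossings$dir,
                                    function(i, d) cross_time(i))

  # excursion between this crossing and the next opposite crossing (or end)
  keep <- logical(nrow(crossings))
  last_dir <- 0
  for (k in seq_len(nrow(crossings))) {
    d <- crossings$dir[k]
    nxt <- which(crossings$dir[(k + 1):nrow(crossings)] == -d)
    hi <- if (length(nxt)) crossings$idx[k + nxt[1]] else n
    excursion <- max(d * f[(crossings$idx[k] + 1L):hi], 0)
    if (excursion >= hysteresis && d != last_dir) {
      keep[k] <- TRUE
      last_dir <- d
    }
  }
  kept <- crossings[keep, ]
  # closure crossings: a limb that settles to exactly zero (apnea, record
  # tail) must still close, so the return-to-baseline rule accepts f reaching
  # zero rather than strictly crossing it
  up_c <- which(f[-n] < 0 & f[-1] >= 0)
  dn_c <- which(f[-n] > 0 & f[-1] <= 0)
  structure(list(insp = kept$time[kept$dir == 1],
                 exp = kept$time[kept$dir == -1],
                 raw_up = cross_time(up_c),
                 raw_down = cross_time(dn_c)),
            class = "respiq_onsets")
}

#' @export
print.respiq_onsets <- function(x, ...) {
  cat(sprintf("<respiq_onsets> %d inspiration, %d expiration onsets\n",
              length(x$insp), length(x$exp)))
  invisible(x)
}

# Integral of the positive part of the flow over [a, b], trapezoid rule with
# linearly interpolated fractional end samples.
integrate_positive <- function(t, f, a, b) {
  fa <- approx(t, f, xout = a, rule = 2)$y
  fb <- approx(t, f, xout = b, rule = 2)$y
  inner <- which(t > a & t < b)
  tt <- c(a, t[inner], b)
  ff <- pmax(c(fa, f[inner], fb), 0)
  trapz(tt, ff)
}

#' Segment a flow trace into breath cycles and apnea intervals
#'
#' One cycle per consecutive pair of inspiration onsets containing one
#' expiration onset; its tidal volume is the integral of the inspiratory
#' (positive) limb, its class follows [classify_cycle_duration()] (boundaries
#' closed: 3 s is fast, 6 s is slow), and it is marked unreliable when more
#' than half of its samples are masked. When the gap from an expiration onset
#' to the next inspiration is at least `apnea_min_duration` — or the record
#' ends without a further inspiration — the cycle is closed at the first raw
#' upward zero-crossing after the expiration onset (the end of the expiratory
#' limb) and the remaining onset-free gap becomes an apnea interval.
#'
#' @param onsets A [detect_onsets()] result (or list with `insp`, `exp`, and
#'   optionally `raw_up` elements).
#' @param flow The flow tibble the onsets came from.
#' @param unreliable_mask Optional logical vector aligned with `flow` rows
#'   (e.g. from a reconstruction's reliability gating).
#' @param apnea_min_duration Minimum onset-free gap (s) reported as apnea.
#' @param closure_tol Flow magnitude (L/s) below which the record end counts
#'   as the zero return of a trailing expiratory limb.
#' @return List with `cycles` (tibble: `insp_onset`, `exp_onset`,
#'   `next_insp_onset`, `end`, `duration`, `tidal_volume`, `rate_class`,
#'   `reliable`) and `apnea` (tibble: `start`, `end`).
#' @export
segment_cycles <- function(onsets, flow, unreliable_mask = NULL,
                           apnea_min_duration = 10, closure_tol = 0.03) {
  check_cols(flow, c("t", "flow"), "flow")
  insp <- onsets$insp
  expo <- onsets$exp
  raw_up <- onsets$raw_up %||% insp
  merged <- dplyr::arrange(dplyr::bind_rows(
    tibble(time = insp, dir = 1), tibble(time = expo, dir = -1)), .data$time)
  if (nrow(merged) > 1 && any(diff(merged$dir) == 0)) {
    abort("onsets do not strictly alternate between inspiration and expiration")
  }
  if (!is.null(unreliable_mask) && length(unreliable_mask) != nrow(flow)) {
    abort("unreliable_mask length must match flow rows")
  }

  t0 <- flow$t[1]; t_end <- flow$t[nrow(flow)]
  cycles <- list()
  apnea <- list()

  if (length(insp) == 0) {
    if (t_end - t0 >= apnea_min_duration) {
      apnea[[1]] <- tibble(start = t0, end = t_end)
    }
  } else {
    if (insp[1] - t0 >= apnea_min_duration) {
      apnea[[length(apnea) + 1L]] <- tibble(start = t0, end = insp[1])
    }
    last_end <- t0
    for (j in seq_along(insp)) {
      start <- insp[j]
      next_insp <- if (j < length(insp)) insp[j + 1L] else NA_real_
      upper <- if (is.na(next_insp)) Inf else next_insp
      exp_j <- expo[expo > start & expo < upper]
      if (length(exp_j) != 1L) next  # incomplete or malformed cycle
      gap <- (if (is.na(next_insp)) t_end else next_insp) - exp_j
      end <- next_insp
      if (is.na(next_insp) || gap >= apnea_min_duration) {
        limb_end <- raw_up[raw_up > exp_j]
        limb_end <- if (length(limb_end)) limb_end[1] else NA_real_
        if (is.na(limb_end) && is.na(next_insp) &&
            abs(flow$flow[nrow(flow)]) <= closure_tol) {
          # the record ends within a sample of the limb's zero return
          limb_end <- t_end
        }
        if (is.na(limb_end) || (!is.na(next_insp) && limb_end >= next_insp)) {
          if (is.na(next_insp)) next  # trailing cycle never closed
          limb_end <- next_insp
        }
        end <- limb_end
        gap_start <- end
        gap_end <- if (is.na(next_insp)) t_end else next_insp
        if (gap_end - gap_start >= apnea_min_duration) {
          apnea[[length(apnea) + 1L]] <- tibble(start = gap_start, end = gap_end)
        }
      }
      if (is.na(end) || end <= start) next
      vt <- integrate_positive(flow$t, flow$flow, start, end)
      reliable <- TRUE
      if (!is.null(unreliable_mask)) {
        in_cycle <- flow$t >= start & flow$t <= end
        reliable <- mean(unreliable_mask[in_cycle]) <= 0.5
      }
      cycles[[length(cycles) + 1L]] <- tibble(
        insp_onset = start, exp_onset = exp_j, next_insp_onset = next_insp,
        end = end, duration = end - start, tidal_volume = vt,
        rate_class = classify_cycle_duration(end - start), reliable = reliable)
      last_end <- end
    }
  }

  cycles <- if (length(cycles)) dplyr::bind_rows(cycles) else
    tibble(insp_onset = numeric(), exp_onset = numeric(),
           next_insp_onset = numeric(), end = numeric(), duration = numeric(),
           tidal_volume = numeric(), rate_class = character(),
           reliable = logical())
  apnea <- if (length(apnea)) dplyr::bind_rows(apnea) else
    tibble(start = numeric(), end = numeric())
  list(cycles = cycles, apnea = apnea)
}

#' Count respiratory cycles
#'
#' @param cycles Cycle tibble from [segment_cycles()].
#' @param include_unreliable Count cycles flagged unreliable too?
#' @return Integer count.
#' @export
cycle_count <- function(cycles, include_unreliable = FALSE) {
  if (include_unreliable) nrow(cycles) else sum(cycles$reliable)
}
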
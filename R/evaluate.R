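#' Synchronize a reference flow with a reconstruction
#'
#' Restricts both series to their common time window (maximum of the start
#' times to minimum of the end times) and linearly interpolates the reference
#' onto the prediction grid, which serves as the reference grid.
#'
#' @param reference Tibble with columns `t`, `flow` (the flowmeter signal).
#' @param prediction A [predict_mc()] result, or a tibble with columns `t`
#'   and `flow_mean`.
#' @return Tibble on the prediction grid inside the common window: `t`,
#'   `flow_ref`, `flow_pred`, and (when available) `flow_sd`, `reliability`,
#'   `unreliable`.
#' @export
synchronize <- function(reference, prediction) {
  check_cols(reference, c("t", "flow"), "reference")
  pred <- if (inherits(prediction, "respiq_recon")) prediction$samples else as_tibble(prediction)
  check_cols(pred, c("t", "flow_mean"), "prediction")
  w0 <- max(reference$t[1], pred$t[1])
  w1 <- min(reference$t[nrow(reference)], pred$t[nrow(pred)])
  if (w0 >= w1) abort("reference and prediction time spans do not overlap")
  pred <- pred[pred$t >= w0 & pred$t <= w1, ]
  out <- tibble(t = pred$t,
                flow_ref = approx(reference$t, reference$flow, xout = pred$t)$y,
                flow_pred = pred$flow_mean)
  for (col in intersect(c("flow_sd", "reliability", "unreliable"), names(pred))) {
    out[[col]] <- pred[[col]]
  }
  out
}

#' Pair reference and predicted onsets
#'
#' Greedy nearest-neighbour matching in order of increasing absolute time
#' gap: each onset is used at most once, candidate pairs further apart than
#' `tolerance` are rejected, and exact ties break toward the earlier
#' reference onset. Signed errors are `predicted - reference` (positive =
#' prediction delayed).
#'
#' @param ref_onsets,pred_onsets Sorted numeric vectors of onset times (s).
#' @param tolerance Maximum |gap| for a valid pair, in s.
#' @return An object of class `respiq_pairing`: `pairs` (tibble `ref`,
#'   `pred`, `error`), `unmatched_ref`, `unmatched_pred`, `tolerance`.
#' @export
pair_onsets <- function(ref_onsets, pred_onsets, tolerance) {
  if (tolerance <= 0) abort("tolerance must be > 0")
  cand <- expand.grid(ri = seq_along(ref_onsets), pi = seq_along(pred_onsets))
  if (nrow(cand) > 0) {
    cand$err <- pred_onsets[cand$pi] - ref_onsets[cand$ri]
    cand <- cand[abs(cand$err) <= tolerance, ]
    cand <- cand[order(abs(cand$err), ref_onsets[cand$ri]), ]
  }
  used_r <- logical(length(ref_onsets))
  used_p <- logical(length(pred_onsets))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    ri <- cand$ri[k]; pi <- cand$pi[k]
    if (used_r[ri] || used_p[pi]) next
    used_r[ri] <- TRUE; used_p[pi] <- TRUE
    pairs[[length(pairs) + 1L]] <- tibble(ref = ref_onsets[ri],
                                          pred = pred_onsets[pi],
                                          error = cand$err[k])
  }
  pairs <- if (length(pairs)) dplyr::arrange(dplyr::bind_rows(pairs), .data$ref) else
    tibble(ref = numeric(), pred = numeric(), error = numeric())
  structure(list(pairs = pairs,
                 unmatched_ref = ref_onsets[!used_r],
                 unmatched_pred = pred_onsets[!used_p],
                 tolerance = tolerance),
            class = "respiq_pairing")
}

#' @export
print.respiq_pairing <- function(x, ...) {
  cat(sprintf("<respiq_pairing> %d pairs, %d unmatched reference, %d unmatched predicted (tolerance %.3g s)\n",
              nrow(x$pairs), length(x$unmatched_ref), length(x$unmatched_pred),
              x$tolerance))
  invisible(x)
}

#' Reliability-gated detection rate
#'
#' Fraction of reference inspiration onsets matched by a predicted onset.
#' Reference onsets whose cycles lie wholly inside intervals the prediction
#' flagged unreliable were rejected by the model on purpose; by default they
#' are excluded from the denominator (counted as correctly rejected rather
#' than missed). `strict = TRUE` counts them as misses.
#'
#' @param pairing A [pair_onsets()] result computed after removing predicted
#'   events inside unreliable intervals.
#' @param rejected_ref Times of reference onsets lying wholly inside
#'   prediction-flagged unreliable intervals.
#' @param strict Count rejected reference onsets as misses?
#' @return Fraction in `[0, 1]`.
#' @export
detection_rate <- function(pairing, rejected_ref = numeric(), strict = FALSE) {
  stopifnot(inherits(pairing, "respiq_pairing"))
  matched <- nrow(pairing$pairs)
  unmatched <- pairing$unmatched_ref
  if (!strict) unmatched <- setdiff(unmatched, rejected_ref)
  total <- matched + length(unmatched)
  if (total == 0) abort("no reference cycles to detect")
  matched / total
}

#' Bland-Altman agreement statistics
#'
#' Differences are `pred - ref`; bias is their mean, the limits of agreement
#' are `bias +/- 1.96 * SD`, and the least-squares slope of the differences
#' against the pairwise means indicates amplitude-dependent error
#' (heteroscedasticity).
#'
#' @param ref_values,pred_values Paired numeric vectors, length >= 3.
#' @return One-row tibble: `bias`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `slope`, `n`.
#' @export
bland_altman <- function(ref_values, pred_values) {
  if (length(ref_values) != length(pred_values)) abort("inputs must be paired")
  if (length(ref_values) < 3) abort("Bland-Altman needs at least 3 pairs")
  d <- pred_values - ref_values
  m <- (pred_values + ref_values) / 2
  s <- sd(d)
  slope <- if (sd(m) > 0) unname(coef(lm(d ~ m))[2]) else 0
  tibble(bias = mean(d), sd_diff = s,
         loa_lower = mean(d) - 1.96 * s, loa_upper = mean(d) + 1.96 * s,
         slope = slope, n = length(d))
}

#' Timing-error summary of an onset pairing
#'
#' Signed errors in ms (predicted minus reference), summarised as median and
#' standard deviation, pooled and optionally stratified by the rate class of
#' the cycle each reference onset belongs to.
#'
#' @param pairing A [pair_onsets()] result.
#' @param ref_classes Optional character vector: rate class per pair (same
#'   order as `pairing$pairs`).
#' @return Tibble with columns `rate_class` (`"all"` plus any strata), `n`,
#'   `median_ms`, `sd_ms`.
#' @export
timing_error_stats <- function(pairing, ref_classes = NULL) {
  stopifnot(inherits(pairing, "respiq_pairing"))
  if (nrow(pairing$pairs) == 0) abort("pairing contains no pairs")
  err_ms <- pairing$pairs$error * 1000
  out <- tibble(rate_class = "all", n = length(err_ms),
                median_ms = median(err_ms), sd_ms = sd(err_ms))
  if (!is.null(ref_classes)) {
    strat <- tibble(rate_class = ref_classes, err = err_ms) |>
      dplyr::group_by(.data$rate_class) |>
      dplyr::summarise(n = dplyr::n(), median_ms = median(.data$err),
                       sd_ms = sd(.data$err), .groups = "drop")
    out <- dplyr::bind_rows(out, strat)
  }
  out
}

# Contiguous TRUE-runs of a logical mask on a time grid -> tibble(start, end).
mask_runs <- function(t, mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble(start = t[starts[keep]], end = t[ends[keep]])
}

in_any_interval <- function(x, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(x)))
  purrr::map_lgl(x, function(v) any(v >= intervals$start & v <= intervals$end))
}

#' Evaluate one subject's reconstruction against its reference flow
#'
#' Synchronizes the two series, extracts breath events from both (the
#' reconstruction low-passed at `smooth_hz` before crossing detection, the
#' reference as-is), removes predicted events inside reliability-flagged
#' intervals, pairs onsets, and computes the full per-subject metric set:
#' onset timing errors, reliability-gated detection rate, tidal-volume
#' agreement (including within-subject correlation and Bland-Altman inputs),
#' flow correlation and median absolute flow error over reliable samples.
#' The first and last `edge_trim` seconds are excluded from all metrics
#' (zero-phase filter transients live there).
#'
#' @param reference Tibble `t`, `flow` (L/s).
#' @param recon A [predict_mc()] result for the same record.
#' @param hysteresis Onset hysteresis in L/s.
#' @param smooth_hz Low-pass cutoff for the reconstructed trace.
#' @param edge_trim Seconds trimmed from each end.
#' @param apnea_min_duration See [segment_cycles()].
#' @param tolerance Onset pairing tolerance in s; default half the median
#'   reference cycle duration.
#' @return An object of class `respiq_subject_eval`: metrics (one-row
#'   tibble), pairings, cycle tables and the synchronized samples.
#' @export
evaluate_subject <- function(reference, recon, hysteresis = 0.03,
                             smooth_hz = 2, edge_trim = 5,
                             apnea_min_duration = 10, tolerance = NULL) {
  sync <- synchronize(reference, recon)
  w0 <- sync$t[1] + edge_trim
  w1 <- sync$t[nrow(sync)] - edge_trim
  if (w0 >= w1) abort("record too short for the requested edge trim")

  ref_tb <- tibble(t = sync$t, flow = sync$flow_ref)
  # one smoothed predicted trace for event detection AND tidal-volume
  # integration: regression noise above the respiratory band is not breath
  # signal, and integrating it would corrupt per-cycle volumes
  pred_flow <- sync$flow_pred
  if (!is.null(smooth_hz)) {
    dt <- check_uniform_grid(sync$t)
    bf <- signal::butter(3, min(smooth_hz * 2 * dt, 0.99), type = "low")
    pred_flow <- as.numeric(signal::filtfilt(bf, pred_flow))
  }
  pred_tb <- tibble(t = sync$t, flow = pred_flow)
  unrel <- if ("unreliable" %in% names(sync)) sync$unreliable else rep(FALSE, nrow(sync))

  trim_onsets <- function(o) {
    structure(list(insp = o$insp[o$insp >= w0 & o$insp <= w1],
                   exp = o$exp[o$exp >= w0 & o$exp <= w1],
                   raw_up = o$raw_up, raw_down = o$raw_down),
              class = "respiq_onsets")
  }
  ons_ref <- trim_onsets(detect_onsets(ref_tb, hysteresis))
  ons_pred <- trim_onsets(detect_onsets(pred_tb, hysteresis))

  seg_ref <- segment_cycles(ons_ref, ref_tb, apnea_min_duration = apnea_min_duration)
  seg_pred <- segment_cycles(ons_pred, pred_tb, unreliable_mask = unrel,
                             apnea_min_duration = apnea_min_duration)

  unrel_runs <- mask_runs(sync$t, unrel)
  keep_pred_insp <- !in_any_interval(ons_pred$insp, unrel_runs)
  keep_pred_exp <- !in_any_interval(ons_pred$exp, unrel_runs)

  if (is.null(tolerance)) {
    tolerance <- if (nrow(seg_ref$cycles) > 0) {
      0.5 * median(seg_ref$cycles$duration)
    } else 1
  }

  pairing_insp <- pair_onsets(ons_ref$insp, ons_pred$insp[keep_pred_insp], tolerance)
  pairing_exp <- pair_onsets(ons_ref$exp, ons_pred$exp[keep_pred_exp], tolerance)

  # reference cycles wholly inside prediction-flagged intervals: rejected
  ref_cyc <- seg_ref$cycles
  wholly_flagged <- purrr::map_lgl(seq_len(nrow(ref_cyc)), function(j) {
    idx <- sync$t >= ref_cyc$insp_onset[j] & sync$t <= ref_cyc$end[j]
    sum(idx) > 0 && all(unrel[idx])
  })
  rejected_ref <- ref_cyc$insp_onset[wholly_flagged]
  det <- detection_rate(pairing_insp, rejected_ref = rejected_ref)

  # pair cycles through their inspiration onsets for tidal-volume agreement
  vt_pairs <- pairing_insp$pairs |>
    dplyr::inner_join(dplyr::select(ref_cyc, "insp_onset", vt_ref = "tidal_volume",
                                    "rate_class"),
                      by = c(ref = "insp_onset")) |>
    dplyr::inner_join(dplyr::select(seg_pred$cycles, "insp_onset",
                                    vt_pred = "tidal_volume"),
                      by = c(pred = "insp_onset"))

  onset_class <- function(pairing) {
    idx <- purrr::map_int(pairing$pairs$ref, function(r) {
      j <- which(ref_cyc$insp_onset <= r & ref_cyc$end >= r)
      if (length(j)) j[1] else NA_integer_
    })
    ifelse(is.na(idx), "normal", ref_cyc$rate_class[idx])
  }
  insp_stats <- timing_error_stats(pairing_insp, onset_class(pairing_insp))
  exp_stats <- if (nrow(pairing_exp$pairs) > 0) timing_error_stats(pairing_exp) else
    tibble(rate_class = "all", n = 0L, median_ms = NA_real_, sd_ms = NA_real_)

  trimmed <- sync$t >= w0 & sync$t <= w1
  ok <- trimmed & !unrel
  flow_r <- if (sum(ok) > 2 && sd(sync$flow_ref[ok]) > 0 && sd(sync$flow_pred[ok]) > 0) {
    cor(sync$flow_ref[ok], sync$flow_pred[ok])
  } else NA_real_
  medae <- median(abs(sync$flow_pred[ok] - sync$flow_ref[ok]))

  vt_r <- if (nrow(vt_pairs) > 2 && sd(vt_pairs$vt_ref) > 0 && sd(vt_pairs$vt_pred) > 0) {
    cor(vt_pairs$vt_ref, vt_pairs$vt_pred)
  } else NA_real_

  metrics <- tibble(
    subject_id = recon$subject_id, fold = recon$fold,
    n_ref_cycles = nrow(ref_cyc),
    n_pred_cycles = cycle_count(seg_pred$cycles),
    detection_rate = det,
    insp_median_ms = insp_stats$median_ms[1], insp_sd_ms = insp_stats$sd_ms[1],
    exp_median_ms = exp_stats$median_ms[1], exp_sd_ms = exp_stats$sd_ms[1],
    vt_abs_median_l = if (nrow(vt_pairs)) median(abs(vt_pairs$vt_pred - vt_pairs$vt_ref)) else NA_real_,
    vt_bias_l = if (nrow(vt_pairs)) mean(vt_pairs$vt_pred - vt_pairs$vt_ref) else NA_real_,
    vt_r = vt_r, flow_r = flow_r, medae_flow_l = medae,
    prop_unreliable = mean(unrel))

  structure(list(metrics = metrics, pairing_insp = pairing_insp,
                 pairing_exp = pairing_exp, insp_stats = insp_stats,
                 cycles_ref = ref_cyc, cycles_pred = seg_pred$cycles,
                 apnea_ref = seg_ref$apnea, vt_pairs = vt_pairs,
                 rejected_ref = rejected_ref, sync = sync,
                 tolerance = tolerance, window = c(w0, w1)),
            class = "respiq_subject_eval")
}

#' Full agreement report for a cross-validated reconstruction
#'
#' Evaluates every subject with [evaluate_subject()] and pools the results:
#' pooled onset-error medians over concatenated per-subject errors, pooled
#' detection rate (total matched over total reference onsets), Bland-Altman
#' analysis over all tidal-volume pairs, and pooled flow correlation.
#'
#' @param cv A [cross_validated_reconstruction()] result.
#' @param ... Passed to [evaluate_subject()].
#' @return An object of class `respiq_agreement`: `per_subject` (tibble, one
#'   row each), `pooled` (one-row tibble), `bland_altman`, and the per-subject
#'   evaluations in `details`.
#' @export
full_report <- function(cv, ...) {
  check_cols(cv, c("subject_id", "recon", "flow"), "cv")
  details <- purrr::map2(cv$flow, cv$recon, evaluate_subject, ...)
  names(details) <- cv$subject_id
  per_subject <- dplyr::bind_rows(purrr::map(details, "metrics"))

  all_insp <- unlist(purrr::map(details, function(d) d$pairing_insp$pairs$error))
  all_exp <- unlist(purrr::map(details, function(d) d$pairing_exp$pairs$error))
  matched <- sum(purrr::map_int(details, function(d) nrow(d$pairing_insp$pairs)))
  missed <- sum(purrr::map_int(details, function(d) {
    length(setdiff(d$pairing_insp$unmatched_ref, d$rejected_ref))
  }))
  vt_all <- dplyr::bind_rows(purrr::map(details, "vt_pairs"))
  ba <- if (nrow(vt_all) >= 3) bland_altman(vt_all$vt_ref, vt_all$vt_pred) else NULL

  sync_all <- dplyr::bind_rows(purrr::map(details, function(d) {
    ok <- d$sync$t >= d$window[1] & d$sync$t <= d$window[2]
    unrel <- if ("unreliable" %in% names(d$sync)) d$sync$unreliable else FALSE
    d$sync[ok & !unrel, c("flow_ref", "flow_pred")]
  }))

  pooled <- tibble(
    n_subjects = nrow(per_subject),
    n_ref_cycles = sum(per_subject$n_ref_cycles),
    detection_rate = matched / (matched + missed),
    insp_median_ms = median(all_insp * 1000),
    insp_sd_ms = sd(all_insp * 1000),
    exp_median_ms = if (length(all_exp)) median(all_exp * 1000) else NA_real_,
    exp_sd_ms = if (length(all_exp)) sd(all_exp * 1000) else NA_real_,
    vt_abs_median_l = if (nrow(vt_all)) median(abs(vt_all$vt_pred - vt_all$vt_ref)) else NA_real_,
    vt_bias_l = if (!is.null(ba)) ba$bias else NA_real_,
    vt_r_min = min(per_subject$vt_r, na.rm = TRUE),
    flow_r = cor(sync_all$flow_ref, sync_all$flow_pred),
    flow_r_min = min(per_subject$flow_r, na.rm = TRUE),
    medae_flow_l = median(abs(sync_all$flow_pred - sync_all$flow_ref)))

  structure(list(per_subject = per_subject, pooled = pooled,
                 bland_altman = ba, details = details),
            class = "respiq_agreement")
}

#' @export
print.respiq_agreement <- function(x, ...) {
  cat(sprintf("<respiq_agreement> %d subjects, detection rate %.3f, pooled onset medians %+.0f / %+.0f ms (insp/exp)\n",
              x$pooled$n_subjects, x$pooled$detection_rate,
              x$pooled$insp_median_ms, x$pooled$exp_median_ms))
  print(x$per_subject)
  invisible(x)
}

#' @method tidy respiq_agreement
#' @export
tidy.respiq_agreement <- function(x, ...) x$per_subject

#' @method glance respiq_agreement
#' @export
glance.respiq_agreement <- function(x, ...) x$pooled

#' Write an agreement report to disk
#'
#' Writes `report.json` (pooled metrics, per-subject table and Bland-Altman
#' parameters) and `per_subject.csv`.
#'
#' @param report A [full_report()] result.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "respiq_agreement"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  payload <- list(pooled = report$pooled, per_subject = report$per_subject,
                  bland_altman = report$bland_altman)
  jsonlite::write_json(payload, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  readr::write_csv(report$per_subject, file.path(path, "per_subject.csv"))
  invisible(path)
}

#' Read back a written agreement report
#'
#' @param path Directory written by [write_report()].
#' @return List with `pooled`, `per_subject`, `bland_altman` tibbles.
#' @export
read_report <- function(path) {
  f <- file.path(path, "report.json")
  if (!file.exists(f)) abort(sprintf("missing report file '%s'", f))
  raw <- jsonlite::read_json(f, simplifyVector = TRUE)
  list(pooled = as_tibble(raw$pooled), per_subject = as_tibble(raw$per_subject),
       bland_altman = if (!is.null(raw$bland_altman)) as_tibble(raw$bland_altman) else NULL)
}
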
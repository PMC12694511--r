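sine_flow <- function(A = 0.4, T = 4, dur = 12, fs = 100) {
  t <- seq(0, dur, by = 1 / fs)
  tibble::tibble(t = t, flow = A * sin(2 * pi * t / T))
}

test_that("zero-crossing onsets land where the sinusoid crosses", {
  ons <- detect_onsets(sine_flow(), hysteresis = 0)
  expect_equal(ons$insp, c(0, 4, 8), tolerance = 1e-6)
  expect_equal(ons$exp, c(2, 6, 10), tolerance = 1e-6)

  flat <- tibble::tibble(t = seq(0, 10, by = 0.01), flow = 0)
  ons0 <- detect_onsets(flat)
  expect_length(ons0$insp, 0)
  expect_length(ons0$exp, 0)
})

test_that("hysteresis separates noise crossings from breath crossings", {
  set.seed(10)
  t <- seq(0, 30, by = 0.01)
  noise <- tibble::tibble(t = t, flow = runif(length(t), -0.02, 0.02))
  expect_length(detect_onsets(noise, hysteresis = 0.03)$insp, 0)
  ons_raw <- detect_onsets(noise, hysteresis = 0)
  # brute-force crossing count over the same samples
  f <- noise$flow
  n_up <- sum(f[-length(f)] <= 0 & f[-1] > 0)
  expect_gt(length(ons_raw$insp), 50)
  expect_lte(length(ons_raw$insp), n_up)
})

test_that("onset lists strictly alternate and increase on noisy breathing", {
  set.seed(11)
  t <- seq(0, 60, by = 0.01)
  f <- 0.4 * sin(2 * pi * t / 4) + rnorm(length(t), 0, 0.01)
  ons <- detect_onsets(tibble::tibble(t = t, flow = f), hysteresis = 0.03)
  merged <- rbind(data.frame(tm = ons$insp, d = 1),
                  data.frame(tm = ons$exp, d = -1))
  merged <- merged[order(merged$tm), ]
  expect_true(all(diff(merged$tm) > 0))
  expect_true(all(abs(diff(merged$d)) == 2))
})

test_that("a half-sine cycle yields the closed-form tidal volume and class", {
  A <- 0.4; T <- 4
  flow <- sine_flow(A, T, dur = 12)
  seg <- segment_cycles(detect_onsets(flow, hysteresis = 0), flow)
  expect_equal(nrow(seg$cycles), 3)  # the record holds three whole cycles
  expect_equal(seg$cycles$duration, rep(4, 3), tolerance = 1e-3)
  expect_equal(seg$cycles$rate_class, rep("normal", 3))
  expect_equal(seg$cycles$tidal_volume, rep(A * T / pi, 3),
               tolerance = 1e-4 / (A * T / pi))
})

test_that("tidal volume is robust to sub-hysteresis noise", {
  A <- 0.4; T <- 4; h <- 0.03
  clean <- sine_flow(A, T, dur = 12)
  vt_clean <- segment_cycles(detect_onsets(clean, h), clean)$cycles$tidal_volume
  set.seed(12)
  noisy <- clean
  noisy$flow <- noisy$flow + rnorm(nrow(noisy), 0, h / 3)
  vt_noisy <- segment_cycles(detect_onsets(noisy, h), noisy)$cycles$tidal_volume
  expect_equal(length(vt_noisy), length(vt_clean))
  expect_lt(max(abs(vt_noisy - vt_clean) / vt_clean), 0.02)
})

test_that("segmentation recovers scripted cycles exactly, apnea included", {
  script <- breathing_script(tibble::tibble(
    pattern = c("normal", "apnea", "fast", "slow"),
    duration = c(24, 16, 12, 32), rate = c(15, NA, 25, 7.5),
    tidal_volume = c(0.55, 0, 0.45, 0.6)),
    vt_jitter = 0.1, rate_jitter = 0.05, seed = 21)
  flow <- generate_flow(script, sample_rate = 100)
  truth <- scripted_cycles(flow)
  seg <- segment_cycles(detect_onsets(flow, hysteresis = 0.03), flow,
                        apnea_min_duration = 10)
  expect_equal(nrow(seg$cycles), nrow(truth))
  expect_equal(seg$cycles$insp_onset, truth$insp_onset, tolerance = 0.011)
  expect_lt(max(abs(seg$cycles$duration - truth$duration)), 0.011)
  expect_equal(seg$cycles$tidal_volume, truth$tidal_volume, tolerance = 0.02)
  # the scripted 16 s silent gap is reported as apnea
  expect_gte(nrow(seg$apnea), 1)
  expect_true(any(seg$apnea$start >= 23 & seg$apnea$end <= 41))
})

test_that("duration class boundaries are closed as printed", {
  # constructed cycles at exactly the printed boundary durations
  for (case in list(list(T = 2.5, cls = "fast"), list(T = 3, cls = "fast"),
                    list(T = 4.5, cls = "normal"), list(T = 6, cls = "slow"),
                    list(T = 7, cls = "slow"))) {
    flow <- sine_flow(A = 0.4, T = case$T, dur = 3 * case$T, fs = 200)
    seg <- segment_cycles(detect_onsets(flow, hysteresis = 0), flow)
    expect_equal(seg$cycles$rate_class[1], case$cls,
                 label = sprintf("duration %.1f s", case$T))
  }
})

test_that("reliability gating marks and excludes masked cycles", {
  flow <- sine_flow(A = 0.4, T = 4, dur = 20)
  ons <- detect_onsets(flow, hysteresis = 0)
  mask <- flow$t >= 4 & flow$t <= 8  # second cycle fully masked
  seg <- segment_cycles(ons, flow, unreliable_mask = mask)
  expect_false(seg$cycles$reliable[2])
  expect_true(all(seg$cycles$reliable[-2]))
  expect_equal(cycle_count(seg$cycles), nrow(seg$cycles) - 1L)
  expect_equal(cycle_count(seg$cycles, include_unreliable = TRUE),
               nrow(seg$cycles))
  expect_equal(cycle_count(seg$cycles[0, ]), 0L)
})

test_that("non-alternating onset lists are a structural error", {
  flow <- sine_flow()
  bad <- list(insp = c(1, 2), exp = c(5), raw_up = c(1, 2))
  expect_error(segment_cycles(bad, flow), "alternate")
})
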
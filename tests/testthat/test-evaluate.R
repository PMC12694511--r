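# Fabricate a reconstruction object from a deterministic prediction series so
# the evaluation layer can be tested in isolation from the model.
fake_recon <- function(t, flow_pred, reliability = 0, threshold = 0.5,
                       subject_id = "SX") {
  structure(list(
    samples = tibble::tibble(t = t, flow_mean = flow_pred,
                             flow_sd = reliability * 0.5,
                             reliability = rep_len(reliability, length(t)),
                             unreliable = rep_len(reliability, length(t)) > threshold),
    threshold = threshold, s_ref = 0.5, subject_id = subject_id,
    fold = 1L, mc_passes = 10L, stride = 1L), class = "respiq_recon")
}

test_that("synchronization picks the common window and interpolates", {
  ref <- tibble::tibble(t = seq(0, 100, by = 0.01), flow = sin(seq(0, 100, by = 0.01)))
  pred <- fake_recon(seq(5, 90, by = 0.01), cos(seq(5, 90, by = 0.01)))
  sync <- synchronize(ref, pred)
  expect_equal(range(sync$t), c(5, 90))
  expect_equal(sync$flow_ref, sin(sync$t), tolerance = 1e-4)

  # identical grids: identity
  same <- synchronize(ref, fake_recon(ref$t, ref$flow))
  expect_identical(same$flow_ref, same$flow_pred)

  # interpolated value equals the hand-computed blend of bracketing samples
  coarse <- tibble::tibble(t = c(0, 1, 2), flow = c(0, 4, -2))
  fine <- fake_recon(seq(0, 2, by = 0.25), 0)
  sy <- synchronize(coarse, fine)
  expect_equal(sy$flow_ref[sy$t == 0.75], 0.25 * 0 + 0.75 * 4)
  expect_equal(sy$flow_ref[sy$t == 1.5], 0.5 * 4 + 0.5 * (-2))

  expect_error(synchronize(tibble::tibble(t = 0:10, flow = 0),
                           fake_recon(20:30, 0)), "overlap")
})

test_that("onset pairing matches nearest neighbours one-to-one", {
  ref <- c(1, 5, 9)
  same <- pair_onsets(ref, ref, tolerance = 1)
  expect_equal(nrow(same$pairs), 3)
  expect_equal(same$pairs$error, rep(0, 3))

  shifted <- pair_onsets(ref, ref + 0.060, tolerance = 1)
  expect_equal(shifted$pairs$error, rep(0.060, 3), tolerance = 1e-12)
  expect_length(shifted$unmatched_ref, 0)

  # beyond tolerance nothing pairs; inside it everything does
  expect_equal(nrow(pair_onsets(ref, ref + 2, tolerance = 1)$pairs), 0)
  expect_equal(nrow(pair_onsets(ref, ref + 0.5, tolerance = 1)$pairs), 3)
})

test_that("greedy pairing equals the exhaustive minimum-cost assignment", {
  ref <- c(1.0, 2.0, 3.0)
  pred <- c(1.4, 2.45)
  tol <- 1
  pairing <- pair_onsets(ref, pred, tol)
  # brute force over all one-to-one assignments of pred onto ref
  best <- NULL
  for (a in 1:3) for (b in setdiff(1:3, a)) {
    err <- c(pred[1] - ref[a], pred[2] - ref[b])
    if (all(abs(err) <= tol)) {
      cost <- sum(abs(err))
      if (is.null(best) || cost < best$cost) {
        best <- list(cost = cost, assign = c(a, b))
      }
    }
  }
  expect_equal(sort(pairing$pairs$ref), sort(ref[best$assign]))
  expect_equal(sum(abs(pairing$pairs$error)), best$cost, tolerance = 1e-12)
})

test_that("pairing is symmetric under swapping roles, with errors negated", {
  set.seed(13)
  a <- sort(runif(8, 0, 60))
  b <- sort(a + rnorm(8, 0, 0.2))
  ab <- pair_onsets(a, b, tolerance = 1.5)
  ba <- pair_onsets(b, a, tolerance = 1.5)
  expect_equal(nrow(ab$pairs), nrow(ba$pairs))
  expect_equal(sort(ab$pairs$error), sort(-ba$pairs$error), tolerance = 1e-12)
})

test_that("detection rate counts matches over eligible reference onsets", {
  ref <- seq_len(50)
  pred <- ref[-50]  # one miss
  pairing <- pair_onsets(ref, pred, tolerance = 0.4)
  expect_equal(detection_rate(pairing), 49 / 50)
  expect_equal(detection_rate(pair_onsets(ref, ref, 0.4)), 1.0)
  # a rejected (reliability-flagged) reference onset leaves the denominator
  expect_equal(detection_rate(pairing, rejected_ref = 50), 1.0)
  expect_equal(detection_rate(pairing, rejected_ref = 50, strict = TRUE), 0.98)
})

test_that("Bland-Altman statistics match their definitions", {
  set.seed(14)
  ref <- runif(40, 0.3, 0.8)
  same <- bland_altman(ref, ref)
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_lower, same$loa_upper, same$slope), c(0, 0, 0))

  shifted <- bland_altman(ref, ref - 0.33)
  expect_equal(shifted$bias, -0.33)
  expect_equal(shifted$sd_diff, 0)

  prop <- bland_altman(ref, 0.6 * ref)
  expect_lt(prop$slope, 0)
  # closed-form least squares on the constructed pairs
  d <- 0.6 * ref - ref; m <- (0.6 * ref + ref) / 2
  expect_equal(prop$slope, cov(d, m) / var(m), tolerance = 1e-12)
  expect_equal(prop$bias, mean(d))
  expect_error(bland_altman(1:2, 1:2), "3 pairs")
})

test_that("timing-error summaries match brute-force statistics", {
  ref <- seq(0, 36, by = 4)
  const <- pair_onsets(ref, ref + 0.060, tolerance = 1)
  st <- timing_error_stats(const)
  expect_equal(st$median_ms, 60, tolerance = 1e-9)
  expect_equal(st$sd_ms, 0, tolerance = 1e-9)

  alt <- pair_onsets(ref, ref + rep(c(0.05, -0.05), 5), tolerance = 1)
  expect_equal(timing_error_stats(alt)$median_ms, 0)

  set.seed(15)
  errs <- rnorm(10, 0.02, 0.05)
  rnd <- pair_onsets(ref, ref + errs, tolerance = 1)
  st <- timing_error_stats(rnd, ref_classes = rep(c("fast", "slow"), 5))
  expect_equal(st$median_ms[st$rate_class == "all"], median(errs * 1000))
  expect_equal(st$sd_ms[st$rate_class == "all"], sd(errs * 1000))
  expect_equal(st$median_ms[st$rate_class == "fast"],
               median(errs[c(TRUE, FALSE)] * 1000))
  expect_error(timing_error_stats(pair_onsets(1, 10, 0.5)), "no pairs")
})

# a deterministic end-to-end evaluation case: prediction = scaled + delayed
# reference, so every metric has a known value
eval_case <- function(t0 = 0) {
  script <- breathing_script(tibble::tibble(
    pattern = c("normal", "slow"), duration = c(80, 40),
    rate = c(15, 7.5), tidal_volume = c(0.55, 0.6)),
    vt_jitter = 0.1, seed = 31)
  flow <- generate_flow(script, sample_rate = 100)
  flow$t <- flow$t + t0
  delay <- 0.06
  pred_flow <- approx(flow$t + delay, 0.8 * flow$flow, xout = flow$t,
                      rule = 2)$y
  list(flow = flow, recon = fake_recon(flow$t, pred_flow))
}

test_that("a delayed, scaled prediction yields the expected agreement metrics", {
  ec <- eval_case()
  ev <- evaluate_subject(ec$flow, ec$recon, tolerance = 1)
  m <- ev$metrics
  expect_equal(m$detection_rate, 1.0)
  expect_equal(m$insp_median_ms, 60, tolerance = 0.25)
  expect_equal(m$exp_median_ms, 60, tolerance = 0.25)
  expect_lt(m$insp_sd_ms, 20)
  expect_gt(m$vt_r, 0.95)           # trends preserved under amplitude bias
  expect_equal(m$vt_bias_l, -0.2 * mean(ev$vt_pairs$vt_ref), tolerance = 0.15)
  expect_gt(m$flow_r, 0.99)
})

test_that("agreement metrics are invariant to uniform time translation", {
  a <- eval_case(0)
  b <- eval_case(500)
  ma <- evaluate_subject(a$flow, a$recon, tolerance = 1)$metrics
  mb <- evaluate_subject(b$flow, b$recon, tolerance = 1)$metrics
  expect_equal(ma$insp_median_ms, mb$insp_median_ms, tolerance = 1e-6)
  expect_equal(ma$detection_rate, mb$detection_rate)
  expect_equal(ma$vt_bias_l, mb$vt_bias_l, tolerance = 1e-6)
})

test_that("identical traces give perfect agreement end to end", {
  ec <- eval_case()
  perfect <- fake_recon(ec$flow$t, ec$flow$flow)
  ev <- evaluate_subject(ec$flow, perfect, tolerance = 1, smooth_hz = NULL)
  expect_equal(ev$metrics$detection_rate, 1.0)
  expect_equal(ev$metrics$insp_median_ms, 0, tolerance = 1e-6)
  expect_equal(ev$metrics$vt_bias_l, 0, tolerance = 1e-9)
  expect_equal(ev$metrics$medae_flow_l, 0, tolerance = 1e-12)
})

test_that("reports pool per-subject errors correctly and round-trip to disk", {
  ec1 <- eval_case()
  cv_like <- tibble::tibble(
    subject_id = c("A", "B"),
    recon = list(ec1$recon, fake_recon(ec1$flow$t, ec1$flow$flow, subject_id = "B")),
    flow = list(ec1$flow, ec1$flow))
  rep <- full_report(cv_like, tolerance = 1)
  expect_s3_class(rep, "respiq_agreement")
  all_errs <- unlist(purrr::map(rep$details, function(d) d$pairing_insp$pairs$error))
  expect_equal(rep$pooled$insp_median_ms, median(all_errs * 1000))
  expect_equal(tidy(rep), rep$per_subject)
  expect_equal(glance(rep), rep$pooled)

  dir <- withr::local_tempdir()
  write_report(rep, dir)
  back <- read_report(dir)
  expect_equal(back$pooled$detection_rate, rep$pooled$detection_rate)
  expect_equal(back$per_subject$subject_id, rep$per_subject$subject_id)
  expect_equal(back$bland_altman$bias, rep$bland_altman$bias, tolerance = 1e-12)
})
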
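# Shared fixtures. Heavy end-to-end artefacts are computed once per test run
# and memoised here so several test files can interrogate the same run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# One clean simulated subject (120 s, default profile), with its I/Q record.
single_subject <- function() {
  fixture("single_subject", function() {
    script <- breathing_script(
      tibble::tibble(pattern = c("normal", "fast"),
                     duration = c(80, 40), rate = c(15, 25),
                     tidal_volume = c(0.55, 0.45), ie = c(0.8, 1)),
      seed = 3)
    flow <- generate_flow(script, sample_rate = 100)
    iq <- simulate_iq(flow, dipole_geometry(), medium_model(), carrier_config(),
                      subject_profile(), seed = 5)
    list(script = script, flow = flow, iq = iq)
  })
}

# The full-scale cross-validated run: 6 subjects x 180 s, subject-grouped
# 3-fold cross-validation with the published model configuration.
e2e_run <- function() {
  fixture("e2e_run", function() {
    run_pipeline(respiq_config(seed = 1), quiet = TRUE)
  })
}

# Reliability demonstration: an extra subject with a low-signal interval,
# reconstructed with a model trained on clean subjects only.
dropout_demo <- function() {
  fixture("dropout_demo", function() {
    res <- e2e_run()
    bundle <- attr(res$cv, "fits")[[1]]
    extra <- simulate_cohort(n_subjects = 1, duration_s = 180, seed = 101,
                             gain_range = c(1.2, 1.2), dropout_subject = 1,
                             dropout_window = c(95, 120),
                             dropout_attenuation = 0.05)
    recon <- reconstruct_record(bundle, extra$iq[[1]], seed = 11,
                                subject_id = "DX")
    list(flow = extra$flow[[1]], iq = extra$iq[[1]], recon = recon,
         window = c(95, 120))
  })
}

sample_skewness <- function(x) {
  mean((x - mean(x))^3) / sd(x)^3
}
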
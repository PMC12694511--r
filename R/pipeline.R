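#' Run configuration for a full reconstruction experiment
#'
#' Bundles the simulator, preprocessing, model and evaluation settings that a
#' complete run needs, with the package defaults. Every stochastic stage
#' derives its own seed deterministically from the global seed plus a stage
#' label, so a configuration plus one integer reproduces a run exactly.
#'
#' @param n_subjects,duration_s Cohort size and per-subject record length.
#' @param gain_range Coupling-gain magnitude range across subjects.
#' @param dropout_subject Subject index given a low-signal interval (`NA` none).
#' @param k Cross-validation folds (subject-grouped).
#' @param feature_rate Feature grid rate, Hz.
#' @param train_stride,predict_stride Row decimation for training / MC
#'   inference (see [cross_validated_reconstruction()]).
#' @param threshold Reliability threshold.
#' @param hysteresis,smooth_hz,edge_trim,apnea_min_duration Evaluation
#'   settings (see [evaluate_subject()]).
#' @param model An [mlp_config()].
#' @param seed Global integer seed.
#' @return An object of class `respiq_config` (a named list).
#' @export
respiq_config <- function(n_subjects = 6, duration_s = 180,
                          gain_range = c(0.5, 2), dropout_subject = NA,
                          k = 3, feature_rate = 100, train_stride = 12,
                          predict_stride = 4, threshold = 0.5,
                          hysteresis = 0.03, smooth_hz = 2, edge_trim = 5,
                          apnea_min_duration = 10,
                          model = mlp_config(), seed = 1L) {
  structure(list(n_subjects = n_subjects, duration_s = duration_s,
                 gain_range = gain_range, dropout_subject = dropout_subject,
                 k = k, feature_rate = feature_rate,
                 train_stride = train_stride, predict_stride = predict_stride,
                 threshold = threshold, hysteresis = hysteresis,
                 smooth_hz = smooth_hz, edge_trim = edge_trim,
                 apnea_min_duration = apnea_min_duration, model = model,
                 seed = as.integer(seed)),
            class = "respiq_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path File path.
#' @param config A [respiq_config()].
#' @return `read_config()` returns a `respiq_config`; `write_config()` the
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "respiq_config"))
  x <- unclass(config)
  x$model <- unclass(x$model)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing config file '%s'", path))
  x <- yaml::read_yaml(path)
  model_args <- x$model %||% list()
  x$model <- NULL
  base <- respiq_config()
  known <- intersect(names(x), names(base))
  unknown <- setdiff(names(x), names(base))
  if (length(unknown)) {
    abort(paste("unknown config field(s):", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(unclass(base), x)
  cfg$model <- do.call(mlp_config, model_args)
  cfg$seed <- as.integer(cfg$seed)
  cfg$dropout_subject <- if (is.null(cfg$dropout_subject) ||
                             is.na(cfg$dropout_subject)) NA else cfg$dropout_subject
  structure(cfg, class = "respiq_config")
}

#' Run the full simulate-reconstruct-evaluate pipeline
#'
#' Simulates the configured cohort, builds features, trains the
#' subject-grouped cross-validated MLP, reconstructs every subject with
#' Monte-Carlo-dropout reliability, and evaluates agreement. When `out_dir`
#' is given, the datasets, report and a stamped run log (config hash, seed,
#' stage timings) are written there; an existing output directory stamped
#' with a different config hash is refused unless `force = TRUE`.
#'
#' @param config A [respiq_config()].
#' @param seed Overrides `config$seed` when given.
#' @param out_dir Optional output directory.
#' @param force Overwrite an output directory with a mismatched config hash.
#' @param quiet Suppress progress messages.
#' @return List with `cohort`, `cv` (reconstructions) and `report`.
#' @export
run_pipeline <- function(config = respiq_config(), seed = NULL,
                         out_dir = NULL, force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "respiq_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  hash <- config_hash(unclass(config))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  if (!is.null(out_dir)) {
    stamp_file <- file.path(out_dir, "config_hash.txt")
    if (file.exists(stamp_file)) {
      old <- readLines(stamp_file, warn = FALSE)[1]
      if (!identical(old, hash) && !force) {
        abort(sprintf("output directory '%s' was produced with config hash %s (this run: %s); use force = TRUE to overwrite",
                      out_dir, old, hash))
      }
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  timings <- list()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(Sys.time() - t0, units = "secs")

  t0 <- tic()
  cohort <- simulate_cohort(
    n_subjects = config$n_subjects, duration_s = config$duration_s,
    seed = config$seed, gain_range = config$gain_range,
    dropout_subject = config$dropout_subject, flow_rate = config$feature_rate)
  timings$simulate <- toc(t0)
  say("simulated %d subjects x %.0f s (%.1f s)", nrow(cohort),
      config$duration_s, timings$simulate)

  t0 <- tic()
  cv <- cross_validated_reconstruction(
    cohort, k = config$k, config = config$model, seed = config$seed,
    feature_rate = config$feature_rate, train_stride = config$train_stride,
    predict_stride = config$predict_stride, threshold = config$threshold)
  timings$reconstruct <- toc(t0)
  say("cross-validated reconstruction done (%.1f s)", timings$reconstruct)

  t0 <- tic()
  report <- full_report(cv, hysteresis = config$hysteresis,
                        smooth_hz = config$smooth_hz,
                        edge_trim = config$edge_trim,
                        apnea_min_duration = config$apnea_min_duration)
  timings$evaluate <- toc(t0)
  say("evaluation done (%.1f s): detection %.3f, insp median %+.0f ms",
      timings$evaluate, report$pooled$detection_rate, report$pooled$insp_median_ms)

  if (!is.null(out_dir)) {
    for (s in seq_len(nrow(cohort))) {
      meta <- c(list(seed = config$seed, config_hash = hash),
                profile_meta(cohort$profile[[s]]))
      write_dataset(cohort$flow[[s]], cohort$iq[[s]],
                    file.path(out_dir, cohort$subject_id[s]), meta = meta)
    }
    write_report(report, out_dir)
    writeLines(hash, file.path(out_dir, "config_hash.txt"))
    yaml::write_yaml(list(config_hash = hash, seed = config$seed,
                          timings = timings),
                     file.path(out_dir, "run_log.yaml"))
  }
  list(cohort = cohort, cv = cv, report = report, config_hash = hash,
       timings = timings)
}

profile_meta <- function(profile) {
  list(subject_id = profile$subject_id,
       coupling_gain_mod = Mod(profile$coupling_gain),
       coupling_gain_arg = Arg(profile$coupling_gain),
       noise_sd = profile$noise_sd,
       dropout_intervals = if (nrow(profile$dropout_intervals)) {
         as.list(as.data.frame(profile$dropout_intervals))
       } else NULL)
}
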
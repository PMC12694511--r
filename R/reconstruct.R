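#' Subject-grouped fold plan
#'
#' Assigns whole subjects to folds so that no subject's samples ever span the
#' training and validation side of the same model (group k-fold). Assignment
#' is balanced (fold sizes differ by at most one subject) and deterministic
#' under `seed`; subject order in the input does not matter.
#'
#' @param subject_ids Character vector of subject ids (duplicates allowed).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Tibble with columns `subject_id`, `fold`.
#' @export
make_fold_plan <- function(subject_ids, k = 10, seed = 1L) {
  ids <- sort(unique(subject_ids))
  if (length(ids) < k) {
    abort(sprintf("need at least k = %d distinct subjects, got %d", k, length(ids)))
  }
  set.seed(derive_seed(seed, "fold_plan"))
  shuffled <- sample(ids)
  tibble(subject_id = shuffled,
         fold = rep_len(seq_len(k), length(ids))) |>
    dplyr::arrange(.data$subject_id)
}

#' Monte-Carlo-dropout flow reconstruction for one record
#'
#' Runs the configured number of stochastic forward passes, inverse-transforms
#' every pass back to L/s, and summarises them per sample: `flow_mean` and
#' `flow_sd` are the across-pass mean and standard deviation in physical
#' units. The reliability score is `flow_sd / s_ref`, where `s_ref` is the
#' robust scale (IQR) of the training-fold flow targets in L/s, so a score of
#' 1 means the model's spread equals the typical flow spread it was trained
#' on; samples with score above `threshold` (default 0.5, the balanced
#' operating point) are masked unreliable.
#'
#' To bound inference cost, passes can be evaluated on every `stride`-th
#' feature row and interpolated back to the full grid (respiratory flow lives
#' well below the grid Nyquist, so this loses nothing at moderate strides).
#'
#' @param fit A trained [mlp_fit()].
#' @param features Scaled feature tibble (`t` + feature columns) for the
#'   record to reconstruct.
#' @param target_state The training fold's target transform
#'   ([fit_transform_state()] on the `flow` column), used to inverse-transform
#'   each pass.
#' @param s_ref Robust scale (IQR) of the training targets in L/s.
#' @param threshold Reliability threshold (dimensionless).
#' @param seed Integer seed for the dropout streams.
#' @param stride Evaluate passes on every `stride`-th row (>= 1).
#' @param subject_id,fold Provenance labels carried into the result.
#' @return An object of class `respiq_recon` with element `samples`: a tibble
#'   `t`, `flow_mean`, `flow_sd`, `reliability`, `unreliable`.
#' @export
predict_mc <- function(fit, features, target_state, s_ref, threshold = 0.5,
                       seed = 1L, stride = 1L, subject_id = NA_character_,
                       fold = NA_integer_) {
  stopifnot(inherits(fit, "respiq_mlp"))
  if (s_ref <= 0) abort("s_ref must be > 0")
  feats <- as_tibble(features)
  cols <- setdiff(names(feats), "t")
  rows <- seq(1L, nrow(feats), by = as.integer(stride))
  if (rows[length(rows)] != nrow(feats)) rows <- c(rows, nrow(feats))
  x <- as.matrix(feats[rows, cols])
  passes <- mlp_mc_passes(fit, x, seed = seed)
  phys <- apply(passes, 2, invert_transform, state = target_state, column = "flow")
  mu_s <- rowMeans(phys)
  sd_s <- apply(phys, 1, sd)
  t_s <- feats$t[rows]
  mu <- approx(t_s, mu_s, xout = feats$t, rule = 2)$y
  sdv <- approx(t_s, sd_s, xout = feats$t, rule = 2)$y
  rel <- sdv / s_ref
  structure(list(
    samples = tibble(t = feats$t, flow_mean = mu, flow_sd = sdv,
                     reliability = rel, unreliable = rel > threshold),
    threshold = threshold, s_ref = s_ref, subject_id = subject_id,
    fold = fold, mc_passes = ncol(passes), stride = as.integer(stride)),
    class = "respiq_recon")
}

#' @export
print.respiq_recon <- function(x, ...) {
  cat(sprintf("<respiq_recon> %s: %d samples, %.1f%% unreliable (threshold %.2f, %d MC passes)\n",
              x$subject_id %||% "?", nrow(x$samples),
              100 * mean(x$samples$unreliable), x$threshold, x$mc_passes))
  invisible(x)
}

#' @method tidy respiq_recon
#' @export
tidy.respiq_recon <- function(x, ...) {
  dplyr::mutate(x$samples, subject_id = x$subject_id, fold = x$fold,
                .before = 1)
}

#' @method glance respiq_recon
#' @export
glance.respiq_recon <- function(x, ...) {
  tibble(subject_id = x$subject_id, fold = x$fold, n = nrow(x$samples),
         prop_unreliable = mean(x$samples$unreliable),
         median_reliability = median(x$samples$reliability),
         threshold = x$threshold, s_ref = x$s_ref)
}

#' Subject-independent cross-validated flow reconstruction
#'
#' For every fold of a subject-grouped plan, fits the feature and target
#' transform states on the training subjects only (leakage guard), trains the
#' MLP on their (decimated) feature rows, and reconstructs each held-out
#' subject with Monte-Carlo dropout — so every subject's reconstruction comes
#' from a model that never saw that subject. The flow target is the reference
#' flow linearly interpolated onto the feature grid; all reported flows are
#' inverse-transformed back to L/s.
#'
#' @param cohort Nested tibble as from [simulate_cohort()] (columns
#'   `subject_id`, `flow`, `iq` at minimum).
#' @param k Number of folds.
#' @param config An [mlp_config()].
#' @param seed Global seed; folds and subjects derive their own streams.
#' @param feature_rate Feature grid rate in Hz.
#' @param train_stride Take every `train_stride`-th feature row for training
#'   (respiratory content is band-limited far below the grid rate, so
#'   decimated rows carry the same information at a fraction of the cost).
#' @param predict_stride Stride for Monte-Carlo inference (see
#'   [predict_mc()]).
#' @param threshold Reliability threshold.
#' @return Tibble with one row per subject: `subject_id`, `fold`, list-columns
#'   `recon` ([predict_mc()] results) and `flow` (the reference flow), with
#'   the fold plan and per-fold fits attached as attributes `"fold_plan"` and
#'   `"fits"`.
#' @export
cross_validated_reconstruction <- function(cohort, k = 3, config = mlp_config(),
                                           seed = 1L, feature_rate = 100,
                                           train_stride = 12L,
                                           predict_stride = 4L,
                                           threshold = 0.5) {
  check_cols(cohort, c("subject_id", "flow", "iq"), "cohort")
  cohort <- dplyr::arrange(as_tibble(cohort), .data$subject_id)
  plan <- make_fold_plan(cohort$subject_id, k = k, seed = seed)

  missing <- setdiff(cohort$subject_id, plan$subject_id)
  if (length(missing) > 0) {
    abort(paste("fold plan does not cover subject(s):", paste(missing, collapse = ", ")))
  }

  prepared <- purrr::map2(cohort$iq, cohort$flow, function(iq, flow) {
    feats <- build_features(iq, state = "raw", sample_rate = feature_rate)
    target <- approx(flow$t, flow$flow, xout = feats$t, rule = 2)$y
    list(features = feats, target = target)
  })
  names(prepared) <- cohort$subject_id

  fits <- list()
  recon_rows <- vector("list", nrow(cohort))
  for (f in sort(unique(plan$fold))) {
    train_ids <- plan$subject_id[plan$fold != f]
    val_ids <- intersect(cohort$subject_id, plan$subject_id[plan$fold == f])
    if (length(val_ids) == 0) next

    tr <- purrr::map(train_ids, function(sid) {
      p <- prepared[[sid]]
      rows <- seq(1L, nrow(p$features), by = as.integer(train_stride))
      list(features = p$features[rows, ], target = p$target[rows])
    })
    tr_feats <- dplyr::bind_rows(purrr::map(tr, "features"))
    tr_target <- unlist(purrr::map(tr, "target"))

    feat_state <- fit_transform_state(tr_feats)
    target_state <- fit_transform_state(tibble(t = 0, flow = tr_target))
    s_ref <- unname(diff(quantile(tr_target, c(0.25, 0.75), names = FALSE)))

    x_tr <- as.matrix(apply_transform(tr_feats, feat_state, clip = 8)[-1])
    y_tr <- apply_transform(tibble(flow = tr_target), target_state)$flow
    fit <- mlp_fit(x_tr, y_tr, config = config,
                   seed = derive_seed(seed, paste0("fold/", f)))
    fits[[as.character(f)]] <- list(fit = fit, feat_state = feat_state,
                                    target_state = target_state, s_ref = s_ref,
                                    train_ids = train_ids)

    for (sid in val_ids) {
      scaled <- apply_transform(prepared[[sid]]$features, feat_state, clip = 8)
      recon <- predict_mc(fit, scaled, target_state, s_ref,
                          threshold = threshold,
                          seed = derive_seed(seed, paste0("predict/", sid)),
                          stride = predict_stride, subject_id = sid,
                          fold = f)
      recon_rows[[match(sid, cohort$subject_id)]] <- recon
    }
  }

  still_missing <- cohort$subject_id[purrr::map_lgl(recon_rows, is.null)]
  if (length(still_missing) > 0) {
    abort(paste("no reconstruction produced for subject(s):",
                paste(still_missing, collapse = ", ")))
  }
  out <- tibble(
    subject_id = cohort$subject_id,
    fold = purrr::map_int(recon_rows, function(r) as.integer(r$fold)),
    recon = recon_rows,
    flow = cohort$flow)
  attr(out, "fold_plan") <- plan
  attr(out, "fits") <- fits
  out
}

#' Reconstruct a new record with an already-trained fold model
#'
#' Applies one fold's trained bundle (model, feature transform state, target
#' transform state, reference scale) from
#' [cross_validated_reconstruction()]'s `"fits"` attribute to a new I/Q
#' record, e.g. a recording from a subject the model never saw.
#'
#' @param bundle One element of `attr(cv, "fits")`.
#' @param iq I/Q tibble (`t`, `i`, `q`).
#' @param feature_rate Feature grid rate in Hz.
#' @param stride Monte-Carlo inference stride (see [predict_mc()]).
#' @param threshold Reliability threshold.
#' @param seed Integer seed for the dropout streams.
#' @param subject_id Label carried into the result.
#' @return A [predict_mc()] result.
#' @export
reconstruct_record <- function(bundle, iq, feature_rate = 100, stride = 4L,
                               threshold = 0.5, seed = 1L,
                               subject_id = NA_character_) {
  feats <- build_features(iq, state = "raw", sample_rate = feature_rate)
  scaled <- apply_transform(feats, bundle$feat_state, clip = 8)
  predict_mc(bundle$fit, scaled, bundle$target_state, bundle$s_ref,
             threshold = threshold, seed = seed, stride = stride,
             subject_id = subject_id)
}
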
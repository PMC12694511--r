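#' Plot a reconstructed flow trace
#'
#' Mean reconstructed flow with a +/- 1 SD Monte-Carlo ribbon; intervals the
#' reliability score flags as unreliable are shaded.
#'
#' @param object A [predict_mc()] result.
#' @param reference Optional reference flow tibble (`t`, `flow`) to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot respiq_recon
#' @method autoplot respiq_recon
#' @export
autoplot.respiq_recon <- function(object, reference = NULL, ...) {
  s <- object$samples
  runs <- mask_runs(s$t, s$unreliable)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$t))
  if (nrow(runs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = runs,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "red", alpha = 0.12)
  }
  p <- p + ggplot2::geom_ribbon(
    ggplot2::aes(ymin = .data$flow_mean - .data$flow_sd,
                 ymax = .data$flow_mean + .data$flow_sd),
    fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$flow_mean), colour = "steelblue")
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_line(
      data = reference, ggplot2::aes(x = .data$t, y = .data$flow),
      colour = "darkgreen", linewidth = 0.3, alpha = 0.8)
  }
  p + ggplot2::labs(x = "time (s)", y = "flow (L/s)",
                    title = sprintf("Reconstructed flow%s",
                                    if (!is.na(object$subject_id)) paste0(" - ", object$subject_id) else ""))
}

#' Bland-Altman plot of tidal-volume agreement
#'
#' @param object A [full_report()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot respiq_agreement
#' @method autoplot respiq_agreement
#' @export
autoplot.respiq_agreement <- function(object, ...) {
  vt <- dplyr::bind_rows(purrr::map(object$details, "vt_pairs"), .id = "subject_id")
  if (nrow(vt) == 0) abort("report contains no tidal-volume pairs to plot")
  vt$mean_vt <- (vt$vt_ref + vt$vt_pred) / 2
  vt$diff_vt <- vt$vt_pred - vt$vt_ref
  ba <- object$bland_altman
  p <- ggplot2::ggplot(vt, ggplot2::aes(x = .data$mean_vt, y = .data$diff_vt,
                                        colour = .data$subject_id)) +
    ggplot2::geom_point(alpha = 0.7)
  if (!is.null(ba)) {
    p <- p +
      ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
      ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                          linetype = "dashed")
  }
  p + ggplot2::labs(x = "mean tidal volume (L)",
                    y = "predicted - reference (L)",
                    title = "Tidal-volume agreement (Bland-Altman)")
}

#' Reliability-score timeline for a reconstruction
#'
#' @param recon A [predict_mc()] result.
#' @return A ggplot object with the score and its threshold.
#' @export
plot_reliability <- function(recon) {
  stopifnot(inherits(recon, "respiq_recon"))
  ggplot2::ggplot(recon$samples, ggplot2::aes(x = .data$t, y = .data$reliability)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_hline(yintercept = recon$threshold, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "reliability score",
                  title = "Monte-Carlo-dropout reliability score")
}
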
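#' Plot a ROC curve
#'
#' @param object A `roc_curve` from [roc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-frame risk profile of a clip
#'
#' Runs all geometry/motion modules on a clip and plots their per-frame
#' risks over time.
#'
#' @param clip A [skeleton_clip()].
#' @param plane A [floor_plane()].
#' @param params A [local_params()] tibble.
#' @param cfg A [window_config()].
#' @return A ggplot object.
#' @export
plot_risk_profile <- function(clip, plane, params = preset_local_params(),
                              cfg = window_config()) {
  series <- list(
    run = risk_run(clip, plane, alpha_of(params, "run"), cfg),
    jump = risk_jump(clip, plane, alpha_of(params, "jump"), cfg),
    sway = risk_sway(clip, plane, alpha_of(params, "sway")),
    lean = risk_lean(clip, plane, alpha_of(params, "lean")),
    foot_altitude = risk_foot_altitude(clip, plane,
                                       alpha_of(params, "foot_altitude")),
    head_altitude = risk_head_altitude(clip, plane,
                                       alpha_of(params, "head_altitude"))
  )
  df <- purrr::imap_dfr(series, function(s, nm) {
    tibble::tibble(frame = s$frame, module = nm, risk = s$risk)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$risk,
                                   colour = .data$module)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Frame", y = "Fall risk", colour = "Module") +
    ggplot2::theme_minimal()
}

#' Plot a calibration fit
#'
#' Scatter of (stimulus, ground truth) calibration pairs with the fitted
#' sigmoid risk map overlaid.
#'
#' @param pairs A data frame with `d` and `p` columns.
#' @param alpha The fitted risk-map scale (e.g. from [fit_alpha()]).
#' @return A ggplot object.
#' @export
plot_calibration <- function(pairs, alpha) {
  pairs <- tibble::as_tibble(pairs)
  grid <- tibble::tibble(d = seq(0, max(pairs$d) * 1.1, length.out = 200))
  grid$p <- 1 - exp(-grid$d^2 / alpha)
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$d, y = .data$p)) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "Stimulus d", y = "Fall risk",
                  title = sprintf("alpha = %.4g", alpha)) +
    ggplot2::theme_minimal()
}
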
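#' Fit a module's local risk-map parameter
#'
#' Linearized least squares for the sigmoid risk map `p = 1 - exp(-d^2 /
#' alpha)`: each calibration pair (stimulus `d_i`, ground-truth risk `p_i`)
#' contributes the linear equation `-ln(1 - p_i) * alpha = d_i^2`, and the
#' over-determined system is solved in closed form,
#' `alpha = sum(a_i b_i) / sum(a_i^2)` with `a_i = -ln(1 - p_i)` and
#' `b_i = d_i^2`. Pairs with `p_i = 0` contribute nothing (their `a_i` is
#' zero); pairs with `p_i >= 1` are rejected (log singularity).
#'
#' @param pairs A data frame with columns `d` (non-negative stimulus) and
#'   `p` (ground-truth risk in `[0, 1)`).
#' @return A list with `alpha` and `fit_error` (mean absolute deviation
#'   between the fitted risk map and the ground truths).
#' @export
#' @examples
#' fit_alpha(data.frame(d = 1, p = 1 - exp(-1)))  # alpha = 1 exactly
fit_alpha <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("d", "p") %in% names(pairs)))
  if (any(pairs$p >= 1)) stop("ground-truth risks must be strictly below 1")
  if (any(pairs$p < 0)) stop("ground-truth risks must be non-negative")
  a <- -log(1 - pairs$p)
  b <- pairs$d^2
  if (sum(a^2) <= 0) stop("uninformative calibration set: all risks are zero")
  alpha <- sum(a * b) / sum(a^2)
  if (alpha <= 0) stop("calibration produced a non-positive alpha")
  fitted <- 1 - exp(-pairs$d^2 / alpha)
  list(alpha = alpha, fit_error = mean(abs(fitted - pairs$p)))
}

#' Clip-level stimulus of a risk module
#'
#' The temporal mean of a module's raw per-frame stimulus (decision distance
#' for the posture modules, speed for running, height standard deviation for
#' jumping, sway distance, lean angle, altitude) — the `d` that calibration
#' regresses against ground-truth risks.
#'
#' @param clip A [skeleton_clip()].
#' @param plane A [floor_plane()].
#' @param module One of [module_names()].
#' @param models Optional posture-model list (needed for the posture
#'   modules and the sitting gate).
#' @param cfg A [window_config()].
#' @return Mean stimulus (scalar).
#' @export
clip_stimulus <- function(clip, plane, module, models = NULL,
                          cfg = window_config()) {
  module <- match.arg(module, module_names())
  seated <- if (!is.null(models$sitting)) {
    detect_sitting_clip(models$sitting, clip)
  } else NULL
  one <- 1  # placeholder alpha: stimulus does not depend on it
  s <- switch(
    module,
    push_up_climb = ,
    pull_up_climb = {
      mdl <- models[[module]]
      if (is.null(mdl)) stop("posture model required for ", module)
      X <- clip_feature_matrix(clip)
      ok <- stats::complete.cases(X)
      d <- numeric(nrow(X))
      if (any(ok)) d[ok] <- decision_distance(mdl, X[ok, , drop = FALSE])
      pmax(d, 0)
    },
    run = risk_run(clip, plane, one, cfg)$stimulus,
    jump = risk_jump(clip, plane, one, cfg)$stimulus,
    sway = risk_sway(clip, plane, one, seated = seated)$stimulus,
    lean = risk_lean(clip, plane, one)$stimulus,
    foot_altitude = risk_foot_altitude(clip, plane, one,
                                       seated = seated)$stimulus,
    head_altitude = risk_head_altitude(clip, plane, one)$stimulus
  )
  mean(s)
}

#' Calibrate all modules from labeled clips
#'
#' For each module, reduces its labeled calibration clips to (mean stimulus,
#' ground-truth risk) pairs and fits alpha by [fit_alpha()]. Modules without
#' calibration clips keep their preset alpha (with a warning).
#'
#' @param clips_by_module A named list (names from [module_names()]), each
#'   element a list of labeled [skeleton_clip()]s (`p_gt` set).
#' @param plane A [floor_plane()].
#' @param models Optional posture-model list.
#' @param preset Fallback [local_params()] (default
#'   [preset_local_params()]).
#' @param cfg A [window_config()].
#' @return A [local_params()] tibble with an extra `fit_error` column
#'   (NA for preset-kept modules).
#' @export
calibrate_modules <- function(clips_by_module, plane, models = NULL,
                              preset = preset_local_params(),
                              cfg = window_config()) {
  out <- preset
  out$fit_error <- NA_real_
  for (m in module_names()) {
    clips <- clips_by_module[[m]]
    if (is.null(clips) || length(clips) == 0) {
      warning("no calibration clips for module '", m, "'; preset alpha kept")
      next
    }
    pairs <- tibble::tibble(
      d = vapply(clips, clip_stimulus, numeric(1), plane = plane,
                 module = m, models = models, cfg = cfg),
      p = vapply(clips, function(cl) cl$p_gt, numeric(1))
    )
    fit <- fit_alpha(pairs)
    out$alpha[out$module == m] <- fit$alpha
    out$fit_error[out$module == m] <- fit$fit_error
  }
  out
}
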
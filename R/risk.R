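#' The eight behavioral risk modules
#'
#' Fixed module order used for local parameters, risk vectors and fusion:
#' two posture modules (push-up climb, pull-up climb), two motion modules
#' (rush running, high jumping), two balance modules (body sway, body lean)
#' and two altitude modules (foot altitude, head altitude).
#'
#' @return Character vector of the 8 module names.
#' @export
module_names <- function() {
  c("push_up_climb", "pull_up_climb", "run", "jump",
    "sway", "lean", "foot_altitude", "head_altitude")
}

# criterion group of each module (posture / motion / balance / altitude)
module_criteria <- function() {
  c(push_up_climb = "posture", pull_up_climb = "posture",
    run = "motion", jump = "motion",
    sway = "balance", lean = "balance",
    foot_altitude = "altitude", head_altitude = "altitude")
}

#' Local risk-map parameters
#'
#' One positive scale parameter `alpha` per module, controlling how fast the
#' sigmoid risk map `1 - exp(-d^2 / alpha)` saturates with the module's
#' stimulus `d`. The shipped preset is a reference set reported for a
#' real-world deployment; [calibrate_modules()] is the normative way to
#' obtain parameters for any given data source, since the stimulus scale
#' (and hence the unit of alpha) is data-dependent.
#'
#' @param alphas Named numeric vector (names from [module_names()]) or a
#'   data frame with columns `module` and `alpha`.
#' @return A tibble with columns `module` and `alpha`.
#' @export
#' @examples
#' preset_local_params()
local_params <- function(alphas) {
  if (is.data.frame(alphas)) {
    out <- tibble::as_tibble(alphas)[, c("module", "alpha")]
  } else {
    out <- tibble::tibble(module = names(alphas), alpha = unname(alphas))
  }
  out <- out[match(module_names(), out$module), ]
  if (any(is.na(out$alpha)) || any(out$alpha <= 0)) {
    stop("local_params needs one positive alpha per module")
  }
  out
}

#' @rdname local_params
#' @export
preset_local_params <- function() {
  local_params(c(push_up_climb = 0.167, pull_up_climb = 0.168,
                 run = 0.009, jump = 0.017, sway = 0.008, lean = 0.115,
                 foot_altitude = 0.217, head_altitude = 0.214))
}

alpha_of <- function(params, module) {
  params$alpha[match(module, params$module)]
}

#' Sliding-window configuration for the motion modules
#'
#' @param velocity_smoothing Centered moving-average width (frames) applied
#'   to the ground-projected centroid velocity (default 5).
#' @param variance_window Trailing window length (frames) for the centroid
#'   height variance (default 30, i.e. 1 s at 30 Hz).
#' @return A list of class `window_config`.
#' @export
window_config <- function(velocity_smoothing = 5, variance_window = 30) {
  stopifnot(velocity_smoothing >= 2, variance_window >= 2)
  structure(list(velocity_smoothing = as.integer(velocity_smoothing),
                 variance_window = as.integer(variance_window)),
            class = "window_config")
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, width) {
  n <- length(x)
  half <- (width - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Shared per-clip kinematic context.
clip_context <- function(clip, plane) {
  arr <- clip_arrays(clip)
  fl <- fill_untracked(arr)
  list(arr = arr, pos = fl$pos, missing = fl$missing,
       centroid = centroid_track(fl$pos, fl$missing),
       plane = plane, n = dim(fl$pos)[1])
}

centroid_speed <- function(ctx, frame_rate, cfg) {
  gp <- ground_project(ctx$centroid, ctx$plane)
  n <- nrow(gp)
  vel <- matrix(0, n, 2)
  if (n >= 3) {
    vel[2:(n - 1), ] <- (gp[3:n, ] - gp[1:(n - 2), ]) * frame_rate / 2
  }
  vel[1, ] <- (gp[2, ] - gp[1, ]) * frame_rate
  vel[n, ] <- (gp[n, ] - gp[n - 1, ]) * frame_rate
  vel[, 1] <- moving_average(vel[, 1], cfg$velocity_smoothing)
  vel[, 2] <- moving_average(vel[, 2], cfg$velocity_smoothing)
  sqrt(rowSums(vel^2))
}

# Trailing-window population variance (windows shrink at the clip start).
trailing_variance <- function(x, width) {
  n <- length(x)
  w <- pmin(seq_len(n), width)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n)
  m <- (cs[i + 1] - cs[i + 1 - w]) / w
  pmax((cs2[i + 1] - cs2[i + 1 - w]) / w - m^2, 0)
}

#' Rush-running risk (ground-projected centroid speed)
#'
#' The centroid is projected onto the floor plane, differentiated over time
#' (centered finite differences, smoothed by a short centered moving
#' average), and the speed `||V_c||` in m/s drives the risk
#' `1 - exp(-||V_c||^2 / alpha)`. Vertical motion does not contribute.
#'
#' @param clip A [skeleton_clip()].
#' @param plane A [floor_plane()].
#' @param alpha Positive risk-map scale ((m/s)^2).
#' @param cfg A [window_config()].
#' @return A tibble with columns `frame`, `stimulus` (speed, m/s), `risk`.
#' @export
risk_run <- function(clip, plane, alpha, cfg = window_config()) {
  ctx <- clip_context(clip, plane)
  if (ctx$n < 2) stop("need at least 2 frames")
  speed <- centroid_speed(ctx, clip$frame_rate, cfg)
  tibble::tibble(frame = ctx$arr$frame, stimulus = speed,
                 risk = 1 - exp(-speed^2 / alpha))
}

#' High-jumping risk (centroid height variance)
#'
#' The variance of the centroid's height above the floor over a trailing
#' window drives `1 - exp(-sigma^2 / alpha)`. The per-frame stimulus column
#' reports the standard deviation (so that, like every other module, risk is
#' `1 - exp(-stimulus^2 / alpha)`).
#'
#' @inheritParams risk_run
#' @param alpha Positive risk-map scale (m^2).
#' @return A tibble with columns `frame`, `stimulus` (height sd, m), `risk`;
#'   attribute `window_truncated` is TRUE when the clip is shorter than the
#'   window.
#' @export
risk_jump <- function(clip, plane, alpha, cfg = window_config()) {
  ctx <- clip_context(clip, plane)
  h <- point_plane_distance(ctx$centroid, plane)
  v <- trailing_variance(h, cfg$variance_window)
  out <- tibble::tibble(frame = ctx$arr$frame, stimulus = sqrt(v),
                        risk = 1 - exp(-v / alpha))
  attr(out, "window_truncated") <- ctx$n < cfg$variance_window
  out
}

# Vectorized sway distances for ground-projected centroid and feet.
sway_distances <- function(pc, lf, rf, tol = 0.01) {
  dx <- rf[, 1] - lf[, 1]
  dz <- rf[, 2] - lf[, 2]
  len <- sqrt(dx^2 + dz^2)
  d_line <- abs(-dz * pc[, 1] + dx * pc[, 2] + dz * lf[, 1] - dx * lf[, 2]) /
    ifelse(len > 0, len, 1)
  mid <- (lf + rf) / 2
  d_point <- sqrt(rowSums((pc - mid)^2))
  ifelse(len < tol, d_point, d_line)
}

#' Body-sway risk (centroid offset from the base of support)
#'
#' The ground-projected centroid's perpendicular distance to the
#' base-of-support line through the two ground-projected feet drives
#' `1 - exp(-d^2 / alpha)`. Frames flagged seated are forced to zero risk
#' (a seated toddler legitimately rests its weight off the foot line);
#' frames whose feet cannot be located get zero risk and mark the module
#' partially disabled.
#'
#' @inheritParams risk_run
#' @param alpha Positive risk-map scale (m^2).
#' @param seated Optional per-frame logical mask of seated frames.
#' @return A tibble with `frame`, `stimulus` (m), `risk`, `available`;
#'   attribute `partially_disabled`.
#' @export
risk_sway <- function(clip, plane, alpha, seated = NULL) {
  ctx <- clip_context(clip, plane)
  if (is.null(seated)) seated <- rep(FALSE, ctx$n)
  lf_i <- match("FOOT_LEFT", joint_names())
  rf_i <- match("FOOT_RIGHT", joint_names())
  avail <- !(ctx$missing[, lf_i] | ctx$missing[, rf_i]) &
    !is.na(ctx$centroid[, 1])
  pc <- ground_project(ctx$centroid, plane)
  lf <- ground_project(ctx$pos[, lf_i, , drop = TRUE], plane)
  rf <- ground_project(ctx$pos[, rf_i, , drop = TRUE], plane)
  d <- sway_distances(pc, lf, rf)
  d[!avail] <- 0
  risk <- 1 - exp(-d^2 / alpha)
  risk[!avail | seated] <- 0
  stim <- d
  stim[seated] <- 0
  out <- tibble::tibble(frame = ctx$arr$frame, stimulus = stim, risk = risk,
                        available = avail)
  attr(out, "partially_disabled") <- any(!avail)
  out
}

#' Body-lean risk (spine angle against the floor normal)
#'
#' The angle (radians) between the hip-center-to-shoulder-center spine
#' vector and the floor normal drives `1 - exp(-theta^2 / alpha)`; zero for
#' an upright pose, saturating as the trunk approaches horizontal. Invariant
#' to the spine vector's magnitude.
#'
#' @inheritParams risk_run
#' @param alpha Positive risk-map scale (rad^2).
#' @return A tibble with `frame`, `stimulus` (rad), `risk`, `available`.
#' @export
risk_lean <- function(clip, plane, alpha) {
  ctx <- clip_context(clip, plane)
  hc <- match("HIP_CENTER", joint_names())
  sc <- match("SHOULDER_CENTER", joint_names())
  spine <- ctx$pos[, sc, , drop = TRUE] - ctx$pos[, hc, , drop = TRUE]
  len <- sqrt(rowSums(spine^2))
  avail <- len > .Machine$double.eps &
    !(ctx$missing[, hc] | ctx$missing[, sc])
  nrm <- plane_normal(plane)
  cosang <- as.vector(spine %*% nrm) / ifelse(len > 0, len, 1)
  theta <- acos(clamp(cosang, -1, 1))
  theta[!avail] <- 0
  tibble::tibble(frame = ctx$arr$frame, stimulus = theta,
                 risk = ifelse(avail, 1 - exp(-theta^2 / alpha), 0),
                 available = avail)
}

#' Foot-altitude risk (feet midpoint height over the floor)
#'
#' The altitude of the midpoint between the two feet (plane residual times
#' tilt cosine; see [point_plane_distance()]) drives
#' `1 - exp(-d^2 / alpha)`. Seated frames are forced to zero; frames with
#' unlocatable feet are disabled (the head-altitude module takes over
#' there).
#'
#' @inheritParams risk_sway
#' @param alpha Positive risk-map scale (m^2).
#' @return A tibble with `frame`, `stimulus` (m), `risk`, `available`.
#' @export
risk_foot_altitude <- function(clip, plane, alpha, seated = NULL) {
  ctx <- clip_context(clip, plane)
  if (is.null(seated)) seated <- rep(FALSE, ctx$n)
  lf_i <- match("FOOT_LEFT", joint_names())
  rf_i <- match("FOOT_RIGHT", joint_names())
  avail <- !(ctx$missing[, lf_i] | ctx$missing[, rf_i])
  mid <- (ctx$pos[, lf_i, , drop = TRUE] + ctx$pos[, rf_i, , drop = TRUE]) / 2
  d <- point_plane_distance(mid, plane)
  d[!avail] <- 0
  risk <- 1 - exp(-d^2 / alpha)
  risk[!avail | seated] <- 0
  stim <- d
  stim[seated] <- 0
  tibble::tibble(frame = ctx$arr$frame, stimulus = stim, risk = risk,
                 available = avail)
}

#' Head-altitude risk (head height over the floor, minus body height)
#'
#' Fallback altitude measure for frames whose feet are occluded: the head's
#' altitude minus the estimated body height `H` approximates the altitude of
#' the (invisible) lowest joint under an upright-pose assumption. Positive
#' excess `d` drives `1 - exp(-d^2 / alpha)`; a crouching head (negative
#' excess) clamps to zero.
#'
#' @inheritParams risk_run
#' @param alpha Positive risk-map scale (m^2).
#' @return A tibble with `frame`, `stimulus` (m, clamped at 0), `risk`,
#'   `available`.
#' @export
risk_head_altitude <- function(clip, plane, alpha) {
  ctx <- clip_context(clip, plane)
  head_i <- match("HEAD", joint_names())
  H <- height_track(ctx$pos, ctx$missing)
  avail <- !ctx$missing[, head_i] & !is.na(H)
  dh <- point_plane_distance(ctx$pos[, head_i, , drop = TRUE], plane)
  d <- dh - H
  d[!avail | is.na(d)] <- 0
  stim <- pmax(d, 0)
  tibble::tibble(frame = ctx$arr$frame, stimulus = stim,
                 risk = ifelse(avail & d > 0, 1 - exp(-d^2 / alpha), 0),
                 available = avail)
}

#' Clip-level risk vector over the eight modules
#'
#' Runs every risk module on a clip and aggregates each module's per-frame
#' risks to their temporal mean, producing the 8-vector that the multi-modal
#' fusion consumes. Climbing risks come from the per-frame decision
#' distances of the supplied posture models through [risk_from_distance()].
#' Gating: frames detected as seated (sitting-posture SVM) or tracked in
#' seated mode zero the sway and foot-altitude risks; the head-altitude
#' module runs only on frames whose feet are occluded (untracked with no
#' history, or seated tracking mode). A module that is disabled or fails on
#' every frame reports risk 0 with `enabled = FALSE`.
#'
#' @param clip A [skeleton_clip()].
#' @param plane A [floor_plane()].
#' @param models Optional named list of posture models (`push_up_climb`,
#'   `pull_up_climb`, `sitting`); missing climb models disable the posture
#'   modules, a missing sitting model disables the sitting gate.
#' @param params A [local_params()] tibble (default [preset_local_params()]).
#' @param cfg A [window_config()].
#' @param modes Optional per-frame tracking-mode vector (`"default"` /
#'   `"seated"`, from [detect_occlusion()]); computed from the clip's depth
#'   profile when present.
#' @return A one-row tibble: `clip_id`, `p_<module>` for the eight modules,
#'   `enabled_<module>` flags, and the clip's `p_gt` and `behavior` if set.
#' @export
clip_risk_vector <- function(clip, plane, models = NULL,
                             params = preset_local_params(),
                             cfg = window_config(), modes = NULL) {
  ctx <- clip_context(clip, plane)
  n <- ctx$n
  if (is.null(modes) && !is.null(clip$depth_profile)) {
    modes <- detect_occlusion(clip$depth_profile)$mode
  }
  if (is.null(modes)) modes <- rep("default", n)
  seated_mode <- modes == "seated"

  sitting <- if (!is.null(models$sitting)) {
    detect_sitting_clip(models$sitting, clip)
  } else rep(FALSE, n)
  seated <- sitting | seated_mode

  lf_i <- match("FOOT_LEFT", joint_names())
  rf_i <- match("FOOT_RIGHT", joint_names())
  feet_occluded <- ctx$missing[, lf_i] | ctx$missing[, rf_i] | seated_mode

  p <- stats::setNames(numeric(8), module_names())
  enabled <- stats::setNames(logical(8), module_names())

  # posture modules
  X <- clip_feature_matrix(clip)
  ok <- stats::complete.cases(X)
  for (m in c("push_up_climb", "pull_up_climb")) {
    if (!is.null(models[[m]])) {
      r <- numeric(n)
      if (any(ok)) {
        d <- decision_distance(models[[m]], X[ok, , drop = FALSE])
        r[ok] <- risk_from_distance(d, alpha_of(params, m))
      }
      p[m] <- mean(r)
      enabled[m] <- any(ok)
    }
  }

  # motion modules
  p["run"] <- mean(risk_run(clip, plane, alpha_of(params, "run"), cfg)$risk)
  enabled["run"] <- TRUE
  p["jump"] <- mean(risk_jump(clip, plane, alpha_of(params, "jump"), cfg)$risk)
  enabled["jump"] <- TRUE

  # balance modules
  sw <- risk_sway(clip, plane, alpha_of(params, "sway"), seated = seated)
  sw$risk[feet_occluded] <- 0
  p["sway"] <- mean(sw$risk)
  enabled["sway"] <- any(sw$available & !feet_occluded)
  le <- risk_lean(clip, plane, alpha_of(params, "lean"))
  p["lean"] <- mean(le$risk)
  enabled["lean"] <- any(le$available)

  # altitude modules: foot altitude where feet are visible, head altitude on
  # the occluded frames
  fa <- risk_foot_altitude(clip, plane, alpha_of(params, "foot_altitude"),
                           seated = seated)
  fa$risk[feet_occluded] <- 0
  p["foot_altitude"] <- mean(fa$risk)
  enabled["foot_altitude"] <- any(fa$available & !feet_occluded)
  ha <- risk_head_altitude(clip, plane, alpha_of(params, "head_altitude"))
  ha$risk[!feet_occluded] <- 0
  p["head_altitude"] <- mean(ha$risk)
  enabled["head_altitude"] <- any(ha$available & feet_occluded)

  p[!enabled] <- 0

  out <- tibble::as_tibble(as.list(stats::setNames(p, paste0("p_", names(p)))))
  out <- dplyr::bind_cols(
    tibble::tibble(clip_id = clip$clip_id %||% NA_character_),
    out,
    tibble::as_tibble(as.list(stats::setNames(enabled,
                                              paste0("enabled_", names(enabled)))))
  )
  out$p_gt <- clip$p_gt %||% NA_real_
  out$behavior <- clip$behavior %||% NA_character_
  out
}

#' Assess a set of clips
#'
#' Maps [clip_risk_vector()] over a list of clips and binds the rows.
#'
#' @param clips A list of [skeleton_clip()] objects.
#' @inheritParams clip_risk_vector
#' @return A tibble with one risk-vector row per clip.
#' @export
assess_clips <- function(clips, plane, models = NULL,
                         params = preset_local_params(),
                         cfg = window_config()) {
  purrr::map_dfr(clips, clip_risk_vector, plane = plane, models = models,
                 params = params, cfg = cfg)
}

risk_columns <- function() paste0("p_", module_names())

# 8-column risk matrix from an assess_clips() tibble.
risk_matrix <- function(risks) {
  as.matrix(risks[, risk_columns()])
}
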
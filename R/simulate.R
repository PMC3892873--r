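#' The ten simulated behavior types
#'
#' Five typically safe behaviors (sitting, standing, walking, jumping rope,
#' dancing) and five typically fall-risky ones (rush running, high jumping,
#' tumbling, climbing, standing on furniture).
#'
#' @return Character vector of the 10 behavior names.
#' @export
behavior_types <- function() {
  c("sitting", "standing", "walking", "jumping_rope", "dancing",
    "rush_running", "high_jumping", "tumbling", "climbing",
    "standing_on_furniture")
}

safe_behaviors <- function() behavior_types()[1:5]
risky_behaviors <- function() behavior_types()[6:10]

#' Simulator plausibility constants
#'
#' Kinematic ceilings of the behavior generator: maximum running speed,
#' jump amplitude, sway offset, lean angle and furniture height for a
#' toddler-scale (about 0.88 m) skeleton. All in meters / degrees.
#'
#' @return Named list of constants.
#' @export
simulation_config <- function() {
  list(v_max = 2.5,           # m/s, rush-running ceiling
       h_max = 0.35,          # m, jump amplitude ceiling
       sway_max = 0.4,        # m, lateral centroid offset ceiling
       lean_max = 60,         # degrees
       furniture_height = 0.6 # m
  )
}

# Reference sigmoid scales of the simulated expert: used by the
# alpha-labeled calibration sets (label = 1 - exp(-d^2 / alpha_star)).
generator_alpha_star <- function() {
  c(push_up_climb = 0.5, pull_up_climb = 0.5, run = 2.8, jump = 0.006,
    sway = 0.065, lean = 0.6, foot_altitude = 0.16, head_altitude = 0.16)
}

# ---- templates -------------------------------------------------------------

standing_template <- function() {
  tibble::tribble(
    ~joint, ~x, ~y, ~z,
    "HIP_CENTER",      0.00, 0.45, 0.00,
    "SPINE",           0.00, 0.58, 0.00,
    "SHOULDER_CENTER", 0.00, 0.72, 0.00,
    "HEAD",            0.00, 0.85, 0.00,
    "SHOULDER_LEFT",  -0.11, 0.70, 0.00,
    "ELBOW_LEFT",     -0.13, 0.55, 0.00,
    "WRIST_LEFT",     -0.14, 0.42, 0.00,
    "HAND_LEFT",      -0.15, 0.36, 0.00,
    "SHOULDER_RIGHT",  0.11, 0.70, 0.00,
    "ELBOW_RIGHT",     0.13, 0.55, 0.00,
    "WRIST_RIGHT",     0.14, 0.42, 0.00,
    "HAND_RIGHT",      0.15, 0.36, 0.00,
    "HIP_LEFT",       -0.07, 0.42, 0.00,
    "KNEE_LEFT",      -0.08, 0.22, 0.00,
    "ANKLE_LEFT",     -0.09, 0.05, 0.00,
    "FOOT_LEFT",      -0.10, 0.02, 0.00,
    "HIP_RIGHT",       0.07, 0.42, 0.00,
    "KNEE_RIGHT",      0.08, 0.22, 0.00,
    "ANKLE_RIGHT",     0.09, 0.05, 0.00,
    "FOOT_RIGHT",      0.10, 0.02, 0.00
  )
}

seated_template <- function() {
  tibble::tribble(
    ~joint, ~x, ~y, ~z,
    "HIP_CENTER",      0.00, 0.26, 0.02,
    "SPINE",           0.00, 0.40, 0.00,
    "SHOULDER_CENTER", 0.00, 0.54, 0.00,
    "HEAD",            0.00, 0.67, 0.00,
    "SHOULDER_LEFT",  -0.11, 0.52, 0.00,
    "ELBOW_LEFT",     -0.13, 0.38, 0.05,
    "WRIST_LEFT",     -0.14, 0.30, 0.12,
    "HAND_LEFT",      -0.15, 0.28, 0.16,
    "SHOULDER_RIGHT",  0.11, 0.52, 0.00,
    "ELBOW_RIGHT",     0.13, 0.38, 0.05,
    "WRIST_RIGHT",     0.14, 0.30, 0.12,
    "HAND_RIGHT",      0.15, 0.28, 0.16,
    "HIP_LEFT",       -0.07, 0.24, 0.04,
    "KNEE_LEFT",      -0.08, 0.24, 0.20,
    "ANKLE_LEFT",     -0.09, 0.05, 0.22,
    "FOOT_LEFT",      -0.10, 0.02, 0.26,
    "HIP_RIGHT",       0.07, 0.24, 0.04,
    "KNEE_RIGHT",      0.08, 0.24, 0.20,
    "ANKLE_RIGHT",     0.09, 0.05, 0.22,
    "FOOT_RIGHT",      0.10, 0.02, 0.26
  )
}

# Arm pose targets, interpolated toward by the climbing effects.
pull_up_targets <- function() {
  list(SHOULDER = c(0.11, 0.74, 0.00), ELBOW = c(0.12, 0.88, 0.05),
       WRIST = c(0.12, 1.00, 0.08), HAND = c(0.12, 1.06, 0.10))
}

push_up_targets <- function() {
  list(SHOULDER = c(0.11, 0.68, 0.06), ELBOW = c(0.13, 0.60, 0.18),
       WRIST = c(0.13, 0.55, 0.32), HAND = c(0.13, 0.52, 0.40))
}

# ---- effects ---------------------------------------------------------------

default_effects <- function() {
  list(seated = FALSE, speed = 0, bounce_amp = 0, bounce_freq = 2,
       gait_amp = 0, gait_freq = 2, sway_offset = 0, lean_deg = 0,
       altitude = 0, arm_raise = 0, push_up = 0)
}

# Behavior -> kinematic effects. Intensity in [0, 1] monotonically drives
# the behavior's dominant stimulus; risky behaviors keep a nonzero floor so
# that every risky clip is genuinely risky.
behavior_effects <- function(behavior, intensity,
                             climb_variant = c("pull_up", "push_up")) {
  behavior <- match.arg(behavior, behavior_types())
  climb_variant <- match.arg(climb_variant)
  i <- clamp(intensity, 0, 1)
  e <- default_effects()
  switch(behavior,
    sitting = {
      e$seated <- TRUE
    },
    standing = NULL,
    walking = {
      e$speed <- 0.3 + 0.6 * i
      e$gait_amp <- 0.06
      e$bounce_amp <- 0.02
    },
    jumping_rope = {
      e$bounce_amp <- 0.04 + 0.06 * i
      e$bounce_freq <- 2.5
      e$gait_amp <- 0.03
    },
    dancing = {
      e$sway_offset <- 0.05 + 0.10 * i
      e$lean_deg <- 10 + 10 * i
      e$gait_amp <- 0.04
      e$bounce_amp <- 0.02
    },
    rush_running = {
      e$speed <- 1.5 + 1.0 * i
      e$gait_amp <- 0.12
      e$gait_freq <- 3
      e$bounce_amp <- 0.03
      e$bounce_freq <- 3
    },
    high_jumping = {
      e$bounce_amp <- 0.24 + 0.11 * i
      e$bounce_freq <- 1.5
    },
    tumbling = {
      e$lean_deg <- 30 + 30 * i
      e$sway_offset <- 0.15 + 0.15 * i
    },
    climbing = {
      if (climb_variant == "pull_up") e$arm_raise <- 0.7 + 0.3 * i
      else e$push_up <- 0.7 + 0.3 * i
      e$altitude <- 0.10 + 0.15 * i
      e$lean_deg <- 10 + 15 * i
    },
    standing_on_furniture = {
      e$altitude <- 0.35 + 0.25 * i
    }
  )
  e
}

#' Ground-truth label rule of the simulated expert
#'
#' Deterministic stand-in for the expert questionnaire: maps a behavior and
#' its intensity to a ground-truth fall risk on the 0-1 scale in 0.1 steps.
#' Safe behaviors always land at or below 0.4, risky behaviors at or above
#' 0.6 (never exactly at the 0.5 decision boundary). This rule replaces the
#' human labeler of a real deployment; it is an explicit simulator
#' convention, not a claim about any real label distribution.
#'
#' @param behavior One of [behavior_types()].
#' @param intensity Intensity in `[0, 1]`.
#' @return Ground-truth risk in 0.1 steps.
#' @export
label_rule <- function(behavior, intensity) {
  behavior <- match.arg(behavior, behavior_types())
  i <- clamp(intensity, 0, 1)
  l <- switch(behavior,
    sitting = 0.1, standing = 0.1,
    walking = 0.1 + 0.2 * i,
    jumping_rope = 0.2 + 0.2 * i,
    dancing = 0.2 + 0.2 * i,
    rush_running = 0.5 + 0.4 * i,
    high_jumping = 0.6 + 0.3 * i,
    tumbling = 0.6 + 0.3 * i,
    climbing = 0.6 + 0.3 * i,
    standing_on_furniture = 0.6 + 0.3 * i
  )
  l <- round(l * 10) / 10
  if (behavior %in% safe_behaviors()) clamp(l, 0, 0.4) else clamp(l, 0.6, 0.9)
}

rot_x <- function(p, theta, center) {
  # rotate (y, z) about the x axis around `center`
  dy <- p[, 2] - center[2]
  dz <- p[, 3] - center[3]
  p[, 2] <- center[2] + cos(theta) * dy - sin(theta) * dz
  p[, 3] <- center[3] + sin(theta) * dy + cos(theta) * dz
  p
}

rot_z_scene <- function(p, phi) {
  x <- cos(phi) * p[, 1] - sin(phi) * p[, 2]
  y <- sin(phi) * p[, 1] + cos(phi) * p[, 2]
  p[, 1] <- x
  p[, 2] <- y
  p
}

#' Generate a synthetic behavior clip
#'
#' Builds a kinematically plausible 20-joint toddler skeleton clip for one
#' of the ten behavior types: locomotion as translation with a sinusoidal
#' gait, jumping as whole-body vertical oscillation, sway as a lateral
#' offset of the body over the feet, lean as a trunk rotation about the
#' hips, climbing as arm-elevated (pull-up) or arms-pressing (push-up)
#' static poses, furniture standing as a whole-body vertical offset —
#' plus i.i.d. Gaussian joint jitter. A matching per-frame depth profile is
#' attached; an optional occlusion episode marks the lower-body joints
#' untracked and drops the lower-body depth. Fully seeded: the same seed
#' reproduces the clip bit for bit.
#'
#' @param behavior One of [behavior_types()].
#' @param intensity Behavior intensity in `[0, 1]` (default 0.5);
#'   monotonically drives the behavior's dominant stimulus.
#' @param duration Clip length in seconds (default 3).
#' @param frame_rate Frames per second (default 30).
#' @param noise_sd Gaussian joint jitter, meters (default 0.005).
#' @param seed Integer seed.
#' @param climb_variant `"pull_up"` or `"push_up"` (climbing only).
#' @param occlusion Optional `c(start_frame, end_frame)` lower-body
#'   occlusion episode.
#' @param scene_tilt_deg Tilt of the whole scene (skeleton and implied
#'   floor) about the camera z axis, degrees (default 0). Use
#'   [generate_floor()] with the same tilt for a consistent floor cloud.
#' @param effects Optional named list overriding individual kinematic
#'   effects (see the fields of the internal default set: `speed`,
#'   `bounce_amp`, `sway_offset`, `lean_deg`, `altitude`, `arm_raise`,
#'   `push_up`, ...); used by calibration sweeps.
#' @param p_gt Ground-truth label; defaults to [label_rule()].
#' @return A [skeleton_clip()] with `p_gt`, `behavior` and a depth profile.
#' @export
generate_clip <- function(behavior, intensity = 0.5, duration = 3,
                          frame_rate = 30, noise_sd = 0.005, seed = 1,
                          climb_variant = c("pull_up", "push_up"),
                          occlusion = NULL, scene_tilt_deg = 0,
                          effects = NULL, p_gt = NULL) {
  behavior <- match.arg(behavior, behavior_types())
  climb_variant <- match.arg(climb_variant)
  e <- behavior_effects(behavior, intensity, climb_variant)
  if (!is.null(effects)) {
    stopifnot(all(names(effects) %in% names(default_effects())))
    e[names(effects)] <- effects
  }
  n <- max(2L, round(duration * frame_rate))
  tmpl <- if (e$seated) seated_template() else standing_template()
  base <- as.matrix(tmpl[, c("x", "y", "z")])
  rownames(base) <- tmpl$joint
  jn <- joint_names()
  base <- base[jn, , drop = FALSE]

  arm_joints <- c("SHOULDER", "ELBOW", "WRIST", "HAND")
  apply_arm_pose <- function(pos, targets, r) {
    for (j in arm_joints) {
      for (side in c("LEFT", "RIGHT")) {
        nm <- paste0(j, "_", side)
        tgt <- targets[[j]]
        if (side == "LEFT") tgt[1] <- -tgt[1]
        pos[nm, ] <- (1 - r) * pos[nm, ] + r * tgt
      }
    }
    pos
  }
  if (e$arm_raise > 0) base <- apply_arm_pose(base, pull_up_targets(), e$arm_raise)
  if (e$push_up > 0) base <- apply_arm_pose(base, push_up_targets(), e$push_up)

  upper <- setdiff(jn, c("FOOT_LEFT", "FOOT_RIGHT", "ANKLE_LEFT",
                         "ANKLE_RIGHT", "KNEE_LEFT", "KNEE_RIGHT",
                         "HIP_LEFT", "HIP_RIGHT"))
  above_hip <- jn[base[, 2] > base["HIP_CENTER", 2]]
  theta <- e$lean_deg * pi / 180
  phi <- scene_tilt_deg * pi / 180
  t_s <- (seq_len(n) - 1) / frame_rate

  occluded_frames <- rep(FALSE, n)
  if (!is.null(occlusion)) {
    occluded_frames[seq(occlusion[1], min(occlusion[2], n))] <- TRUE
  }
  lower_joints <- setdiff(jn, upper_body_joints())

  jitter <- with_seed(seed, array(stats::rnorm(n * 20 * 3, 0, noise_sd),
                                  c(n, 20, 3)))

  frames <- vector("list", n)
  for (f in seq_len(n)) {
    pos <- base
    if (theta != 0) {
      pos[above_hip, ] <- rot_x(pos[above_hip, , drop = FALSE], theta,
                                pos["HIP_CENTER", ])
    }
    if (e$gait_amp > 0) {
      s <- e$gait_amp * sin(2 * pi * e$gait_freq * t_s[f])
      for (side in c("LEFT", "RIGHT")) {
        sgn <- if (side == "LEFT") 1 else -1
        for (j in c("FOOT", "ANKLE")) {
          pos[paste0(j, "_", side), 1] <- pos[paste0(j, "_", side), 1] + sgn * s
        }
        for (j in c("WRIST", "HAND")) {
          pos[paste0(j, "_", side), 1] <- pos[paste0(j, "_", side), 1] - sgn * s / 2
        }
      }
    }
    if (e$sway_offset > 0) pos[upper, 3] <- pos[upper, 3] + e$sway_offset
    if (e$bounce_amp > 0) {
      pos[, 2] <- pos[, 2] +
        e$bounce_amp / 2 * (1 - cos(2 * pi * e$bounce_freq * t_s[f]))
    }
    if (e$altitude > 0) pos[, 2] <- pos[, 2] + e$altitude
    if (e$speed > 0) pos[, 1] <- pos[, 1] + e$speed * t_s[f]
    if (phi != 0) pos <- rot_z_scene(pos, phi)
    pos <- pos + jitter[f, , ]

    frames[[f]] <- tibble::tibble(
      frame = f, t = t_s[f], joint = jn,
      x = unname(pos[, 1]), y = unname(pos[, 2]), z = unname(pos[, 3]),
      tracked = !(occluded_frames[f] & jn %in% lower_joints)
    )
  }
  fr <- dplyr::bind_rows(frames)

  depth_noise <- with_seed(sub_seed(seed, "depth"),
                           matrix(stats::rnorm(2 * n, 0, 0.01), n, 2))
  upper_depth <- 2.5 + depth_noise[, 1]
  lower_depth <- 2.5 + depth_noise[, 2]
  lower_depth[occluded_frames] <- upper_depth[occluded_frames] - 0.6
  profile <- tibble::tibble(frame = seq_len(n),
                            upper_mean_depth = upper_depth,
                            lower_mean_depth = lower_depth)

  skeleton_clip(fr, frame_rate = frame_rate,
                p_gt = p_gt %||% label_rule(behavior, intensity),
                behavior = behavior,
                clip_id = sprintf("%s_i%02.0f_s%d", behavior,
                                  round(intensity * 100), seed),
                depth_profile = profile)
}

#' Generate a combined-behavior clip
#'
#' Superimposes the kinematic effects of two behaviors (e.g. simultaneously
#' swaying and jumping, or climbing at an altitude): amplitude-like effects
#' take the elementwise maximum across the components, speeds add, and the
#' ground-truth label is the maximum of the component labels plus 0.1,
#' capped at 1.
#'
#' @param behaviors Character vector of 2 behavior types.
#' @param intensities Intensities, recycled to length 2.
#' @inheritParams generate_clip
#' @return A [skeleton_clip()] tagged `"<b1>+<b2>"`.
#' @export
generate_combined_clip <- function(behaviors, intensities = 0.5,
                                   duration = 3, frame_rate = 30,
                                   noise_sd = 0.005, seed = 1,
                                   climb_variant = c("pull_up", "push_up")) {
  stopifnot(length(behaviors) == 2)
  climb_variant <- match.arg(climb_variant)
  intensities <- rep_len(intensities, 2)
  e1 <- behavior_effects(behaviors[1], intensities[1], climb_variant)
  e2 <- behavior_effects(behaviors[2], intensities[2], climb_variant)
  merged <- default_effects()
  for (nm in names(merged)) {
    merged[[nm]] <- if (nm == "seated") e1$seated || e2$seated
    else if (nm == "speed") e1$speed + e2$speed
    else max(e1[[nm]], e2[[nm]])
  }
  p_gt <- min(1, max(label_rule(behaviors[1], intensities[1]),
                     label_rule(behaviors[2], intensities[2])) + 0.1)
  clip <- generate_clip(behaviors[1], intensities[1], duration, frame_rate,
                        noise_sd, seed, climb_variant, effects = merged,
                        p_gt = p_gt)
  clip$behavior <- paste(behaviors, collapse = "+")
  clip$clip_id <- sprintf("%s_s%d", clip$behavior, seed)
  clip
}

#' Generate a synthetic floor point cloud
#'
#' Samples points on a plane through the origin tilted by `tilt_deg` about
#' the camera z axis, perturbs them along the plane normal, and mixes in
#' uniform outliers above the floor. Seeded and reproducible.
#'
#' @param tilt_deg Floor tilt in degrees (0 = horizontal `y = 0`).
#' @param extent Side length of the sampled floor patch, meters.
#' @param n_points Total number of points.
#' @param noise_sd Gaussian noise along the plane normal, meters.
#' @param outlier_frac Fraction of uniform outliers in `[0, 1)`.
#' @param seed Integer seed.
#' @return A tibble with columns `x`, `y`, `z`; attribute `normal` carries
#'   the true unit plane normal.
#' @export
generate_floor <- function(tilt_deg = 0, extent = 3, n_points = 500,
                           noise_sd = 0, outlier_frac = 0, seed = 1) {
  stopifnot(outlier_frac >= 0, outlier_frac < 1)
  n_out <- round(n_points * outlier_frac)
  n_in <- n_points - n_out
  phi <- tilt_deg * pi / 180
  normal <- c(-sin(phi), cos(phi), 0)
  pts <- with_seed(seed, {
    u <- stats::runif(n_in, -extent / 2, extent / 2)
    w <- stats::runif(n_in, -extent / 2, extent / 2)
    inl <- cbind(cos(phi) * u, sin(phi) * u, w)
    if (noise_sd > 0) {
      inl <- inl + outer(stats::rnorm(n_in, 0, noise_sd), normal)
    }
    out <- NULL
    if (n_out > 0) {
      out <- cbind(stats::runif(n_out, -extent / 2, extent / 2),
                   stats::runif(n_out, 0.1, 1.5),
                   stats::runif(n_out, -extent / 2, extent / 2))
    }
    rbind(inl, out)
  })
  cloud <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3])
  attr(cloud, "normal") <- normal
  cloud
}

#' Generate a labeled behavior corpus
#'
#' Builds `n_clips` single- and combined-behavior clips with ground-truth
#' labels from [label_rule()], balanced to the requested safe/risky mix
#' (labels land strictly on either side of 0.5), and records a stratified
#' train/test split. Behaviors cycle deterministically within each side;
#' intensities are drawn uniformly; a fraction of the risky clips are
#' combined-behavior clips.
#'
#' @param n_clips Number of clips (default 200).
#' @param mix Named vector `c(safe = , risky = )` summing to 1 (default
#'   50/50).
#' @param seed Integer seed.
#' @param combined_frac Fraction of risky clips that combine two risky
#'   behaviors (default 0.2).
#' @param noise_sd Joint jitter passed to [generate_clip()].
#' @param train_frac Fraction assigned to the training split (default 0.5).
#' @return A list with `clips` (list of [skeleton_clip()]) and `labels`
#'   (tibble: `clip_id`, `behavior`, `intensity`, `p_gt`, `split`).
#' @export
generate_dataset <- function(n_clips = 200, mix = c(safe = 0.5, risky = 0.5),
                             seed = 1, combined_frac = 0.2,
                             noise_sd = 0.005, train_frac = 0.5) {
  stopifnot(abs(sum(mix) - 1) < 1e-8)
  n_safe <- round(n_clips * mix[["safe"]])
  n_risky <- n_clips - n_safe
  n_comb <- round(n_risky * combined_frac)

  safe_b <- rep_len(safe_behaviors(), n_safe)
  risky_b <- rep_len(risky_behaviors(), n_risky - n_comb)
  comb_pairs <- list(c("high_jumping", "tumbling"),
                     c("climbing", "standing_on_furniture"),
                     c("rush_running", "high_jumping"))
  combos <- rep_len(comb_pairs, n_comb)

  intens <- with_seed(sub_seed(seed, "intensity"), stats::runif(n_clips))
  variants <- rep_len(c("pull_up", "push_up"), n_clips)

  clips <- vector("list", n_clips)
  rows <- vector("list", n_clips)
  k <- 0
  specs <- c(lapply(safe_b, function(b) list(b = b, comb = NULL)),
             lapply(risky_b, function(b) list(b = b, comb = NULL)),
             lapply(combos, function(p) list(b = NULL, comb = p)))
  for (sp in specs) {
    k <- k + 1
    s <- sub_seed(seed, paste0("clip", k))
    if (is.null(sp$comb)) {
      cl <- generate_clip(sp$b, intensity = intens[k], noise_sd = noise_sd,
                          seed = s, climb_variant = variants[k])
    } else {
      cl <- generate_combined_clip(sp$comb, intensities = intens[k],
                                   noise_sd = noise_sd, seed = s,
                                   climb_variant = variants[k])
    }
    cl$clip_id <- sprintf("clip%03d_%s", k, cl$behavior)
    clips[[k]] <- cl
    rows[[k]] <- tibble::tibble(clip_id = cl$clip_id, behavior = cl$behavior,
                                intensity = intens[k], p_gt = cl$p_gt)
  }
  labels <- dplyr::bind_rows(rows)
  # stratified alternating train/test split within safe and risky strata
  labels$split <- NA_character_
  for (side in list(labels$p_gt > 0.5, labels$p_gt < 0.5)) {
    idx <- which(side)
    n_train <- round(length(idx) * train_frac)
    take <- rep("test", length(idx))
    take[seq_len(length(idx)) %% 2 == 1] <- "train"
    if (sum(take == "train") != n_train) {
      take <- c(rep("train", n_train), rep("test", length(idx) - n_train))
    }
    labels$split[idx] <- take
  }
  list(clips = clips, labels = labels)
}

#' Generate a posture-classifier training set
#'
#' Balanced frames of a target posture class (push-up climb, pull-up climb
#' or sitting) against a mixed negative class (standing, walking and — for
#' the climb classes — sitting poses), as raw 60-dimensional feature
#' vectors. Separable by construction: the positive poses differ from every
#' negative pose in arm elevation (climbs) or hip height (sitting).
#'
#' @param class `"push_up"`, `"pull_up"` or `"sitting"`.
#' @param n_per_class Frames per class (default 90).
#' @param seed Integer seed.
#' @param noise_sd Joint jitter (default 0.005).
#' @return A list with `x` (matrix, 2 * n_per_class rows) and `y` (+1/-1).
#' @export
generate_posture_training <- function(class = c("push_up", "pull_up",
                                                "sitting"),
                                      n_per_class = 90, seed = 1,
                                      noise_sd = 0.005) {
  class <- match.arg(class)
  pos_spec <- switch(class,
    push_up = list(behavior = "climbing", variant = "push_up"),
    pull_up = list(behavior = "climbing", variant = "pull_up"),
    sitting = list(behavior = "sitting", variant = "pull_up"))
  neg_behaviors <- if (class == "sitting") {
    c("standing", "walking", "dancing")
  } else {
    # elevated non-climbing poses keep the climb boundary from firing on
    # mere altitude
    c("standing", "walking", "sitting", "standing_on_furniture",
      "high_jumping")
  }

  frames_from <- function(behavior, variant, n_frames, seed, intensities) {
    out <- list()
    k <- 0
    while (length(out) == 0 || nrow(do.call(rbind, out)) < n_frames) {
      k <- k + 1
      cl <- generate_clip(behavior, intensity = intensities[(k - 1) %%
                                                  length(intensities) + 1],
                          duration = 1, noise_sd = noise_sd,
                          seed = sub_seed(seed, paste0(behavior, k)),
                          climb_variant = variant)
      out[[k]] <- clip_feature_matrix(cl)
    }
    do.call(rbind, out)[seq_len(n_frames), , drop = FALSE]
  }

  xp <- frames_from(pos_spec$behavior, pos_spec$variant, n_per_class,
                    sub_seed(seed, "pos"), c(0.2, 0.5, 0.8))
  n_each <- ceiling(n_per_class / length(neg_behaviors))
  xn <- do.call(rbind, lapply(seq_along(neg_behaviors), function(i) {
    frames_from(neg_behaviors[i], "pull_up", n_each,
                sub_seed(seed, paste0("neg", i)), c(0.3, 0.7))
  }))[seq_len(n_per_class), , drop = FALSE]

  list(x = rbind(xp, xn), y = c(rep(1, n_per_class), rep(-1, n_per_class)))
}

#' Train the three posture models on synthetic data
#'
#' Convenience wrapper: trains push-up climb, pull-up climb and sitting
#' classifiers on [generate_posture_training()] sets.
#'
#' @param n_per_class Frames per class per model (default 90).
#' @param seed Integer seed.
#' @param cost Soft-margin penalty (default 1).
#' @return Named list of [train_posture()] fits (`push_up_climb`,
#'   `pull_up_climb`, `sitting`).
#' @export
train_synthetic_postures <- function(n_per_class = 90, seed = 1, cost = 1) {
  fit_one <- function(class) {
    ts <- generate_posture_training(class, n_per_class,
                                    seed = sub_seed(seed, class))
    train_posture(ts$x, ts$y, cost = cost)
  }
  list(push_up_climb = fit_one("push_up"),
       pull_up_climb = fit_one("pull_up"),
       sitting = fit_one("sitting"))
}

#' Generate a per-module calibration set
#'
#' Twenty (by default) labeled clips per module mixing normal ADL with the
#' module's fall-prone action swept over intensity — the synthetic analogue
#' of an expert-labeled calibration recording. Two labelers are available:
#' `"rule"` labels each clip by [label_rule()] (behavior-level expert
#' judgment), `"alpha"` labels it by the simulated expert's internal
#' sigmoid `1 - exp(-d^2 / alpha_star)` applied to the clip's measured mean
#' stimulus (a perfectly model-consistent expert, used for recovery
#' checks).
#'
#' @param module One of [module_names()].
#' @param plane A [floor_plane()] (needed by the `"alpha"` labeler).
#' @param models Posture-model list (needed for the posture modules).
#' @param n_clips Number of clips (default 20).
#' @param labeler `"rule"` or `"alpha"`.
#' @param alpha_star Sigmoid scale of the `"alpha"` labeler (defaults to
#'   the simulator's reference value for the module).
#' @param seed Integer seed.
#' @param noise_sd Joint jitter.
#' @return A list of labeled [skeleton_clip()]s.
#' @export
generate_calibration_clips <- function(module, plane = floor_plane(0, 1, 0, 0),
                                       models = NULL, n_clips = 20,
                                       labeler = c("rule", "alpha"),
                                       alpha_star = NULL, seed = 1,
                                       noise_sd = 0.005) {
  module <- match.arg(module, module_names())
  labeler <- match.arg(labeler)
  if (is.null(alpha_star)) alpha_star <- generator_alpha_star()[[module]]

  spec <- switch(module,
    push_up_climb = list(risky = "climbing", variant = "push_up",
                         safe = c("standing", "walking")),
    pull_up_climb = list(risky = "climbing", variant = "pull_up",
                         safe = c("standing", "walking")),
    run = list(risky = "rush_running", variant = "pull_up",
               safe = c("standing", "walking")),
    jump = list(risky = "high_jumping", variant = "pull_up",
                safe = c("standing", "jumping_rope")),
    sway = list(risky = "tumbling", variant = "pull_up",
                safe = c("standing", "dancing")),
    lean = list(risky = "tumbling", variant = "pull_up",
                safe = c("standing", "dancing")),
    foot_altitude = list(risky = "standing_on_furniture", variant = "pull_up",
                         safe = c("standing", "walking")),
    head_altitude = list(risky = "standing_on_furniture", variant = "pull_up",
                         safe = c("standing", "walking"))
  )
  occl <- if (module == "head_altitude") c(10, 90) else NULL

  n_risky <- ceiling(n_clips / 2)
  n_safe <- n_clips - n_risky
  beh <- c(rep(spec$risky, n_risky), rep_len(spec$safe, n_safe))
  intens <- c(seq(0, 1, length.out = n_risky),
              with_seed(sub_seed(seed, "cal_i"), stats::runif(n_safe)))

  clips <- lapply(seq_along(beh), function(k) {
    generate_clip(beh[k], intensity = intens[k], noise_sd = noise_sd,
                  seed = sub_seed(seed, paste0(module, k)),
                  climb_variant = spec$variant, occlusion = occl)
  })
  if (labeler == "alpha") {
    for (k in seq_along(clips)) {
      d <- clip_stimulus(clips[[k]], plane, module, models = models)
      clips[[k]]$p_gt <- 1 - exp(-d^2 / alpha_star)
    }
  }
  clips
}
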
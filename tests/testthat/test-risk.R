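standing_frame <- function() {
  tmpl <- toddlerfall:::standing_template()
  make_frame(stats::setNames(
    lapply(seq_len(nrow(tmpl)), function(i) unlist(tmpl[i, c("x", "y", "z")])),
    tmpl$joint))
}

test_that("a stationary skeleton has zero run and jump risk", {
  clip <- static_clip(standing_frame(), n = 40)
  rr <- risk_run(clip, flat_floor(), alpha = 0.009)
  expect_equal(rr$risk, rep(0, 40))
  rj <- risk_jump(clip, flat_floor(), alpha = 0.017)
  expect_equal(rj$risk, rep(0, 40))
})

test_that("ground-projected speed ignores vertical bounce exactly", {
  v <- 1.2
  fr <- standing_frame()
  offsets <- lapply(1:60, function(f) {
    t <- (f - 1) / 30
    c(v * t, 0.1 * sin(2 * pi * 2 * t), 0)  # translation + vertical bounce
  })
  clip <- offset_clip(fr, offsets)
  rr <- risk_run(clip, flat_floor(), alpha = 1)
  expect_equal(rr$stimulus, rep(v, 60), tolerance = 1e-9)
  expect_equal(rr$risk, rep(1 - exp(-v^2), 60), tolerance = 1e-9)
  expect_error(risk_run(static_clip(standing_frame(), n = 2), flat_floor(), 1),
               NA)
})

test_that("alternating centroid height gives variance h^2 and the closed-form risk", {
  h <- 0.15
  alpha <- 0.017
  offsets <- lapply(1:40, function(f) c(0, h * (-1)^f, 0))
  clip <- offset_clip(standing_frame(), offsets)
  rj <- risk_jump(clip, flat_floor(), alpha, cfg = window_config(5, 30))
  # once the trailing window holds an even count of alternating heights
  full <- rj$risk[seq(30, 40, by = 2)]
  expect_equal(full, rep(1 - exp(-h^2 / alpha), length(full)),
               tolerance = 1e-9)
  # a window longer than the clip is flagged and computed on the full clip
  short <- offset_clip(standing_frame(), offsets[1:10])
  rs <- risk_jump(short, flat_floor(), alpha, cfg = window_config(5, 30))
  expect_true(attr(rs, "window_truncated"))
})

test_that("run and jump risks grow with the simulator intensity", {
  speeds <- vapply(seq(0, 1, length.out = 5), function(i) {
    cl <- generate_clip("rush_running", i, duration = 1, noise_sd = 0,
                        seed = 1)
    mean(risk_run(cl, flat_floor(), alpha = 2.8)$risk)
  }, numeric(1))
  expect_true(all(diff(speeds) > 0))
  jumps <- vapply(seq(0, 1, length.out = 5), function(i) {
    cl <- generate_clip("high_jumping", i, duration = 2, noise_sd = 0,
                        seed = 1)
    mean(risk_jump(cl, flat_floor(), alpha = 0.006)$risk)
  }, numeric(1))
  expect_true(all(diff(jumps) > 0))
})

test_that("sway risk follows the base-of-support geometry and the seated gate", {
  # centroid on the foot line: zero risk
  clip0 <- static_clip(standing_frame(), n = 6)
  r0 <- risk_sway(clip0, flat_floor(), alpha = 0.008)
  expect_true(all(r0$risk < 1e-6))

  # body shifted laterally off the feet: known distance drives the risk
  off <- 0.3
  fr <- standing_frame()
  shift <- !fr$joint %in% c("FOOT_LEFT", "FOOT_RIGHT")
  fr$z[shift] <- fr$z[shift] + off
  clip1 <- static_clip(fr, n = 6)
  r1 <- risk_sway(clip1, flat_floor(), alpha = 0.008)
  pc <- ground_project(body_centroid(fr), flat_floor())
  lf <- ground_project(unlist(fr[fr$joint == "FOOT_LEFT", c("x", "y", "z")]),
                       flat_floor())
  rf <- ground_project(unlist(fr[fr$joint == "FOOT_RIGHT", c("x", "y", "z")]),
                       flat_floor())
  d_expect <- unname(base_of_support_distance(pc, lf, rf))
  expect_equal(r1$stimulus, rep(d_expect, 6), tolerance = 1e-9)
  expect_equal(r1$risk, rep(1 - exp(-d_expect^2 / 0.008), 6),
               tolerance = 1e-9)

  # seated frames are forced to zero regardless of geometry
  r1s <- risk_sway(clip1, flat_floor(), alpha = 0.008,
                   seated = rep(TRUE, 6))
  expect_equal(r1s$risk, rep(0, 6))

  # large offsets saturate: the documented scalar value
  expect_equal(1 - exp(-1 / 0.008), 1, tolerance = 1e-10)
})

test_that("lean risk is the spine angle against the normal, scale-free", {
  fr <- standing_frame()
  clip <- static_clip(fr, n = 4)
  r <- risk_lean(clip, flat_floor(), alpha = 0.115)
  expect_true(all(r$risk < 1e-6))  # upright spine

  # lying direction: theta = pi/2, risk saturates
  fr2 <- make_frame(list(SHOULDER_CENTER = c(0.8, 0, 0),
                         HEAD = c(1, 0, 0)))
  r2 <- risk_lean(static_clip(fr2, n = 4), flat_floor(), alpha = 0.115)
  expect_equal(r2$stimulus, rep(pi / 2, 4))
  expect_equal(r2$risk, rep(1 - exp(-(pi / 2)^2 / 0.115), 4))
  expect_equal(r2$risk[1], 1, tolerance = 1e-8)

  # invariance to spine magnitude
  fr3 <- make_frame(list(SHOULDER_CENTER = c(0.08, 0, 0)))
  r3 <- risk_lean(static_clip(fr3, n = 4), flat_floor(), alpha = 0.115)
  expect_equal(r3$stimulus, r2$stimulus, tolerance = 1e-12)

  # zero spine vector: flagged unavailable, zero risk
  fr4 <- make_frame()
  r4 <- risk_lean(static_clip(fr4, n = 4), flat_floor(), alpha = 0.115)
  expect_equal(r4$risk, rep(0, 4))
  expect_false(any(r4$available))
})

test_that("foot altitude risk matches the closed form and the seated gate", {
  fr <- standing_frame()
  clip <- static_clip(fr, n = 4)
  r <- risk_foot_altitude(clip, flat_floor(), alpha = 0.217)
  expect_true(all(r$risk < 0.005))  # feet on the floor (y = 0.02)

  off <- 0.6 - 0.02  # lift the feet midpoint to exactly 0.6 m
  fr2 <- fr
  fr2$y <- fr2$y + off
  r2 <- risk_foot_altitude(static_clip(fr2, n = 4), flat_floor(),
                           alpha = 0.217)
  expect_equal(r2$stimulus, rep(0.6, 4), tolerance = 1e-12)
  expect_equal(r2$risk, rep(1 - exp(-0.36 / 0.217), 4), tolerance = 1e-12)
  expect_equal(r2$risk[1], 0.810, tolerance = 1e-3)

  # seated on a sofa 0.4 m up: gated to zero
  fr3 <- fr
  fr3$y <- fr3$y + 0.4
  r3 <- risk_foot_altitude(static_clip(fr3, n = 4), flat_floor(),
                           alpha = 0.217, seated = rep(TRUE, 4))
  expect_equal(r3$risk, rep(0, 4))
})

test_that("head altitude risk uses the body-height offset with clamping", {
  chain <- list(HEAD = c(0, 1.4, 0), SHOULDER_CENTER = c(0, 1.2, 0),
                SPINE = c(0, 1.0, 0), HIP_CENTER = c(0, 0.8, 0),
                HIP_LEFT = c(0, 0.6, 0), KNEE_LEFT = c(0, 0.4, 0),
                ANKLE_LEFT = c(0, 0.2, 0), FOOT_LEFT = c(0, 0, 0),
                HIP_RIGHT = c(0, 0.6, 0), KNEE_RIGHT = c(0, 0.4, 0),
                ANKLE_RIGHT = c(0, 0.2, 0), FOOT_RIGHT = c(0, 0, 0))
  fr <- make_frame(chain)  # H = 1.4, head altitude 1.4 -> d = 0
  r <- risk_head_altitude(static_clip(fr, n = 4), flat_floor(), alpha = 0.214)
  expect_equal(r$risk, rep(0, 4), tolerance = 1e-9)

  # standing on a 0.5 m platform: d = 0.5
  fr2 <- fr
  fr2$y <- fr2$y + 0.5
  r2 <- risk_head_altitude(static_clip(fr2, n = 4), flat_floor(),
                           alpha = 0.214)
  expect_equal(r2$stimulus, rep(0.5, 4), tolerance = 1e-12)
  expect_equal(r2$risk, rep(1 - exp(-0.25 / 0.214), 4), tolerance = 1e-12)
  expect_equal(r2$risk[1], 0.689, tolerance = 1e-3)

  # crouching: head below H clamps to zero
  fr3 <- fr
  fr3$y[fr3$joint == "HEAD"] <- 1.0
  r3 <- risk_head_altitude(static_clip(fr3, n = 4), flat_floor(),
                           alpha = 0.214)
  expect_equal(r3$risk, rep(0, 4))
})

test_that("clip risk vector aggregates temporal means and respects gating", {
  models <- synthetic_models_small()
  quiet <- generate_clip("standing", 0, noise_sd = 0, seed = 5)
  rv <- clip_risk_vector(quiet, flat_floor(), models = models)
  expect_true(all(toddlerfall:::risk_matrix(rv) < 0.02))

  # a constant per-frame risk aggregates to exactly that value
  off <- 0.58
  fr <- standing_frame()
  fr$y <- fr$y + off
  clipc <- static_clip(fr, n = 8)
  rvc <- clip_risk_vector(clipc, flat_floor(),
                          params = preset_local_params())
  expect_equal(rvc$p_foot_altitude, 1 - exp(-0.36 / 0.217),
               tolerance = 1e-9)

  # a high-jumping clip is dominated by the jump module
  jumpy <- generate_clip("high_jumping", 0.9, noise_sd = 0.002, seed = 6)
  params <- local_params(toddlerfall:::generator_alpha_star())
  rvj <- clip_risk_vector(jumpy, flat_floor(), models = models,
                          params = params)
  pj <- toddlerfall:::risk_matrix(rvj)[1, ]
  expect_equal(names(which.max(pj)), "p_jump")

  # every risk lies in [0, 1)
  expect_true(all(pj >= 0 & pj < 1))
})

test_that("forcing the sitting gate zeroes exactly sway and foot altitude", {
  clip <- generate_clip("tumbling", 0.8, noise_sd = 0.002, seed = 7)
  base <- clip_risk_vector(clip, flat_floor())
  gated <- clip_risk_vector(clip, flat_floor(),
                            models = list(sitting = always_sitting_model()))
  expect_equal(gated$p_sway, 0)
  expect_equal(gated$p_foot_altitude, 0)
  expect_gt(base$p_sway, 0)
  same <- c("p_push_up_climb", "p_pull_up_climb", "p_run", "p_jump",
            "p_lean", "p_head_altitude")
  expect_equal(gated[, same], base[, same])
})

test_that("disabled modules report zero risk", {
  clip <- generate_clip("standing", 0.5, seed = 8)
  rv <- clip_risk_vector(clip, flat_floor())  # no posture models supplied
  expect_equal(rv$p_push_up_climb, 0)
  expect_equal(rv$p_pull_up_climb, 0)
  expect_false(rv$enabled_push_up_climb)
  expect_false(rv$enabled_pull_up_climb)
})
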
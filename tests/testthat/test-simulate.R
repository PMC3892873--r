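test_that("clip generation is deterministic under a fixed seed", {
  c1 <- generate_clip("dancing", 0.7, seed = 9)
  c2 <- generate_clip("dancing", 0.7, seed = 9)
  expect_identical(as_tibble(c1), as_tibble(c2))
  expect_identical(c1$depth_profile, c2$depth_profile)
  c3 <- generate_clip("dancing", 0.7, seed = 10)
  expect_false(identical(as_tibble(c1), as_tibble(c3)))
  expect_error(generate_clip("cartwheel"), "arg")
})

test_that("a resting clip scores near zero on all modules under preset alpha", {
  models <- synthetic_models_small()
  clip <- generate_clip("standing", 0, seed = 13)
  rv <- clip_risk_vector(clip, flat_floor(), models = models,
                         params = preset_local_params())
  expect_true(all(toddlerfall:::risk_matrix(rv) < 0.05))
})

test_that("rush running at full intensity reaches the speed ceiling", {
  clip <- generate_clip("rush_running", 1, noise_sd = 0.002, seed = 14)
  v <- risk_run(clip, flat_floor(), alpha = 1)$stimulus
  v_max <- simulation_config()$v_max
  expect_lt(abs(mean(v) - v_max) / v_max, 0.05)
})

test_that("floor generation honors tilt, noise, outliers and seeding", {
  f0 <- generate_floor(tilt_deg = 0, n_points = 50, seed = 1)
  expect_equal(f0$y, rep(0, 50))  # noiseless horizontal floor is exact
  expect_identical(generate_floor(seed = 5), generate_floor(seed = 5))
  f1 <- generate_floor(tilt_deg = 8, n_points = 200, noise_sd = 0.002,
                       outlier_frac = 0.25, seed = 2)
  expect_equal(nrow(f1), 200)
  nrm <- attr(f1, "normal")
  resid <- abs(as.matrix(f1) %*% nrm)
  expect_gte(sum(resid < 0.01), 150)   # the 75% inliers
  expect_gte(sum(resid > 0.05), 30)    # outliers really are off-plane
})

test_that("dataset labels split exactly by the requested mix", {
  ds <- generate_dataset(n_clips = 40, seed = 15)
  expect_length(ds$clips, 40)
  expect_equal(sum(ds$labels$p_gt > 0.5), 20)
  expect_equal(sum(ds$labels$p_gt < 0.5), 20)
  expect_false(any(ds$labels$p_gt == 0.5))
  expect_equal(sum(ds$labels$split == "train"), 20)
  # split is stratified: half of each side trains
  expect_equal(sum(ds$labels$split == "train" & ds$labels$p_gt > 0.5), 10)
  # a different seed keeps the same label marginals
  ds2 <- generate_dataset(n_clips = 40, seed = 16)
  expect_equal(sum(ds2$labels$p_gt > 0.5), 20)
  expect_false(identical(ds$labels$p_gt, ds2$labels$p_gt))
})

test_that("the label rule keeps safe and risky behaviors on their sides", {
  for (b in toddlerfall:::safe_behaviors()) {
    for (i in c(0, 0.5, 1)) expect_lte(label_rule(b, i), 0.4)
  }
  for (b in toddlerfall:::risky_behaviors()) {
    for (i in c(0, 0.5, 1)) expect_gte(label_rule(b, i), 0.6)
  }
  # 0.1-step questionnaire scale
  expect_equal(label_rule("walking", 0.37) * 10,
               round(label_rule("walking", 0.37) * 10))
})

test_that("combined clips take the max component label plus one step", {
  cc <- generate_combined_clip(c("high_jumping", "tumbling"),
                               intensities = c(0.8, 0.3), seed = 17)
  expected <- min(1, max(label_rule("high_jumping", 0.8),
                         label_rule("tumbling", 0.3)) + 0.1)
  expect_equal(cc$p_gt, expected)
  expect_equal(cc$behavior, "high_jumping+tumbling")
  # both component stimuli are present in the kinematics
  rj <- risk_jump(cc, flat_floor(), alpha = 0.006)
  rl <- risk_lean(cc, flat_floor(), alpha = 0.6)
  expect_gt(mean(rj$risk), 0.3)
  expect_gt(mean(rl$risk), 0.1)
})

test_that("each module's clip risk rises monotonically with intensity", {
  sweeps <- list(
    run = "rush_running", jump = "high_jumping",
    lean = "tumbling", foot_altitude = "standing_on_furniture")
  params <- local_params(toddlerfall:::generator_alpha_star())
  intens <- seq(0, 1, length.out = 10)
  for (m in names(sweeps)) {
    r <- vapply(seq_along(intens), function(k) {
      cl <- generate_clip(sweeps[[m]], intens[k], duration = 1.5,
                          noise_sd = 0.002, seed = 70 + k)
      mean(switch(m,
        run = risk_run(cl, flat_floor(), alpha_of(params, "run"))$risk,
        jump = risk_jump(cl, flat_floor(), alpha_of(params, "jump"))$risk,
        lean = risk_lean(cl, flat_floor(), alpha_of(params, "lean"))$risk,
        foot_altitude = risk_foot_altitude(
          cl, flat_floor(), alpha_of(params, "foot_altitude"))$risk))
    }, numeric(1))
    expect_gte(cor(intens, r, method = "spearman"), 0.9)
  }
})

test_that("risky behaviors respond on their tabulated criteria", {
  # expected dominant criteria: running/jumping = motion, tumbling =
  # balance, climbing = posture, furniture standing = altitude
  models <- synthetic_models_small()
  params <- local_params(toddlerfall:::generator_alpha_star())
  crit <- toddlerfall:::module_criteria()
  expected <- list(
    rush_running = c("motion", "balance"),
    high_jumping = c("motion", "altitude"),
    tumbling = c("posture", "balance"),
    climbing = c("posture", "balance", "altitude"),
    standing_on_furniture = "altitude")
  for (b in names(expected)) {
    cl <- generate_clip(b, 0.7, noise_sd = 0.002, seed = 80,
                        climb_variant = "pull_up")
    rv <- toddlerfall:::risk_matrix(
      clip_risk_vector(cl, flat_floor(), models = models, params = params))[1, ]
    by_crit <- tapply(rv, crit[module_names()], max)
    expect_true(names(which.max(by_crit)) %in% expected[[b]],
                label = paste("dominant criterion for", b))
  }
})
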
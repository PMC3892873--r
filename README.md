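# toddlerfall

Early-warning fall-risk assessment for toddler behaviors, computed from
20-joint 3D skeleton streams (Kinect-style, 30 Hz) and a detected floor
plane.

Unlike a fall *detector*, which reacts after a child is already on the
ground, an early-warning system scores the *behaviors that precede falls* —
climbing, rushing, jumping high, swaying off balance, playing at an
altitude — a few seconds before anything happens, so a caregiver can
intervene. `toddlerfall` implements such a system end to end for people
working on skeleton-based behavior analysis and digital child-safety
monitoring: the eight behavioral risk modules, their local calibration, the
multi-modal fusion and alarm, an evaluation layer, and a parametric
simulator of labeled toddler behavior clips so the whole pipeline can be
trained and tested without sensor hardware.

## The model

Every module converts a per-frame kinematic **stimulus** `d` into a fall
risk through the same saturating map

```
p = 1 − exp(−d² / α),        α > 0,
```

with a module-specific, locally calibrated scale `α`. The eight modules and
their stimuli, organized by the four criteria *posture*, *motion*,
*balance* and *altitude*:

| # | module | criterion | stimulus `d` |
|---|--------|-----------|--------------|
| 1 | push-up climb | posture | signed SVM decision distance (quadratic kernel, 60-dim joint vector); `d ≤ 0 → p = 0` |
| 2 | pull-up climb | posture | same, for the arms-overhead climb |
| 3 | rush running | motion | ground-projected centroid speed ‖V_c‖ (m/s) |
| 4 | high jumping | motion | sd of the centroid's height over a trailing window |
| 5 | body sway | balance | distance of the ground-projected centroid from the base-of-support line through the two feet |
| 6 | body lean | balance | angle between the hip→shoulder spine vector and the floor normal (rad) |
| 7 | foot altitude | altitude | altitude of the feet midpoint over the floor plane |
| 8 | head altitude | altitude | head altitude minus estimated body height (engaged only while the feet are occluded) |

The floor plane `Ax + By + Cz + D = 0` is estimated from a 3D point cloud
by seeded RANSAC with a total-least-squares refit. A sitting-posture SVM
and a depth-profile occlusion detector gate the sway and foot-altitude
modules off whenever the child is seated or the lower body is hidden.

**Calibration.** Each `α` is fit from expert-labeled clips by the
linearized least squares `−ln(1 − p_i) · α = d_i²`, solved in closed form
(`fit_alpha()`).

**Fusion and alarm.** The clip-level risk 8-vector `{p₁…p₈}` (temporal
means; disabled modules enter as 0) is fused either by the rank-weighted
mean

```
p_overall = [ p₍₁₎(1−β) + Σᵢ₌₂ⁿ p₍ᵢ₎ (β^{i−1} − β^i) ] / (1 − β^n),
```

whose parameter `β` interpolates between the maximum (β = 0) and the mean
(β → 1) of the sorted risks and is fit by a recursive grid search
(`fit_beta()`), followed by a strict threshold `p_overall > T` (T = 0.5 by
default); or by an RBF-kernel SVM on the risk vectors with `(C, γ)` chosen
by a recursive cross-validated grid search (`train_svm_fusion()`).

## Worked example

```r
library(toddlerfall)

# 1. Detect the floor from a (synthetic) point cloud
cloud <- generate_floor(tilt_deg = 3, n_points = 400, noise_sd = 0.003,
                        outlier_frac = 0.1, seed = 11)
plane <- fit_floor_ransac(cloud, seed = 11)
plane
#> <floor_plane> -0.0524x + 0.9986y + 0.0003z + -0.0003 = 0 (tilt_cos 0.9986, 360 inliers)

# 2. Train the posture classifiers and calibrate the risk maps
models <- train_synthetic_postures(seed = 42)
cal <- lapply(stats::setNames(nm = module_names()), function(m)
  generate_calibration_clips(m, plane = plane, models = models, seed = 100))
params <- calibrate_modules(cal, plane, models = models)
params
#> # A tibble: 8 × 3
#>   module          alpha fit_error
#> 1 push_up_climb 0.648      0.129
#> 2 pull_up_climb 0.651      0.131
#> 3 run           2.84       0.0654
#> 4 jump          0.00600    0.0962
#> 5 sway          0.0246     0.0598
#> 6 lean          0.435      0.0836
#> 7 foot_altitude 0.165      0.0863
#> 8 head_altitude 0.133      0.0905

# 3. Score one fall-risky clip
clip <- generate_clip("climbing", intensity = 0.8, seed = 7)
clip_risk_vector(clip, plane, models = models, params = params)
#>   p_push_up_climb p_pull_up_climb p_run p_jump p_sway p_lean p_foot_altitude p_head_altitude
#> 1            0.11            0.83     0      0   0.23   0.29            0.29               0

# 4. Fuse, alarm, evaluate on a labeled 60-clip corpus (30 train / 30 test)
ds <- generate_dataset(n_clips = 60, seed = 3)
risks <- assess_clips(ds$clips, plane, models = models, params = params)
risks$split <- ds$labels$split
fusion <- fit_beta(risks[risks$split == "train", ])
fusion
#> <wmean_fusion> beta = 0.012 (fit error 0.0756), alarm T = 0.5
evaluate_fusion(fusion, risks[risks$split == "test", ])$metrics
#>   accuracy   tpr   fpr
#> 1      100   100     0
```

Reading the numbers: the calibrated `alpha` values are in each stimulus's
own squared unit (e.g. 2.84 (m/s)² for running means a 1.7 m/s dash scores
risk ≈ 0.64). The climbing clip fires the pull-up-climb module (0.83) with
secondary lean/altitude responses — exactly the behavior's tabulated
criteria — and the fitted `beta` near 0 means the best fusion is close to
"take the maximum module risk", with 100% alarm accuracy on the held-out
half of this small corpus.

The same steps are available from the shell through the thin dispatcher in
`inst/cli/toddlerfall` (`simulate`, `simulate-dataset`, `train-posture`,
`calibrate`, `assess`, `fuse-fit`, `evaluate`).

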
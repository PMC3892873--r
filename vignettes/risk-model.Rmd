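---
title: "The toddlerfall risk model: modules, calibration, fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The toddlerfall risk model: modules, calibration, fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toddlerfall)
```

`toddlerfall` assesses the fall risk of toddler behaviors observed as
20-joint 3D skeleton streams. This vignette is the package's own account of
the science: the model and its assumptions, the parameters that matter, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the known limits.

## The sigmoid risk map

Every behavioral module reduces a frame to a non-negative stimulus $d$ —
a speed, a distance, an angle, a classifier margin — and maps it to a risk

$$ p(d) = 1 - e^{-d^2/\alpha}, \qquad \alpha > 0. $$

The map is zero at zero stimulus, monotone, and saturates below 1; $\alpha$
is the squared stimulus scale at which risk reaches $1 - e^{-1} \approx
0.63$. Because each module's stimulus lives in its own unit, each $\alpha$
does too ((m/s)² for running, rad² for leaning, m² for the distance-based
modules, a squared classifier margin for the climbs). The package ships a
reference preset (`preset_local_params()`) taken from a real-world
deployment of this model family, but those values are tied to that
deployment's stimulus scales — with metric stimuli, $\alpha_{run} = 0.009$
(m/s)² saturates at walking pace. Calibration against labeled data from
your own source (`calibrate_modules()`) is therefore the normative way to
obtain parameters; the preset is a fallback and a documentation aid.

## The eight modules and their gates

Two *posture* modules detect push-up climbs (pressing down on a low object)
and pull-up climbs (reaching overhead) with soft-margin SVMs on the
normalized 60-dimensional joint-coordinate vector, using the quadratic
kernel $K(x, x') = (x \cdot x' + 1)^2$. The stimulus is the raw
decision-function value $f(x)$ (the functional margin), clamped at zero on
the non-climb side: we use $f(x)$ itself rather than the geometric margin
$f(x)/\lVert w \rVert$ because $\lVert w \rVert$ is awkward to interpret
under a kernel and any fixed rescaling is absorbed into $\alpha$ during
calibration.

Two *motion* modules track the body centroid, computed as the center of
mass of the 19 bones under a uniform-rod assumption (bone-length-weighted
midpoints; an unweighted variant is available via
`body_centroid(weighted = FALSE)`). Rush running uses the speed of the
ground-projected centroid — centered finite differences smoothed by a
5-frame centered moving average; vertical motion is invisible to it by
construction. High jumping uses the variance of the centroid's height above
the floor over a trailing 30-frame (1 s) window. Neither window length is
dictated by the model; 5 frames suppresses gait-cycle jitter without
blunting genuine speed changes at 30 Hz, and 1 s spans at least one full
jump cycle. Population (not sample) variance is used, so a height
alternating $\pm h$ gives exactly $\sigma^2 = h^2$.

Two *balance* modules: body sway is the distance from the ground-projected
centroid to the 2D line through the two ground-projected feet (the base of
support), falling back to the point-to-point distance when the feet
coincide within 1 cm; body lean is the angle between the hip-to-shoulder
spine vector and the floor normal. Both are zeroed while a sitting posture
is detected (a third SVM, same construction), because a seated child
legitimately rests its weight off the foot line.

Two *altitude* modules: foot altitude is the height of the feet midpoint
over the floor plane, also gated by the sitting detector (feet dangling
from a sofa are not a hazard). When the feet are occluded — untracked with
no history, or the tracker is in seated mode — the head-altitude module
takes over on exactly those frames: head altitude minus the estimated body
height approximates the altitude of the invisible lowest joint, under an
upright-pose assumption, clamped at zero for crouching. Body height is the
summed bone-length chain head → shoulder center → spine → hip center plus
the left/right-averaged leg chain; the chain is a design choice (the
head-to-foot path is the only chain consistent with the upright-pose use),
and leg averaging suppresses single-side tracking noise.

## Floor geometry

The floor plane is fit by RANSAC: 500 seeded 3-point hypotheses (or
exhaustive enumeration when the cloud is small enough for the budget),
inliers within 2 cm perpendicular distance, and a final total-least-squares
refit on the winning inlier set. Coefficients are normalized to a unit
normal with $B \ge 0$ so the normal points camera-up.

Two deliberate conventions deserve a note. First, the altitude measure
multiplies the plane-equation residual by $\cos\theta_k$, the cosine of the
angle between the camera's vertical axis and the floor normal. The residual
alone *is* the perpendicular distance, so this extra factor slightly
shrinks altitudes on tilted floors; it is retained as the model family's
printed form (the bias is $< 1.5\%$ below $10^\circ$ tilt and vanishes on a
level floor), and `point_plane_distance(strict = FALSE)` exposes the pure
geometric distance. Second, ground projection expresses points in a
deterministic in-plane basis $u = \widehat{x - (x \cdot n)n}$ (falling back
to the z axis if degenerate) and $v = u \times n$, oriented so that a
horizontal floor reproduces the raw $(x, z)$ coordinates exactly — the
special case in which base-of-support formulas are usually written.

## Calibration

Given labeled clips, each module's stimulus is aggregated to its clip-level
temporal mean $\bar d$ and paired with the expert risk $p$. Inverting the
sigmoid linearizes the fit: $-\ln(1 - p_i)\,\alpha = \bar d_i^2$, solved in
closed form as $\alpha = \sum a_i b_i / \sum a_i^2$. Averaging the
*stimulus* (rather than the per-frame risks) before fitting keeps this
system linear; the alternative — fitting to clip-mean risks — would make
Eq.-level least squares nonlinear for no gain at the 20-clips-per-module
scale. Pairs with $p = 0$ contribute nothing (their $a_i$ vanishes), and
$p \ge 1$ is rejected outright rather than clipped, because the log
singularity would otherwise silently dominate the fit.

## Fusion and the alarm

The clip risk vector $\{p_1 \dots p_8\}$ (zeros for disabled modules) is
fused by one of two schemes.

*Rank-weighted mean:* sorted descending, the risks are averaged with
geometrically decaying weights controlled by $\beta \in [0, 1)$; $\beta=0$
is the maximum, $\beta \to 1$ the arithmetic mean, and $\beta = 0.5$ gives
the halving weights $1/2, 1/4, \dots$ normalized by $1 - 2^{-n}$. $\beta$
is fit by a recursive grid search (coarse step 0.01 on $[0, 0.99]$, two
refinement levels dividing the step by 10) minimizing the mean absolute
error against the ground-truth risks — deterministic, and verified in the
tests against an exhaustive fine grid. The alarm fires on
$p_{overall} > T$ strictly; a tie does not alarm. $T = 0.5$ by default and
is the user's sensitivity dial.

*SVM fusion:* an RBF-kernel classifier on the risk vectors, labels from
thresholding the ground truth at $T$, with $(C, \gamma)$ selected by the
standard LIBSVM-style lattice $C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$
(step $2^2$), refined once at step $2^{1/2}$, under seeded stratified
5-fold cross-validation. Grid ranges and refinement depth are design
choices; the spec of the search (recursive, CV-scored) matters more than
the exact lattice.

## Occlusion handling

Lower-body occlusion is detected from a per-frame depth profile (mean depth
of the upper vs lower body region, split at HIP_CENTER): when the lower
mean drops more than `delta` = 0.3 m below the upper for `hold` = 3
consecutive frames, tracking switches to the seated (upper-body) mode, and
back symmetrically. The hold debounces single-frame flickers and makes the
mode stream piecewise constant. In seated mode the sway and foot-altitude
modules are disabled and head altitude takes over. The 0.3 m / 3-frame
defaults encode "a clearly closer occluder, persisting for 100 ms"; both
are exposed.

## What the simulator emulates — and what it does not

`generate_clip()` builds kinematically plausible 20-joint trajectories for
ten behavior types (five typically safe: sitting, standing, walking,
jumping rope, dancing; five fall-risky: rush running, high jumping,
tumbling, climbing, standing on furniture) on a toddler-scale (~0.88 m)
template: locomotion is translation plus a sinusoidal antiphase gait,
jumping a whole-body vertical oscillation, sway a lateral offset of the
body over the feet, lean a trunk rotation about the hips, climbing an
arm-pose interpolation (pull-up or push-up variant), furniture standing a
whole-body vertical offset — plus i.i.d. Gaussian joint jitter (default
5 mm) and a matching depth profile. The plausibility ceilings (run 2.5 m/s,
jump amplitude 0.35 m, sway 0.4 m, lean 60°, furniture 0.6 m) are package
constants chosen once as realistic for an energetic toddler; nothing in the
model depends on their exact values. Each behavior's `intensity` in
$[0, 1]$ monotonically drives its dominant stimulus, with risky behaviors
keeping a nonzero floor so that every risky clip is genuinely risky.

Ground-truth labels come from a deterministic `label_rule()` emulating an
expert questionnaire on a 0–1 scale in 0.1 steps: safe behaviors land at or
below 0.4, risky at or above 0.6, and combined clips take the maximum
component label plus 0.1 (capped at 1). A second labeler is available for
recovery experiments: a model-consistent expert that scores clips through
the sigmoid at a known $\alpha^\star$, which is what lets the test suite
check end-to-end parameter recovery.

What passing tests on this corpus show: the geometry, gating, calibration
and fusion machinery are correct and the pipeline separates
by-construction-separable behaviors. What they do not show: robustness to
real skeleton-tracker noise (which is temporally correlated and
pose-dependent, not i.i.d.), to anthropometric variation across children,
to mislabeled or ambiguous expert ratings, or to behaviors outside the ten
templates. High-intensity dancing is the deliberately hardest negative
class — its sway approaches tumbling levels — and it accounts for
essentially all residual false alarms in the benchmark.

## Numerical choices and degenerate inputs

- Feature normalization uses the population standard deviation, making the
  training pipeline exactly invariant under duplicating the training set;
  zero-variance dimensions get unit scale and are recorded.
- Untracked joints are forward-filled from the most recent tracked frame
  within the clip only (on-line behavior); a joint with no history makes
  that frame unusable for the posture features, and such frames are
  downgraded, not imputed.
- All-coincident joints give a zero-length bone skeleton; the centroid then
  falls back to the unweighted midpoint mean (= the common point), and
  a zero spine vector disables the lean module for that frame rather than
  producing an arbitrary angle.
- libsvm is run at tolerance $10^{-6}$ so independent fits agree to the
  probe-grid tolerances asserted in the tests; the fitted decision function
  is extracted into plain coefficient form, which serializes to JSON and
  reproduces libsvm's own predictions to $10^{-8}$.
- Backward feature elimination breaks ties toward the lowest feature index
  and reuses one seeded stratified fold assignment throughout, making the
  greedy path fully deterministic.
- Every stochastic routine (RANSAC, fold assignment, grid refinement, the
  simulator) takes an explicit integer seed; derived sub-seeds stay below
  $2^{31}$.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
posture classifiers train on 90 frames per class; calibration uses 20
labeled clips per module (half safe, half module-risky, intensity-swept);
the end-to-end benchmark uses 200 three-second clips at 30 Hz (100 train /
100 test, labels split 50/50), on which both fusion schemes are required to
reach at least 90% held-out alarm accuracy. Oracle-style checks use 100
random poses against arclength integration for the centroid and $10^6$
sampled line points for the base-of-support distance.

## Known limitations

The head-altitude fallback assumes an upright pose; a child crouching on a
table under occlusion is under-scored. The sitting gate is per-frame, so a
single misclassified frame re-enables sway/foot-altitude for that frame
only — robust in aggregate but visible in per-frame traces. The weighted
mean with small $\beta$ is nearly the max of eight risks, so a single
miscalibrated module can drive false alarms; the SVM scheme is less
interpretable but more forgiving there. Skeletons are consumed, not
produced: joint tracking quality is upstream of everything this package
computes.
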
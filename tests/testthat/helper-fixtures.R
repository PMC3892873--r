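# Shared fixtures: frames, clips and reference geometry built in code.

flat_floor <- function() floor_plane(0, 1, 0, 0)

# A single skeleton frame from a named list of joint positions; joints not
# named sit at `default`.
make_frame <- function(positions = list(), default = c(0, 0, 0),
                       frame = 1L, t = 0, tracked_off = character()) {
  jn <- joint_names()
  pos <- matrix(rep(default, each = 20), nrow = 20,
                dimnames = list(jn, NULL))
  for (nm in names(positions)) pos[nm, ] <- positions[[nm]]
  tibble::tibble(frame = frame, t = t, joint = jn,
                 x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 tracked = !(jn %in% tracked_off))
}

# Replicate one frame into a static clip.
static_clip <- function(frame, n = 10, frame_rate = 30, ...) {
  frames <- dplyr::bind_rows(lapply(seq_len(n), function(f) {
    fr <- frame
    fr$frame <- f
    fr$t <- (f - 1) / frame_rate
    fr
  }))
  skeleton_clip(frames, frame_rate = frame_rate, ...)
}

# A clip applying a per-frame whole-body offset function (frame -> xyz) to a
# base frame.
offset_clip <- function(base_frame, offsets, frame_rate = 30, ...) {
  frames <- dplyr::bind_rows(lapply(seq_along(offsets), function(f) {
    fr <- base_frame
    fr$frame <- f
    fr$t <- (f - 1) / frame_rate
    fr$x <- fr$x + offsets[[f]][1]
    fr$y <- fr$y + offsets[[f]][2]
    fr$z <- fr$z + offsets[[f]][3]
    fr
  }))
  skeleton_clip(frames, frame_rate = frame_rate, ...)
}

# Random generic pose (no anatomy implied), tracked everywhere.
random_frame <- function(seed) {
  set.seed(seed)
  make_frame(stats::setNames(
    lapply(joint_names(), function(j) stats::runif(3, -1, 1)),
    joint_names()))
}

# Rigid motion: random rotation (QR of a Gaussian matrix) + translation.
random_rigid <- function(seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = stats::rnorm(3, sd = 0.5))
}

apply_rigid <- function(frame, rigid) {
  xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% t(rigid$R)
  frame$x <- xyz[, 1] + rigid$t[1]
  frame$y <- xyz[, 2] + rigid$t[2]
  frame$z <- xyz[, 3] + rigid$t[3]
  frame
}

# Independent centroid oracle: per-bone trapezoid integration of position
# over arclength (exact for straight rods), normalized by total length.
centroid_by_integration <- function(frame, k = 200) {
  frame <- frame[match(joint_names(), frame$joint), ]
  P <- as.matrix(frame[, c("x", "y", "z")])
  rownames(P) <- frame$joint
  edges <- bone_edges()
  num <- c(0, 0, 0)
  den <- 0
  for (b in seq_len(nrow(edges))) {
    a <- P[edges$from[b], ]
    bb <- P[edges$to[b], ]
    len <- sqrt(sum((bb - a)^2))
    if (len == 0) next
    ts <- seq(0, 1, length.out = k)
    pts <- outer(1 - ts, a) + outer(ts, bb)
    w <- rep(len / (k - 1), k)
    w[c(1, k)] <- w[c(1, k)] / 2  # trapezoid end weights
    num <- num + colSums(pts * w)
    den <- den + sum(w)
  }
  if (den == 0) colMeans(P[unique(unlist(bone_edges())), , drop = FALSE])
  else num / den
}

# A posture-model stub whose decision function is always positive
# (forces the sitting gate on for every frame).
always_sitting_model <- function() {
  structure(
    list(sv = matrix(0, 1, 60), coefs = 1, rho = -1, kernel_degree = 1,
         cost = 1, feature_mask = 1:60,
         norm_stats = list(mean = rep(0, 60), sd = rep(1, 60),
                           constant_dims = integer())),
    class = "posture_model")
}

# Cached small posture models (training is the slow part of the suite).
synthetic_models_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- train_synthetic_postures(n_per_class = 30,
                                                           seed = 42)
    cache
  }
})
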
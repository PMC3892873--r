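test_that("joint enumeration and bone tree have the expected structure", {
  expect_length(joint_names(), 20)
  expect_equal(anyDuplicated(joint_names()), 0)
  edges <- bone_edges()
  expect_equal(nrow(edges), 19)
  expect_true(all(c(edges$from, edges$to) %in% joint_names()))
  # a tree: every joint except the root appears exactly once as a child
  expect_equal(sort(edges$to), sort(setdiff(joint_names(), "HIP_CENTER")))
})

test_that("frame feature vector places coordinates by joint order, not row order", {
  expect_equal(frame_feature_vector(make_frame()), rep(0, 60))

  fr <- make_frame(list(HEAD = c(0, 1.0, 2.0)))
  v <- frame_feature_vector(fr)
  slot <- (match("HEAD", joint_names()) - 1) * 3
  expect_equal(v[slot + 1:3], c(0, 1.0, 2.0))
  expect_equal(sum(v != 0), 2)

  fr2 <- random_frame(7)
  shuffled <- fr2[sample(nrow(fr2)), ]
  expect_identical(frame_feature_vector(fr2), frame_feature_vector(shuffled))

  expect_error(
    frame_feature_vector(make_frame(tracked_off = "FOOT_LEFT")),
    "untracked joint")
})

test_that("normalization is an exact round trip and handles edge cases", {
  set.seed(1)
  X <- matrix(rnorm(10 * 60), 10, 60)
  X[, 5] <- 3  # constant dimension
  st <- fit_normalization(X)
  expect_equal(st$sd[5], 1)
  expect_true(5 %in% st$constant_dims)
  v <- rnorm(60)
  expect_equal(normalize_features(denormalize_features(v, st), st), v,
               tolerance = 1e-12)
  expect_equal(denormalize_features(normalize_features(X, st), st), X,
               tolerance = 1e-12)
  # features equal to the mean map to zero
  expect_equal(normalize_features(st$mean, st), rep(0, 60))
  st2 <- list(mean = rep(0, 60), sd = rep(2, 60))
  expect_equal(normalize_features(rep(2, 60), st2), rep(1, 60))
})

test_that("body centroid matches arclength integration on random poses", {
  p <- c(0.3, -0.2, 1.1)
  expect_equal(unname(body_centroid(make_frame(default = p))[1:3]), p)

  for (seed in 1:10) {
    fr <- random_frame(seed)
    expect_equal(unname(body_centroid(fr)[1:3]),
                 unname(centroid_by_integration(fr)), tolerance = 1e-6)
  }
})

test_that("body centroid is equivariant under rigid motion", {
  fr <- random_frame(3)
  c0 <- unname(body_centroid(fr)[1:3])
  for (seed in 1:5) {
    rg <- random_rigid(seed)
    c1 <- unname(body_centroid(apply_rigid(fr, rg))[1:3])
    expect_equal(c1, as.vector(rg$R %*% c0) + rg$t, tolerance = 1e-9)
  }
})

test_that("partial centroid drops bones with untracked endpoints", {
  fr <- make_frame(list(HAND_LEFT = c(5, 5, 5)), tracked_off = "HAND_LEFT")
  cen <- body_centroid(fr)
  expect_true(attr(cen, "partial"))
  expect_equal(unname(cen[1:3]), c(0, 0, 0))  # the wild hand is excluded
})

test_that("body height sums the head-to-foot chain with leg averaging", {
  chain <- list(HEAD = c(0, 1.4, 0), SHOULDER_CENTER = c(0, 1.2, 0),
                SPINE = c(0, 1.0, 0), HIP_CENTER = c(0, 0.8, 0),
                HIP_LEFT = c(0, 0.6, 0), KNEE_LEFT = c(0, 0.4, 0),
                ANKLE_LEFT = c(0, 0.2, 0), FOOT_LEFT = c(0, 0, 0),
                HIP_RIGHT = c(0, 0.6, 0), KNEE_RIGHT = c(0, 0.4, 0),
                ANKLE_RIGHT = c(0, 0.2, 0), FOOT_RIGHT = c(0, 0, 0))
  fr <- make_frame(chain)
  expect_equal(body_height(fr), 1.4)

  # homogeneity: doubling all coordinates doubles the height
  fr2 <- fr
  fr2[, c("x", "y", "z")] <- fr2[, c("x", "y", "z")] * 2
  expect_equal(body_height(fr2), 2.8)

  # rigid-motion invariance
  for (seed in 1:3) {
    expect_equal(body_height(apply_rigid(fr, random_rigid(seed))), 1.4,
                 tolerance = 1e-9)
  }

  expect_equal(body_height(make_frame()), 0)
  expect_error(body_height(make_frame(tracked_off = "KNEE_LEFT")),
               "height unavailable")
})

test_that("spine vector runs from hip center to shoulder center", {
  fr <- make_frame(list(SHOULDER_CENTER = c(0, 0.5, 0)))
  expect_equal(unname(spine_vector(fr)), c(0, 0.5, 0))
  expect_equal(unname(spine_vector(make_frame())), c(0, 0, 0))
  # translation invariance
  fr2 <- fr
  fr2[, c("x", "y", "z")] <- sweep(as.matrix(fr2[, c("x", "y", "z")]), 2,
                                   c(1, -2, 3), "+")
  expect_equal(unname(spine_vector(fr2)), c(0, 0.5, 0))
  expect_error(spine_vector(make_frame(tracked_off = "HIP_CENTER")),
               "untracked")
})

test_that("untracked joints are forward-filled within a clip", {
  fr1 <- make_frame(list(HEAD = c(0, 1, 0)))
  fr2 <- make_frame(list(HEAD = c(9, 9, 9)), tracked_off = "HEAD")
  fr2$frame <- 2L
  fr3 <- make_frame()
  fr3$frame <- 3L
  clip <- skeleton_clip(dplyr::bind_rows(fr1, fr2, fr3))
  X <- suppressWarnings(toddlerfall:::clip_feature_matrix(clip))
  slot <- (match("HEAD", joint_names()) - 1) * 3
  expect_equal(X[2, slot + 1:3], c(0, 1, 0))   # filled from frame 1
  expect_equal(X[3, slot + 1:3], c(0, 0, 0))   # tracked again

  # no history: the frame is reported unusable, later frames unaffected
  fr1b <- make_frame(tracked_off = "HEAD")
  clip2 <- skeleton_clip(dplyr::bind_rows(fr1b, fr3))
  X2 <- toddlerfall:::clip_feature_matrix(clip2)
  expect_true(all(is.na(X2[1, ])))
  expect_false(anyNA(X2[2, ]))
})
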
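toy_separable <- function(n = 10, gap = 1, seed = 2, p = 2) {
  set.seed(seed)
  x1 <- matrix(rnorm(n * p, mean = -gap), n, p)
  x2 <- matrix(rnorm(n * p, mean = gap), n, p)
  list(x = rbind(x1, x2), y = c(rep(-1, n), rep(1, n)))
}

test_that("a separable toy set is classified perfectly, boundary at zero", {
  x <- matrix(c(-1.2, -1, 1, 1.2), ncol = 1)
  y <- c(-1, -1, 1, 1)
  m <- train_posture(x, y, kernel_degree = 1)
  d <- decision_distance(m, x)
  expect_equal(sign(d), y)
  # symmetric data: the boundary sits at the midpoint
  expect_equal(decision_distance(m, matrix(0)), 0, tolerance = 1e-6)
  # margin support vectors have |d| = 1
  expect_equal(abs(decision_distance(m, matrix(c(-1, 1), ncol = 1))),
               c(1, 1), tolerance = 1e-3)
})

test_that("training requires two classes with >= 2 examples each", {
  expect_error(train_posture(matrix(rnorm(6), 3), rep(1, 3), ),
               "both classes")
  expect_error(train_posture(matrix(rnorm(6), 3), c(1, -1, 1)),
               "2 examples")
})

test_that("decision function matches an independent libsvm evaluation", {
  ts <- toy_separable(15, gap = 1.5, seed = 3, p = 4)
  m <- train_posture(ts$x, ts$y)
  # independent route: e1071's own predict on identically prepared inputs
  st <- fit_normalization(ts$x)
  xn <- normalize_features(ts$x, st)
  fit <- e1071::svm(xn, factor(ts$y, levels = c(1, -1)), scale = FALSE,
                    kernel = "polynomial", degree = 2, gamma = 1, coef0 = 1,
                    cost = 1, tolerance = 1e-6)
  set.seed(8)
  probe <- matrix(rnorm(10 * 4), 10, 4)
  dv <- attr(stats::predict(fit, normalize_features(probe, st),
                            decision.values = TRUE), "decision.values")
  sgn <- if (startsWith(colnames(dv)[1], "1")) 1 else -1
  expect_equal(decision_distance(m, probe), sgn * as.vector(dv),
               tolerance = 1e-8)
  # sign(d) reproduces the training labels on separable data
  expect_equal(sign(decision_distance(m, ts$x)), ts$y)
})

test_that("duplicating every training point leaves the decision unchanged", {
  ts <- toy_separable(12, gap = 2, seed = 5, p = 3)
  m1 <- train_posture(ts$x, ts$y)
  m2 <- train_posture(rbind(ts$x, ts$x), c(ts$y, ts$y))
  set.seed(11)
  probe <- matrix(rnorm(20 * 3), 20, 3)
  expect_equal(decision_distance(m1, probe), decision_distance(m2, probe),
               tolerance = 1e-6)
})

test_that("independent solver runs agree on a probe grid", {
  ts <- toy_separable(20, gap = 1, seed = 6, p = 5)
  m1 <- train_posture(ts$x, ts$y)
  m2 <- train_posture(ts$x, ts$y)
  set.seed(12)
  probe <- matrix(rnorm(30 * 5), 30, 5)
  expect_equal(decision_distance(m1, probe), decision_distance(m2, probe),
               tolerance = 1e-6)
})

test_that("risk map clamps the non-climb side and rises with distance", {
  expect_equal(risk_from_distance(0, 0.167), 0)
  expect_equal(risk_from_distance(-3, 0.167), 0)
  expect_equal(risk_from_distance(0.5, 0.167), 1 - exp(-0.25 / 0.167))
  expect_equal(risk_from_distance(0.5, 0.167), 0.776, tolerance = 1e-3)
  d <- seq(0.01, 1, length.out = 50)
  r <- risk_from_distance(d, 0.2)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r < 1))
  # monotone in 1/alpha as well
  expect_true(all(risk_from_distance(d, 0.1) > risk_from_distance(d, 0.2)))
  expect_error(risk_from_distance(1, 0), "positive")
  expect_error(risk_from_distance(1, -1), "positive")
})

test_that("backward elimination removes a harmful noise feature", {
  set.seed(21)
  n <- 12
  y <- rep(c(1, -1), each = n)
  x_good <- c(rnorm(n, 1.5, 0.5), rnorm(n, -1.5, 0.5))
  x <- cbind(x_good, matrix(rnorm(2 * n * 2, 0, 6), 2 * n, 2))  # loud noise
  res <- backward_feature_elimination(x, y, folds = 5, seed = 1)
  expect_true(1 %in% res$mask)
  expect_lt(length(res$mask), 3)
  expect_gt(res$final_accuracy, res$initial_accuracy)
  expect_equal(nrow(res$history), 3 - length(res$mask))
})

test_that("an already-optimal feature set is a fixed point", {
  set.seed(22)
  n <- 20
  y <- rep(c(1, -1), each = n)
  x <- cbind(c(rnorm(n, 2, 0.2), rnorm(n, -2, 0.2)),
             c(rnorm(n, 1, 0.2), rnorm(n, -1, 0.2)))
  res <- backward_feature_elimination(x, y, folds = 5, seed = 1)
  # both features are discriminative: nothing can be removed with strict gain
  expect_equal(res$final_accuracy, 1)
  expect_equal(res$initial_accuracy, 1)
  expect_equal(res$mask, 1:2)
})

test_that("sitting detector separates seated from standing poses", {
  models <- synthetic_models_small()
  seated <- generate_clip("sitting", 0.5, duration = 0.5, seed = 91)
  standing <- generate_clip("standing", 0.5, duration = 0.5, seed = 92)
  fr_seated <- as_tibble(seated)[as_tibble(seated)$frame == 1, ]
  fr_standing <- as_tibble(standing)[as_tibble(standing)$frame == 1, ]
  expect_true(detect_sitting(models$sitting, fr_seated))
  expect_false(detect_sitting(models$sitting, fr_standing))
})

test_that("synthetic climb training frames are separable by construction", {
  ts <- generate_posture_training("pull_up", n_per_class = 30, seed = 5)
  m <- train_posture(ts$x, ts$y)
  expect_equal(sign(decision_distance(m, ts$x)), ts$y)  # 100% on training
})
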
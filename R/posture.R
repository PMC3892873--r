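#' Train a static-posture max-margin classifier
#'
#' Fits a soft-margin SVM on normalized 60-dimensional skeleton feature
#' vectors with the polynomial kernel `K(x, x') = (x . x' + 1)^degree`
#' (degree 2 — the quadratic kernel — by default). Used for the push-up
#' climb, pull-up climb and sitting posture detectors. Training goes through
#' libsvm (via e1071); the fitted decision function is extracted into a
#' self-contained, serializable form.
#'
#' @param x Numeric matrix of raw (unnormalized) feature vectors, one row per
#'   frame.
#' @param y Labels: +1 for the target posture, -1 otherwise.
#' @param kernel_degree Polynomial kernel degree (default 2).
#' @param cost Soft-margin penalty C (default 1).
#' @param feature_mask Optional integer vector of feature columns to use
#'   (default all).
#' @param norm_stats Optional precomputed [fit_normalization()] statistics;
#'   fitted on `x` when NULL.
#' @return An object of class `posture_model`.
#' @export
train_posture <- function(x, y, kernel_degree = 2, cost = 1,
                          feature_mask = NULL, norm_stats = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 / -1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (min(table(y)) < 2) stop("need at least 2 examples per class")
  if (is.null(norm_stats)) norm_stats <- fit_normalization(x)
  if (is.null(feature_mask)) feature_mask <- seq_len(ncol(x))

  xn <- normalize_features(x, norm_stats)[, feature_mask, drop = FALSE]
  yf <- factor(y, levels = c(1, -1))
  fit <- e1071::svm(xn, yf, scale = FALSE, kernel = "polynomial",
                    degree = kernel_degree, gamma = 1, coef0 = 1,
                    cost = cost, tolerance = 1e-6)
  dv <- attr(stats::predict(fit, xn, decision.values = TRUE),
             "decision.values")
  # libsvm's decision sign follows its internal label order; orient it so
  # that positive distance always means the +1 (target posture) class
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  sgn <- if (identical(first, "1")) 1 else -1

  structure(
    list(
      sv = unname(fit$SV),
      coefs = as.vector(fit$coefs) * sgn,
      rho = fit$rho * sgn,
      kernel_degree = kernel_degree,
      cost = cost,
      feature_mask = as.integer(feature_mask),
      norm_stats = norm_stats
    ),
    class = "posture_model"
  )
}

#' @export
print.posture_model <- function(x, ...) {
  cat(sprintf(
    "<posture_model> degree-%d polynomial kernel, C = %g, %d support vectors, %d/%d features\n",
    x$kernel_degree, x$cost, nrow(x$sv), length(x$feature_mask),
    length(x$norm_stats$mean)))
  invisible(x)
}

poly_kernel <- function(U, V, degree) (tcrossprod(U, V) + 1)^degree

#' Signed decision distance of a posture model
#'
#' Value of the fitted decision function (the unnormalized functional
#' margin): positive when the frame is classified as the target posture, with
#' magnitude growing with classification confidence. This raw distance is the
#' stimulus that the climbing risk maps (see [risk_from_distance()]) convert
#' to a fall risk.
#'
#' @param model A [train_posture()] fit.
#' @param x A raw feature vector or matrix of vectors (full dimensionality;
#'   the model applies its own normalization and feature mask).
#' @return Signed numeric distance(s).
#' @export
decision_distance <- function(model, x) {
  single <- is.null(dim(x))
  x <- if (single) matrix(x, nrow = 1) else as.matrix(x)
  xn <- normalize_features(x, model$norm_stats)[, model$feature_mask,
                                                drop = FALSE]
  d <- as.vector(poly_kernel(xn, model$sv, model$kernel_degree) %*%
                   model$coefs) - model$rho
  d
}

#' Map a signed decision distance to a fall risk
#'
#' The climbing-posture risk map: `1 - exp(-d^2 / alpha)` on the positive
#' (climbing) side of the hyperplane and exactly 0 otherwise. `alpha` sets
#' the distance scale at which the risk saturates and is determined by local
#' calibration (see [fit_alpha()]).
#'
#' @param d Signed decision distance(s).
#' @param alpha Positive scale parameter.
#' @return Risk(s) in `[0, 1)`.
#' @export
#' @examples
#' risk_from_distance(0.5, alpha = 0.167)
risk_from_distance <- function(d, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0) {
    stop("alpha must be a positive scalar")
  }
  ifelse(d > 0, 1 - exp(-d^2 / alpha), 0)
}

# Deterministic stratified fold assignment.
make_folds <- function(y, folds, seed) {
  idx <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      members <- which(y == cl)
      members <- members[sample.int(length(members))]
      idx[members] <- rep_len(seq_len(folds), length(members))
    }
  })
  idx
}

cv_accuracy <- function(x, y, fold_id, kernel_degree, cost) {
  correct <- 0L
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    fit <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr], levels = c(1, -1)),
                      scale = FALSE, kernel = "polynomial",
                      degree = kernel_degree, gamma = 1, coef0 = 1,
                      cost = cost)
    pred <- stats::predict(fit, x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == factor(y[!tr], levels = c(1, -1)))
  }
  correct / length(y)
}

#' Backward feature elimination for a posture classifier
#'
#' Greedy wrapper selection: at each step, the single feature whose removal
#' gives the best strict improvement in stratified k-fold cross-validation
#' accuracy is dropped; the loop stops when no removal improves. Ties are
#' broken toward the lowest feature index; fold assignment is fixed by the
#' seed, so the procedure is deterministic.
#'
#' @inheritParams train_posture
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A list with `mask` (retained feature indices), `initial_accuracy`,
#'   `final_accuracy`, and a `history` tibble of removals.
#' @export
backward_feature_elimination <- function(x, y, folds = 5, seed = 1,
                                         kernel_degree = 2, cost = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stats_ <- fit_normalization(x)
  xn <- normalize_features(x, stats_)
  fold_id <- make_folds(y, folds, seed)
  mask <- seq_len(ncol(x))
  acc <- cv_accuracy(xn[, mask, drop = FALSE], y, fold_id, kernel_degree, cost)
  initial <- acc
  history <- list()
  while (length(mask) > 1) {
    cand <- vapply(seq_along(mask), function(i) {
      cv_accuracy(xn[, mask[-i], drop = FALSE], y, fold_id,
                  kernel_degree, cost)
    }, numeric(1))
    best <- which.max(cand)  # ties: lowest index wins
    if (cand[best] <= acc) break
    history[[length(history) + 1]] <-
      tibble::tibble(removed = mask[best], cv_accuracy = cand[best])
    acc <- cand[best]
    mask <- mask[-best]
  }
  list(mask = mask, initial_accuracy = initial, final_accuracy = acc,
       history = if (length(history)) dplyr::bind_rows(history)
                 else tibble::tibble(removed = integer(),
                                     cv_accuracy = numeric()))
}

#' Detect a sitting posture in a frame
#'
#' True when the sitting-posture model's decision function is positive. A
#' positive detection gates the body-sway and foot-altitude modules off (a
#' seated toddler is allowed to have its centroid off the foot line and its
#' feet above the floor).
#'
#' @param model A sitting [train_posture()] fit.
#' @param frame A single-frame data frame (`joint`, `x`, `y`, `z`,
#'   `tracked`).
#' @return Logical.
#' @export
detect_sitting <- function(model, frame) {
  decision_distance(model, frame_feature_vector(frame)) > 0
}

# Per-frame sitting mask for a whole clip; frames whose feature vector is
# unavailable (untracked joints without history) are treated as not seated.
detect_sitting_clip <- function(model, clip) {
  X <- clip_feature_matrix(clip)
  ok <- stats::complete.cases(X)
  out <- rep(FALSE, nrow(X))
  if (any(ok)) out[ok] <- decision_distance(model, X[ok, , drop = FALSE]) > 0
  out
}
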
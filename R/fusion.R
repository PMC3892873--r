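#' Rank-weighted mean of module risks
#'
#' Diminishing-weight fusion: the module risks are sorted in descending
#' order and averaged with geometrically decaying rank weights,
#' `p_overall = [p_(1) (1 - beta) + sum_{i>=2} p_(i) (beta^{i-1} - beta^i)]
#' / (1 - beta^n)`. At `beta = 0` this is exactly the maximum risk; as
#' `beta` approaches 1 it approaches the arithmetic mean; at `beta = 0.5`
#' the normalized weights are (1/2, 1/4, 1/8, ...) / (1 - 2^-n).
#'
#' @param risks Numeric vector of module risks (disabled modules enter as
#'   0), or a one-row risk tibble from [clip_risk_vector()].
#' @param beta Diminishing-weight parameter in `[0, 1)`.
#' @return The overall risk (scalar in `[0, 1]`).
#' @export
#' @examples
#' weighted_mean_risk(c(0.8, 0.2), beta = 0.5)  # 0.6
weighted_mean_risk <- function(risks, beta) {
  if (is.data.frame(risks)) risks <- as.numeric(risk_matrix(risks)[1, ])
  if (beta < 0 || beta >= 1) stop("beta must lie in [0, 1)")
  p <- sort(risks, decreasing = TRUE)
  n <- length(p)
  i <- seq_len(n)
  # beta^(i-1) - beta^i, with 0^0 = 1 at beta = 0
  w <- beta^(i - 1) * (1 - beta)
  sum(p * w) / (1 - beta^n)
}

#' Alarm decision by thresholding
#'
#' Strict threshold on the overall risk: an alarm is triggered only when
#' `overall > T`; an exact tie does not alarm.
#'
#' @param overall Overall risk(s).
#' @param T Alarm threshold in (0, 1), default 0.5.
#' @return Logical.
#' @export
alarm <- function(overall, T = 0.5) {
  if (T <= 0 || T >= 1) stop("T must lie in (0, 1)")
  overall > T
}

wmean_fit_error <- function(R, p_gt, beta) {
  mean(abs(apply(R, 1, weighted_mean_risk, beta = beta) - p_gt))
}

#' Fit the diminishing-weight parameter
#'
#' Recursive 1-D grid search for the `beta` minimizing the mean absolute
#' difference between the rank-weighted overall risk and the ground-truth
#' risks: a coarse grid over \[0, 0.99\] with step 0.01, refined twice
#' around the incumbent with the step divided by 10 each level.
#' Deterministic.
#'
#' @param risks A risk tibble from [assess_clips()] (with `p_gt` filled) or
#'   a numeric matrix of risk vectors.
#' @param p_gt Ground-truth risks (taken from `risks$p_gt` when omitted).
#' @return A list with `beta` and `fit_error`, of class `wmean_fusion`
#'   together with the alarm threshold `T`.
#' @export
fit_beta <- function(risks, p_gt = NULL, T = 0.5) {
  R <- if (is.data.frame(risks)) risk_matrix(risks) else as.matrix(risks)
  if (is.null(p_gt)) {
    stopifnot(is.data.frame(risks), "p_gt" %in% names(risks))
    p_gt <- risks$p_gt
  }
  if (nrow(R) < 2) stop("need at least 2 training clips")

  step <- 0.01
  grid <- seq(0, 0.99, by = step)
  err <- vapply(grid, function(b) wmean_fit_error(R, p_gt, b), numeric(1))
  best <- grid[which.min(err)]
  for (level in 1:2) {
    lo <- max(0, best - step)
    hi <- min(0.99, best + step)
    step <- step / 10
    grid <- seq(lo, hi, by = step)
    err <- vapply(grid, function(b) wmean_fit_error(R, p_gt, b), numeric(1))
    best <- grid[which.min(err)]
  }
  structure(list(scheme = "weighted_mean", beta = best,
                 fit_error = min(err), T = T),
            class = c("wmean_fusion", "fusion_model"))
}

#' @export
print.wmean_fusion <- function(x, ...) {
  cat(sprintf("<wmean_fusion> beta = %.3f (fit error %.4f), alarm T = %g\n",
              x$beta, x$fit_error, x$T))
  invisible(x)
}

rbf_kernel <- function(U, V, gamma) {
  d2 <- outer(rowSums(U^2), rowSums(V^2), "+") - 2 * tcrossprod(U, V)
  exp(-gamma * pmax(d2, 0))
}

svm_cv_accuracy <- function(X, y, cost, gamma, fold_id) {
  correct <- 0L
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    fit <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr], levels = c(1, -1)),
                      scale = FALSE, kernel = "radial", gamma = gamma,
                      cost = cost)
    pred <- stats::predict(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(pred == factor(y[!tr], levels = c(1, -1)))
  }
  correct / length(y)
}

#' Train the SVM fusion classifier
#'
#' RBF-kernel SVM on the 8-dimensional clip risk vectors, with alarm labels
#' obtained by thresholding the ground-truth risks at `T`. The penalty `C`
#' and kernel width `gamma` are selected by a recursive 2-D grid search
#' maximizing stratified k-fold cross-validation accuracy: a coarse
#' LIBSVM-style lattice `C in 2^(-5..15)`, `gamma in 2^(-15..3)` with step
#' `2^2`, refined once around the incumbent with step `2^0.5`.
#'
#' @param risks A risk tibble from [assess_clips()] or a numeric matrix.
#' @param p_gt Ground-truth risks (taken from `risks$p_gt` when omitted).
#' @param T Alarm threshold on `p_gt` (default 0.5).
#' @param folds CV folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return A fitted fusion model of class `svm_fusion`.
#' @export
train_svm_fusion <- function(risks, p_gt = NULL, T = 0.5, folds = 5,
                             seed = 1) {
  X <- if (is.data.frame(risks)) risk_matrix(risks) else as.matrix(risks)
  if (is.null(p_gt)) {
    stopifnot(is.data.frame(risks), "p_gt" %in% names(risks))
    p_gt <- risks$p_gt
  }
  y <- ifelse(p_gt > T, 1, -1)
  if (length(unique(y)) < 2) {
    stop("both alarm classes must be present after thresholding")
  }
  fold_id <- make_folds(y, folds, seed)

  search <- function(log2C, log2g) {
    grid <- expand.grid(log2C = log2C, log2g = log2g)
    grid$acc <- mapply(function(lc, lg) {
      svm_cv_accuracy(X, y, 2^lc, 2^lg, fold_id)
    }, grid$log2C, grid$log2g)
    grid[which.max(grid$acc), ]  # ties: first (lowest C, then gamma) wins
  }
  coarse <- search(seq(-5, 15, by = 2), seq(-15, 3, by = 2))
  fine <- search(seq(coarse$log2C - 2, coarse$log2C + 2, by = 0.5),
                 seq(coarse$log2g - 2, coarse$log2g + 2, by = 0.5))
  cost <- 2^fine$log2C
  gamma <- 2^fine$log2g

  fit <- e1071::svm(X, factor(y, levels = c(1, -1)), scale = FALSE,
                    kernel = "radial", gamma = gamma, cost = cost)
  dv <- attr(stats::predict(fit, X, decision.values = TRUE),
             "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  sgn <- if (identical(first, "1")) 1 else -1

  structure(
    list(scheme = "svm", cost = cost, gamma = gamma, T = T,
         cv_accuracy = fine$acc,
         sv = unname(fit$SV), coefs = as.vector(fit$coefs) * sgn,
         rho = fit$rho * sgn),
    class = c("svm_fusion", "fusion_model")
  )
}

#' @export
print.svm_fusion <- function(x, ...) {
  cat(sprintf(
    "<svm_fusion> RBF kernel, C = %g, gamma = %g (CV accuracy %.3f), %d support vectors\n",
    x$cost, x$gamma, x$cv_accuracy, nrow(x$sv)))
  invisible(x)
}

fusion_decision <- function(model, X) {
  as.vector(rbf_kernel(X, model$sv, model$gamma) %*% model$coefs) - model$rho
}

#' Overall risk / alarm prediction from a fusion model
#'
#' For the weighted-mean scheme, the overall risk is the rank-weighted mean
#' at the fitted `beta` and the alarm thresholds it at `T`; for the SVM
#' scheme, the alarm follows the sign of the decision function.
#'
#' @param model A [fit_beta()] or [train_svm_fusion()] fit.
#' @param risks A risk tibble (any number of rows) or numeric matrix /
#'   vector of 8 module risks.
#' @return A tibble with columns `overall` (NA for the SVM scheme, which
#'   yields no calibrated risk) and `alarm` (logical).
#' @export
predict_alarm <- function(model, risks) {
  X <- if (is.data.frame(risks)) risk_matrix(risks)
       else if (is.null(dim(risks))) matrix(risks, nrow = 1)
       else as.matrix(risks)
  if (inherits(model, "wmean_fusion")) {
    overall <- apply(X, 1, weighted_mean_risk, beta = model$beta)
    tibble::tibble(overall = overall, alarm = alarm(overall, model$T))
  } else if (inherits(model, "svm_fusion")) {
    d <- fusion_decision(model, X)
    tibble::tibble(overall = NA_real_, alarm = d > 0)
  } else {
    stop("unknown fusion model")
  }
}
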
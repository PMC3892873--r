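#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a posture model
#'
#' One row per support vector: its dual coefficient (alpha_j y_j on the
#' oriented decision scale).
#'
#' @param x A `posture_model`.
#' @param ... Unused.
#' @return A tibble with `sv_index` and `coef`.
#' @method tidy posture_model
#' @export
tidy.posture_model <- function(x, ...) {
  tibble::tibble(sv_index = seq_along(x$coefs), coef = x$coefs)
}

#' @rdname tidy.posture_model
#' @method glance posture_model
#' @export
glance.posture_model <- function(x, ...) {
  tibble::tibble(n_support = nrow(x$sv), kernel_degree = x$kernel_degree,
                 cost = x$cost, n_features = length(x$feature_mask),
                 bias = x$rho)
}

#' Tidy a fusion model
#'
#' The model's parameters in long form (`term`, `estimate`).
#'
#' @param x A fusion model ([fit_beta()] or [train_svm_fusion()]).
#' @param ... Unused.
#' @method tidy fusion_model
#' @export
tidy.fusion_model <- function(x, ...) {
  if (inherits(x, "wmean_fusion")) {
    tibble::tibble(term = c("beta", "T"), estimate = c(x$beta, x$T))
  } else {
    tibble::tibble(term = c("cost", "gamma", "T"),
                   estimate = c(x$cost, x$gamma, x$T))
  }
}

#' @rdname tidy.fusion_model
#' @method glance fusion_model
#' @export
glance.fusion_model <- function(x, ...) {
  if (inherits(x, "wmean_fusion")) {
    tibble::tibble(scheme = "weighted_mean", fit_error = x$fit_error)
  } else {
    tibble::tibble(scheme = "svm", cv_accuracy = x$cv_accuracy,
                   n_support = nrow(x$sv))
  }
}

#' Tidy a floor plane
#'
#' @param x A [floor_plane()].
#' @param ... Unused.
#' @return A one-row tibble with the plane coefficients, tilt cosine and
#'   inlier count.
#' @method tidy floor_plane
#' @export
tidy.floor_plane <- function(x, ...) {
  tibble::tibble(A = x$A, B = x$B, C = x$C, D = x$D,
                 tilt_cos = x$tilt_cos, inlier_count = x$inlier_count)
}
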
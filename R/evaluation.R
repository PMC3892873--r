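#' Confusion matrix of alarm decisions
#'
#' Clips with ground-truth risk strictly above `T` are the positive
#' (fall-prone) samples; alarms are the predictions. Counts are exact
#' integers.
#'
#' @param p_gt Ground-truth risks.
#' @param alarms Logical alarm decisions, same length.
#' @param T Positive-class threshold on the ground truth (default 0.5).
#' @return A one-row tibble with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(p_gt, alarms, T = 0.5) {
  if (length(p_gt) != length(alarms)) stop("length mismatch")
  pos <- p_gt > T
  tibble::tibble(
    TP = sum(pos & alarms), FP = sum(!pos & alarms),
    FN = sum(pos & !alarms), TN = sum(!pos & !alarms)
  )
}

#' Accuracy, TPR and FPR of a confusion matrix
#'
#' Exact integer arithmetic reported as percentages: accuracy
#' `(TP + TN) / (P + N)`, true-positive rate `TP / P`, false-positive rate
#' `FP / N`. A rate whose denominator is zero is reported as NA with a
#' warning.
#'
#' @param cm A data frame (or one-row tibble) with columns `TP`, `FP`,
#'   `FN`, `TN`.
#' @return A one-row tibble with `accuracy`, `tpr`, `fpr` (percent).
#' @export
#' @examples
#' metrics(data.frame(TP = 47, FP = 3, FN = 5, TN = 45))  # 92% accurate
metrics <- function(cm) {
  stopifnot(all(c("TP", "FP", "FN", "TN") %in% names(cm)))
  P <- cm$TP + cm$FN
  N <- cm$FP + cm$TN
  if (P == 0 || N == 0) warning("a rate denominator is zero; rate undefined")
  tibble::tibble(
    accuracy = 100 * (cm$TP + cm$TN) / (P + N),
    tpr = if (P > 0) 100 * cm$TP / P else NA_real_,
    fpr = if (N > 0) 100 * cm$FP / N else NA_real_
  )
}

#' ROC curve of overall risks
#'
#' Sweeps the alarm threshold over `[0, 1]` (strict alarms, `overall > T`)
#' and reports the (FPR, TPR) staircase, including the (0, 0) and (1, 1)
#' endpoints. The area under the curve is computed by the trapezoid rule;
#' `auc_mw` is the equivalent Mann-Whitney statistic (probability that a
#' random positive outscores a random negative, ties counting half), kept
#' as an internal consistency check.
#'
#' @param p_gt Ground-truth risks.
#' @param overall Overall risk scores, same length.
#' @param thresholds Thresholds to sweep (default: all distinct scores plus
#'   the ends), sorted increasingly.
#' @param T Ground-truth positive threshold (default 0.5).
#' @return A tibble of class `roc_curve` with columns `threshold`, `fpr`,
#'   `tpr` (proportions in `[0, 1]`), and attributes `auc` and `auc_mw`.
#' @export
roc <- function(p_gt, overall, thresholds = NULL, T = 0.5) {
  if (length(p_gt) != length(overall)) stop("length mismatch")
  pos <- p_gt > T
  P <- sum(pos)
  N <- sum(!pos)
  if (P == 0 || N == 0) stop("need both positive and negative samples")
  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(-Inf, overall, Inf)))
  } else {
    thresholds <- sort(thresholds)
  }
  pts <- purrr::map_dfr(thresholds, function(th) {
    al <- overall > th
    tibble::tibble(threshold = th,
                   fpr = sum(!pos & al) / N,
                   tpr = sum(pos & al) / P)
  })
  pts <- dplyr::arrange(pts, .data$fpr, .data$tpr)
  pts <- dplyr::bind_rows(tibble::tibble(threshold = Inf, fpr = 0, tpr = 0),
                          pts,
                          tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  pts <- dplyr::distinct(pts, .data$fpr, .data$tpr, .keep_all = TRUE)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  # Mann-Whitney form: P(score_pos > score_neg) + P(tie) / 2
  r <- rank(overall)
  auc_mw <- (sum(r[pos]) - P * (P + 1) / 2) / (P * N)
  structure(pts, class = c("roc_curve", class(pts)),
            auc = auc, auc_mw = auc_mw)
}

#' Area under a [roc()] curve
#'
#' @param curve A `roc_curve` object.
#' @return Trapezoid AUC in `[0, 1]`.
#' @export
roc_auc <- function(curve) attr(curve, "auc")

#' End-to-end evaluation of a fusion model on labeled risk vectors
#'
#' Predicts alarms with [predict_alarm()], counts the confusion matrix and
#' metrics against the ground truths, and (for the weighted-mean scheme)
#' attaches the ROC curve of the overall risks.
#'
#' @param model A fusion model.
#' @param risks A labeled risk tibble from [assess_clips()].
#' @param T Ground-truth positive threshold (default the model's `T`).
#' @return A list with `confusion`, `metrics`, `predictions`, and `roc`
#'   (NULL for the SVM scheme).
#' @export
evaluate_fusion <- function(model, risks, T = model$T) {
  pred <- predict_alarm(model, risks)
  cm <- confusion(risks$p_gt, pred$alarm, T = T)
  rc <- if (inherits(model, "wmean_fusion")) {
    roc(risks$p_gt, pred$overall, T = T)
  } else NULL
  list(confusion = cm, metrics = metrics(cm), predictions = pred, roc = rc)
}
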
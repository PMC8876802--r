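## Threshold-swept verification metrics. A sample is accepted as the target
## when its target probability strictly exceeds the threshold; FAR and FRR
## are swept over thresholds 0.00, 0.01, ..., 1.00 and the equal error rate
## is read off where they are closest.

#' Confusion counts at one decision threshold
#'
#' A sample is classified as target iff `p_target > threshold` (strict).
#'
#' @param p_target target-class probabilities.
#' @param is_target logical truth, same length; both classes must occur.
#' @param threshold decision threshold in `[0, 1]`.
#' @return list with integer counts `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at_threshold <- function(p_target, is_target, threshold) {
  if (length(p_target) != length(is_target)) {
    stop_invalid("'p_target' and 'is_target' must have equal length")
  }
  if (!any(is_target) || all(is_target)) {
    stop_invalid("both classes must be present in 'is_target'")
  }
  pred <- p_target > threshold
  list(TP = sum(pred & is_target), FP = sum(pred & !is_target),
       TN = sum(!pred & !is_target), FN = sum(!pred & is_target))
}

#' False acceptance rate, FP / (FP + TN)
#' @param counts confusion counts from [confusion_at_threshold()].
#' @return rate in `[0, 1]`.
#' @export
far <- function(counts) {
  if (counts$FP + counts$TN == 0) {
    stop_invalid("FAR undefined: no non-target samples (FP + TN = 0)")
  }
  counts$FP / (counts$FP + counts$TN)
}

#' False rejection rate, FN / (FN + TP)
#' @param counts confusion counts from [confusion_at_threshold()].
#' @return rate in `[0, 1]`.
#' @export
frr <- function(counts) {
  if (counts$FN + counts$TP == 0) {
    stop_invalid("FRR undefined: no target samples (FN + TP = 0)")
  }
  counts$FN / (counts$FN + counts$TP)
}

#' FAR/FRR curve over the standard 101-threshold grid
#'
#' @inheritParams confusion_at_threshold
#' @param thresholds threshold grid; default 0 to 1 in steps of 0.01.
#' @return data.frame with columns `threshold`, `far`, `frr`.
#' @export
threshold_curve <- function(p_target, is_target,
                            thresholds = seq(0, 1, by = 0.01)) {
  if (length(p_target) != length(is_target)) {
    stop_invalid("'p_target' and 'is_target' must have equal length")
  }
  if (!any(is_target) || all(is_target)) {
    stop_invalid("both classes must be present in 'is_target'")
  }
  n_tar <- sum(is_target)
  n_non <- sum(!is_target)
  fars <- vapply(thresholds, function(t) sum(p_target[!is_target] > t) / n_non,
                 numeric(1))
  frrs <- vapply(thresholds, function(t) sum(p_target[is_target] <= t) / n_tar,
                 numeric(1))
  data.frame(threshold = thresholds, far = fars, frr = frrs)
}

#' Equal error rate and verification accuracy from a threshold curve
#'
#' Selects the threshold minimizing `|FAR - FRR|` (ties broken toward the
#' smallest threshold); there `EER = (FAR + FRR) / 2` and verification
#' accuracy is `1 - EER`.
#'
#' @param curve data.frame from [threshold_curve()].
#' @return list of class `eer_result` with `eer`, `threshold`, `far`,
#'   `frr`, `accuracy`.
#' @export
eer <- function(curve) {
  if (!is.data.frame(curve) || nrow(curve) == 0) {
    stop_invalid("'curve' must be a non-empty threshold curve")
  }
  i <- which.min(abs(curve$far - curve$frr))
  e <- (curve$far[i] + curve$frr[i]) / 2
  structure(list(eer = e, threshold = curve$threshold[i],
                 far = curve$far[i], frr = curve$frr[i], accuracy = 1 - e),
            class = "eer_result")
}

#' @export
print.eer_result <- function(x, ...) {
  cat(sprintf("EER %.4f at threshold %.2f (FAR %.4f, FRR %.4f); accuracy %.4f\n",
              x$eer, x$threshold, x$far, x$frr, x$accuracy))
  invisible(x)
}

#' EER-based verification accuracy of scores against truth
#'
#' @inheritParams confusion_at_threshold
#' @return accuracy in `[0, 1]` (`1 - EER`).
#' @export
verification_accuracy <- function(p_target, is_target) {
  eer(threshold_curve(p_target, is_target))$accuracy
}

#' Cross-period accuracy of a model ensemble
#'
#' Scores the test samples with every model in the ensemble, computes each
#' model's EER-based accuracy, and averages: the ensemble mean is the final
#' verification accuracy.
#'
#' @param ensemble a `verifier_ensemble` (or list of `voice_verifier`s).
#' @param x_test feature matrix, 60 columns.
#' @param is_target logical truth per row.
#' @return list with `per_model` (data.frame: `model`, `seed`, `eer`,
#'   `threshold`, `accuracy`) and `mean_accuracy`.
#' @export
evaluate_cross_period <- function(ensemble, x_test, is_target) {
  if (length(ensemble) == 0) stop_invalid("'ensemble' must be non-empty")
  rows <- lapply(seq_along(ensemble), function(i) {
    p <- predict(ensemble[[i]], x_test)$p_target
    r <- eer(threshold_curve(p, is_target))
    data.frame(model = i, seed = ensemble[[i]]$seed, eer = r$eer,
               threshold = r$threshold, accuracy = r$accuracy)
  })
  per_model <- do.call(rbind, rows)
  list(per_model = per_model, mean_accuracy = mean(per_model$accuracy))
}
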
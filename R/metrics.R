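# Binarization, ROC/AUC, and evaluation summaries.

#' Threshold probabilities into 0/1 labels
#'
#' Label 1 iff `probability > threshold` (strict: a probability exactly at
#' the threshold maps to 0).
#'
#' @param probabilities numeric vector in `[0, 1]`
#' @param threshold decision threshold (default 0.5)
#' @return integer 0/1 vector
#' @export
binarize <- function(probabilities, threshold = 0.5) {
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]")
  }
  as.integer(probabilities > threshold)
}

#' ROC curve points
#'
#' Computes the ROC curve over all distinct score thresholds, with tied
#' scores collapsed (so the trapezoidal area equals the Mann-Whitney
#' average-rank statistic). Points run from (0, 0) to (1, 1) and are
#' nondecreasing in both coordinates.
#'
#' @param scores numeric scores, higher = more likely positive
#' @param labels 0/1 labels
#' @return data.frame with columns `fpr`, `tpr`
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # cumulative counts at each distinct threshold
  last <- cumsum(table(factor(s, levels = unique(s))))
  tp <- cumsum(l)[last]
  fp <- (seq_along(l) - cumsum(l))[last]
  data.frame(fpr = c(0, fp / n0, 1), tpr = c(0, tp / n1, 1))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of [roc_points()]; with the average-rank tie
#' convention this equals the Mann-Whitney U statistic divided by
#' `n1 * n0`.
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`
#' @export
auc_score <- function(scores, labels) {
  r <- roc_points(scores, labels)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}

#' Evaluate scores against labels
#'
#' Accuracy after strict thresholding plus the ROC curve and AUC. If only
#' one class is present the accuracy is still returned and `auc` /
#' `roc_points` are `NA` with a warning.
#'
#' @param scores predicted probabilities in `[0, 1]`
#' @param labels 0/1 ground-truth labels
#' @param threshold decision threshold (default 0.5)
#' @return list with `accuracy`, `roc`, `auc`, `n`
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  acc <- mean(binarize(scores, threshold) == labels)
  if (length(unique(labels)) < 2L) {
    warning("single-class labels: AUC undefined")
    return(list(accuracy = acc, roc = NULL, auc = NA_real_,
                n = length(labels)))
  }
  list(accuracy = acc, roc = roc_points(scores, labels),
       auc = auc_score(scores, labels), n = length(labels))
}
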
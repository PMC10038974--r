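#' @title ROC analysis and threshold evaluation
#' @name classify
#' @description
#' ROC curves for predicting the genotype-defined PM phenotype from an
#' ln-scale marker, Youden-optimal threshold selection, DeLong confidence
#' intervals for the AUC, and confusion-matrix evaluation (sensitivity,
#' specificity, PPV, NPV, Matthews correlation coefficient) of a threshold
#' on any cohort. Markers may point either way: for the metabolic ratios low
#' values predict PM; for the solanidine concentration high values do.
NULL

# orient scores so that larger oriented score = more PM-like
.orient <- function(scores, direction) {
  direction <- match.arg(direction, c("low", "high"))
  if (direction == "low") -scores else scores
}

#' ROC curve for a PM-predicting marker
#'
#' Candidate thresholds are the midpoints between adjacent distinct score
#' values, plus -Inf/+Inf sentinels; predictions are inclusive
#' (`score <= t` for `direction = "low"`, `score >= t` for `"high"`). The
#' AUC is the trapezoidal area, which for this construction equals the
#' Mann-Whitney probability that a random PM scores more PM-like than a
#' random non-PM (ties counted 1/2).
#'
#' @param scores Numeric marker values (ln scale in this pipeline).
#' @param labels Logical (or 0/1): `TRUE` = PM.
#' @param direction `"low"` if low scores predict PM, `"high"` otherwise.
#' @param marker Optional marker name carried in the result.
#' @return A list of class `"roc_result"`: `marker`, `direction`, `points`
#'   (data.frame threshold/fpr/tpr/sensitivity/specificity, ordered by
#'   increasing fpr) and `auc`.
#' @export
roc_curve <- function(scores, labels, direction = c("low", "high"),
                      marker = NULL) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (!any(labels) || all(labels)) {
    stop("ROC needs both PM and non-PM observations")
  }
  s <- .orient(scores, direction)
  u <- sort(unique(s))
  cand_o <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  # oriented prediction: positive iff oriented score >= oriented threshold
  tpr <- vapply(cand_o, function(t) mean(s[labels] >= t), numeric(1))
  fpr <- vapply(cand_o, function(t) mean(s[!labels] >= t), numeric(1))
  thr <- if (direction == "low") -cand_o else cand_o
  ord <- order(fpr, tpr)
  points <- data.frame(threshold = thr[ord], fpr = fpr[ord], tpr = tpr[ord],
                       sensitivity = tpr[ord], specificity = 1 - fpr[ord])
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  structure(list(marker = marker, direction = direction, points = points,
                 auc = auc),
            class = "roc_result")
}

#' Youden-optimal threshold of a ROC curve
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the candidate
#' thresholds. Ties are broken in favour of higher specificity (a false PM
#' call is the clinically costly error), then of the threshold calling fewer
#' patients PM. When the best J is 0 the marker carries no signal and the
#' result is flagged `degenerate`.
#'
#' @param roc A `"roc_result"`.
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden`,
#'   `degenerate`.
#' @export
optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  p <- roc$points
  j <- p$sensitivity + p$specificity - 1
  # "fewer PM calls" = larger threshold for direction low, smaller for high;
  # on the fpr-ordered points that is always the earlier row, so rank by row
  # order after specificity.
  best <- order(-j, -p$specificity)[1]
  list(threshold = p$threshold[best],
       sensitivity = p$sensitivity[best],
       specificity = p$specificity[best],
       youden = j[best],
       degenerate = j[best] <= 0)
}

#' DeLong 95% confidence interval and test for an AUC
#'
#' Placement-based DeLong variance with a normal-approximation interval
#' clipped to \[0, 1\], and a one-sided z-test of AUC > 0.5.
#'
#' @inheritParams roc_curve
#' @param conf Confidence level (default 0.95).
#' @return List with `auc`, `ci` (length-2 vector), `se`, `p_value`
#'   (one-sided vs 0.5).
#' @export
auc_ci <- function(scores, labels, direction = c("low", "high"), conf = 0.95) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  s <- .orient(scores, direction)
  x <- s[labels]   # PM, expected larger oriented scores
  y <- s[!labels]
  m <- length(x); n <- length(y)
  if (m < 2 || n < 2) stop("DeLong CI needs at least 2 observations per class")
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(a) mean(psi(a, y)), numeric(1))
  v01 <- vapply(y, function(b) mean(psi(x, b)), numeric(1))
  auc <- mean(v10)
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  p <- if (se == 0) {
    if (auc > 0.5) 0 else 1
  } else {
    stats::pnorm((auc - 0.5) / se, lower.tail = FALSE)
  }
  list(auc = auc, ci = ci, se = se, p_value = p)
}

#' Evaluate a fixed threshold on a cohort
#'
#' @inheritParams roc_curve
#' @param threshold Finite decision threshold on the score scale.
#' @return A list of class `"threshold_evaluation"`: counts `tp`, `fp`,
#'   `fn`, `tn` and metrics `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `mcc` (set to 0 and flagged `mcc_degenerate` when its denominator
#'   vanishes); undefined proportions (empty denominator) are `NaN`.
#' @export
#' @examples
#' evaluate_threshold(c(-8, -6, -1, 0), c(TRUE, TRUE, FALSE, FALSE),
#'                    threshold = -4.28, direction = "low")
evaluate_threshold <- function(scores, labels, threshold,
                               direction = c("low", "high")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(threshold))
  labels <- as.logical(labels)
  pred <- if (direction == "low") scores <= threshold else scores >= threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc_degenerate <- denom == 0
  mcc <- if (mcc_degenerate) 0 else (tp * tn - fp * fn) / denom
  structure(list(
    threshold = threshold, direction = direction,
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = tp / (tp + fp), npv = tn / (tn + fn),
    mcc = mcc, mcc_degenerate = mcc_degenerate
  ), class = "threshold_evaluation")
}
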
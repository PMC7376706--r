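#' Empirical ROC curve under the strict-greater positivity rule
#'
#' Builds the full receiver operating characteristic trace for a continuous
#' marker against a binary surgical outcome. A patient is called
#' test-positive at threshold `t` iff their marker value is strictly greater
#' than `t`; values equal to the threshold are test-negative, matching the
#' category coding used for the combined scores (category 1 when `<=` the
#' cutoff). Candidate thresholds are the midpoints between consecutive
#' distinct pooled values, plus `-Inf` and `+Inf` sentinels, so every
#' achievable operating point appears exactly once.
#'
#' @param values numeric marker values, one per patient; must be finite.
#' @param labels outcome labels; anything accepted by the positive-class
#'   normalizer (`"suboptimal"`/`"optimal"` strings, a factor, or a logical
#'   that is `TRUE` for the positive class).
#' @param positive label treated as the positive class (default
#'   `"suboptimal"`, the higher-marker group).
#' @return an object of class `"roc_curve"`: a data frame with columns
#'   `threshold`, `fpr`, `tpr` ordered by increasing threshold (so `fpr` and
#'   `tpr` are non-increasing), with attributes `n_pos` and `n_neg`.
#' @seealso [auc_trapezoid()], [youden_optimal_cutoff()]
#' @examples
#' rc <- roc_curve(c(3, 4, 5, 1, 2, 3), rep(c("suboptimal", "optimal"), each = 3))
#' auc_trapezoid(rc)
#' @export
roc_curve <- function(values, labels, positive = "suboptimal") {
  stop_if_not_finite(values, "marker values")
  is_pos <- as_positive(labels, positive)
  if (length(values) != length(is_pos))
    stop("values and labels must have the same length", call. = FALSE)
  check_two_classes(is_pos)

  pos <- values[is_pos]
  neg <- values[!is_pos]
  v <- sort(unique(values))
  mids <- if (length(v) > 1) (v[-length(v)] + v[-1]) / 2 else numeric(0)
  thr <- c(-Inf, mids, Inf)

  tpr <- vapply(thr, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg > t), numeric(1))

  out <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  attr(out, "n_pos") <- length(pos)
  attr(out, "n_neg") <- length(neg)
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under the ROC curve by trapezoidal integration
#'
#' @param curve a [roc_curve()] object.
#' @return the AUC as a fraction in \[0, 1\].
#' @export
auc_trapezoid <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  # fpr decreases with threshold; integrate over the (fpr, tpr) trace
  f <- curve$fpr
  t <- curve$tpr
  k <- seq_len(nrow(curve) - 1)
  sum((f[k] - f[k + 1]) * (t[k] + t[k + 1]) / 2)
}

#' AUC by tie-corrected pair counting (Mann-Whitney route)
#'
#' The probability that a randomly chosen positive-class patient has a
#' higher marker value than a randomly chosen negative-class patient, ties
#' counted one half: `AUC = U / (n_pos * n_neg)`. Agrees with
#' [auc_trapezoid()] to machine precision on the same data; the two routes
#' are kept separate so each can check the other.
#'
#' @inheritParams roc_curve
#' @return the AUC as a fraction in \[0, 1\].
#' @export
auc_mannwhitney <- function(values, labels, positive = "suboptimal") {
  stop_if_not_finite(values, "marker values")
  is_pos <- as_positive(labels, positive)
  check_two_classes(is_pos)
  n1 <- sum(is_pos)
  n2 <- sum(!is_pos)
  r <- rank(values)                       # midranks handle ties at 1/2
  u <- sum(r[is_pos]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Youden-optimal cutoff point
#'
#' Scans every candidate threshold of a ROC curve and returns the one
#' maximizing Youden's J = sensitivity + specificity - 1. Ties are broken
#' toward the smallest cutoff, i.e. toward higher sensitivity -- the
#' conservative choice when a positive call routes a patient toward
#' additional pre-surgical work-up.
#'
#' @param curve a [roc_curve()] object.
#' @return an object of class `"cutoff_result"`: a list with elements
#'   `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sens <- curve$tpr
  spec <- 1 - curve$fpr
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  i <- best[which.min(curve$threshold[best])]
  structure(
    list(cutoff = curve$threshold[i], sensitivity = sens[i],
         specificity = spec[i], youden_j = j[i]),
    class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Youden-optimal cutoff: %g (J = %.4f)\n", x$cutoff, x$youden_j))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Closed-form Wald interval using the Hanley-McNeil standard error
#' `SE^2 = [A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)] / (n_pos n_neg)`
#' with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`, clipped to \[0, 1\]. This
#' exponential-model approximation needs only the AUC and the group sizes,
#' not the raw data.
#'
#' @param auc AUC as a fraction in \[0, 1\].
#' @param n_pos,n_neg positive/negative class sizes (> 0).
#' @param level confidence level in (0, 1); default 0.95.
#' @return named numeric vector `c(lo = , hi = )`.
#' @references Hanley JA, McNeil BJ (1982) Radiology 143:29-36.
#' @examples
#' auc_ci_hanley_mcneil(0.767, 56, 53)  # c(0.678, 0.856) to 3 decimals
#' @export
auc_ci_hanley_mcneil <- function(auc, n_pos, n_neg, level = 0.95) {
  stopifnot(auc >= 0, auc <= 1, n_pos > 0, n_neg > 0, level > 0, level < 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lo = max(0, auc - z * se), hi = min(1, auc + z * se))
}

#' Number of patients predicted correctly implied by an AUC
#'
#' The figure-legend arithmetic `round(AUC * n_total)`, half-up.
#'
#' @param auc AUC fraction in \[0, 1\].
#' @param n_total total number of patients (> 0).
#' @return integer count.
#' @examples
#' correctly_predicted(0.767, 109)  # 84
#' @export
correctly_predicted <- function(auc, n_total) {
  stopifnot(auc >= 0, auc <= 1, n_total > 0)
  as.integer(round_half_up(auc * n_total))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, n_pos = %d, n_neg = %d\n",
              nrow(x), attr(x, "n_pos"), attr(x, "n_neg")))
  cat(sprintf("AUC (trapezoid) = %.4f\n", auc_trapezoid(x)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, add_diagonal = TRUE, ...) {
  plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "Sensitivity", ...)
  if (add_diagonal) graphics::abline(0, 1, lty = 2, col = "grey60")
  invisible(x)
}
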
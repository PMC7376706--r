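#' Confusion matrix at a fixed cutoff
#'
#' Cross-tabulates predicted against true class at a marker cutoff. A
#' patient is test-positive iff their value is strictly greater than the
#' cutoff (a value exactly equal to the cutoff is test-negative, the same
#' boundary rule as the `{1, 2}` category coding).
#'
#' @inheritParams roc_curve
#' @param cutoff decision threshold (finite).
#' @return object of class `"confusion_matrix"`: list with integer fields
#'   `tp`, `fn`, `tn`, `fp` and derived `n_pos`, `n_neg`.
#' @export
confusion_at_cutoff <- function(values, labels, cutoff, positive = "suboptimal") {
  stop_if_not_finite(values, "marker values")
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff))
    stop("cutoff must be a single non-missing number", call. = FALSE)
  is_pos <- as_positive(labels, positive)
  if (length(values) != length(is_pos))
    stop("values and labels must have the same length", call. = FALSE)
  check_two_classes(is_pos)
  test_pos <- values > cutoff
  confusion_matrix(tp = sum(is_pos & test_pos),
                   fn = sum(is_pos & !test_pos),
                   tn = sum(!is_pos & !test_pos),
                   fp = sum(!is_pos & test_pos))
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fn,tn,fp non-negative integer counts; positive class =
#'   suboptimal cytoreduction, test-positive = above cutoff.
#' @return object of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(tp, fn, tn, fp) {
  cnt <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 tn = as.integer(tn), fp = as.integer(fp),
                 n_pos = as.integer(tp + fn), n_neg = as.integer(tn + fp)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              truth = c("suboptimal", "optimal")))
  print(m)
  invisible(x)
}

#' Diagnostic accuracy panel from a confusion matrix
#'
#' Sensitivity, specificity, accuracy, positive and negative predictive
#' value as exact ratios of the integer counts. A predictive value whose
#' denominator is zero (no positive calls, or no negative calls) is
#' reported as `NA` ("undefined"), never silently as 0 or 1.
#'
#' @param cm a [confusion_matrix()] object with both classes present.
#' @return object of class `"diagnostic_summary"`: list with fields
#'   `sensitivity`, `specificity`, `accuracy`, `ppv`, `npv` (fractions) and
#'   the source `confusion`.
#' @examples
#' summarize_confusion(confusion_matrix(tp = 41, fn = 15, tn = 39, fp = 14))
#' @export
summarize_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$n_pos == 0 || cm$n_neg == 0)
    stop("both classes must be present to summarize", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(sensitivity = cm$tp / cm$n_pos,
         specificity = cm$tn / cm$n_neg,
         accuracy = (cm$tp + cm$tn) / (cm$n_pos + cm$n_neg),
         ppv = ratio(cm$tp, cm$tp + cm$fp),
         npv = ratio(cm$tn, cm$tn + cm$fn),
         confusion = cm),
    class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", as_percent(v))
  cat(sprintf(
    "sensitivity %s  specificity %s  accuracy %s  PPV %s  NPV %s\n",
    pct(x$sensitivity), pct(x$specificity), pct(x$accuracy),
    pct(x$ppv), pct(x$npv)))
  invisible(x)
}

#' @export
as.data.frame.diagnostic_summary <- function(x, ...) {
  data.frame(sensitivity = x$sensitivity, specificity = x$specificity,
             accuracy = x$accuracy, ppv = x$ppv, npv = x$npv)
}

#' Reconstruct integer confusion counts from published rates
#'
#' Inverts a printed (sensitivity, specificity) pair back to the integer
#' 2x2 counts given the group sizes: `tp` is the integer in `[0, n_pos]`
#' whose ratio is nearest the stated sensitivity (ties resolved to the
#' larger count), `tn` analogously for specificity. Because a rate printed
#' to 3 significant figures pins the count uniquely for groups of ~50, this
#' recovers the exact table behind published accuracy and predictive
#' values.
#'
#' @param sens,spec published rates as fractions in \[0, 1\].
#' @param n_pos,n_neg group sizes (> 0).
#' @return a [confusion_matrix()] object; achieved rates are within
#'   `0.5/n` of the inputs.
#' @examples
#' reconstruct_confusion(0.732, 0.736, 56, 53)  # tp = 41, tn = 39
#' @export
reconstruct_confusion <- function(sens, spec, n_pos, n_neg) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1, n_pos > 0, n_neg > 0)
  nearest <- function(rate, n) {
    k <- 0:n
    d <- abs(k / n - rate)
    max(k[d <= min(d) + 1e-12])      # ties -> larger count
  }
  tp <- nearest(sens, n_pos)
  tn <- nearest(spec, n_neg)
  confusion_matrix(tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn)
}
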
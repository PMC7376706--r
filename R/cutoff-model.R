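#' Fit a single-marker (or panel-score) cutoff model
#'
#' The workhorse of the package: given one continuous marker and the
#' surgical outcome, builds the empirical ROC curve, selects the
#' Youden-optimal cutoff point (or evaluates a supplied, pinned cutoff),
#' and assembles the full diagnostic report for that marker -- confusion
#' matrix and rate panel at the cutoff, AUC with Hanley-McNeil confidence
#' interval, the implied number of correctly predicted patients, group
#' summary statistics, and the two between-group tests (Mann-Whitney U and
#' Welch t).
#'
#' @param x marker values (default method) or a formula `group ~ marker`.
#' @param ... passed between methods.
#' @return object of class `"roc_cutoff"`; see Details for components.
#'   Methods: [print.roc_cutoff()], [summary.roc_cutoff()],
#'   [coef.roc_cutoff()], [predict.roc_cutoff()], [plot.roc_cutoff()].
#' @details The returned list carries `marker`, `curve` ([roc_curve()]),
#'   `auc`, `auc_ci`, `cutoff`, `youden_j`, `diagnostics`
#'   ([summarize_confusion()] output), `correct_n`, `group_summary` (one
#'   row per group: n, mean, sd, median, min, max), `tests` (list with
#'   `mann_whitney` and `t_welch`), and `n_pos`/`n_neg`.
#' @examples
#' coh <- generate_cohort(default_study_params(), seed = 1)
#' fit <- roc_cutoff(group ~ ca125, data = coh)
#' coef(fit)
#' @export
roc_cutoff <- function(x, ...) UseMethod("roc_cutoff")

#' @rdname roc_cutoff
#' @param labels outcome labels (see [roc_curve()]).
#' @param positive positive-class label (default `"suboptimal"`).
#' @param cutoff optional pinned cutoff; when `NULL` (default) the
#'   Youden-optimal cutoff is selected from the ROC curve.
#' @param conf_level confidence level for the AUC interval.
#' @param marker display name for the marker.
#' @export
roc_cutoff.default <- function(x, labels, positive = "suboptimal",
                               cutoff = NULL, conf_level = 0.95,
                               marker = "marker", ...) {
  curve <- roc_curve(x, labels, positive)
  n_pos <- attr(curve, "n_pos")
  n_neg <- attr(curve, "n_neg")
  auc <- auc_trapezoid(curve)
  ci <- auc_ci_hanley_mcneil(auc, n_pos, n_neg, conf_level)

  if (is.null(cutoff)) {
    cr <- youden_optimal_cutoff(curve)
    cutoff <- cr$cutoff
  }
  cm <- confusion_at_cutoff(x, labels, cutoff, positive)
  diag <- summarize_confusion(cm)

  is_pos <- as_positive(labels, positive)
  pos <- x[is_pos]; neg <- x[!is_pos]
  gs <- data.frame(
    group = c("suboptimal", "optimal"), n = c(n_pos, n_neg),
    mean = c(mean(pos), mean(neg)), sd = c(stats::sd(pos), stats::sd(neg)),
    median = c(stats::median(pos), stats::median(neg)),
    min = c(min(pos), min(neg)), max = c(max(pos), max(neg)))

  structure(
    list(marker = marker, curve = curve, auc = auc, auc_ci = ci,
         conf_level = conf_level, cutoff = cutoff,
         youden_j = diag$sensitivity + diag$specificity - 1,
         diagnostics = diag,
         correct_n = correctly_predicted(auc, n_pos + n_neg),
         group_summary = gs,
         tests = list(mann_whitney = mann_whitney_u(pos, neg),
                      t_welch = t_test_unpaired(pos, neg, welch = TRUE)),
         n_pos = n_pos, n_neg = n_neg, positive = positive),
    class = "roc_cutoff")
}

#' @rdname roc_cutoff
#' @param formula a formula `outcome ~ marker` with one term on each side.
#' @param data data frame (typically a cohort) holding both columns.
#' @export
roc_cutoff.formula <- function(x, data, ...) {
  formula <- x
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2) stop("formula must be of the form outcome ~ marker", call. = FALSE)
  roc_cutoff.default(mf[[2]], mf[[1]], marker = names(mf)[2], ...)
}

#' @export
print.roc_cutoff <- function(x, ...) {
  cat(sprintf("Cutoff model for %s (positive class: %s; n = %d + %d)\n",
              x$marker, x$positive, x$n_pos, x$n_neg))
  cat(sprintf("  cutoff %.6g | AUC %.3f (%d%% CI %.3f-%.3f) | %d/%d predicted correctly\n",
              x$cutoff, x$auc, round(100 * x$conf_level),
              x$auc_ci[["lo"]], x$auc_ci[["hi"]], x$correct_n,
              x$n_pos + x$n_neg))
  cat("  ")
  print(x$diagnostics)
  invisible(x)
}

#' @export
#' @method summary roc_cutoff
summary.roc_cutoff <- function(object, ...) {
  print(object)
  cat("\nGroup summaries:\n")
  print(object$group_summary, row.names = FALSE, digits = 4)
  cat("\nBetween-group tests:\n  ")
  print(object$tests$mann_whitney)
  cat("  ")
  print(object$tests$t_welch)
  invisible(object)
}

#' @export
#' @method coef roc_cutoff
coef.roc_cutoff <- function(object, ...) {
  c(cutoff = object$cutoff,
    sensitivity = object$diagnostics$sensitivity,
    specificity = object$diagnostics$specificity,
    youden_j = object$youden_j,
    auc = object$auc)
}

#' Classify new marker values at the fitted cutoff
#'
#' @param object a fitted [roc_cutoff()] model.
#' @param newdata numeric marker values (or a data frame holding the
#'   marker column).
#' @param type `"class"` for predicted outcome labels, `"category"` for
#'   the `{1, 2}` category coding used in combined scores.
#' @param ... ignored.
#' @return factor of predicted classes, or integer categories.
#' @export
#' @method predict roc_cutoff
predict.roc_cutoff <- function(object, newdata, type = c("class", "category"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    if (!object$marker %in% names(newdata))
      stop("newdata has no column '", object$marker, "'", call. = FALSE)
    newdata <- newdata[[object$marker]]
  }
  cat2 <- dichotomize(newdata, object$cutoff)
  if (type == "category") return(cat2)
  factor(ifelse(cat2 == 2L, "suboptimal", "optimal"),
         levels = c("suboptimal", "optimal"))
}

#' @export
#' @method plot roc_cutoff
plot.roc_cutoff <- function(x, ...) {
  plot(x$curve, main = sprintf("%s: AUC %.3f", x$marker, x$auc), ...)
  graphics::points(1 - x$diagnostics$specificity, x$diagnostics$sensitivity,
                   pch = 19, col = "red3")
  invisible(x)
}
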
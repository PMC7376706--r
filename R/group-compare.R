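#' Mann-Whitney U test between two groups
#'
#' The U statistic is computed by tie-aware rank arithmetic (equivalent to
#' pair counting with ties worth one half), so that the identity
#' `U = AUC * n_x * n_y` with [auc_mannwhitney()] holds exactly. The
#' two-sided p-value uses the normal approximation with tie-corrected
#' variance and continuity correction via [stats::wilcox.test()].
#'
#' @param x,y numeric samples (non-empty, finite).
#' @return object of class `"test_result"`: list with `statistic` (U for
#'   `x` over `y`), `p_value`, `method`, `n`.
#' @examples
#' mann_whitney_u(c(3, 4, 5), c(1, 2, 3))$statistic  # 8.5
#' @export
mann_whitney_u <- function(x, y) {
  stop_if_not_finite(x, "x"); stop_if_not_finite(y, "y")
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    p <- 1                               # all values tied: no evidence either way
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  test_result(u, p, "Mann-Whitney U (normal approximation, tie-corrected)",
              c(nx, ny))
}

#' Unpaired two-sample t-test
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param welch use the Welch (unequal-variance) form; `FALSE` pools the
#'   variance.
#' @return a `"test_result"` with the t statistic.
#' @export
t_test_unpaired <- function(x, y, welch = TRUE) {
  stop_if_not_finite(x, "x"); stop_if_not_finite(y, "y")
  if (length(x) < 2 || length(y) < 2)
    stop("each sample must have at least 2 observations", call. = FALSE)
  method <- if (welch) "Welch unpaired t" else "pooled unpaired t"
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(test_result(0, 1, method, c(length(x), length(y))))
    stop("zero variance in both samples with unequal means: t undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  test_result(unname(ht$statistic), ht$p.value, method, c(length(x), length(y)))
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction, `df = (r-1)(c-1)`. Errors if any
#' expected count is zero (a degenerate margin) rather than returning a
#' meaningless statistic.
#'
#' @param table matrix of non-negative counts.
#' @return a `"test_result"` with the chi-square statistic and a `df` field.
#' @examples
#' chi_square_test(matrix(c(30, 10, 10, 30), 2))$statistic  # 20
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || anyNA(table)) stop("counts must be non-negative", call. = FALSE)
  exp_cnt <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(exp_cnt == 0))
    stop("expected count of zero: degenerate table margin", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  out <- test_result(unname(ht$statistic), ht$p.value,
                     "Pearson chi-square (no continuity correction)", dim(table))
  out$df <- unname(ht$parameter)
  out
}

test_result <- function(statistic, p_value, method, n) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}
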
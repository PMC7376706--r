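#' Published study summary rates
#'
#' Loads the printed diagnostic-rate table and ROC-figure legends of the
#' 109-patient reference study shipped with the package: per marker/panel
#' the cutoff point, sensitivity, specificity, accuracy, PPV, NPV (one
#' decimal percentages), the AUC with its printed confidence interval and
#' correctly-predicted count, and the group summary statistics
#' (mean/SD/median/range per surgical group).
#'
#' @param path JSON file; defaults to the copy in the package's `extdata`.
#' @return nested list with `n_pos`, `n_neg`, `n_total` and `panels`.
#' @export
published_table2 <- function(path = system.file("extdata", "published_table2.json",
                                                package = "cytoROC")) {
  if (!nzchar(path) || !file.exists(path))
    stop("published-table fixture not found", call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Verify published rates against exact integer arithmetic
#'
#' For each published marker/panel row, back-solves the integer confusion
#' matrix from the printed sensitivity/specificity and the group sizes
#' ([reconstruct_confusion()]), recomputes every rate from the exact
#' counts, and compares with the printed cells at one-decimal half-up
#' rounding. Also re-derives each figure legend's correctly-predicted
#' count from its AUC, and the Hanley-McNeil confidence interval from the
#' AUC and group sizes. Disagreements are reported, not hidden: a printed
#' cell that was truncated rather than rounded, or a count/interval that
#' the printed AUC cannot reproduce, shows up as `agree = FALSE`.
#'
#' @param published a list as returned by [published_table2()].
#' @return object of class `"published_verification"`: list of data frames
#'   `cells` (rate cells), `counts` (figure-legend counts) and `ci`
#'   (confidence-interval endpoints, with absolute deviations).
#' @export
verify_published_table <- function(published = published_table2()) {
  np <- published$n_pos; nn <- published$n_neg; nt <- published$n_total
  stopifnot(np > 0, nn > 0, nt == np + nn)

  cells <- list(); counts <- list(); cis <- list()
  for (nm in names(published$panels)) {
    p <- published$panels[[nm]]
    rates <- unlist(p[c("sens_pct", "spec_pct", "acc_pct", "ppv_pct", "npv_pct")])
    if (anyNA(rates) || any(rates < 0) || any(rates > 100))
      stop("panel '", nm, "': printed rates must be percentages in [0, 100]",
           call. = FALSE)

    cm <- reconstruct_confusion(p$sens_pct / 100, p$spec_pct / 100, np, nn)
    d <- summarize_confusion(cm)
    rec <- c(sens_pct = as_percent(d$sensitivity),
             spec_pct = as_percent(d$specificity),
             acc_pct = as_percent(d$accuracy),
             ppv_pct = as_percent(d$ppv),
             npv_pct = as_percent(d$npv))
    cells[[nm]] <- data.frame(
      panel = nm, cell = names(rec), printed = unname(rates),
      recomputed = unname(rec), agree = unname(abs(rec - rates) < 0.05),
      tp = cm$tp, tn = cm$tn)

    if (!is.null(p$auc_pct)) {
      auc <- p$auc_pct / 100
      if (auc < 0 || auc > 1) stop("panel '", nm, "': AUC out of [0, 100]%", call. = FALSE)
      n_rec <- correctly_predicted(auc, nt)
      counts[[nm]] <- data.frame(panel = nm, printed = p$correct_n,
                                 recomputed = n_rec,
                                 agree = n_rec == p$correct_n)
      ci <- auc_ci_hanley_mcneil(auc, np, nn)
      cis[[nm]] <- data.frame(
        panel = nm, end = c("lo", "hi"),
        printed_pct = c(p$ci_lo_pct, p$ci_hi_pct),
        recomputed_pct = as_percent(unname(ci)),
        deviation = abs(unname(ci) - c(p$ci_lo_pct, p$ci_hi_pct) / 100))
    }
  }
  structure(list(cells = do.call(rbind, cells),
                 counts = do.call(rbind, counts),
                 ci = do.call(rbind, cis)),
            class = "published_verification")
}

#' @export
print.published_verification <- function(x, ...) {
  bad <- x$cells[!x$cells$agree, ]
  cat(sprintf("Rate cells: %d/%d agree with exact integer arithmetic\n",
              sum(x$cells$agree), nrow(x$cells)))
  if (nrow(bad)) {
    cat("  disagreements (printed vs recomputed):\n")
    for (i in seq_len(nrow(bad)))
      cat(sprintf("    %s %s: %.1f vs %.1f\n", bad$panel[i], bad$cell[i],
                  bad$printed[i], bad$recomputed[i]))
  }
  badc <- x$counts[!x$counts$agree, ]
  cat(sprintf("Correct-count legends: %d/%d agree\n",
              sum(x$counts$agree), nrow(x$counts)))
  for (i in seq_len(nrow(badc)))
    cat(sprintf("    %s: printed %d vs recomputed %d\n", badc$panel[i],
                badc$printed[i], badc$recomputed[i]))
  cat(sprintf("AUC CI endpoints: max |deviation| = %.4f\n", max(x$ci$deviation)))
  invisible(x)
}
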
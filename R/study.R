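#' Run the full six-panel cutoff study on a cohort
#'
#' Reproduces the analysis shape of the motivating study in two stages.
#' Stage 1 fits a [roc_cutoff()] model to each single marker (CA-125,
#' FASN, GLS). Stage 2 freezes the stage-1 cutoffs for CA-125 and GLS,
#' builds the three multiplicative combined panels (CA-125+FASN,
#' CA-125+GLS, CA-125+FASN+GLS; see [default_panel_specs()] for the
#' numeric/category role assignment), and fits the same cutoff model to
#' each panel score. No joint optimization of cutoffs is attempted.
#'
#' @param cohort a cohort data frame with `group`, `ca125`, `fasn`, `gls`
#'   columns (see [generate_cohort()] / [read_cohort_csv()]).
#' @param pinned_cutoffs optional named numeric vector pinning cutoffs
#'   instead of re-deriving them by Youden's J; recognized names are the
#'   six panel names (`ca125`, `fasn`, `gls`, `ca125_fasn`, `ca125_gls`,
#'   `ca125_fasn_gls`). Pinning `ca125`/`gls` also fixes the category
#'   cutoffs used inside the combined scores.
#' @param conf_level AUC confidence level.
#' @return object of class `"study_report"`: list with `fits` (six
#'   [roc_cutoff()] objects), `cutoffs` (the cutoffs actually used for
#'   dichotomization), `panel_specs`, and cohort metadata.
#' @examples
#' coh <- generate_cohort(default_study_params(), seed = 42)
#' rep <- run_study(coh, pinned_cutoffs = c(ca125 = 248.55, gls = 22.895))
#' as.data.frame(rep)
#' @export
run_study <- function(cohort, pinned_cutoffs = NULL, conf_level = 0.95) {
  cohort <- validate_cohort(cohort, markers = c("ca125", "fasn", "gls"))
  if (!all(c("ca125", "fasn", "gls") %in% names(cohort)))
    stop("cohort must contain ca125, fasn and gls columns", call. = FALSE)
  pin <- function(nm) if (!is.null(pinned_cutoffs) && nm %in% names(pinned_cutoffs))
    pinned_cutoffs[[nm]] else NULL

  # stage 1: single markers
  singles <- c("ca125", "fasn", "gls")
  fits <- lapply(singles, function(m)
    roc_cutoff(cohort[[m]], cohort$group, cutoff = pin(m), marker = m,
               conf_level = conf_level))
  names(fits) <- singles

  # stage 2: combined panels at the frozen stage-1 category cutoffs
  specs <- default_panel_specs(
    ca125_cutoff = if (!is.null(pin("ca125"))) pin("ca125") else fits$ca125$cutoff,
    gls_cutoff = if (!is.null(pin("gls"))) pin("gls") else fits$gls$cutoff)
  for (nm in names(specs)) {
    panel <- build_combined_panel(cohort, specs[[nm]])
    fits[[nm]] <- roc_cutoff(panel$score, cohort$group, cutoff = pin(nm),
                             marker = nm, conf_level = conf_level)
  }

  structure(
    list(fits = fits,
         cutoffs = vapply(fits, `[[`, numeric(1), "cutoff"),
         panel_specs = specs,
         n_pos = sum(cohort$group == "suboptimal"),
         n_neg = sum(cohort$group == "optimal")),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Cutoff study: %d suboptimal + %d optimal patients, 6 panels\n\n",
              x$n_pos, x$n_neg))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
#' @method summary study_report
summary.study_report <- function(object, ...) {
  print(object)
  cat("\nCombined-panel construction:\n")
  for (s in object$panel_specs) { cat("  "); print(s) }
  invisible(object)
}

#' Flatten a study report to a table of published-style columns
#'
#' One row per marker/panel with the cutoff, the five diagnostic rates as
#' one-decimal percentages, the AUC with its confidence interval, the
#' implied correctly-predicted count, and the two test p-values.
#'
#' @param x a `study_report`.
#' @param ... ignored.
#' @return data frame, six rows.
#' @export
as.data.frame.study_report <- function(x, ...) {
  do.call(rbind, lapply(names(x$fits), function(nm) {
    f <- x$fits[[nm]]
    d <- f$diagnostics
    data.frame(
      variable = nm, cutoff = f$cutoff,
      sensitivity_pct = as_percent(d$sensitivity),
      specificity_pct = as_percent(d$specificity),
      accuracy_pct = as_percent(d$accuracy),
      ppv_pct = as_percent(d$ppv), npv_pct = as_percent(d$npv),
      auc = f$auc, auc_lo = f$auc_ci[["lo"]], auc_hi = f$auc_ci[["hi"]],
      correct_n = f$correct_n,
      p_mann_whitney = f$tests$mann_whitney$p_value,
      p_t_welch = f$tests$t_welch$p_value)
  }))
}

#' Write a study report to JSON (and optionally a flat CSV)
#'
#' @param report a `study_report`.
#' @param json_path output JSON path.
#' @param csv_path optional path for the flat per-panel table
#'   (published-table column order).
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "study_report"))
  flat <- as.data.frame(report)
  payload <- list(
    n_pos = report$n_pos, n_neg = report$n_neg,
    cutoffs = as.list(report$cutoffs),
    panels = lapply(report$fits, function(f) {
      d <- f$diagnostics
      list(marker = f$marker, cutoff = f$cutoff, auc = f$auc,
           auc_ci = as.list(f$auc_ci), correct_n = f$correct_n,
           diagnostics = list(sensitivity = d$sensitivity,
                              specificity = d$specificity,
                              accuracy = d$accuracy, ppv = d$ppv, npv = d$npv),
           confusion = d$confusion[c("tp", "fn", "tn", "fp")],
           group_summary = f$group_summary,
           tests = list(
             mann_whitney = f$tests$mann_whitney[c("statistic", "p_value")],
             t_welch = f$tests$t_welch[c("statistic", "p_value")]))
    }))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(flat, csv_path, row.names = FALSE)
  invisible(json_path)
}
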
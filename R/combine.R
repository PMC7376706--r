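#' Dichotomize a marker value into a category value
#'
#' The `{1, 2}` coding used by the multiplicative combined scores: category
#' 1 when the value is at or below the cutoff, category 2 when strictly
#' above it.
#'
#' @param value numeric marker value(s), finite.
#' @param cutoff finite cutoff.
#' @return integer vector of 1s and 2s.
#' @examples
#' dichotomize(600, 248.55)     # 2
#' dichotomize(248.55, 248.55)  # 1 (boundary is inclusive on the low side)
#' @export
dichotomize <- function(value, cutoff) {
  stop_if_not_finite(value, "value")
  stop_if_not_finite(cutoff, "cutoff")
  ifelse(value > cutoff, 2L, 1L)
}

#' Multiplicative combined biomarker score
#'
#' One marker keeps its numeric serum level; each remaining marker
#' contributes a factor of 1 or 2 according to whether it exceeds its own
#' cutoff. The combined score is the product, so it lives on the numeric
#' marker's scale inflated by up to `2^k` for `k` category markers.
#'
#' @param numeric_value non-negative numeric level(s) of the marker kept
#'   numeric.
#' @param categories vector (or list of vectors, one per category marker)
#'   of category values, each in `{1, 2}`.
#' @return numeric score(s).
#' @examples
#' combined_score(37.50, 2)        # 75.0
#' combined_score(0.11, c(2, 1))   # 0.22
#' @export
combined_score <- function(numeric_value, categories) {
  stop_if_not_finite(numeric_value, "numeric marker value")
  if (any(numeric_value < 0)) stop("numeric marker value must be >= 0", call. = FALSE)
  if (is.list(categories)) categories <- do.call(cbind, categories)
  if (length(categories) == 0) stop("at least one category value is required", call. = FALSE)
  if (!all(categories %in% c(1, 2)))
    stop("category values must be 1 or 2", call. = FALSE)
  if (is.matrix(categories)) {
    numeric_value * apply(categories, 1, prod)
  } else {
    numeric_value * prod(categories)
  }
}

#' Specify a combined-score panel
#'
#' @param numeric_marker name of the marker whose raw level enters the
#'   product.
#' @param category_markers named numeric vector of cutoffs, one per
#'   category marker (names are marker column names); must not include the
#'   numeric marker.
#' @return object of class `"combined_spec"`.
#' @export
combined_spec <- function(numeric_marker, category_markers) {
  stopifnot(is.character(numeric_marker), length(numeric_marker) == 1)
  if (length(category_markers) < 1 || is.null(names(category_markers)))
    stop("category_markers must be a named vector of cutoffs", call. = FALSE)
  stop_if_not_finite(unname(category_markers), "category cutoffs")
  if (numeric_marker %in% names(category_markers))
    stop("numeric marker cannot also be a category marker", call. = FALSE)
  structure(list(numeric_marker = numeric_marker,
                 category_markers = category_markers),
            class = "combined_spec")
}

#' @export
print.combined_spec <- function(x, ...) {
  cats <- paste(sprintf("%s (1: <= %g, 2: > %g)", names(x$category_markers),
                        x$category_markers, x$category_markers),
                collapse = " x ")
  cat(sprintf("combined score: %s (numeric) x %s\n", x$numeric_marker, cats))
  invisible(x)
}

#' The three study combination panels
#'
#' The panels evaluated alongside the single markers, with the numeric /
#' category role assignment fixed by the published panel ranges (every
#' printed range endpoint is a product of one marker's printed extreme with
#' category values): CA-125+FASN keeps FASN numeric with CA-125 as the
#' category marker; CA-125+GLS keeps GLS numeric with CA-125 categorical;
#' the triple keeps FASN numeric with CA-125 and GLS categorical.
#'
#' @param ca125_cutoff,gls_cutoff category cutoffs for CA-125 and GLS.
#'   Defaults are the published study cutoffs; in a full pipeline run they
#'   are replaced by the cutoffs selected on the cohort at hand.
#' @return named list of three [combined_spec()] objects
#'   (`ca125_fasn`, `ca125_gls`, `ca125_fasn_gls`).
#' @export
default_panel_specs <- function(ca125_cutoff = 248.55, gls_cutoff = 22.895) {
  list(
    ca125_fasn = combined_spec("fasn", c(ca125 = ca125_cutoff)),
    ca125_gls = combined_spec("gls", c(ca125 = ca125_cutoff)),
    ca125_fasn_gls = combined_spec("fasn", c(ca125 = ca125_cutoff,
                                             gls = gls_cutoff)))
}

#' Compute a combined-score panel over a cohort
#'
#' @param cohort cohort data frame containing every marker named in `spec`.
#' @param spec a [combined_spec()].
#' @return data frame `patient_id`, `score`, in cohort order.
#' @export
build_combined_panel <- function(cohort, spec) {
  stopifnot(inherits(spec, "combined_spec"))
  need <- c(spec$numeric_marker, names(spec$category_markers))
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing marker column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cats <- lapply(names(spec$category_markers), function(m)
    dichotomize(cohort[[m]], spec$category_markers[[m]]))
  score <- combined_score(cohort[[spec$numeric_marker]], cats)
  data.frame(patient_id = if ("patient_id" %in% names(cohort))
               cohort$patient_id else seq_len(nrow(cohort)),
             score = score)
}
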
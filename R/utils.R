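#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.5 -> 1`), the convention used
#' throughout the reported percentage tables. Base [round()] rounds half to
#' even, which disagrees on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector, rounded.
#' @examples
#' round_half_up(73.35, 1)   # 73.4
#' round(73.35, 1)           # 73.3 under round-half-even (representation permitting)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny eps absorbs binary representation error on exact decimal ties
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a fraction as a one-decimal percentage
#'
#' @param x fraction in \[0, 1\] (NA allowed).
#' @return numeric percentage rounded half-up to one decimal.
#' @export
as_percent <- function(x) round_half_up(100 * x, 1)

# -- internal input checks -----------------------------------------------

stop_if_not_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(what, " must be finite and non-missing", call. = FALSE)
  invisible(x)
}

# Normalize an outcome-label vector to a logical "is positive class"
# (positive class = suboptimal cytoreduction). Accepts logicals, factors,
# or character labels; case-insensitive.
as_positive <- function(labels, positive = "suboptimal") {
  if (is.logical(labels)) return(labels)
  lab <- tolower(trimws(as.character(labels)))
  pos <- lab == tolower(positive)
  known <- pos | lab %in% c("optimal", "suboptimal", tolower(positive))
  if (!all(known))
    stop("unknown outcome label(s): ",
         paste(unique(lab[!known]), collapse = ", "), call. = FALSE)
  pos
}

check_two_classes <- function(is_pos) {
  if (!any(is_pos) || all(is_pos))
    stop("both outcome classes must be present", call. = FALSE)
  invisible(is_pos)
}
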
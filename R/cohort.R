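#' Marker distribution parameters
#'
#' One serum marker's sampling distribution within one surgical-outcome
#' group: a lognormal (right-skewed markers such as CA-125 and FASN) or a
#' truncated normal (near-symmetric markers such as GLS), truncated to the
#' clinically observed range by rejection.
#'
#' @param name marker identifier, e.g. `"ca125"`.
#' @param family `"lognormal"` or `"truncated-normal"`.
#' @param mu location: log-scale median for the lognormal, natural-scale
#'   mean for the normal.
#' @param sigma scale parameter, `>= 0` (log-scale SD for the lognormal).
#' @param lo,hi truncation bounds in marker units; `lo < hi`, and `lo >= 0`
#'   for the lognormal.
#' @return object of class `"marker_params"`.
#' @export
marker_params <- function(name, family = c("lognormal", "truncated-normal"),
                          mu, sigma, lo = 0, hi = Inf) {
  family <- match.arg(family)
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (!(lo < hi)) stop("lo must be < hi", call. = FALSE)
  if (family == "lognormal" && lo < 0)
    stop("lognormal truncation bound lo must be >= 0", call. = FALSE)
  structure(list(name = name, family = family, mu = mu, sigma = sigma,
                 lo = lo, hi = hi),
            class = "marker_params")
}

#' Moment-match a lognormal to a published mean and median
#'
#' For `X ~ lognormal(mu, sigma)`, `median(X) = exp(mu)` and
#' `mean(X) = exp(mu + sigma^2/2)`, so a (mean, median) pair determines the
#' parameters in closed form: `mu = log(median)`,
#' `sigma = sqrt(2 log(mean/median))`. This is how group summary tables
#' reporting only "mean +/- SD" and "median" are turned into a generative
#' model for a right-skewed marker.
#'
#' @param mean,median positive reals with `mean >= median` (a lognormal's
#'   mean never falls below its median).
#' @return named numeric vector `c(mu = , sigma = )`.
#' @examples
#' fit_lognormal_from_mean_median(1157.62, 600)  # mu 6.397, sigma 1.146
#' @export
fit_lognormal_from_mean_median <- function(mean, median) {
  if (!is.finite(mean) || !is.finite(median) || mean <= 0 || median <= 0)
    stop("mean and median must be positive and finite", call. = FALSE)
  if (mean < median)
    stop("a lognormal cannot have mean below median", call. = FALSE)
  c(mu = log(median), sigma = sqrt(2 * log(mean / median)))
}

#' Group-level generator parameters
#'
#' @param group `"suboptimal"` or `"optimal"`.
#' @param n patient count (> 0).
#' @param markers named list of [marker_params()], one per marker.
#' @param covariates optional named list of category-probability vectors
#'   (each named, in \[0,1\], summing to 1 within 1e-9), e.g. FIGO stage and
#'   histopathology proportions.
#' @return object of class `"group_params"`.
#' @export
group_params <- function(group = c("suboptimal", "optimal"), n, markers,
                         covariates = NULL) {
  group <- match.arg(group)
  if (!is.numeric(n) || n <= 0 || n != round(n)) stop("n must be a positive integer", call. = FALSE)
  stopifnot(is.list(markers), length(markers) > 0, !is.null(names(markers)))
  for (m in markers) stopifnot(inherits(m, "marker_params"))
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      p <- covariates[[nm]]
      if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9 || is.null(names(p)))
        stop("covariate '", nm, "' probabilities must be named, in [0,1], sum to 1",
             call. = FALSE)
    }
  }
  structure(list(group = group, n = as.integer(n), markers = markers,
                 covariates = covariates),
            class = "group_params")
}

#' Default generator parameters emulating the motivating study
#'
#' Two groups of n = 56 (suboptimal cytoreduction) and n = 53 (optimal)
#' patients. CA-125 and FASN are strongly right-skewed (published group
#' means far exceed medians) and are modelled lognormal via
#' [fit_lognormal_from_mean_median()]; GLS has mean approximately equal to
#' its median and is modelled normal with the published mean and SD. All
#' six marker-by-group distributions are truncated to the published
#' min-max ranges. Stage and histopathology category proportions follow
#' the published background-characteristics table.
#'
#' @param covariates logical; include stage/histology sampling (default TRUE).
#' @return list with elements `suboptimal` and `optimal`, each a
#'   [group_params()].
#' @export
default_study_params <- function(covariates = TRUE) {
  ln <- function(name, mean, median, lo, hi) {
    p <- fit_lognormal_from_mean_median(mean, median)
    marker_params(name, "lognormal", mu = p[["mu"]], sigma = p[["sigma"]],
                  lo = lo, hi = hi)
  }
  tn <- function(name, mean, sd, lo, hi)
    marker_params(name, "truncated-normal", mu = mean, sigma = sd, lo = lo, hi = hi)

  cov_sub <- cov_opt <- NULL
  if (covariates) {
    cov_sub <- list(
      stage = c(II = 8, III = 38, IV = 10) / 56,
      histology = c(serous = 18, mucinous = 12, endometrioid = 14,
                    clear_cell = 8, others = 4) / 56)
    cov_opt <- list(
      stage = c(II = 34, III = 19, IV = 0) / 53,
      histology = c(serous = 9, mucinous = 26, endometrioid = 7,
                    clear_cell = 8, others = 3) / 53)
  }

  list(
    suboptimal = group_params(
      "suboptimal", n = 56,
      markers = list(
        ca125 = ln("ca125", 1157.62, 600.00, lo = 4.29, hi = 9934.00),
        fasn  = ln("fasn", 0.58, 0.50, lo = 0.11, hi = 1.59),
        gls   = tn("gls", 25.19, 5.415, lo = 14.27, hi = 37.50)),
      covariates = cov_sub),
    optimal = group_params(
      "optimal", n = 53,
      markers = list(
        ca125 = ln("ca125", 237.52, 120.30, lo = 5.10, hi = 1941.90),
        fasn  = ln("fasn", 0.46, 0.37, lo = 0.03, hi = 1.19),
        gls   = tn("gls", 20.83, 5.562, lo = 10.81, hi = 38.01)),
      covariates = cov_opt))
}

# rejection-sample n values from one marker_params; errors out if the
# acceptance rate collapses (inconsistent bounds)
draw_marker <- function(mp, n) {
  out <- numeric(0)
  drawn <- 0
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 100L)
    x <- switch(mp$family,
      "lognormal" = stats::rlnorm(m, meanlog = mp$mu, sdlog = mp$sigma),
      "truncated-normal" = stats::rnorm(m, mean = mp$mu, sd = mp$sigma))
    drawn <- drawn + m
    out <- c(out, x[x >= mp$lo & x <= mp$hi])
    if (drawn >= 100L * n && length(out) < 0.01 * drawn)
      stop("rejection rate > 99% for marker '", mp$name,
           "': truncation bounds inconsistent with (mu, sigma)", call. = FALSE)
  }
  out[seq_len(n)]
}

#' Generate a synthetic two-group patient cohort
#'
#' Draws each marker independently per patient from its configured family,
#' rejecting values outside the truncation range; optional covariates are
#' drawn from their category proportions independently of the markers.
#' Identical `(params, seed)` always yields an identical cohort.
#'
#' @param params list with `suboptimal` and `optimal` [group_params()]
#'   entries (see [default_study_params()]).
#' @param seed integer RNG seed (required; there is no implicit global
#'   state dependence).
#' @return a `cohort`: data frame with columns `patient_id`, `group`
#'   (factor, levels suboptimal/optimal), one numeric column per marker,
#'   and any covariate columns.
#' @examples
#' coh <- generate_cohort(default_study_params(), seed = 42)
#' table(coh$group)
#' @export
generate_cohort <- function(params, seed) {
  stopifnot(is.list(params), all(c("suboptimal", "optimal") %in% names(params)))
  if (missing(seed) || !is.numeric(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))

  one_group <- function(gp) {
    df <- data.frame(group = rep(gp$group, gp$n), stringsAsFactors = FALSE)
    for (nm in names(gp$markers)) df[[nm]] <- draw_marker(gp$markers[[nm]], gp$n)
    for (nm in names(gp$covariates)) {
      p <- gp$covariates[[nm]]
      df[[nm]] <- sample(names(p), gp$n, replace = TRUE, prob = p)
    }
    df
  }
  out <- rbind(one_group(params$suboptimal), one_group(params$optimal))
  out <- cbind(patient_id = sprintf("P%03d", seq_len(nrow(out))), out)
  out$group <- factor(out$group, levels = c("suboptimal", "optimal"))
  class(out) <- c("cohort", "data.frame")
  out <- validate_cohort(out)
  out
}

#' Validate a cohort data frame
#'
#' Checks the invariants every downstream stage relies on: known group
#' labels, and finite non-negative marker values with none missing.
#'
#' @param cohort a cohort data frame.
#' @param markers marker column names expected to be present.
#' @return the validated cohort, invisibly classed as `"cohort"`.
#' @export
validate_cohort <- function(cohort, markers = intersect(c("ca125", "fasn", "gls"),
                                                        names(cohort))) {
  stopifnot(is.data.frame(cohort))
  if (!all(c("group") %in% names(cohort)))
    stop("cohort must have a 'group' column", call. = FALSE)
  g <- tolower(trimws(as.character(cohort$group)))
  bad <- which(!g %in% c("suboptimal", "optimal"))
  if (length(bad))
    stop("unknown group label in row ", bad[1], ": '", cohort$group[bad[1]], "'",
         call. = FALSE)
  cohort$group <- factor(g, levels = c("suboptimal", "optimal"))
  for (m in markers) {
    v <- cohort[[m]]
    if (!is.numeric(v))
      stop("marker column '", m, "' is not numeric", call. = FALSE)
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop("marker '", m, "' invalid (missing, non-finite or negative) in row ",
           bad[1], call. = FALSE)
  }
  if (!inherits(cohort, "cohort")) class(cohort) <- c("cohort", class(cohort))
  invisible(cohort)
}

# -- CSV / JSON external interfaces --------------------------------------

csv_marker_map <- c(ca125 = "ca125_u_ml", fasn = "fasn_ng_ml", gls = "gls_ng_ml")

#' Write a cohort to CSV
#'
#' Uses the documented schema
#' `patient_id,group,ca125_u_ml,fasn_ng_ml,gls_ng_ml[,stage,histology]`
#' with full-precision marker values and `"suboptimal"`/`"optimal"` group
#' strings.
#'
#' @param cohort a cohort data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (nm in names(csv_marker_map))
    if (nm %in% names(out)) names(out)[names(out) == nm] <- csv_marker_map[[nm]]
  out$group <- as.character(out$group)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Accepts the schema written by [write_cohort_csv()]; group labels are
#' case-insensitive and normalized, unknown columns are preserved, and any
#' invalid marker value is reported with its row number.
#'
#' @param path CSV file path.
#' @return a validated cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (nm in names(csv_marker_map)) {
    long <- csv_marker_map[[nm]]
    if (long %in% names(df)) names(df)[names(df) == long] <- nm
  }
  if (!any(names(csv_marker_map) %in% names(df)))
    stop("no marker columns found (expected e.g. ca125_u_ml)", call. = FALSE)
  validate_cohort(df)
}

#' Write generator parameters as JSON
#'
#' @param params list of two [group_params()] as from [default_study_params()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  unclassed <- lapply(params, function(gp) {
    gp <- unclass(gp)
    gp$markers <- lapply(gp$markers, unclass)
    gp$covariates <- lapply(gp$covariates, as.list)
    gp
  })
  jsonlite::write_json(unclassed, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read generator parameters from JSON
#'
#' @param path JSON file written by [write_params_json()].
#' @return list of two [group_params()].
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(gp) {
    mk <- lapply(gp$markers, function(m)
      marker_params(m$name, m$family, mu = m$mu, sigma = m$sigma,
                    lo = m$lo, hi = if (is.null(m$hi)) Inf else m$hi))
    cov <- if (!is.null(gp$covariates) && length(gp$covariates))
      lapply(gp$covariates, unlist) else NULL
    group_params(gp$group, n = gp$n, markers = mk, covariates = cov)
  })
}
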
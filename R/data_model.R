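#' Construct a survey-data object
#'
#' Bundles a site x occasion x year detection/nondetection array with its
#' labels and checks the basic invariants of a camera-trap detection history:
#' every cell is 0 (sampled, no detection), 1 (sampled, detection) or `NA`
#' (occasion not sampled).
#'
#' @param y 3-d array, sites x occasions x years, values 0/1/`NA`.
#' @param site_ids character vector of site labels; defaults to
#'   `"site_1"..."site_N"`.
#' @param year_labels vector of calendar years (or other year labels);
#'   defaults to `1..K`.
#' @return An object of class `survey_data`: a list with elements `y`,
#'   `n_sites`, `n_occasions`, `n_years`, `site_ids`, `year_labels`.
#' @export
survey_data <- function(y, site_ids = NULL, year_labels = NULL) {
  if (!is.array(y) || length(dim(y)) != 3L)
    stop("`y` must be a 3-d array (sites x occasions x years)", call. = FALSE)
  vals <- y[!is.na(y)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stop("detection array entries must be 0, 1 or NA", call. = FALSE)
  d <- dim(y)
  if (is.null(site_ids)) site_ids <- paste0("site_", seq_len(d[1]))
  if (is.null(year_labels)) year_labels <- seq_len(d[3])
  if (length(site_ids) != d[1])
    stop("length(site_ids) does not match dim(y)[1]", call. = FALSE)
  if (length(year_labels) != d[3])
    stop("length(year_labels) does not match dim(y)[3]", call. = FALSE)
  structure(
    list(y = y, n_sites = d[1], n_occasions = d[2], n_years = d[3],
         site_ids = as.character(site_ids), year_labels = year_labels),
    class = "survey_data")
}

#' @export
print.survey_data <- function(x, ...) {
  det <- sum(x$y == 1, na.rm = TRUE)
  eff <- sum(!is.na(x$y))
  cat("Camera-trap survey:", x$n_sites, "sites x", x$n_occasions,
      "occasions x", x$n_years, "years\n")
  cat("  sampled occasions:", eff, " detections:", det, "\n")
  invisible(x)
}

#' Aggregate daily camera records into sampling occasions
#'
#' Collapses a daily detection/effort sequence for one site-year into
#' occasion-level detection/nondetection outcomes. An occasion is scored 1 if
#' at least one detection fell on an operating day within the block, 0 if all
#' its operating days lacked detections, and `NA` if no operating day fell in
#' the block. Days are blocked in calendar order; a trailing partial block
#' (fewer than `occasion_length` days) is retained rather than dropped, so no
#' effort is discarded.
#'
#' @param operating integer/logical vector, one entry per calendar day of the
#'   deployment: was the camera operating that day?
#' @param detection integer/logical vector, same length: was the species
#'   detected that day? Detections are only legal on operating days.
#' @param occasion_length number of days per occasion (default 5).
#' @return Integer vector of occasion outcomes (0/1/`NA`).
#' @export
aggregate_occasions <- function(operating, detection, occasion_length = 5) {
  if (length(occasion_length) != 1L || is.na(occasion_length) ||
      occasion_length < 1)
    stop("`occasion_length` must be a single day count >= 1", call. = FALSE)
  occasion_length <- as.integer(occasion_length)
  operating <- as.integer(operating)
  detection <- as.integer(detection)
  if (length(operating) != length(detection))
    stop("`operating` and `detection` must have equal length", call. = FALSE)
  if (any(detection == 1 & operating == 0))
    stop("detection recorded on a non-operating day: inconsistent data",
         call. = FALSE)
  n_days <- length(operating)
  if (n_days == 0L) return(integer(0))
  occ_of_day <- (seq_len(n_days) - 1L) %/% occasion_length + 1L
  n_occ <- max(occ_of_day)
  vapply(seq_len(n_occ), function(j) {
    idx <- occ_of_day == j
    if (!any(operating[idx] == 1L)) return(NA_integer_)
    as.integer(any(detection[idx] == 1L))
  }, integer(1))
}

#' Standardize a covariate to mean zero and unit variance
#'
#' Centering and scaling use the sample mean and sample standard deviation
#' (denominator n - 1); the transform parameters are returned so the same
#' transform can be replayed on new data or inverted.
#'
#' @param x numeric vector (or matrix, standardized over all cells jointly).
#' @param center,scale optional transform parameters to reuse; computed from
#'   `x` when `NULL`.
#' @return List with `values` (same shape as `x`), `center` and `scale`.
#' @export
standardize <- function(x, center = NULL, scale = NULL) {
  v <- as.numeric(x)
  if (sum(is.finite(v)) < 2L)
    stop("need at least 2 finite values to standardize", call. = FALSE)
  if (is.null(center)) center <- mean(v, na.rm = TRUE)
  if (is.null(scale)) scale <- stats::sd(v, na.rm = TRUE)
  if (!is.finite(scale) || scale == 0)
    stop("degenerate covariate: constant values cannot be standardized",
         call. = FALSE)
  out <- (x - center) / scale
  list(values = out, center = center, scale = scale)
}

#' Invert a standardization transform
#'
#' @param z standardized values.
#' @param center,scale the transform parameters returned by [standardize()].
#' @return Values on the original scale.
#' @export
destandardize <- function(z, center, scale) z * scale + center

#' Pearson correlation with a collinearity warning
#'
#' Sample Pearson correlation between two covariates, warning when |r| reaches
#' the screening threshold used to flag collinear predictors.
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @param warn_threshold absolute correlation at which to warn (default 0.7).
#' @return The correlation coefficient, in [-1, 1].
#' @export
pearson_r <- function(x, y, warn_threshold = 0.7) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant input", call. = FALSE)
  r <- stats::cor(x, y, method = "pearson")
  if (abs(r) >= warn_threshold)
    warning(sprintf("covariates are collinear (Pearson's r = %.2f)", r),
            call. = FALSE)
  r
}

#' Construct a covariate set
#'
#' Holds the raw occurrence and detection covariates of the analysis and their
#' standardized versions. Site covariates (elevation, distance to the park
#' border) are standardized over sites; the snare count, a site-by-year
#' covariate, is standardized over all site-year cells jointly with a single
#' mean/sd so a given count means the same thing in every year. The quadratic
#' elevation term is the square of *standardized* elevation and is itself left
#' unstandardized, which keeps it centered near the data and roughly
#' orthogonal to the linear term.
#'
#' @param elev_m elevation in meters a.s.l., one value per site.
#' @param border_dist shortest distance to the park border, one value per
#'   site (any consistent length unit).
#' @param snares nonnegative snare counts, sites x years matrix (or `NULL`
#'   for a model without the snare covariate; zeros are substituted).
#' @param ban binary year-level indicator for the firewood-collection ban;
#'   must be 0/1 and monotone nondecreasing over ordered years.
#' @param n_years number of survey years (needed when `snares` is `NULL`).
#' @return Object of class `covariate_set` with raw and standardized columns
#'   plus the recorded transforms.
#' @export
covariate_set <- function(elev_m, border_dist, snares = NULL, ban = NULL,
                          n_years = if (!is.null(snares)) ncol(snares) else
                            length(ban)) {
  n_sites <- length(elev_m)
  if (length(border_dist) != n_sites)
    stop("`elev_m` and `border_dist` must have one value per site",
         call. = FALSE)
  if (is.null(n_years) || !length(n_years))
    stop("cannot infer `n_years`; supply snares, ban, or n_years",
         call. = FALSE)
  if (is.null(snares)) snares <- matrix(0, n_sites, n_years)
  snares <- as.matrix(snares)
  if (nrow(snares) != n_sites || ncol(snares) != n_years)
    stop("`snares` must be a sites x years matrix", call. = FALSE)
  if (any(snares < 0)) stop("snare counts must be nonnegative", call. = FALSE)
  if (is.null(ban)) ban <- rep(0L, n_years)
  if (length(ban) != n_years || !all(ban %in% c(0, 1)))
    stop("`ban` must be a 0/1 vector with one entry per year", call. = FALSE)
  if (any(diff(ban) < 0))
    stop("`ban` must be monotone nondecreasing (a one-way policy switch)",
         call. = FALSE)

  elev_t <- standardize(elev_m)
  border_t <- standardize(border_dist)
  snares_constant <- stats::sd(as.numeric(snares)) == 0
  if (snares_constant) {
    # a structurally-zero snare covariate (snares excluded from the model)
    snares_t <- list(values = snares * 0, center = 0, scale = 1)
  } else {
    snares_t <- standardize(snares)
  }
  structure(
    list(elev_raw = elev_m, border_raw = border_dist, snares_raw = snares,
         ban = as.integer(ban),
         elev_std = elev_t$values, elev2_std = elev_t$values^2,
         border_std = border_t$values, snares_std = snares_t$values,
         transforms = list(elev = elev_t[c("center", "scale")],
                           border = border_t[c("center", "scale")],
                           snares = snares_t[c("center", "scale")]),
         n_sites = n_sites, n_years = n_years),
    class = "covariate_set")
}

#' Model specification
#'
#' Which covariate terms enter the occurrence and detection models, the
#' occasion length, and the prior scale for Bayesian fitting. Terms switched
#' off here are structurally fixed at zero in the parameter vector (e.g. the
#' snare covariate is dropped for species whose detections snares cannot
#' plausibly affect).
#'
#' @param include_snares include the snare count in the occurrence model?
#' @param include_ban include the ban indicator in the occurrence model?
#' @param occasion_length_days days per sampling occasion (default 5).
#' @param prior_sd standard deviation of the independent Normal(0, sd) priors
#'   placed on every free logit-scale parameter (default 10).
#' @param first_year_includes_ban include the ban term in the first-year
#'   occurrence predictor? Default `FALSE`: the first-year model carries only
#'   its own intercept and the site/site-year covariates.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(include_snares = TRUE, include_ban = TRUE,
                       occasion_length_days = 5, prior_sd = 10,
                       first_year_includes_ban = FALSE) {
  if (occasion_length_days < 1)
    stop("`occasion_length_days` must be >= 1", call. = FALSE)
  if (!is.finite(prior_sd) || prior_sd <= 0)
    stop("`prior_sd` must be a positive real", call. = FALSE)
  structure(
    list(include_snares = isTRUE(include_snares),
         include_ban = isTRUE(include_ban),
         occasion_length_days = as.integer(occasion_length_days),
         prior_sd = prior_sd,
         first_year_includes_ban = isTRUE(first_year_includes_ban)),
    class = "model_spec")
}

#' Validate survey data, covariates and model spec jointly
#'
#' Cross-checks dimensions, missing-data patterns and covariate completeness
#' before fitting. Issues are returned as a machine-readable data frame with a
#' severity column; any `"fatal"` issue should abort fitting (the fitting
#' functions call this and do abort).
#'
#' @param sd a [survey_data()] object.
#' @param cv a [covariate_set()] object.
#' @param spec a [model_spec()] object.
#' @return Data frame with columns `severity` ("fatal"/"warning") and
#'   `message`; zero rows when everything is consistent.
#' @export
validate_inputs <- function(sd, cv, spec = model_spec()) {
  issues <- list()
  add <- function(severity, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, message = message, stringsAsFactors = FALSE)

  if (!inherits(sd, "survey_data")) add("fatal", "sd is not a survey_data object")
  if (!inherits(cv, "covariate_set")) add("fatal", "cv is not a covariate_set object")
  if (length(issues)) return(do.call(rbind, issues))

  if (cv$n_sites != sd$n_sites)
    add("fatal", sprintf("covariates describe %d sites but survey has %d",
                         cv$n_sites, sd$n_sites))
  if (cv$n_years != sd$n_years)
    add("fatal", sprintf("covariates describe %d years but survey has %d",
                         cv$n_years, sd$n_years))
  if (anyNA(cv$elev_std) || anyNA(cv$border_std) || anyNA(cv$snares_std))
    add("fatal", "covariates contain missing values")
  if (all(is.na(sd$y)))
    add("fatal", "survey contains no sampled occasion at all")

  if (!length(issues) || !any(vapply(issues, function(i) i$severity,
                                     "") == "fatal")) {
    eff <- apply(!is.na(sd$y), c(1, 3), sum)  # sampled occasions per site-year
    empty_sites <- rowSums(eff) == 0
    if (any(empty_sites))
      add("warning", sprintf(
        "site contributes nothing (all years missing): %s",
        paste(sd$site_ids[empty_sites], collapse = ", ")))
    if (any(colSums(eff) == 0))
      add("warning", "at least one year has zero effort at every site")
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(0), message = character(0),
               stringsAsFactors = FALSE)
}
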
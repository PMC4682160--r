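#' Log-spaced area grid from plot scale to reserve scale
#' @param plot_area_ha smallest area (ha).
#' @param reserve_ha largest area (ha).
#' @param n number of grid points.
#' @return numeric vector of areas.
#' @export
area_grid <- function(plot_area_ha = 0.09, reserve_ha = 8000, n = 200) {
  exp(seq(log(plot_area_ha), log(reserve_ha), length.out = n))
}

#' Linear richness reference between a reference taxon and a focal taxon
#'
#' Ordinary least squares of the focal taxon's model-predicted richness on
#' the reference (woody-plant role) taxon's, over paired predictions at
#' log-spaced areas up to `calibration_max_ha`. Extrapolating this line to
#' the reserve scale gives the "linear expectation" a practitioner would
#' form from small-scale data.
#'
#' @param reference,taxon `model_selection` objects with valid best fits.
#' @param calibration_max_ha upper end of the calibration range (ha).
#' @param plot_area_ha lower end of the calibration range.
#' @param n_calib_points number of calibration areas.
#' @return list: `slope`, `intercept`, `r_squared`, `calibration_areas`.
#' @export
linear_reference <- function(reference, taxon, calibration_max_ha = 1,
                             plot_area_ha = 0.09, n_calib_points = 20) {
  areas <- area_grid(plot_area_ha, calibration_max_ha, n_calib_points)
  rf <- reference$best_fit
  tf <- taxon$best_fit
  if (!.usable_best(reference) || !.usable_best(taxon))
    stop("both selections must have a valid best model")
  x <- evaluate_model(rf$model, rf$params, areas)
  y <- evaluate_model(tf$model, tf$params, areas)
  if (stats::sd(x) < 1e-10 * max(abs(x), 1))
    stop("reference predictions constant over the calibration range")
  ols <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(ols)[2]),
       intercept = unname(stats::coef(ols)[1]),
       r_squared = summary(ols)$r.squared,
       calibration_areas = areas)
}

#' Deviation of a taxon's richness from its linear reference prediction
#'
#' Compares the taxon's nonlinear (model-based) richness with the richness
#' predicted by extrapolating the small-scale linear relationship with the
#' reference taxon ([linear_reference()]) across the whole area grid.
#'
#' @inheritParams linear_reference
#' @param line result of [linear_reference()].
#' @param areas_ha areas at which to evaluate (default: full log grid to
#'   8,000 ha).
#' @return data.frame (`congruence_curve`): `taxon`, `area_ha`,
#'   `nonlinear_pred`, `linear_pred`, `deviation`, `deviation_pct`
#'   (percent of the nonlinear prediction).
#' @export
congruence_deviation <- function(reference, taxon, line,
                                 areas_ha = area_grid()) {
  rf <- reference$best_fit
  tf <- taxon$best_fit
  nl <- evaluate_model(tf$model, tf$params, areas_ha)
  lin <- line$intercept +
    line$slope * evaluate_model(rf$model, rf$params, areas_ha)
  out <- data.frame(taxon = taxon$taxon_name, area_ha = areas_ha,
                    nonlinear_pred = nl, linear_pred = lin,
                    deviation = nl - lin,
                    deviation_pct = 100 * (nl - lin) / nl,
                    stringsAsFactors = FALSE)
  class(out) <- c("congruence_curve", "data.frame")
  out
}

#' Relative richness profiles and cross-taxon percent deviation
#'
#' For each taxon, r_t(A) = S_hat_t(A) / gamma_hat_t (clipped to \[0, 1\])
#' expresses the fraction of the taxon's overall estimated richness
#' attained by area A. D_t(A) = 100 * (r_t(A) - rbar(A)) / rbar(A) is the
#' percent deviation from the cross-taxon mean profile: positive for taxa
#' that accumulate their richness at smaller scales than the average
#' (low-turnover, bacteria-like), negative for late accumulators
#' (high-turnover, lepidopteran-like).
#'
#' @param selections named list of `model_selection` objects (>= 2 taxa).
#' @param gamma_hats named vector of overall richness estimates, one per
#'   taxon (the selected model evaluated at the reserve scale).
#' @param areas_ha evaluation grid.
#' @param percent_of_mean if `FALSE`, D is reported in percentage points
#'   (100 * (r_t - rbar)) instead of percent of the mean.
#' @return data.frame: `taxon`, `area_ha`, `relative_richness`,
#'   `mean_relative_richness`, `deviation_pct`.
#' @export
relative_profiles <- function(selections, gamma_hats,
                              areas_ha = area_grid(),
                              percent_of_mean = TRUE) {
  if (length(selections) < 2) stop("need >= 2 taxa")
  taxa <- names(selections)
  if (is.null(taxa) || !all(taxa %in% names(gamma_hats)))
    stop("selections and gamma_hats must be named consistently")
  r <- vapply(taxa, function(t) {
    f <- selections[[t]]$best_fit
    pmin(pmax(evaluate_model(f$model, f$params, areas_ha) /
                gamma_hats[[t]], 0), 1)
  }, numeric(length(areas_ha)))
  r <- matrix(r, nrow = length(areas_ha), dimnames = list(NULL, taxa))
  rbar <- rowMeans(r)
  if (any(rbar == 0))
    stop("mean relative richness is zero at some grid point; start the ",
         "grid at the plot scale")
  dev <- if (percent_of_mean) 100 * (r - rbar) / rbar else 100 * (r - rbar)
  out <- data.frame(
    taxon = rep(taxa, each = length(areas_ha)),
    area_ha = rep(areas_ha, length(taxa)),
    relative_richness = as.vector(r),
    mean_relative_richness = rep(rbar, length(taxa)),
    deviation_pct = as.vector(dev),
    stringsAsFactors = FALSE)
  class(out) <- c("relative_richness_profile", "data.frame")
  out
}
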
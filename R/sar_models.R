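#' The eight species-area model forms
#'
#' Catalogue of the functional forms fitted to accumulation curves. `S` is
#' expected richness, `A` area in hectares. Asymptotic forms imply a finite
#' regional richness; the power and (semi-log) exponential forms do not.
#'
#' \describe{
#'   \item{power}{S = c * A^z (2 params)}
#'   \item{exponential}{S = c + z * log(A) (2 params, natural log)}
#'   \item{negexpo}{S = d * (1 - exp(-z * A)) (2 params, asymptote d)}
#'   \item{monod}{S = d * A / (c + A) (2 params, asymptote d)}
#'   \item{rational}{S = (c + z * A) / (1 + d * A) (3 params, asymptote z/d)}
#'   \item{logistic}{S = d / (1 + exp(-z * A + c)) (3 params, asymptote d)}
#'   \item{lomolino}{S = d / (1 + f^log10(z / A)) (3 params, asymptote d;
#'     z is the area of half-saturation, log base 10)}
#'   \item{weibull}{S = d * (1 - exp(-c * A^z)) (3 params, asymptote d)}
#' }
#'
#' Parameter bounds used in fitting: c > 0, z > 0, d > 0, f > 1.
#'
#' @return data.frame with columns `name`, `n_params`, `asymptotic`.
#' @export
sar_model_specs <- function() {
  data.frame(
    name = c("power", "exponential", "negexpo", "monod",
             "rational", "logistic", "lomolino", "weibull"),
    n_params = c(2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L),
    asymptotic = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

.sar_param_names <- list(
  power = c("c", "z"), exponential = c("c", "z"),
  negexpo = c("d", "z"), monod = c("d", "c"),
  rational = c("c", "z", "d"), logistic = c("d", "z", "c"),
  lomolino = c("d", "z", "f"), weibull = c("d", "c", "z"))

#' Evaluate a species-area model
#'
#' @param model model name; one of [sar_model_specs()]`$name`.
#' @param params named numeric vector with the model's parameters (see
#'   [sar_model_specs()] for names).
#' @param area_ha positive area(s) in hectares; vectorised.
#' @return expected richness S(A).
#' @export
evaluate_model <- function(model, params, area_ha) {
  need <- .sar_param_names[[model]]
  if (is.null(need)) stop("unknown model '", model, "'")
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  if (any(area_ha <= 0)) stop("area_ha must be positive")
  p <- as.list(params[need])
  A <- area_ha
  switch(model,
    power       = p$c * A^p$z,
    exponential = p$c + p$z * log(A),
    negexpo     = p$d * (1 - exp(-p$z * A)),
    monod       = p$d * A / (p$c + A),
    rational    = (p$c + p$z * A) / (1 + p$d * A),
    logistic    = p$d / (1 + exp(-p$z * A + p$c)),
    lomolino    = p$d / (1 + p$f^(log10(p$z / A))),
    weibull     = p$d * (1 - exp(-p$c * A^p$z)))
}

#' Theoretical asymptote of an asymptotic model, NA otherwise
#' @inheritParams evaluate_model
#' @return the model's limiting richness as area grows, or `NA`.
#' @export
model_asymptote <- function(model, params) {
  switch(model,
    negexpo = , monod = , logistic = , lomolino = ,
    weibull = unname(params["d"]),
    rational = unname(params["z"] / params["d"]),
    NA_real_)
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = n * ln(RSS/n) + 2K + 2K(K+1)/(n - K - 1), with K the number of
#' fitted parameters plus one for the error variance.
#'
#' @param rss residual sum of squares (> 0; exactly 0 returns `-Inf` with
#'   a warning, flagging a perfect fit).
#' @param n_points number of fitted points.
#' @param n_params number of model parameters (error variance added
#'   internally).
#' @return the AICc value.
#' @export
aicc <- function(rss, n_points, n_params) {
  K <- n_params + 1
  if (n_points - K - 1 <= 0)
    stop("AICc undefined: need n_points > n_params + 2")
  if (rss < 0) stop("rss must be non-negative")
  if (rss == 0) {
    warning("rss = 0: perfect fit, AICc = -Inf")
    return(-Inf)
  }
  n_points * log(rss / n_points) + 2 * K + 2 * K * (K + 1) / (n_points - K - 1)
}

# deterministic multi-start grids, scaled by the data ranges
.sar_start_grid <- function(model, A, S) {
  maxS <- max(S); maxA <- max(A)
  minS <- max(min(S), 1e-3)
  d_grid <- c(1, 1.5, 3) * maxS
  grid <- switch(model,
    power = expand.grid(c = c(0.1, 0.5, 1, 2, 5) * maxS,
                        z = c(0.1, 0.5, 1, 2)),
    exponential = {
      ols <- stats::coef(stats::lm(S ~ log(A)))
      rbind(data.frame(c = max(ols[1], 1e-3), z = max(ols[2], 1e-3)),
            expand.grid(c = c(0.5, 1) * maxS,
                        z = c(0.1, 0.5, 1) * maxS))
    },
    negexpo = expand.grid(d = d_grid, z = c(0.1, 0.5, 1, 2, 5) / maxA),
    monod = expand.grid(d = d_grid, c = c(0.1, 0.5, 1, 2, 5) * maxA),
    rational = {
      g <- expand.grid(asym = d_grid, d = c(0.1, 0.5, 1, 2, 5) / maxA,
                       c = c(0.1, 1) * minS)
      data.frame(c = g$c, z = g$asym * g$d, d = g$d)
    },
    logistic = {
      g <- expand.grid(d = d_grid, z = c(1, 2, 5, 10) / maxA,
                       mid = c(0.25, 0.5) * maxA)
      data.frame(d = g$d, z = g$z, c = g$z * g$mid)
    },
    lomolino = expand.grid(d = d_grid, z = c(0.1, 0.5, 1, 2, 5) * maxA,
                           f = c(1.5, 5, 10)),
    weibull = expand.grid(d = d_grid, c = c(0.1, 0.5, 1, 2, 5) / maxA,
                          z = c(0.5, 1, 2)),
    stop("unknown model '", model, "'"))
  grid[.sar_param_names[[model]]]
}

.sar_lower <- function(model) {
  eps <- 1e-8
  lw <- rep(eps, length(.sar_param_names[[model]]))
  names(lw) <- .sar_param_names[[model]]
  if (model == "lomolino") lw["f"] <- 1 + eps
  lw
}

# Levenberg-Marquardt least squares from a set of starts; best RSS among
# converged starts wins.  Seed-free and deterministic.
.fit_sar_engine <- function(model, A, S, starts) {
  lower <- .sar_lower(model)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- pmax(unlist(starts[i, , drop = TRUE]), lower)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = par0,
        lower = lower,
        fn = function(p) S - evaluate_model(model, p, A),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(params = stats::setNames(unname(fit$par),
                                            names(par0)),
                   rss = rss)
  }
  if (is.null(best))
    return(list(params = NULL, rss = NA_real_, converged = FALSE))
  c(best, list(converged = TRUE))
}

#' Fit one species-area model to an accumulation curve
#'
#' Unweighted least squares of mean richness against cumulative area, by
#' deterministic multi-start Levenberg-Marquardt minimisation (the start
#' grid is scaled from the data ranges, so fitting needs no seed).
#' Residual validation ([validate_fit()]) is applied to the converged fit.
#'
#' @param model model name from [sar_model_specs()].
#' @param curve an `accumulation_curve`.
#' @param alpha significance level of the residual-validation tests.
#' @return a `sar_fit` list: `model`, `params`, `rss`, `n_points`, `K`,
#'   `aicc`, `converged`, `residuals_normal`, `normality_p`,
#'   `homoscedastic`, `homoscedasticity_p`, `valid`.
#' @export
fit_model <- function(model, curve, alpha = 0.05) {
  np <- sar_model_specs()$n_params[sar_model_specs()$name == model]
  if (!length(np)) stop("unknown model '", model, "'")
  if (nrow(curve) < np + 2)
    stop("curve has ", nrow(curve), " points; need >= ", np + 2)
  A <- curve$area_ha
  S <- curve$mean_richness
  eng <- .fit_sar_engine(model, A, S, .sar_start_grid(model, A, S))
  n <- length(A)
  fit <- list(model = model, params = eng$params, rss = eng$rss,
              n_points = n, K = np + 1L,
              aicc = NA_real_, converged = eng$converged,
              residuals_normal = NA, normality_p = NA_real_,
              homoscedastic = NA, homoscedasticity_p = NA_real_,
              valid = FALSE)
  class(fit) <- "sar_fit"
  if (!eng$converged) return(fit)
  fit$aicc <- if (eng$rss == 0) {
    warning("rss = 0: perfect fit, AICc = -Inf")
    -Inf
  } else aicc(eng$rss, n, np)
  fit$fitted <- evaluate_model(model, eng$params, A)
  fit$residuals <- S - fit$fitted
  validate_fit(fit, alpha = alpha)
}

#' @export
print.sar_fit <- function(x, ...) {
  cat("sar_fit '", x$model, "': ", sep = "")
  if (!x$converged) {
    cat("did not converge\n")
  } else {
    cat(paste(names(x$params), signif(x$params, 4), sep = "=",
              collapse = ", "),
        "; RSS=", signif(x$rss, 4), ", AICc=", signif(x$aicc, 5),
        ", valid=", x$valid, "\n", sep = "")
  }
  invisible(x)
}

#' Residual validation of a fitted species-area model
#'
#' Flags fits whose residuals are non-normal (Lilliefors test) or
#' heteroscedastic (Pearson correlation test between absolute residuals
#' and fitted values). A model failing either check is excluded from the
#' AICc competition. Degenerate cases — fewer than 5 residuals, or an
#' (essentially) perfect fit with no residual variance — skip the tests
#' and pass, with a message.
#'
#' @param fit a converged `sar_fit`.
#' @param alpha significance level; flags pass when p >= alpha.
#' @return the `sar_fit` with validation fields filled and `valid`
#'   updated (`valid = converged & residuals_normal & homoscedastic`).
#' @export
validate_fit <- function(fit, alpha = 0.05) {
  if (!fit$converged) stop("cannot validate a fit that did not converge")
  r <- fit$residuals
  scale <- max(abs(fit$fitted), 1)
  if (length(r) < 5 || stats::sd(r) < 1e-8 * scale) {
    message("residual validation skipped (", length(r),
            " residuals, sd ", signif(stats::sd(r), 3), "): flags pass")
    fit$residuals_normal <- TRUE
    fit$homoscedastic <- TRUE
  } else {
    fit$normality_p <- nortest::lillie.test(r)$p.value
    fit$residuals_normal <- fit$normality_p >= alpha
    ct <- suppressWarnings(stats::cor.test(abs(r), fit$fitted,
                                           method = "pearson"))
    fit$homoscedasticity_p <- ct$p.value
    fit$homoscedastic <- fit$homoscedasticity_p >= alpha
  }
  fit$valid <- fit$converged && fit$residuals_normal && fit$homoscedastic
  fit
}

#' Fit all eight species-area models to a curve
#' @inheritParams fit_model
#' @return named list of `sar_fit` objects (one per form).
#' @export
fit_all_models <- function(curve, alpha = 0.05) {
  specs <- sar_model_specs()
  fits <- lapply(specs$name, function(m)
    suppressMessages(suppressWarnings(fit_model(m, curve, alpha = alpha))))
  names(fits) <- specs$name
  fits
}

#' AICc model selection among validated fits
#'
#' The winner is the valid (converged, normal, homoscedastic) fit with the
#' lowest AICc; ties are broken by lower RSS, then by model-name order.
#' `unambiguous` records whether every other valid fit trails by more than
#' `threshold` AICc units.
#'
#' With `fallback = TRUE` (used by the pipeline), a curve for which the
#' validation step excludes every converged form — typical of strongly
#' saturating taxa whose residual variance collapses near the asymptote,
#' where the tests reject on numerical noise — falls back to AICc
#' competition among all converged fits instead of erroring; the result
#' carries `fallback = TRUE` so downstream tables can flag it.
#'
#' @param fits named list of `sar_fit` objects (e.g. [fit_all_models()]).
#' @param threshold delta-AICc cutoff for an unambiguous winner.
#' @param taxon_name label carried into the result.
#' @param fallback if `TRUE`, compete among converged fits when no fit
#'   passes validation (default errors).
#' @return a `model_selection` list: `taxon_name`, `fits`, `best`,
#'   `best_fit`, `delta_aicc`, `unambiguous`, `fallback`.
#' @export
select_model <- function(fits, threshold = 2, taxon_name = "taxon",
                         fallback = FALSE) {
  valid <- vapply(fits, function(f) isTRUE(f$valid), logical(1))
  used_fallback <- FALSE
  if (!any(valid)) {
    conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    if (!fallback || !any(conv))
      stop("no admissible model: all fits invalid")
    message("no fit passed residual validation for '", taxon_name,
            "'; falling back to AICc among converged fits")
    valid <- conv
    used_fallback <- TRUE
  }
  av <- vapply(seq_along(fits), function(i)
    if (valid[i]) fits[[i]]$aicc else NA_real_, numeric(1))
  rssv <- vapply(seq_along(fits), function(i)
    if (valid[i]) fits[[i]]$rss else NA_real_, numeric(1))
  ord <- order(av, rssv, names(fits), na.last = TRUE)
  best <- names(fits)[ord[1]]
  delta <- av - av[ord[1]]
  # -Inf best (perfect fit) leaves finite competitors at +Inf delta
  delta[is.nan(delta)] <- 0
  others <- delta[valid & names(fits) != best]
  unambiguous <- if (length(others)) min(others) > threshold else TRUE
  structure(list(taxon_name = taxon_name, fits = fits, best = best,
                 best_fit = fits[[best]], delta_aicc = delta,
                 unambiguous = unambiguous, fallback = used_fallback),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("model_selection '", x$taxon_name, "': best = ", x$best,
      if (x$unambiguous) " (unambiguous)" else " (ambiguous)", "\n",
      sep = "")
  invisible(x)
}

# a selection is usable downstream if its best fit passed validation, or
# converged and was chosen by the documented fallback rule
.usable_best <- function(selection) {
  isTRUE(selection$best_fit$valid) ||
    (isTRUE(selection$fallback) && isTRUE(selection$best_fit$converged))
}

#' Summary table of a model selection
#' @param object a `model_selection`.
#' @param ... unused.
#' @return data.frame with one row per model form.
#' @export
summary.model_selection <- function(object, ...) {
  data.frame(
    taxon = object$taxon_name,
    model = names(object$fits),
    converged = vapply(object$fits, `[[`, logical(1), "converged"),
    rss = vapply(object$fits, function(f)
      if (f$converged) f$rss else NA_real_, numeric(1)),
    aicc = vapply(object$fits, function(f)
      if (f$converged) f$aicc else NA_real_, numeric(1)),
    delta_aicc = object$delta_aicc,
    valid = vapply(object$fits, function(f) isTRUE(f$valid), logical(1)),
    best = names(object$fits) == object$best,
    unambiguous = object$unambiguous,
    row.names = NULL, stringsAsFactors = FALSE)
}

# plot-level bootstrap: resample plots with replacement, rebuild the exact
# accumulation curve, refit the selected form (warm start at the point
# estimate, grid fallback), and hand the refitted params plus the
# replicate curve to `fun`.  Returns a list of fun() results, NULL where
# the refit failed.
.bootstrap_refit <- function(cm, model, point_params, n_bootstrap, seed,
                             mean_plot_area_ha, fun) {
  P <- n_plots(cm)
  with_seed(seed, {
    lapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(P, replace = TRUE)
      bcm <- community_matrix(cm$counts[idx, , drop = FALSE],
                              plot_ids = paste0("b", seq_len(P)),
                              species_ids = cm$species_ids,
                              taxon_name = cm$taxon_name, mode = cm$mode)
      bc <- accumulate_exact(bcm, mean_plot_area_ha = mean_plot_area_ha)
      A <- bc$area_ha; S <- bc$mean_richness
      # warm start at the point estimate; full grid only on failure
      eng <- .fit_sar_engine(model, A, S,
                             as.data.frame(as.list(point_params)))
      if (!eng$converged)
        eng <- .fit_sar_engine(model, A, S, .sar_start_grid(model, A, S))
      if (!eng$converged) return(NULL)
      fun(eng$params, bc)
    })
  })
}

#' Extrapolate richness to a target area with bootstrap confidence bands
#'
#' Evaluates the selected model at `area_ha`. Confidence intervals come
#' from a nonparametric bootstrap over plots: plots are resampled with
#' replacement, the exact accumulation curve rebuilt, the selected model
#' form refitted, and the richness re-evaluated. Because a resample holds
#' fewer unique plots than the original design, replicate richness is
#' systematically biased low; the 2.5/97.5 replicate percentiles are
#' therefore recentred at the point estimate (bias-corrected percentile
#' interval: the replicate mean's offset from the point estimate is
#' subtracted from both bounds).
#'
#' @param selection a `model_selection` with a valid best fit.
#' @param area_ha target area(s) in hectares.
#' @param cm the `community_matrix` behind the curve; required for the
#'   bootstrap (omit or set `n_bootstrap = 0` for point estimates only).
#' @param reference_area_ha area whose estimate normalises
#'   `fraction_of_reference` (the "reserve" scale).
#' @param n_bootstrap bootstrap replicates.
#' @param seed integer seed for the bootstrap resampling.
#' @param mean_plot_area_ha plot area used when rebuilding bootstrap
#'   curves.
#' @return data.frame (`richness_estimate`) with one row per target area:
#'   `taxon`, `model`, `area_ha`, `richness`, `ci_low`, `ci_high`,
#'   `fraction_of_reference`.
#' @export
extrapolate <- function(selection, area_ha, cm = NULL,
                        reference_area_ha = 8000, n_bootstrap = 0,
                        seed = 1L, mean_plot_area_ha = 0.09) {
  fit <- selection$best_fit
  if (!.usable_best(selection)) stop("selection has no valid best model")
  pred <- evaluate_model(fit$model, fit$params, area_ha)
  ref <- evaluate_model(fit$model, fit$params, reference_area_ha)
  out <- data.frame(taxon = selection$taxon_name, model = fit$model,
                    area_ha = area_ha, richness = pred,
                    ci_low = NA_real_, ci_high = NA_real_,
                    fraction_of_reference = pred / ref,
                    stringsAsFactors = FALSE)
  if (n_bootstrap > 0 && !is.null(cm)) {
    reps <- .bootstrap_refit(cm, fit$model, fit$params, n_bootstrap, seed,
                             mean_plot_area_ha,
                             function(p, ...) evaluate_model(fit$model, p, area_ha))
    ok <- !vapply(reps, is.null, logical(1))
    if (mean(ok) < 0.5) {
      warning("bootstrap refit failed in ", sum(!ok), "/", length(reps),
              " replicates; CI omitted")
    } else {
      mat <- do.call(rbind, reps[ok])
      bias <- colMeans(mat) - pred
      out$ci_low <- apply(mat, 2, stats::quantile, probs = 0.025) - bias
      out$ci_high <- apply(mat, 2, stats::quantile, probs = 0.975) - bias
    }
  }
  class(out) <- c("richness_estimate", "data.frame")
  out
}
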
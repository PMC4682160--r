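#' Additive turnover partition of estimated overall richness
#'
#' Decomposes the model-estimated richness of the reference area (gamma)
#' into the mean observed per-plot richness (alpha) plus effective species
#' turnover (beta) between successive nested area scales:
#' gamma = alpha_plot + beta_plot + beta_s2 + ... + beta_reserve,
#' where beta_plot is the gap between the fitted curve at one plot's area
#' and observed alpha, and each further beta is the fitted-curve increment
#' between adjacent scales.
#'
#' Small negative components (possible from model lack-of-fit near the
#' origin) are clipped to zero with the deficit carried into the next
#' larger scale, so the additive identity holds exactly.
#'
#' @param selection a `model_selection` with a valid best model.
#' @param curve the `accumulation_curve` the model was fitted to; its k=1
#'   value supplies observed alpha.
#' @param scales_ha strictly increasing areas; the first is the plot
#'   scale, the last the reference ("reserve") area.
#' @param plot_area_ha true mean plot area at which the fitted curve is
#'   evaluated for beta_plot (the first element of `scales_ha` is treated
#'   as the nominal label of that scale).
#' @return a `turnover_partition` list: `taxon_name`, `gamma_hat`,
#'   `alpha_plot`, `components` (named absolute betas), `relative`
#'   (components / gamma, including the alpha share), `ci` (NULL until
#'   [partition_ci()]), `clipped` (logical, any clipping applied).
#' @export
partition_turnover <- function(selection, curve, scales_ha = c(0.1, 0.5, 1, 10, 8000),
                               plot_area_ha = 0.09) {
  fit <- selection$best_fit
  if (!.usable_best(selection)) stop("selection has no valid best model")
  if (any(diff(scales_ha) <= 0)) stop("scales_ha must be strictly increasing")
  alpha <- curve$mean_richness[curve$k == 1]
  if (!length(alpha)) stop("curve lacks a k = 1 point")
  eval_areas <- c(plot_area_ha, scales_ha[-1])
  S_hat <- evaluate_model(fit$model, fit$params, eval_areas)
  non_mono <- which(diff(S_hat) < -1e-9 * max(abs(S_hat)))
  if (length(non_mono))
    stop("fitted curve decreases between scales ",
         scales_ha[non_mono[1]], " and ", scales_ha[non_mono[1] + 1], " ha")
  gamma <- S_hat[length(S_hat)]
  comps <- c(S_hat[1] - alpha, diff(S_hat))
  names(comps) <- c("plot", paste0(scales_ha[-1], "_ha"))
  names(comps)[length(comps)] <- "reserve"
  # clip negatives, deficit absorbed by the adjacent larger scale
  clipped <- FALSE
  for (i in seq_along(comps)) {
    if (comps[i] < 0) {
      clipped <- TRUE
      if (i < length(comps)) {
        comps[i + 1] <- comps[i + 1] + comps[i]
        comps[i] <- 0
      } else {
        # last scale under-shot: absorb into alpha to preserve additivity
        alpha <- alpha + comps[i]
        comps[i] <- 0
      }
    }
  }
  if (clipped)
    message("negative turnover component(s) clipped for '",
            selection$taxon_name, "'")
  structure(list(
    taxon_name = selection$taxon_name,
    gamma_hat = gamma, alpha_plot = alpha,
    components = comps,
    relative = c(alpha_plot = unname(alpha / gamma), comps / gamma),
    ci = NULL, clipped = clipped), class = "turnover_partition")
}

#' @export
print.turnover_partition <- function(x, ...) {
  cat("turnover_partition '", x$taxon_name, "': gamma = ",
      round(x$gamma_hat, 1), ", alpha_plot = ", round(x$alpha_plot, 1),
      "\n  beta: ", paste(names(x$components),
                          round(x$components, 1), sep = "=",
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Bootstrap confidence intervals for a turnover partition
#'
#' Plot-level bootstrap (as in [extrapolate()]): each replicate resamples
#' plots with replacement, rebuilds the exact accumulation curve, refits
#' the selected model form, and re-derives the full partition. Percentile
#' 2.5/97.5 intervals are attached per component; the replicate component
#' matrix is kept in attribute `"replicates"` (each row sums to that
#' replicate's gamma).
#'
#' @inheritParams partition_turnover
#' @param cm the `community_matrix` behind the curve.
#' @param n_bootstrap bootstrap replicates.
#' @param seed integer seed.
#' @return the `turnover_partition` with `ci` filled (matrix, rows
#'   `alpha_plot` + components, columns `low`/`high`).
#' @export
partition_ci <- function(selection, curve, cm,
                         scales_ha = c(0.1, 0.5, 1, 10, 8000),
                         plot_area_ha = 0.09, n_bootstrap = 200, seed = 1L) {
  part <- partition_turnover(selection, curve, scales_ha, plot_area_ha)
  fit <- selection$best_fit
  model <- fit$model
  reps <- .bootstrap_refit(
    cm, model, fit$params, n_bootstrap, seed, plot_area_ha,
    function(p, curve_b) {
      sel_b <- structure(
        list(taxon_name = part$taxon_name,
             best_fit = list(model = model, params = p, valid = TRUE)),
        class = "model_selection")
      tryCatch(
        suppressMessages(partition_turnover(sel_b, curve_b, scales_ha,
                                            plot_area_ha)),
        error = function(e) NULL)
    })
  rows <- list()
  for (p_b in reps) {
    if (is.null(p_b)) next
    rows[[length(rows) + 1]] <- c(alpha_plot = p_b$alpha_plot,
                                  gamma_hat = p_b$gamma_hat,
                                  p_b$components)
  }
  if (length(rows) < n_bootstrap / 2) {
    warning("bootstrap partition failed in most replicates; CI omitted")
    return(part)
  }
  mat <- do.call(rbind, rows)
  ci <- t(apply(mat, 2, stats::quantile, probs = c(0.025, 0.975)))
  colnames(ci) <- c("low", "high")
  # recentre at the point estimates (replicates are biased low because a
  # resample holds fewer unique plots; see extrapolate()); components stay
  # non-negative
  point <- c(alpha_plot = part$alpha_plot, gamma_hat = part$gamma_hat,
             part$components)
  bias <- colMeans(mat) - point[colnames(mat)]
  ci <- pmax(ci - cbind(bias, bias), 0)
  part$ci <- ci
  attr(part, "replicates") <- mat
  part
}

#' Tidy table of a turnover partition
#' @param part a `turnover_partition`.
#' @return data.frame: taxon, component, absolute, relative, ci_low,
#'   ci_high.
#' @export
partition_table <- function(part) {
  comp <- c(alpha_plot = unname(part$alpha_plot), part$components)
  ci <- part$ci
  data.frame(
    taxon = part$taxon_name,
    component = names(comp),
    absolute = unname(comp),
    relative = unname(comp / part$gamma_hat),
    ci_low = if (is.null(ci)) NA_real_ else ci[names(comp), "low"],
    ci_high = if (is.null(ci)) NA_real_ else ci[names(comp), "high"],
    row.names = NULL, stringsAsFactors = FALSE)
}
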
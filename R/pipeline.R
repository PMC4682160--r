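#' Run the full multi-taxon diversity-scaling analysis
#'
#' Per taxon: permutation accumulation curve, eight-model species-area
#' fit with AICc selection, richness extrapolation to the configured
#' scales, additive turnover partition, and (abundance matrices only)
#' sample-coverage profile. Across taxa: linear-reference congruence
#' against the configured reference taxon and relative-richness
#' deviation profiles. One taxon's failure is isolated: it lands in the
#' failure table and the remaining taxa complete.
#'
#' @param matrices named list of `community_matrix` objects (abundance
#'   mode; incidence is derived internally for accumulation).
#' @param plots a [plot_table()] covering all matrices' plots.
#' @param config a [run_config()].
#' @param reference_taxon name of the taxon playing the woody-plant role
#'   in the congruence stage; `NULL` skips that stage with a warning.
#' @param coverage_ks pool sizes for the coverage profile; `NULL` skips
#'   coverage.
#' @param out_dir optional directory; stage tables and a JSON manifest
#'   are written there as tab-separated text.
#' @return a `pipeline_result` list: `selection` (table), `estimates`,
#'   `partitions`, `profiles`, `congruence`, `coverage`, `failures`,
#'   `objects` (per-taxon fitted objects), `config`.
#' @export
run_pipeline <- function(matrices, plots, config = run_config(),
                         reference_taxon = NULL, coverage_ks = NULL,
                         out_dir = NULL) {
  ds <- align_dataset(matrices, plots)
  matrices <- ds$matrices
  mean_area <- mean(plots$plot_area_ha)
  scales <- config$nominal_scales_ha
  reserve <- scales[length(scales)]
  failures <- data.frame(taxon = character(), stage = character(),
                         reason = character(), stringsAsFactors = FALSE)
  objects <- list()
  sel_rows <- list(); est_rows <- list(); part_rows <- list()
  cov_rows <- list()
  for (nm in names(matrices)) {
    cm <- matrices[[nm]]
    res <- tryCatch({
      if (sum(cm$counts) == 0)
        stop("taxon '", nm, "' has no occurrences")
      curve <- accumulate_permutation(cm, config$n_permutations,
                                      seed = config$rng_seed,
                                      mean_plot_area_ha = mean_area)
      fits <- fit_all_models(curve, alpha = config$validation_alpha)
      sel <- select_model(fits, threshold = config$aicc_delta_threshold,
                          taxon_name = nm, fallback = TRUE)
      est <- extrapolate(sel, area_ha = scales, cm = cm,
                         reference_area_ha = reserve,
                         n_bootstrap = config$n_bootstrap,
                         seed = config$rng_seed,
                         mean_plot_area_ha = mean_area)
      part <- if (config$n_bootstrap > 0) {
        partition_ci(sel, curve, cm, scales_ha = scales,
                     plot_area_ha = mean_area,
                     n_bootstrap = config$n_bootstrap,
                     seed = config$rng_seed)
      } else {
        partition_turnover(sel, curve, scales_ha = scales,
                           plot_area_ha = mean_area)
      }
      list(curve = curve, selection = sel, estimate = est, partition = part)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(taxon = nm, stage = "fit",
                                   reason = conditionMessage(res),
                                   stringsAsFactors = FALSE))
      next
    }
    objects[[nm]] <- res
    sel_rows[[nm]] <- summary(res$selection)
    est_rows[[nm]] <- as.data.frame(res$estimate)
    part_rows[[nm]] <- partition_table(res$partition)
    if (!is.null(coverage_ks) && cm$mode == "abundance") {
      cov <- tryCatch(
        coverage_profile(cm, ks = coverage_ks,
                         max_combinations = config$max_combinations,
                         seed = config$rng_seed),
        error = function(e) e)
      if (inherits(cov, "error")) {
        failures <- rbind(failures,
                          data.frame(taxon = nm, stage = "coverage",
                                     reason = conditionMessage(cov),
                                     stringsAsFactors = FALSE))
      } else cov_rows[[nm]] <- cov
    }
  }
  if (!length(objects)) stop("every taxon failed; nothing to report")
  gammas <- vapply(objects, function(o) o$partition$gamma_hat, numeric(1))
  grid <- area_grid(mean_area, reserve)
  selections <- lapply(objects, `[[`, "selection")
  profiles <- if (length(objects) >= 2) {
    relative_profiles(selections, gammas, areas_ha = grid)
  } else NULL
  congruence <- NULL
  if (is.null(reference_taxon)) {
    warning("no reference taxon configured; congruence stage skipped")
  } else if (!reference_taxon %in% names(objects)) {
    warning("reference taxon '", reference_taxon,
            "' unavailable; congruence stage skipped")
  } else {
    ref_sel <- objects[[reference_taxon]]$selection
    cong <- list()
    for (nm in setdiff(names(objects), reference_taxon)) {
      cc <- tryCatch({
        line <- linear_reference(ref_sel, objects[[nm]]$selection,
                                 plot_area_ha = mean_area)
        congruence_deviation(ref_sel, objects[[nm]]$selection, line,
                             areas_ha = grid)
      }, error = function(e) e)
      if (inherits(cc, "error")) {
        failures <- rbind(failures,
                          data.frame(taxon = nm, stage = "congruence",
                                     reason = conditionMessage(cc),
                                     stringsAsFactors = FALSE))
      } else cong[[nm]] <- cc
    }
    congruence <- if (length(cong)) do.call(rbind, cong) else NULL
  }
  result <- structure(list(
    selection = do.call(rbind, c(sel_rows, list(make.row.names = FALSE))),
    estimates = do.call(rbind, c(est_rows, list(make.row.names = FALSE))),
    partitions = do.call(rbind, c(part_rows, list(make.row.names = FALSE))),
    profiles = profiles, congruence = congruence,
    coverage = if (length(cov_rows))
      do.call(rbind, c(cov_rows, list(make.row.names = FALSE))) else NULL,
    failures = failures, objects = objects, config = config),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result: ", length(x$objects), " taxa analysed, ",
      nrow(x$failures), " stage failure(s)\n", sep = "")
  invisible(x)
}

#' Write all stage tables of a pipeline result
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("selection", "estimates", "partitions", "profiles",
            "congruence", "coverage", "failures")
  for (tb in tabs) {
    if (is.null(result[[tb]])) next
    utils::write.table(result[[tb]],
                       file.path(out_dir, paste0(tb, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    seed = result$config$rng_seed,
    config = unclass(result$config),
    n_taxa = length(result$objects),
    r_version = as.character(getRversion()),
    written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Load a study (matrices + plot table) from a directory
#' @param dir directory of `*.tsv` matrices, a `plots.tsv` table (as
#'   written by [simulate_study()]).
#' @return list: `matrices`, `plots`.
#' @export
load_study <- function(dir) {
  plots <- read_plot_table(file.path(dir, "plots.tsv"))
  files <- setdiff(list.files(dir, pattern = "\\.tsv$", full.names = TRUE),
                   file.path(dir, "plots.tsv"))
  if (!length(files)) stop("no taxon matrices found in ", dir)
  matrices <- lapply(files, read_community_matrix)
  names(matrices) <- vapply(matrices, function(m) m$taxon_name, character(1))
  list(matrices = matrices, plots = plots)
}

#' Distance-sensitivity rerun on a spatially reduced plot subset
#'
#' Re-runs the accumulation + fit + extrapolation chain on a subset of
#' plots (typically [core_subset()]'s spatially compact core) and reports
#' the change in the fraction of reference-scale richness attained at the
#' focal areas, per taxon and on average.
#'
#' @param full a `pipeline_result` from [run_pipeline()].
#' @param matrices,plots the inputs the full run used.
#' @param subset_ids plot ids to retain.
#' @param focal_areas_ha areas at which fractions are compared.
#' @return list: `per_taxon` (data.frame of fractions and deltas),
#'   `mean_delta` (named by focal area), `mean_distance_km` of the
#'   subset.
#' @export
compare_subset <- function(full, matrices, plots, subset_ids,
                           focal_areas_ha = c(1, 10)) {
  config <- full$config
  if (length(subset_ids) < 6)
    stop("subset too small to fit three-parameter models")
  sub_plots <- plots[plots$plot_id %in% subset_ids, , drop = FALSE]
  mean_area <- mean(sub_plots$plot_area_ha)
  reserve <- max(config$nominal_scales_ha)
  rows <- list()
  for (nm in names(full$objects)) {
    cm <- subset_plots(matrices[[nm]], sub_plots$plot_id)
    res <- tryCatch({
      curve <- accumulate_permutation(cm, config$n_permutations,
                                      seed = config$rng_seed,
                                      mean_plot_area_ha = mean_area)
      fits <- fit_all_models(curve, alpha = config$validation_alpha)
      sel <- select_model(fits, threshold = config$aicc_delta_threshold,
                          taxon_name = nm, fallback = TRUE)
      extrapolate(sel, area_ha = focal_areas_ha,
                  reference_area_ha = reserve)
    }, error = function(e) NULL)
    if (is.null(res)) next
    full_est <- full$estimates[full$estimates$taxon == nm &
                                 full$estimates$area_ha %in% focal_areas_ha, ]
    full_frac <- full_est$fraction_of_reference[
      match(focal_areas_ha, full_est$area_ha)]
    rows[[nm]] <- data.frame(
      taxon = nm, area_ha = focal_areas_ha,
      fraction_full = full_frac,
      fraction_subset = res$fraction_of_reference,
      delta = res$fraction_of_reference - full_frac,
      stringsAsFactors = FALSE)
  }
  per_taxon <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  mean_delta <- tapply(per_taxon$delta, per_taxon$area_ha, mean)
  list(per_taxon = per_taxon, mean_delta = mean_delta,
       mean_distance_km = mean_pairwise_distance(plots, subset_ids))
}
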
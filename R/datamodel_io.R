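#' Construct a community matrix for one taxon
#'
#' The atomic input of every analysis stage: a plot-by-species table of
#' counts (abundance mode) or presences (incidence mode). Rows are plots,
#' columns are species or OTUs. All-zero species columns are legal and are
#' preserved on round-trip so that species pools can be carried through
#' subsetting operations.
#'
#' @param counts integer matrix, plots x species, non-negative.
#' @param plot_ids character vector of unique plot identifiers (rows).
#' @param species_ids character vector of unique species identifiers (columns).
#' @param taxon_name label for the taxon the matrix describes.
#' @param mode `"abundance"` (counts) or `"incidence"` (0/1). In incidence
#'   mode any positive count is coerced to 1; the coercion is reported via
#'   `message()` because it is a lossy step (coverage estimation needs the
#'   original abundances).
#' @return an object of class `community_matrix`.
#' @export
community_matrix <- function(counts, plot_ids = rownames(counts),
                             species_ids = colnames(counts),
                             taxon_name = "taxon",
                             mode = c("abundance", "incidence")) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (is.null(plot_ids)) plot_ids <- paste0("P", seq_len(nrow(counts)))
  if (is.null(species_ids)) species_ids <- paste0("sp", seq_len(ncol(counts)))
  plot_ids <- as.character(plot_ids)
  species_ids <- as.character(species_ids)
  if (nrow(counts) != length(plot_ids))
    stop("number of rows (", nrow(counts), ") does not match plot_ids (",
         length(plot_ids), ")")
  if (ncol(counts) != length(species_ids))
    stop("number of columns (", ncol(counts), ") does not match species_ids (",
         length(species_ids), ")")
  dup <- plot_ids[duplicated(plot_ids)]
  if (length(dup))
    stop("duplicate plot id(s): ", paste(unique(dup), collapse = ", "))
  dup <- species_ids[duplicated(species_ids)]
  if (length(dup))
    stop("duplicate species id(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-integer count at row '", plot_ids[bad[1, 1]],
         "', column '", species_ids[bad[1, 2]], "'")
  storage.mode(counts) <- "integer"
  if (mode == "incidence" && any(counts > 1L)) {
    message("coercing ", sum(counts > 1L), " cell(s) > 1 to presence for '",
            taxon_name, "' (incidence mode)")
    counts[counts > 1L] <- 1L
  }
  dimnames(counts) <- list(plot_ids, species_ids)
  structure(
    list(taxon_name = taxon_name, plot_ids = plot_ids,
         species_ids = species_ids, counts = counts, mode = mode),
    class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community_matrix '", x$taxon_name, "' (", x$mode, "): ",
      length(x$plot_ids), " plots x ", length(x$species_ids), " species, ",
      sum(x$counts > 0), " occupied cells\n", sep = "")
  invisible(x)
}

#' Number of plots / species of a community matrix
#' @param cm a `community_matrix`.
#' @return integer count.
#' @export
n_plots <- function(cm) length(cm$plot_ids)

#' @rdname n_plots
#' @export
n_species <- function(cm) length(cm$species_ids)

#' Construct a plot metadata table
#'
#' @param plot_ids unique plot identifiers.
#' @param x,y planar coordinates in km.
#' @param plot_area_ha per-plot sampled area in hectares (a 30 x 30 m plot
#'   is 0.09 ha, the design default).
#' @param ... optional covariate vectors (e.g. environmental gradients),
#'   each of length `length(plot_ids)`.
#' @return a `data.frame` with class `plot_table`.
#' @export
plot_table <- function(plot_ids, x, y, plot_area_ha = 0.09, ...) {
  plot_ids <- as.character(plot_ids)
  if (anyDuplicated(plot_ids))
    stop("duplicate plot id(s): ",
         paste(unique(plot_ids[duplicated(plot_ids)]), collapse = ", "))
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("plot coordinates must be finite")
  plot_area_ha <- rep_len(plot_area_ha, length(plot_ids))
  if (any(!is.finite(plot_area_ha) | plot_area_ha <= 0))
    stop("plot_area_ha must be positive")
  out <- data.frame(plot_id = plot_ids, x_km = x, y_km = y,
                    plot_area_ha = plot_area_ha,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("plot_table", "data.frame")
  out
}

#' Pipeline run configuration
#'
#' Bundles the tunable knobs of the full analysis. The nominal scales are
#' the nested areas of the additive partition; the last one is the
#' reference ("reserve") area that extrapolation targets.
#'
#' @param nominal_scales_ha strictly increasing positive areas (ha).
#' @param n_permutations permutations of plot sampling order for
#'   accumulation curves.
#' @param n_bootstrap plot-level bootstrap replicates for confidence
#'   intervals.
#' @param max_combinations cap on plot combinations evaluated per pool size
#'   in coverage estimation.
#' @param rng_seed integer seed governing all stochastic steps.
#' @param aicc_delta_threshold delta-AICc above which the best model is
#'   called unambiguous.
#' @param validation_alpha significance level of the residual-validation
#'   tests.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(nominal_scales_ha = c(0.1, 0.5, 1, 10, 8000),
                       n_permutations = 999,
                       n_bootstrap = 200,
                       max_combinations = 100000,
                       rng_seed = 1L,
                       aicc_delta_threshold = 2.0,
                       validation_alpha = 0.05) {
  if (any(nominal_scales_ha <= 0) || any(diff(nominal_scales_ha) <= 0))
    stop("nominal_scales_ha must be positive and strictly increasing")
  stopifnot(n_permutations >= 1, n_bootstrap >= 0, max_combinations >= 1,
            aicc_delta_threshold > 0,
            validation_alpha > 0, validation_alpha < 1)
  structure(list(nominal_scales_ha = nominal_scales_ha,
                 n_permutations = as.integer(n_permutations),
                 n_bootstrap = as.integer(n_bootstrap),
                 max_combinations = as.integer(max_combinations),
                 rng_seed = as.integer(rng_seed),
                 aicc_delta_threshold = aicc_delta_threshold,
                 validation_alpha = validation_alpha),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file with any subset of [run_config()]'s fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

# delimiter autodetection: tab by default, comma when the header has more
# commas than tabs
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_com > n_tab) "," else "\t"
}

#' Read a community matrix from delimited text
#'
#' Expects a header row of species ids and a first column of plot ids.
#' Tab-separated by default with comma autodetection.
#'
#' @param path file path.
#' @param mode `"abundance"` or `"incidence"`; see [community_matrix()].
#' @param taxon_name taxon label; defaults to the file name without
#'   extension.
#' @return a `community_matrix`.
#' @export
read_community_matrix <- function(path, mode = c("abundance", "incidence"),
                                  taxon_name = NULL) {
  mode <- match.arg(mode)
  if (is.null(taxon_name))
    taxon_name <- sub("\\.[^.]+$", "", basename(path))
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("matrix file needs a plot-id column and >= 1 species")
  plot_ids <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad))
    stop("cell at row '", plot_ids[bad[1, 1]], "', column '",
         colnames(df)[-1][bad[1, 2]], "' is not a non-negative integer")
  community_matrix(num, plot_ids = plot_ids, species_ids = colnames(df)[-1],
                   taxon_name = taxon_name, mode = mode)
}

#' Write a community matrix as delimited text
#' @param cm a `community_matrix`.
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(cm, path, sep = "\t") {
  df <- data.frame(plot_id = cm$plot_ids, cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plot metadata table from delimited text
#'
#' Requires columns `plot_id`, `x_km`, `y_km`; `plot_area_ha` defaults to
#' 0.09 ha (a 30 x 30 m plot) when the column is absent, with a message.
#'
#' @param path file path.
#' @return a `plot_table`.
#' @export
read_plot_table <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("plot_id", "x_km", "y_km")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("plot table missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(df$x_km)) || any(is.na(df$y_km)))
    stop("plot table has missing coordinates")
  if (!"plot_area_ha" %in% names(df)) {
    message("plot_area_ha column absent; defaulting all plots to 0.09 ha")
    df$plot_area_ha <- 0.09
  }
  extra <- df[setdiff(names(df), c(need, "plot_area_ha"))]
  do.call(plot_table, c(list(plot_ids = df$plot_id, x = df$x_km, y = df$y_km,
                             plot_area_ha = df$plot_area_ha),
                        as.list(extra)))
}

#' Write a plot table as delimited text
#' @param plots a `plot_table`.
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(plots, path, sep = "\t") {
  utils::write.table(as.data.frame(plots), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align community matrices to a plot table
#'
#' Reorders every matrix's rows to the plot table's plot order. The
#' analysis requires a complete plot-by-taxon design, so a plot missing
#' from any matrix (or a matrix plot absent from the table) is an error.
#'
#' @param matrices list of `community_matrix` objects; existing list
#'   names are kept, otherwise taxa are named by their `taxon_name`.
#' @param plots a `plot_table`.
#' @return list with elements `matrices` (aligned, named) and `plots`.
#' @export
align_dataset <- function(matrices, plots) {
  if (!length(matrices)) stop("no taxa provided")
  given <- names(matrices)
  aligned <- lapply(matrices, function(cm) {
    extra <- setdiff(cm$plot_ids, plots$plot_id)
    if (length(extra))
      stop("plot '", extra[1], "' of taxon '", cm$taxon_name,
           "' is absent from the plot table")
    miss <- setdiff(plots$plot_id, cm$plot_ids)
    if (length(miss))
      stop("plot '", miss[1], "' is missing from taxon '",
           cm$taxon_name, "'")
    community_matrix(cm$counts[plots$plot_id, , drop = FALSE],
                     plot_ids = plots$plot_id,
                     species_ids = cm$species_ids,
                     taxon_name = cm$taxon_name, mode = cm$mode)
  })
  names(aligned) <- if (!is.null(given) && all(nzchar(given))) {
    given
  } else {
    vapply(aligned, function(m) m$taxon_name, character(1))
  }
  list(matrices = aligned, plots = plots)
}

# run all RNG inside a local, restorable seed so library functions do not
# perturb the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
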
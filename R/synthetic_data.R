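#' Simulate a heterogeneous plot landscape
#'
#' Places plots uniformly at random in a square landscape and attaches
#' smooth environmental gradients (a linear trend plus seeded Gaussian
#' bumps, standardised to mean 0 / sd 1 across plots). The defaults
#' emulate a 27-plot design of 30 x 30 m plots scattered over a study
#' extent whose mean pairwise plot distance is a few kilometres.
#'
#' @param n_plots number of plots (>= 3).
#' @param extent_km side length of the square landscape; for uniform
#'   points the expected mean pairwise distance is 0.5214 * extent, so the
#'   default 6.5 km yields ~3.4 km, the spacing of the emulated design.
#' @param plot_area_ha per-plot area (0.09 ha = 30 x 30 m).
#' @param n_gradients number of environmental gradient covariates
#'   (elevation-like, pH-like, ...).
#' @param seed integer seed; output is a pure function of seed + config.
#' @return a [plot_table()] with gradient columns `grad1`, `grad2`, ...
#' @export
generate_landscape <- function(n_plots = 27, extent_km = 6.5,
                               plot_area_ha = 0.09, n_gradients = 2,
                               seed = 1L) {
  if (n_plots < 3) stop("n_plots must be >= 3")
  if (extent_km <= 0) stop("extent_km must be positive")
  with_seed(seed, {
    x <- stats::runif(n_plots, 0, extent_km)
    y <- stats::runif(n_plots, 0, extent_km)
    grads <- list()
    if (n_gradients > 0) {
      for (g in seq_len(n_gradients)) {
        theta <- stats::runif(1, 0, 2 * pi)
        field <- cos(theta) * x / extent_km + sin(theta) * y / extent_km
        for (b in 1:3) {        # landscape-scale bumps
          cx <- stats::runif(1, 0, extent_km)
          cy <- stats::runif(1, 0, extent_km)
          amp <- stats::rnorm(1, 0, 0.7)
          w <- stats::runif(1, 0.2, 0.5) * extent_km
          field <- field + amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * w^2))
        }
        grads[[paste0("grad", g)]] <- as.numeric(scale(field))
      }
    }
    do.call(plot_table,
            c(list(plot_ids = sprintf("P%02d", seq_len(n_plots)),
                   x = x, y = y, plot_area_ha = plot_area_ha),
              grads))
  })
}

#' Configuration of one simulated taxon
#'
#' @param taxon_name label.
#' @param pool_size true regional richness (gamma) of the taxon.
#' @param niche_breadth sd of the Gaussian niche kernel on the
#'   standardised gradients; small values mean narrow niches and high
#'   spatial turnover, large values approach spatially uniform occupancy.
#' @param mean_occupancy target mean per-species per-plot occupancy
#'   probability in (0, 1).
#' @param abundance_model `"lognormal"` or `"geometric"` conditional
#'   per-occurrence abundance.
#' @param mean_abundance mean individuals per occurrence before detection
#'   thinning.
#' @param detection_prob per-individual detection probability in (0, 1].
#' @return a `taxon_config` list.
#' @export
taxon_config <- function(taxon_name, pool_size, niche_breadth,
                         mean_occupancy,
                         abundance_model = c("lognormal", "geometric"),
                         mean_abundance = 10, detection_prob = 1) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(pool_size >= 1, niche_breadth > 0,
            mean_occupancy > 0, mean_occupancy < 1,
            mean_abundance > 0,
            detection_prob > 0, detection_prob <= 1)
  structure(list(taxon_name = taxon_name, pool_size = as.integer(pool_size),
                 niche_breadth = niche_breadth,
                 mean_occupancy = mean_occupancy,
                 abundance_model = abundance_model,
                 mean_abundance = mean_abundance,
                 detection_prob = detection_prob),
            class = "taxon_config")
}

#' Built-in taxon presets
#'
#' Three contrasts spanning the turnover gradient of the emulated study:
#' `"bacteria_like"` (broad niches, high occupancy, large OTU pool — most
#' richness already present at small scales), `"woody_plant_like"`
#' (intermediate niches; per-plot richness in the tens, like a woody
#' plant inventory of 25-68 species per plot) and `"lepidopteran_like"`
#' (narrow niches, low occupancy and imperfect detection — richness still
#' climbing at large scales).
#'
#' @param name preset name.
#' @return a [taxon_config()].
#' @export
taxon_preset <- function(name = c("bacteria_like", "woody_plant_like",
                                  "lepidopteran_like")) {
  name <- match.arg(name)
  switch(name,
    bacteria_like = taxon_config(
      "bacteria_like", pool_size = 250, niche_breadth = 6,
      mean_occupancy = 0.75, abundance_model = "geometric",
      mean_abundance = 40, detection_prob = 1),
    woody_plant_like = taxon_config(
      "woody_plant_like", pool_size = 170, niche_breadth = 1.5,
      mean_occupancy = 0.3, abundance_model = "lognormal",
      mean_abundance = 12, detection_prob = 1),
    lepidopteran_like = taxon_config(
      "lepidopteran_like", pool_size = 400, niche_breadth = 0.35,
      mean_occupancy = 0.06, abundance_model = "lognormal",
      mean_abundance = 4, detection_prob = 0.6))
}

#' Simulate a plot-by-species abundance matrix for one taxon
#'
#' Each species receives a niche optimum drawn uniformly over the
#' landscape's gradient ranges; its occupancy probability at a plot is a
#' Gaussian kernel of gradient distance with width `niche_breadth`,
#' rescaled so the grand mean occupancy matches `mean_occupancy` (capped
#' at 1). Presence is Bernoulli; conditional abundance comes from the
#' configured model and is thinned binomially by `detection_prob` (a
#' thinned-to-zero occurrence is a non-detection).
#'
#' @param plots a [plot_table()] with at least one `grad*` column when
#'   `niche_breadth` is finite.
#' @param config a [taxon_config()].
#' @param seed integer seed.
#' @return a `community_matrix` in abundance mode.
#' @export
generate_taxon <- function(plots, config, seed = 1L) {
  grads <- as.matrix(plots[grep("^grad", names(plots))])
  if (!ncol(grads) && is.finite(config$niche_breadth))
    stop("plot table has no gradient columns")
  P <- nrow(plots)
  S <- config$pool_size
  with_seed(seed, {
    # occupancy kernel
    kern <- if (ncol(grads)) {
      opts <- vapply(seq_len(ncol(grads)), function(g)
        stats::runif(S, min(grads[, g]), max(grads[, g])),
        numeric(S))
      d2 <- outer(rep(0, P), rep(0, S))
      for (g in seq_len(ncol(grads)))
        d2 <- d2 + outer(grads[, g], opts[, g], `-`)^2
      exp(-d2 / (2 * config$niche_breadth^2))
    } else matrix(1, P, S)
    p_occ <- pmin(kern * (config$mean_occupancy / mean(kern)), 1)
    pres <- matrix(stats::rbinom(P * S, 1L, as.vector(p_occ)), P, S)
    n_occ <- sum(pres)
    ab <- integer(n_occ)
    if (n_occ) {
      raw <- switch(config$abundance_model,
        lognormal = {
          sdlog <- 1
          pmax(1, round(stats::rlnorm(
            n_occ, log(config$mean_abundance) - sdlog^2 / 2, sdlog)))
        },
        geometric = 1 + stats::rgeom(n_occ,
                                     1 / max(config$mean_abundance, 1)))
      ab <- stats::rbinom(n_occ, raw, config$detection_prob)
    }
    counts <- matrix(0L, P, S)
    counts[pres == 1L] <- as.integer(ab)
    community_matrix(counts,
                     plot_ids = plots$plot_id,
                     species_ids = sprintf("%s_sp%04d", config$taxon_name,
                                           seq_len(S)),
                     taxon_name = config$taxon_name, mode = "abundance")
  })
}

#' Simulate an accumulation curve directly from a species-area form
#'
#' Direct fixture for model-fitting checks: evaluates the chosen form at
#' the cumulative areas of k = 1..n_plots pooled plots and adds Gaussian
#' noise. Noise-free curves lie exactly on the generating model.
#'
#' @param model,params generating form and parameters
#'   (see [evaluate_model()]).
#' @param n_plots number of curve points.
#' @param plot_area_ha area per pooled plot.
#' @param noise_sd sd of additive Gaussian noise (0 for an exact curve).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param taxon_name label for the curve.
#' @return an `accumulation_curve` (method `"synthetic"`).
#' @export
generate_from_sar <- function(model, params, n_plots = 27,
                              plot_area_ha = 0.09, noise_sd = 0,
                              seed = 1L, taxon_name = model) {
  ks <- seq_len(n_plots)
  A <- ks * plot_area_ha
  S <- evaluate_model(model, params, A)
  if (noise_sd > 0)
    S <- with_seed(seed, pmax(0, S + stats::rnorm(n_plots, 0, noise_sd)))
  new_accumulation_curve(k = ks, area_ha = A, mean_richness = S,
                         sd_richness = rep(NA_real_, n_plots),
                         taxon_name = taxon_name, method = "synthetic",
                         n_permutations = 0L)
}

#' Simulate a complete multi-taxon study
#'
#' One landscape plus one community matrix per requested taxon; taxa are
#' preset-based with per-group jitter so groups are internally variable.
#' With the default group sizes this emulates a 43-taxon census: 19
#' bacteria-like, 12 fungi-like (intermediate between bacteria and
#' plants), 1 woody-plant-like, 1 herb-like and 10 arthropod
#' (lepidopteran-like) taxa.
#'
#' @param n_bacteria,n_fungi,n_plants,n_herbs,n_arthropods group sizes.
#' @param landscape optional pre-built [generate_landscape()] result.
#' @param seed integer master seed.
#' @param dir optional directory; when given, matrices and the plot table
#'   are also written as tab-separated files with a JSON manifest.
#' @return list: `plots` (plot_table), `matrices` (named list of
#'   community matrices), `configs` (the taxon_configs used).
#' @export
simulate_study <- function(n_bacteria = 19, n_fungi = 12, n_plants = 1,
                           n_herbs = 1, n_arthropods = 10,
                           landscape = NULL, seed = 1L, dir = NULL) {
  if (is.null(landscape))
    landscape <- generate_landscape(seed = seed)
  fungi_base <- taxon_config("fungi_like", pool_size = 220,
                             niche_breadth = 2.5, mean_occupancy = 0.45,
                             abundance_model = "geometric",
                             mean_abundance = 25)
  groups <- list(
    bacteria = list(n = n_bacteria, base = taxon_preset("bacteria_like")),
    fungi = list(n = n_fungi, base = fungi_base),
    woody_plant = list(n = n_plants, base = taxon_preset("woody_plant_like")),
    herb = list(n = n_herbs,
                base = taxon_config("herb_like", pool_size = 120,
                                    niche_breadth = 1.0,
                                    mean_occupancy = 0.25,
                                    mean_abundance = 8)),
    arthropod = list(n = n_arthropods,
                     base = taxon_preset("lepidopteran_like")))
  configs <- list()
  matrices <- list()
  i <- 0L
  for (gname in names(groups)) {
    g <- groups[[gname]]
    for (j in seq_len(g$n)) {
      i <- i + 1L
      cfg <- g$base
      cfg$taxon_name <- sprintf("%s_%02d", gname, j)
      # mild within-group variation in breadth and pool, seed-derived
      jit <- with_seed(seed + 7919L * i,
                       stats::runif(2, 0.8, 1.25))
      cfg$niche_breadth <- cfg$niche_breadth * jit[1]
      cfg$pool_size <- as.integer(round(cfg$pool_size * jit[2]))
      configs[[cfg$taxon_name]] <- cfg
      matrices[[cfg$taxon_name]] <-
        generate_taxon(landscape, cfg, seed = seed + 104729L + i)
    }
  }
  out <- list(plots = landscape, matrices = matrices, configs = configs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_plot_table(landscape, file.path(dir, "plots.tsv"))
    for (nm in names(matrices))
      write_community_matrix(matrices[[nm]],
                             file.path(dir, paste0(nm, ".tsv")))
    manifest <- list(seed = seed, n_taxa = length(matrices),
                     taxa = names(matrices),
                     n_plots = nrow(landscape),
                     generated = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
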
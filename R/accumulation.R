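#' Species accumulation by permutation of plot sampling order
#'
#' Expected cumulative richness when 1..P plots are pooled, estimated by
#' averaging over random orderings of the plots. A single ordering
#' contributes to every pool size k (cumulative-order accumulation), and
#' pooled richness at k is the number of species present in at least one
#' of the ordering's first k plots.
#'
#' @param cm a [community_matrix()] with at least 2 plots.
#' @param n_permutations number of random orderings (>= 1).
#' @param seed integer seed; identical seeds give identical curves.
#' @param mean_plot_area_ha area per plot used to convert pool size to
#'   cumulative area; defaults to 0.09 ha.
#' @return an `accumulation_curve`: data.frame with columns `k`,
#'   `area_ha`, `mean_richness`, `sd_richness`, plus attributes
#'   `taxon_name`, `method`, `n_permutations`.
#' @seealso [accumulate_exact()] for the analytic expectation.
#' @export
accumulate_permutation <- function(cm, n_permutations = 999, seed = 1L,
                                   mean_plot_area_ha = 0.09) {
  P <- n_plots(cm)
  if (P < 2) stop("accumulation needs at least 2 plots")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  present <- cm$counts > 0L
  S <- ncol(present)
  rich <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      ord <- sample.int(P)
      # first plot (in this ordering) at which each species appears
      first <- rep.int(Inf, S)
      for (pos in seq_len(P)) {
        hit <- present[ord[pos], ] & !is.finite(first)
        if (any(hit)) first[hit] <- pos
      }
      cumsum(tabulate(first[is.finite(first)], nbins = P))
    }, numeric(P))
  })
  rich <- matrix(rich, nrow = P)
  new_accumulation_curve(
    k = seq_len(P),
    area_ha = seq_len(P) * mean_plot_area_ha,
    mean_richness = rowMeans(rich),
    sd_richness = apply(rich, 1, stats::sd),
    taxon_name = cm$taxon_name, method = "permutation",
    n_permutations = n_permutations)
}

#' Exact expected species accumulation
#'
#' Analytic expectation of pooled richness over equiprobable plot subsets:
#' with p_j the number of plots occupied by species j and P plots total,
#' E\[S(k)\] = sum_j (1 - choose(P - p_j, k) / choose(P, k)). This is the
#' hypergeometric (sample-based rarefaction) expectation and serves as the
#' noise-free oracle for the permutation estimator.
#'
#' @inheritParams accumulate_permutation
#' @return an `accumulation_curve` with `method = "exact"` and `NA`
#'   permutation spread.
#' @export
accumulate_exact <- function(cm, mean_plot_area_ha = 0.09) {
  P <- n_plots(cm)
  if (P < 1) stop("accumulation needs at least 1 plot")
  occ <- colSums(cm$counts > 0L)       # plots occupied per species
  occ <- occ[occ > 0]
  ks <- seq_len(P)
  expect <- vapply(ks, function(k) {
    # choose(P - p, k)/choose(P, k), stable via lchoose; 0 when k > P - p
    miss <- ifelse(P - occ >= k,
                   exp(lchoose(P - occ, k) - lchoose(P, k)), 0)
    sum(1 - miss)
  }, numeric(1))
  new_accumulation_curve(
    k = ks, area_ha = ks * mean_plot_area_ha,
    mean_richness = expect, sd_richness = rep(NA_real_, P),
    taxon_name = cm$taxon_name, method = "exact", n_permutations = 0L)
}

new_accumulation_curve <- function(k, area_ha, mean_richness, sd_richness,
                                   taxon_name, method, n_permutations) {
  out <- data.frame(k = as.integer(k), area_ha = area_ha,
                    mean_richness = mean_richness,
                    sd_richness = sd_richness)
  attr(out, "taxon_name") <- taxon_name
  attr(out, "method") <- method
  attr(out, "n_permutations") <- as.integer(n_permutations)
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat("accumulation_curve '", attr(x, "taxon_name"), "' (",
      attr(x, "method"), "): k = 1..", max(x$k), ", richness ",
      round(x$mean_richness[1], 2), " -> ",
      round(x$mean_richness[nrow(x)], 2), "\n", sep = "")
  invisible(x)
}

#' Mean pairwise Euclidean distance between plots
#' @param plots a `plot_table`.
#' @param ids optional subset of plot ids.
#' @return mean pairwise distance in km.
#' @export
mean_pairwise_distance <- function(plots, ids = plots$plot_id) {
  sub <- plots[match(ids, plots$plot_id), , drop = FALSE]
  mean(stats::dist(cbind(sub$x_km, sub$y_km)))
}

#' Spatially compact core subset of plots
#'
#' Emulates restricting an analysis to the core area of a reserve: returns
#' the `n_keep` plots minimising mean pairwise distance. Exhaustive search
#' is used when `choose(P, n_keep)` <= `exhaustive_limit`; otherwise plots
#' are removed greedily, at each step dropping the plot with the largest
#' summed distance to the remaining plots (ties broken by plot-id order).
#'
#' @param plots a `plot_table`.
#' @param n_keep number of plots to retain, `2 <= n_keep < P`.
#' @param exhaustive_limit switch point between exhaustive and greedy
#'   search.
#' @return list with `plot_ids` (kept, in plot-table order),
#'   `mean_distance_km`, and `method` ("exhaustive" or "greedy").
#' @export
core_subset <- function(plots, n_keep, exhaustive_limit = 10000) {
  P <- nrow(plots)
  if (n_keep < 2) stop("n_keep must be >= 2")
  if (n_keep >= P) stop("n_keep must be < number of plots")
  D <- as.matrix(stats::dist(cbind(plots$x_km, plots$y_km)))
  if (choose(P, n_keep) <= exhaustive_limit) {
    combos <- utils::combn(P, n_keep)
    md <- apply(combos, 2, function(idx)
      mean(D[idx, idx][upper.tri(D[idx, idx])]))
    keep <- combos[, which.min(md)]
    method <- "exhaustive"
  } else {
    keep <- seq_len(P)
    while (length(keep) > n_keep) {
      contrib <- rowSums(D[keep, keep, drop = FALSE])
      # largest contribution leaves; which.max takes the first (id order)
      keep <- keep[-which.max(contrib)]
    }
    method <- "greedy"
  }
  keep <- sort(keep)
  sub <- D[keep, keep]
  list(plot_ids = plots$plot_id[keep],
       mean_distance_km = mean(sub[upper.tri(sub)]),
       method = method)
}

#' Restrict a community matrix to a subset of plots
#' @param cm a `community_matrix`.
#' @param plot_ids plots to retain (order preserved as given).
#' @return a `community_matrix` on the subset; all-zero species columns
#'   are retained.
#' @export
subset_plots <- function(cm, plot_ids) {
  miss <- setdiff(plot_ids, cm$plot_ids)
  if (length(miss)) stop("unknown plot id(s): ", paste(miss, collapse = ", "))
  community_matrix(cm$counts[plot_ids, , drop = FALSE], plot_ids = plot_ids,
                   species_ids = cm$species_ids, taxon_name = cm$taxon_name,
                   mode = cm$mode)
}
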
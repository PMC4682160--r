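#' Abundance-based sample coverage
#'
#' Estimated proportion of the community's individuals belonging to
#' species already recorded in the sample:
#' C_hat = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2)),
#' with n the total count, f1 the number of singletons and f2 the number
#' of doubletons. 1 - C_hat is the probability that the next individual
#' sampled belongs to an unrecorded species.
#'
#' @param abundances vector of per-species counts (zeros allowed and
#'   ignored; at least one positive count required).
#' @return coverage estimate in \[0, 1\].
#' @export
sample_coverage <- function(abundances) {
  ab <- abundances[abundances > 0]
  if (!length(ab)) stop("need at least one positive abundance")
  if (any(ab != round(ab))) stop("abundances must be integer counts")
  n <- sum(ab)
  f1 <- sum(ab == 1)
  f2 <- sum(ab == 2)
  if (n == 1) return(0)       # a single individual: nothing is covered
  if (f1 == 0) return(1)
  1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
}

#' Per-sample completeness via bias-corrected Chao1
#'
#' Observed richness divided by the bias-corrected Chao1 asymptotic
#' richness estimate S_obs + f1 (f1 - 1) / (2 (f2 + 1)).
#'
#' @inheritParams sample_coverage
#' @return completeness in \[0, 1\].
#' @export
per_plot_completeness <- function(abundances) {
  ab <- abundances[abundances > 0]
  if (!length(ab)) stop("need at least one positive abundance")
  s_obs <- length(ab)
  f1 <- sum(ab == 1)
  f2 <- sum(ab == 2)
  s_obs / (s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
}

# seeded draw of n_draw distinct k-subsets of seq_len(P) (as a k x n
# matrix), by rejection of duplicates
.sample_combinations <- function(P, k, n_draw, seed) {
  with_seed(seed, {
    seen <- new.env(hash = TRUE)
    out <- matrix(0L, nrow = k, ncol = n_draw)
    got <- 0L
    while (got < n_draw) {
      cand <- sort(sample.int(P, k))
      key <- paste(cand, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        out[, got] <- cand
      }
    }
    out
  })
}

#' Sample coverage over combinations of pooled plots
#'
#' Pools abundances over every combination of `k` plots (exhaustively
#' when `choose(P, k)` does not exceed `max_combinations`, else over a
#' seeded random draw of that many distinct combinations) and applies
#' [sample_coverage()] to each pooled sample.
#'
#' @param cm a `community_matrix` in abundance mode.
#' @param k number of plots pooled per combination.
#' @param max_combinations cap on combinations evaluated.
#' @param seed integer seed used when subsampling combinations.
#' @return a `coverage_result` list: `taxon_name`, `k`,
#'   `n_combinations_evaluated`, `exhaustive`, `mean_coverage`,
#'   `q025`, `q975`, and `coverages` (per-combination values).
#' @export
coverage_by_combination <- function(cm, k, max_combinations = 100000,
                                    seed = 1L) {
  if (cm$mode != "abundance") stop("coverage requires abundances")
  P <- n_plots(cm)
  if (k < 1 || k > P) stop("k must be in 1..", P)
  n_total <- choose(P, k)
  exhaustive <- n_total <= max_combinations
  combos <- if (exhaustive) {
    matrix(utils::combn(P, k), nrow = k)
  } else {
    .sample_combinations(P, k, max_combinations, seed)
  }
  cov <- apply(combos, 2, function(idx)
    sample_coverage(colSums(cm$counts[idx, , drop = FALSE])))
  structure(list(
    taxon_name = cm$taxon_name, k = as.integer(k),
    n_combinations_evaluated = ncol(combos), exhaustive = exhaustive,
    mean_coverage = mean(cov),
    q025 = unname(stats::quantile(cov, 0.025)),
    q975 = unname(stats::quantile(cov, 0.975)),
    coverages = cov), class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat("coverage_result '", x$taxon_name, "' k=", x$k, ": mean ",
      round(x$mean_coverage, 4), " over ", x$n_combinations_evaluated,
      if (x$exhaustive) " (exhaustive)" else " (sampled)",
      " combinations\n", sep = "")
  invisible(x)
}

#' Coverage profile over all pool sizes
#' @inheritParams coverage_by_combination
#' @param ks pool sizes to evaluate (default 1..P).
#' @return data.frame: taxon, k, exhaustive, n_combinations, mean_coverage,
#'   q025, q975.
#' @export
coverage_profile <- function(cm, ks = seq_len(n_plots(cm)),
                             max_combinations = 100000, seed = 1L) {
  rows <- lapply(ks, function(k) {
    r <- coverage_by_combination(cm, k, max_combinations, seed + k)
    data.frame(taxon = r$taxon_name, k = r$k, exhaustive = r$exhaustive,
               n_combinations = r$n_combinations_evaluated,
               mean_coverage = r$mean_coverage, q025 = r$q025,
               q975 = r$q975, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rarefy a count vector to fixed depth
#'
#' Multivariate hypergeometric subsample without replacement down to
#' exactly `depth` individuals, emulating read-depth normalisation of
#' OTU tables. Species order is preserved and zero-count species stay as
#' zeros.
#'
#' @param abundances non-negative integer counts.
#' @param depth target total count (<= `sum(abundances)`).
#' @param seed integer seed.
#' @return integer vector of the same length summing to `depth`.
#' @export
rarefy_counts <- function(abundances, depth, seed = 1L) {
  if (any(abundances < 0) || any(abundances != round(abundances)))
    stop("abundances must be non-negative integers")
  total <- sum(abundances)
  if (depth > total)
    stop("depth (", depth, ") exceeds total count (", total, ")")
  if (depth == total) return(as.integer(abundances))
  with_seed(seed, {
    picked <- sample.int(total, depth)
    sp <- rep.int(seq_along(abundances), abundances)
    tabulate(sp[picked], nbins = length(abundances))
  })
}

#' Rarefy every plot of an abundance matrix to a common depth
#' @param cm a `community_matrix` in abundance mode.
#' @param depth target per-plot total count; plots below `depth` raise an
#'   error.
#' @param seed integer seed (plot-specific streams derived from it).
#' @return a rarefied `community_matrix`.
#' @export
rarefy_matrix <- function(cm, depth, seed = 1L) {
  if (cm$mode != "abundance") stop("rarefaction requires abundances")
  counts <- cm$counts
  for (i in seq_len(nrow(counts)))
    counts[i, ] <- rarefy_counts(counts[i, ], depth, seed = seed + i)
  community_matrix(counts, plot_ids = cm$plot_ids,
                   species_ids = cm$species_ids,
                   taxon_name = cm$taxon_name, mode = "abundance")
}
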
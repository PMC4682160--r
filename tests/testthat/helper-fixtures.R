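# shared fixtures, all built in code

# 3 plots x 2 species: species A everywhere, species B only in plot 1;
# the textbook accumulation example (E[S(2)] = 5/3 by enumeration)
tiny_cm <- function(mode = "abundance") {
  community_matrix(matrix(c(1L, 1L, 1L, 2L, 0L, 0L), nrow = 3,
                          dimnames = list(paste0("P", 1:3), c("A", "B"))),
                   taxon_name = "tiny", mode = mode)
}

# right triangle with legs 3 and 4 km: pairwise distances {3, 4, 5}
triangle_plots <- function() {
  plot_table(plot_ids = c("P1", "P2", "P3"),
             x = c(0, 3, 0), y = c(0, 0, 4))
}

# seeded random occupancy matrix
random_cm <- function(P, S, occ = 0.3, seed = 1, taxon = "rand") {
  set.seed(seed)
  m <- matrix(rbinom(P * S, 1L, occ), P, S)
  # abundance 1-5 where present
  m[m == 1L] <- sample(1:5, sum(m), replace = TRUE)
  community_matrix(m, plot_ids = sprintf("P%02d", seq_len(P)),
                   species_ids = sprintf("s%03d", seq_len(S)),
                   taxon_name = taxon, mode = "abundance")
}

# parameter sets under which each species-area form is well identified
# on cumulative areas 0.09..2.43 ha
sar_truth <- function() {
  list(power = c(c = 30, z = 0.35),
       exponential = c(c = 40, z = 10),
       negexpo = c(d = 100, z = 1.2),
       monod = c(d = 120, c = 0.7),
       rational = c(c = 5, z = 60, d = 0.5),
       logistic = c(d = 80, z = 3, c = 1),
       lomolino = c(d = 100, z = 1.5, f = 3),
       weibull = c(d = 90, c = 1.5, z = 0.8))
}

# model_selection wrapper around a hand-specified form (for partition and
# congruence arithmetic tests)
fake_selection <- function(model, params, taxon = "fake") {
  fit <- list(model = model, params = params, rss = 0, n_points = 27,
              K = length(params) + 1L, aicc = -Inf, converged = TRUE,
              residuals_normal = TRUE, homoscedastic = TRUE, valid = TRUE)
  class(fit) <- "sar_fit"
  structure(list(taxon_name = taxon, fits = setNames(list(fit), model),
                 best = model, best_fit = fit,
                 delta_aicc = setNames(0, model), unambiguous = TRUE,
                 fallback = FALSE),
            class = "model_selection")
}

# curve lying exactly on a model, with an explicit k = 1 alpha override
curve_on_model <- function(model, params, alpha = NULL, n = 27,
                           plot_area = 0.09) {
  cv <- generate_from_sar(model, params, n_plots = n,
                          plot_area_ha = plot_area)
  if (!is.null(alpha)) cv$mean_richness[cv$k == 1] <- alpha
  cv
}
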
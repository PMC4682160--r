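test_that("generators are pure functions of seed and config", {
  l1 <- generate_landscape(seed = 42)
  l2 <- generate_landscape(seed = 42)
  expect_identical(l1, l2)
  expect_false(identical(l1, generate_landscape(seed = 43)))

  cfg <- taxon_preset("woody_plant_like")
  expect_identical(generate_taxon(l1, cfg, seed = 5),
                   generate_taxon(l1, cfg, seed = 5))
  expect_false(identical(generate_taxon(l1, cfg, seed = 5)$counts,
                         generate_taxon(l1, cfg, seed = 6)$counts))

  s1 <- simulate_study(n_bacteria = 1, n_fungi = 1, n_plants = 1,
                       n_herbs = 0, n_arthropods = 1, seed = 9)
  s2 <- simulate_study(n_bacteria = 1, n_fungi = 1, n_plants = 1,
                       n_herbs = 0, n_arthropods = 1, seed = 9)
  expect_identical(lapply(s1$matrices, `[[`, "counts"),
                   lapply(s2$matrices, `[[`, "counts"))
})

test_that("landscape geometry matches the uniform-square expectation", {
  # E[pairwise distance] = 0.5214 * side for uniform points in a square
  md <- vapply(1:200, function(s)
    mean_pairwise_distance(generate_landscape(extent_km = 9, seed = s)),
    numeric(1))
  expect_lt(abs(mean(md) - 0.5214 * 9), 0.1 * 0.5214 * 9)

  # default extent emulates ~3.4 km spacing
  md0 <- vapply(1:100, function(s)
    mean_pairwise_distance(generate_landscape(seed = s)), numeric(1))
  expect_lt(abs(mean(md0) - 3.4), 0.35)

  l0 <- generate_landscape(n_gradients = 0, seed = 1)
  expect_length(grep("^grad", names(l0)), 0)
  expect_error(generate_landscape(n_plots = 2), ">= 3")
})

test_that("the occupancy kernel saturates and thins as configured", {
  land <- generate_landscape(seed = 3)
  # near-ubiquitous taxon: every species in (almost) every plot
  ub <- generate_taxon(land, taxon_config("ub", 50, 100, 0.999), seed = 4)
  expect_equal(n_species(ub), 50)
  expect_gt(mean(ub$counts > 0), 0.99)

  # extreme thinning degrades gracefully to a near-empty matrix
  sparse <- generate_taxon(
    land, taxon_config("sp", 50, 2, 0.2, mean_abundance = 0.5,
                       detection_prob = 0.01), seed = 4)
  expect_lt(mean(sparse$counts > 0), 0.05)
  expect_true(all(sparse$counts >= 0))

  expect_error(taxon_config("bad", 10, 1, 1.5), "mean_occupancy")
  expect_error(taxon_config("bad", 10, -1, 0.5), "niche_breadth")
})

test_that("narrow niches lower the local richness share of the pool", {
  wins <- 0
  for (s in 1:10) {
    land <- generate_landscape(seed = 300 + s)
    narrow <- generate_taxon(land, taxon_config("n", 100, 0.2, 0.2),
                             seed = 400 + s)
    broad <- generate_taxon(land, taxon_config("b", 100, 5, 0.2),
                            seed = 400 + s)
    share <- function(cm) mean(rowSums(cm$counts > 0)) / 100
    if (share(narrow) < share(broad)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("curves simulated from a form are exact at zero noise and
           recoverable", {
  truth <- c(d = 100, z = 5, f = 3)
  cv <- generate_from_sar("lomolino", truth)
  expect_equal(cv$mean_richness,
               evaluate_model("lomolino", truth, cv$area_ha))
  fit <- suppressMessages(fit_model("lomolino", cv))
  expect_lt(abs(fit$params["d"] - 100) / 100, 1e-3)

  noisy <- generate_from_sar("power", c(c = 20, z = 0.25), noise_sd = 2,
                             seed = 5)
  expect_false(all(noisy$mean_richness ==
                     evaluate_model("power", c(c = 20, z = 0.25),
                                    noisy$area_ha)))
  expect_true(all(noisy$mean_richness >= 0))
  expect_identical(generate_from_sar("power", c(c = 20, z = 0.25),
                                     noise_sd = 2, seed = 5),
                   noisy)
})
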
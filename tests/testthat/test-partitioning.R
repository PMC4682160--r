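test_that("partition components are curve increments and sum to gamma", {
  # oracle: direct evaluation of the model at the five scales
  params <- c(d = 100, c = 1)
  sel <- fake_selection("monod", params)
  scales <- c(0.1, 0.5, 1, 10, 8000)
  S <- evaluate_model("monod", params, c(0.09, scales[-1]))
  alpha <- S[1] - 2              # observed alpha below the fitted origin
  cv <- curve_on_model("monod", params, alpha = alpha)
  part <- partition_turnover(sel, cv, scales)
  expect_equal(unname(part$components),
               c(2, S[2] - S[1], S[3] - S[2], S[4] - S[3], S[5] - S[4]))
  expect_equal(part$alpha_plot + sum(part$components), part$gamma_hat,
               tolerance = 1e-12)
  expect_equal(sum(part$relative), 1, tolerance = 1e-12)
  # cumulative fraction is non-decreasing across scales
  cum <- cumsum(c(part$alpha_plot, part$components)) / part$gamma_hat
  expect_true(all(diff(cum) >= 0))
})

test_that("a flat curve yields zero turnover and alpha equals gamma", {
  params <- c(d = 50, z = 500)   # negexpo at its asymptote everywhere
  sel <- fake_selection("negexpo", params)
  cv <- curve_on_model("negexpo", params)
  part <- partition_turnover(sel, cv)
  expect_equal(unname(part$components), rep(0, 5), tolerance = 1e-6)
  expect_equal(part$alpha_plot, part$gamma_hat, tolerance = 1e-6)
})

test_that("negative components are clipped with additivity preserved", {
  params <- c(d = 100, c = 1)
  sel <- fake_selection("monod", params)
  # observed alpha above the fitted curve at the plot scale
  alpha <- evaluate_model("monod", params, 0.09) + 3
  cv <- curve_on_model("monod", params, alpha = alpha)
  expect_message(part <- partition_turnover(sel, cv), "clipped")
  expect_equal(unname(part$components["plot"]), 0)
  expect_true(all(part$components >= 0))
  expect_equal(part$alpha_plot + sum(part$components), part$gamma_hat,
               tolerance = 1e-12)
})

test_that("a non-monotone fitted curve across scales is rejected", {
  # exponential with negative z cannot arise from fitting (z > 0 bound),
  # but partition must still guard against a decreasing evaluated curve
  sel <- fake_selection("exponential", c(c = 10, z = -2))
  cv <- curve_on_model("exponential", c(c = 10, z = 2))
  expect_error(partition_turnover(sel, cv), "decreases")
})

test_that("bootstrap partitions keep additivity per replicate and bracket
           the point estimates", {
  cm <- generate_taxon(generate_landscape(seed = 6),
                       taxon_config("t", 90, 2.5, 0.3), seed = 7)
  cv <- accumulate_exact(cm)
  sel <- suppressMessages(suppressWarnings(
    select_model(fit_all_models(cv), taxon_name = "t", fallback = TRUE)))
  part <- suppressMessages(
    partition_ci(sel, cv, cm, n_bootstrap = 80, seed = 8))
  expect_false(is.null(part$ci))
  reps <- attr(part, "replicates")
  expect_gte(nrow(reps), 40)
  comp_cols <- setdiff(colnames(reps), c("alpha_plot", "gamma_hat"))
  lhs <- reps[, "alpha_plot"] + rowSums(reps[, comp_cols])
  expect_equal(lhs, unname(reps[, "gamma_hat"]),
               tolerance = 1e-9)
  # CI bounds bracket the point estimates
  pts <- c(alpha_plot = part$alpha_plot, part$components)
  expect_true(all(part$ci[names(pts), "low"] <= pts + 1e-9))
  expect_true(all(pts <= part$ci[names(pts), "high"] + 1e-9))
})
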
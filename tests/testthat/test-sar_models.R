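test_that("model formulas evaluate to their closed-form values", {
  expect_equal(evaluate_model("power", c(c = 2, z = 0.5), 9), 6)
  expect_equal(evaluate_model("monod", c(d = 100, c = 1), 1), 50)
  expect_equal(evaluate_model("exponential", c(c = 3, z = 2), exp(1)), 5)
  # asymptotes
  for (m in c("negexpo", "logistic", "lomolino", "weibull"))
    expect_equal(evaluate_model(m, sar_truth()[[m]], 1e12),
                 unname(sar_truth()[[m]]["d"]), tolerance = 1e-3)
  expect_equal(model_asymptote("rational", c(c = 5, z = 60, d = 0.5)), 120)
  expect_error(evaluate_model("power", c(c = 2), 1), "z")
  expect_error(evaluate_model("power", c(c = 2, z = 1), -1), "positive")
  expect_error(evaluate_model("nope", c(a = 1), 1), "unknown")
})

test_that("AICc follows the small-sample formula", {
  expect_equal(aicc(27, 27, 2), 6 + 24 / 23, tolerance = 1e-10)
  expect_equal(aicc(27 * exp(1), 27, 2), 27 + 6 + 24 / 23,
               tolerance = 1e-10)
  # doubling RSS at fixed n, K adds n ln 2
  expect_equal(aicc(10, 20, 3) + 20 * log(2), aicc(20, 20, 3))
  expect_error(aicc(1, 5, 3), "need")
  expect_warning(expect_identical(aicc(0, 27, 2), -Inf), "perfect")
})

test_that("noise-free curves recover their generating parameters", {
  for (m in c("power", "monod", "lomolino")) {
    truth <- sar_truth()[[m]]
    cv <- generate_from_sar(m, truth)
    fit <- suppressMessages(fit_model(m, cv))
    expect_true(fit$converged)
    expect_lt(max(abs(fit$params - truth) / truth), 1e-3)
    expect_lt(fit$rss, 1e-6)
  }
  # a wrong form cannot beat the generating form on its own data
  cv <- generate_from_sar("power", sar_truth()$power)
  f_power <- suppressMessages(fit_model("power", cv))
  f_negexpo <- suppressMessages(fit_model("negexpo", cv))
  expect_gt(f_negexpo$rss, f_power$rss)
  expect_error(fit_model("power", cv[1:3, ]), "points")
})

test_that("residual validation has the intended size and power", {
  mkfit <- function(res, fitted) {
    f <- list(model = "power", params = c(c = 1, z = 1),
              rss = sum(res^2), n_points = length(res), K = 3L, aicc = 0,
              converged = TRUE, residuals = res, fitted = fitted,
              valid = FALSE)
    class(f) <- "sar_fit"
    f
  }
  fitted <- seq(10, 100, length.out = 27)
  # degenerate cases skip the tests and pass
  expect_message(pf <- validate_fit(mkfit(rep(0, 27), fitted)), "skipped")
  expect_true(pf$valid)
  expect_message(sf <- validate_fit(mkfit(rnorm(4), fitted[1:4])),
                 "skipped")
  expect_true(sf$valid)

  # joint size: nominal pass rate (1 - alpha)^2 ~ 0.9, checked within
  # binomial error over 1000 replicates
  set.seed(11)
  pass <- replicate(1000, {
    f <- validate_fit(mkfit(rnorm(27), fitted))
    f$residuals_normal && f$homoscedastic
  })
  expect_gt(mean(pass), 0.87)

  # power against a strong fan pattern
  set.seed(12)
  fan <- replicate(500, {
    f <- validate_fit(mkfit(rnorm(27, 0, 0.1 * fitted), fitted))
    !f$homoscedastic
  })
  expect_gt(mean(fan), 0.8)
})

test_that("selection picks the lowest-AICc valid fit and flags ambiguity", {
  mk <- function(aicc, rss = 1, valid = TRUE) {
    f <- list(model = "x", params = c(c = 1), rss = rss, n_points = 27,
              K = 3L, aicc = aicc, converged = TRUE, valid = valid)
    class(f) <- "sar_fit"
    f
  }
  fits <- list(a = mk(10), b = mk(13), c = mk(20))
  sel <- select_model(fits, threshold = 2)
  expect_identical(sel$best, "a")
  expect_equal(unname(sel$delta_aicc), c(0, 3, 10))
  expect_true(sel$unambiguous)

  expect_false(select_model(list(a = mk(10), b = mk(11)))$unambiguous)

  # an invalid lowest-AICc fit is excluded from the competition
  sel2 <- select_model(list(a = mk(5, valid = FALSE), b = mk(10),
                            c = mk(14)))
  expect_identical(sel2$best, "b")

  expect_error(select_model(list(a = mk(1, valid = FALSE))), "admissible")
  expect_message(
    sel3 <- select_model(list(a = mk(3, valid = FALSE),
                              b = mk(1, valid = FALSE)), fallback = TRUE),
    "falling back")
  expect_identical(sel3$best, "b")
  expect_true(sel3$fallback)
})

test_that("extrapolation reaches the asymptote and normalises fractions", {
  sel <- fake_selection("monod", c(d = 100, c = 1))
  est <- extrapolate(sel, area_ha = 1e12, reference_area_ha = 1e12)
  expect_equal(est$richness, 100, tolerance = 1e-9)
  expect_equal(est$fraction_of_reference, 1)

  est2 <- extrapolate(sel, area_ha = c(1, 10), reference_area_ha = 8000)
  expect_lt(est2$fraction_of_reference[1], est2$fraction_of_reference[2])

  # bootstrap CI brackets the point estimate on a well-behaved taxon
  cm <- generate_taxon(generate_landscape(seed = 2),
                       taxon_config("t", 80, 2.5, 0.3), seed = 3)
  cv <- accumulate_exact(cm)
  sel2 <- suppressMessages(suppressWarnings(
    select_model(fit_all_models(cv), taxon_name = "t", fallback = TRUE)))
  est3 <- extrapolate(sel2, area_ha = 8000, cm = cm,
                      reference_area_ha = 8000, n_bootstrap = 60, seed = 4)
  expect_true(est3$ci_low <= est3$richness && est3$richness <= est3$ci_high)
})

test_that("bootstrap confidence bands narrow with more plots", {
  width_at <- function(n_plots, seed) {
    land <- generate_landscape(n_plots = n_plots, seed = seed)
    cm <- generate_taxon(land, taxon_config("t", 100, 2.5, 0.3),
                         seed = seed + 50)
    cv <- accumulate_exact(cm)
    sel <- suppressMessages(suppressWarnings(
      select_model(fit_all_models(cv), taxon_name = "t", fallback = TRUE)))
    est <- extrapolate(sel, area_ha = 8000, cm = cm,
                       reference_area_ha = 8000, n_bootstrap = 60,
                       seed = seed)
    est$ci_high - est$ci_low
  }
  w12 <- vapply(1:4, function(s) width_at(12, s), numeric(1))
  w27 <- vapply(1:4, function(s) width_at(27, s), numeric(1))
  expect_lt(mean(w27), mean(w12))
})
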
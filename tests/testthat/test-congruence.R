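test_that("proportional curves give an exact linear reference and zero
           deviation", {
  woody <- fake_selection("power", c(c = 10, z = 0.3), taxon = "woody")
  taxon <- fake_selection("power", c(c = 20, z = 0.3), taxon = "double")
  line <- linear_reference(woody, taxon)
  expect_equal(line$slope, 2, tolerance = 1e-10)
  expect_equal(line$intercept, 0, tolerance = 1e-8)
  expect_equal(line$r_squared, 1, tolerance = 1e-10)
  dev <- congruence_deviation(woody, taxon, line)
  expect_true(all(abs(dev$deviation) < 1e-8))
})

test_that("an additive offset is recovered as the intercept", {
  woody <- fake_selection("exponential", c(c = 40, z = 10), taxon = "w")
  taxon <- fake_selection("exponential", c(c = 45, z = 10), taxon = "t")
  line <- linear_reference(woody, taxon)
  expect_equal(line$slope, 1, tolerance = 1e-10)
  expect_equal(line$intercept, 5, tolerance = 1e-8)
})

test_that("deviation signs reflect relative saturation speed", {
  woody <- fake_selection("power", c(c = 30, z = 0.25), taxon = "w")
  # early-saturating taxon (bacteria-like): linear reference over-predicts
  # at the reserve scale
  early <- fake_selection("monod", c(d = 120, c = 0.1), taxon = "early")
  line_e <- linear_reference(woody, early)
  dev_e <- congruence_deviation(woody, early, line_e, areas_ha = 8000)
  expect_lt(dev_e$deviation, 0)
  # late-saturating taxon (lepidopteran-like): linear reference built at
  # small scales under-predicts at the reserve scale
  late <- fake_selection("power", c(c = 10, z = 0.6), taxon = "late")
  line_l <- linear_reference(woody, late)
  dev_l <- congruence_deviation(woody, late, line_l, areas_ha = 8000)
  expect_gt(dev_l$deviation, 0)

  # degenerate reference is refused
  flat <- fake_selection("negexpo", c(d = 50, z = 500), taxon = "flat")
  expect_error(linear_reference(flat, woody), "constant")
})

test_that("relative profiles average to the mean and D sums to zero", {
  # r(1 ha) = 1/(c+1) for monod d = gamma: c = 2/3 -> 0.6, c = 4 -> 0.2
  sels <- list(hi = fake_selection("monod", c(d = 100, c = 2 / 3), "hi"),
               lo = fake_selection("monod", c(d = 100, c = 4), "lo"))
  prof <- relative_profiles(sels, c(hi = 100, lo = 100),
                            areas_ha = c(1, 8000))
  at1 <- prof[prof$area_ha == 1, ]
  expect_equal(at1$relative_richness[at1$taxon == "hi"], 0.6)
  expect_equal(at1$relative_richness[at1$taxon == "lo"], 0.2)
  expect_equal(at1$mean_relative_richness, rep(0.4, 2))
  expect_equal(at1$deviation_pct[at1$taxon == "hi"], 50)
  expect_equal(at1$deviation_pct[at1$taxon == "lo"], -50)

  # identical curves: D identically zero
  same <- list(a = fake_selection("monod", c(d = 80, c = 1), "a"),
               b = fake_selection("monod", c(d = 80, c = 1), "b"))
  prof2 <- relative_profiles(same, c(a = 80, b = 80))
  expect_true(all(abs(prof2$deviation_pct) < 1e-10))

  # equal-weight deviations cancel at every grid point (antisymmetry)
  sels3 <- list(hi = sels$hi, lo = sels$lo,
                mid = fake_selection("monod", c(d = 100, c = 1.5), "mid"))
  prof3 <- relative_profiles(sels3, c(hi = 100, lo = 100, mid = 100))
  resid <- tapply(prof3$relative_richness - prof3$mean_relative_richness,
                  prof3$area_ha, sum)
  expect_true(all(abs(resid) < 1e-10))

  # percentage-point variant
  prof4 <- relative_profiles(sels, c(hi = 100, lo = 100),
                             areas_ha = 1, percent_of_mean = FALSE)
  expect_equal(sort(prof4$deviation_pct), c(-20, 20))
  expect_error(relative_profiles(sels["hi"], c(hi = 100)), ">= 2")
})
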
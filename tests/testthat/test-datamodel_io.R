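test_that("community matrices parse, coerce incidence, and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("plot_id\tspA\tspB", "P1\t2\t0", "P2\t1\t1", "P3\t0\t3"), tmp)
  cm <- read_community_matrix(tmp, mode = "abundance", taxon_name = "t")
  expect_identical(unname(colSums(cm$counts)), c(3, 4))
  expect_identical(cm$plot_ids, c("P1", "P2", "P3"))

  expect_message(
    inc <- read_community_matrix(tmp, mode = "incidence", taxon_name = "t"),
    "coercing")
  expect_identical(as.vector(inc$counts),
                   c(1L, 1L, 0L, 0L, 1L, 1L))

  # round-trip preserves counts, ids, order, and all-zero columns
  cm2 <- community_matrix(cbind(cm$counts, empty = 0L), taxon_name = "t")
  out <- withr::local_tempfile(fileext = ".tsv")
  write_community_matrix(cm2, out)
  back <- read_community_matrix(out, taxon_name = "t")
  expect_identical(back$counts, cm2$counts)
  expect_identical(back$species_ids, cm2$species_ids)

  # comma-delimited input is autodetected
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plot_id,spA,spB", "P1,2,0", "P2,1,1"), csv)
  expect_identical(unname(colSums(read_community_matrix(csv)$counts)),
                   c(3, 1))
})

test_that("community matrix validation names the offending cell or id", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("plot_id\tspA", "P1\t2", "P1\t1"), tmp)
  expect_error(read_community_matrix(tmp), "P1")
  writeLines(c("plot_id\tspA", "P1\t-2"), tmp)
  expect_error(read_community_matrix(tmp), "P1.*spA")
  writeLines(c("plot_id\tspA", "P1\t1.5"), tmp)
  expect_error(read_community_matrix(tmp), "P1.*spA")
  expect_error(community_matrix(matrix(-1, 1, 1)), "negative")
})

test_that("plot tables validate areas and default to 0.09 ha", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(plot_id = sprintf("P%02d", 1:27),
                   x_km = runif(27), y_km = runif(27),
                   plot_area_ha = 0.09)
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  pt <- read_plot_table(tmp)
  expect_equal(sum(pt$plot_area_ha), 2.43)

  df$plot_area_ha[3] <- 0
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_plot_table(tmp), "positive")

  df$plot_area_ha <- NULL
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(pt2 <- read_plot_table(tmp), "0.09")
  expect_true(all(pt2$plot_area_ha == 0.09))

  df$x_km[1] <- NA
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(read_plot_table(tmp)), "coordinate")
})

test_that("align_dataset orders matrices by the plot table and is idempotent", {
  plots <- plot_table(c("P1", "P2", "P3"), x = 1:3, y = 1:3)
  cm_rev <- subset_plots(tiny_cm(), c("P3", "P1", "P2"))
  ds <- align_dataset(list(cm_rev, tiny_cm()), plots)
  expect_identical(ds$matrices[[1]]$plot_ids, plots$plot_id)
  expect_identical(ds$matrices[[1]]$counts, tiny_cm()$counts)
  ds2 <- align_dataset(ds$matrices, plots)
  expect_identical(ds2$matrices, ds$matrices)

  cm_small <- subset_plots(tiny_cm(), c("P1", "P2"))
  expect_error(align_dataset(list(cm_small), plots), "P3.*tiny")
  plots_big <- plot_table(c("P1", "P2", "P3", "P9"), x = 1:4, y = 1:4)
  expect_error(align_dataset(list(tiny_cm()), plots_big), "P9")
  expect_error(align_dataset(list(), plots), "no taxa")
})

test_that("run configuration validates scales and reads from YAML", {
  cfg <- run_config()
  expect_equal(cfg$nominal_scales_ha, c(0.1, 0.5, 1, 10, 8000))
  expect_equal(cfg$n_permutations, 999L)
  expect_equal(cfg$max_combinations, 100000L)
  expect_error(run_config(nominal_scales_ha = c(1, 0.5)), "increasing")
  expect_error(run_config(validation_alpha = 1.2))

  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_permutations: 99", "rng_seed: 7"), tmp)
  cfg2 <- read_run_config(tmp)
  expect_equal(cfg2$n_permutations, 99L)
  expect_equal(cfg2$rng_seed, 7L)
  writeLines("bogus_key: 1", tmp)
  expect_error(read_run_config(tmp), "bogus_key")
})
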
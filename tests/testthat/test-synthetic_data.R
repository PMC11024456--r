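test_that("the same config and seed reproduce the study exactly", {
  cfg <- sim_config(species = "tundra", n_per_cell = 3, seed = 9)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$truth$diet, s2$truth$diet)
  expect_identical(s1$metadata, s2$metadata)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(tag_jump_rate = 1.5), "rates")
  expect_error(sim_config(breadth_alpha = 0), "positive")
  expect_error(sim_config(n_taxa = c(plant = 0, bryophyte = 2, arthropod = 2,
                                     lichen = 2, mushroom = 2)),
               "at least one taxon")
})

test_that("the zero-noise limit reproduces the marker-restricted truth", {
  cfg <- sim_config(species = "bank", n_per_cell = 3, markers = "sper01",
                    exact_counts = TRUE, tag_jump_rate = 0,
                    outlier_replicate_rate = 0, replicate_failure_rate = 0,
                    marker_bias_sd = 0, controls = FALSE, seed = 13)
  sim <- simulate_study(cfg)
  prof <- replicate_profiles(sim$tables$sper01)
  pm <- metadiet:::count_matrix(prof, id_col = "replicate_id")
  truth <- metadiet:::count_matrix(sim$truth$diet, id_col = "sample_id")
  plant_taxa <- colnames(pm)
  truth_m <- metadiet:::row_normalize(truth[, plant_taxa, drop = FALSE])
  for (i in seq_len(nrow(pm))) {
    # absolute deviation bounded by integer rounding at the replicate's depth
    expect_lt(max(abs(pm[i, ] - truth_m[prof$sample_id[i], ])), 0.01)
  }
})

test_that("clean replicate counts are unbiased for depth x truth", {
  # >= 200 clean replicates pooled: pooled RRA regresses on truth with slope 1
  cfg <- sim_config(species = "bank", n_per_cell = 20, markers = "sper01",
                    tag_jump_rate = 0, outlier_replicate_rate = 0,
                    replicate_failure_rate = 0, marker_bias_sd = 0,
                    controls = FALSE, seed = 31)
  sim <- simulate_study(cfg)
  prof <- replicate_profiles(sim$tables$sper01)
  expect_gte(nrow(prof), 200)
  pm <- metadiet:::count_matrix(prof, id_col = "replicate_id")
  truth <- metadiet:::count_matrix(sim$truth$diet, id_col = "sample_id")
  truth_m <- metadiet:::row_normalize(truth[, colnames(pm), drop = FALSE])
  x <- as.vector(truth_m[prof$sample_id, ])
  y <- as.vector(pm)
  slope <- coef(lm(y ~ x))[["x"]]
  expect_equal(slope, 1, tolerance = 0.05)
})

test_that("tag jumps move the configured share of reads", {
  cfg <- sim_config(species = "bank", n_per_cell = 13, markers = "euka02",
                    tag_jump_rate = 0.02, outlier_replicate_rate = 0,
                    replicate_failure_rate = 0, marker_bias_sd = 0, seed = 41)
  sim <- simulate_study(cfg)
  realized <- sim$truth$tag_jumps$rate_realized
  expect_gt(realized, 0.015)
  expect_lt(realized, 0.025)
})

test_that("spiked outliers sit farther from their sample mean than clean replicates", {
  cfg <- sim_config(species = "tundra", n_per_cell = 8, markers = "sper01",
                    tag_jump_rate = 0, replicate_failure_rate = 0,
                    outlier_replicate_rate = 3 / 96, marker_bias_sd = 0,
                    controls = FALSE, seed = 51)
  sim <- simulate_study(cfg)
  d <- replicate_distances(replicate_profiles(sim$tables$sper01))
  spiked <- sim$truth$outliers$replicate_id
  expect_gt(length(spiked), 0)
  dw_spiked <- d$dw$dw[d$dw$replicate_id %in% spiked]
  dw_clean <- d$dw$dw[!d$dw$replicate_id %in% spiked]
  # expected separation (a donor can occasionally resemble the host sample)
  expect_gt(mean(dw_spiked), 2 * mean(dw_clean))
  expect_gt(median(dw_spiked), quantile(dw_clean, 0.9))
})

test_that("simulated tables round-trip through the I/O layer", {
  cfg <- sim_config(species = "tundra", n_per_cell = 2, markers = "sper01",
                    seed = 61)
  sim <- simulate_study(cfg)
  tb <- sim$tables$sper01
  dir <- withr::local_tempdir()
  m <- metadiet:::count_matrix(tb)
  wide <- dplyr::bind_cols(tibble::tibble(motu_id = colnames(m)),
                           tibble::as_tibble(t(m), .name_repair = "minimal"))
  readr::write_tsv(wide, file.path(dir, "counts.tsv"), progress = FALSE)
  readr::write_tsv(tb[, c("replicate_id", "sample_id")],
                   file.path(dir, "map.tsv"), progress = FALSE)
  back <- read_replicate_table(file.path(dir, "counts.tsv"), "sper01",
                               map = file.path(dir, "map.tsv"))
  expect_equal(metadiet:::count_matrix(back), m)
})

test_that("recovery experiment reports coherent metrics on one study", {
  cfg <- sim_config(species = "tundra", n_per_cell = 5,
                    markers = c("sper01", "euka02"),
                    tag_jump_rate = 0, replicate_failure_rate = 0,
                    outlier_replicate_rate = 2 / 60, marker_bias_sd = 0,
                    seed = 71)
  rec <- run_recovery_experiment(cfg, n_studies = 1)
  ps <- tidy(rec)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$n_spiked, 4L)  # 2 markers x round(rate x 60)
  expect_true(ps$sensitivity >= 0 && ps$sensitivity <= 1)
  expect_gt(ps$spearman_truth, 0.5)
  expect_named(glance(rec),
               c("n_studies", "sensitivity", "false_removal", "spearman_truth",
                 "diversity_bias"))
})
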
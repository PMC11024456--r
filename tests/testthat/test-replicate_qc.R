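test_that("replicate_profiles normalizes rows and flags zero-read replicates", {
  counts <- rbind(r1 = c(10L, 30L, 60L), r2 = c(0L, 0L, 0L), r3 = c(7L, 0L, 0L))
  colnames(counts) <- paste0("m", 1:3)
  tb <- make_table(counts, c("s1", "s1", "s2"))
  prof <- replicate_profiles(tb)
  expect_equal(unname(as.numeric(prof[prof$replicate_id == "r1", paste0("m", 1:3)])),
               c(0.1, 0.3, 0.6))
  expect_equal(attr(prof, "excluded"), "r2")
  # single-MOTU replicate normalizes to 1
  expect_equal(as.numeric(prof[prof$replicate_id == "r3", "m1"]), 1)
  expect_true(all(abs(rowSums(metadiet:::count_matrix(prof, id_col = "replicate_id")) - 1) < 1e-12))
})

test_that("replicate_distances matches hand-computed dw and db", {
  tb <- qc_hand_fixture()
  d <- replicate_distances(replicate_profiles(tb))
  # all six replicates sit 0.1 from their sample mean in both coordinates
  expect_equal(d$dw$dw, rep(sqrt(0.02), 6), tolerance = 1e-12)
  expect_equal(sort(d$db),
               sort(c(sqrt(0.5), sqrt(1.28), sqrt(0.18))), tolerance = 1e-12)
  # identical replicates of one sample -> dw = 0
  tb2 <- make_table(rbind(r1 = c(m1 = 5L, m2 = 5L), r2 = c(m1 = 5L, m2 = 5L),
                          r3 = c(m1 = 9L, m2 = 1L)),
                    c("s1", "s1", "s2"))
  d2 <- replicate_distances(replicate_profiles(tb2))
  expect_equal(d2$dw$dw[d2$dw$sample_id == "s1"], c(0, 0))
  # orthogonal unit profiles -> db = sqrt(2)
  tb3 <- make_table(rbind(r1 = c(m1 = 10L, m2 = 0L), r2 = c(m1 = 0L, m2 = 10L)),
                    c("s1", "s2"))
  expect_equal(replicate_distances(replicate_profiles(tb3))$db, sqrt(2))
  # fewer than 2 samples is an error
  tb4 <- make_table(rbind(r1 = c(m1 = 1L), r2 = c(m1 = 2L)), c("s1", "s1"))
  expect_error(replicate_distances(replicate_profiles(tb4)), "2 samples")
})

test_that("estimate_threshold separates, falls back, and is stable under seed", {
  # separated distributions: threshold in the gap
  thr <- estimate_threshold(list(dw = c(0.01, 0.05, 0.1), db = c(0.8, 0.9, 1.0)))
  expect_gt(thr, 0.1); expect_lt(thr, 0.8)
  # degenerate dw all zero: midpoint rule gives 0.2
  expect_equal(estimate_threshold(list(dw = rep(0, 5), db = c(0.4, 0.5, 0.6))), 0.2)
  # empty input errors
  expect_error(estimate_threshold(list(dw = numeric(), db = 1)), "non-empty")
  # overlapping simulated distributions: KDE crossing lands between the modes
  set.seed(11)
  dw <- abs(rnorm(200, 0, 0.05))
  db <- rnorm(200, 0.5, 0.05)
  t1 <- estimate_threshold(list(dw = dw, db = db))
  t2 <- estimate_threshold(list(dw = dw, db = db))
  expect_gt(t1, 0.15); expect_lt(t1, 0.35)
  expect_identical(t1, t2)
})

test_that("iterative filter is a fixpoint on clean data and respects max_iter", {
  # identical duplicate replicates: one iteration, nothing removed
  counts <- rbind(r1 = c(8L, 2L), r2 = c(8L, 2L), r3 = c(2L, 8L), r4 = c(2L, 8L))
  colnames(counts) <- c("m1", "m2")
  tb <- make_table(counts, c("s1", "s1", "s2", "s2"))
  res <- filter_replicates_iterative(tb)
  expect_equal(nrow(res$report$removed), 0L)
  expect_equal(res$report$n_iterations, 1L)
  expect_true(res$report$converged)
  expect_equal(nrow(res$table), 4L)
})

test_that("a swapped-in outlier replicate is removed and clean ones kept", {
  cfg <- sim_config(species = "tundra", n_per_cell = 5, markers = "sper01",
                    tag_jump_rate = 0, replicate_failure_rate = 0,
                    outlier_replicate_rate = 2 / 60, marker_bias_sd = 0,
                    controls = FALSE, seed = 101)
  sim <- simulate_study(cfg)
  tb <- sim$tables$sper01
  spiked <- sim$truth$outliers$replicate_id
  expect_length(spiked, 2L)
  res <- filter_replicates_iterative(tb)
  removed <- res$report$removed$replicate_id
  expect_true(all(spiked %in% removed))
  # false removals stay rare
  expect_lte(length(setdiff(removed, spiked)), 3L)
  # idempotent after convergence: rerunning removes nothing
  res2 <- filter_replicates_iterative(res$table)
  expect_equal(nrow(res2$report$removed), 0L)

  # max_iter = 1 performs exactly one pass
  res1 <- filter_replicates_iterative(tb, max_iter = 1)
  expect_equal(res1$report$n_iterations, 1L)
})

test_that("average_replicates takes the unweighted mean of profiles", {
  tb <- make_table(rbind(r1 = c(m1 = 10L, m2 = 0L), r2 = c(m1 = 0L, m2 = 10L),
                         r3 = c(m1 = 4L, m2 = 6L)),
                   c("s1", "s1", "s2"))
  avg <- average_replicates(tb)
  m <- metadiet:::count_matrix(avg, id_col = "sample_id")
  expect_equal(unname(m["s1", ]), c(0.5, 0.5))     # mean of (1,0) and (0,1)
  expect_equal(unname(m["s2", ]), c(0.4, 0.6))     # single replicate = itself
  expect_true(all(abs(rowSums(m) - 1) < 1e-12))
  # hand-computed three-replicate mean
  tb3 <- make_table(rbind(r1 = c(m1 = 10L, m2 = 0L), r2 = c(m1 = 5L, m2 = 5L),
                          r3 = c(m1 = 2L, m2 = 8L), r4 = c(m1 = 1L, m2 = 0L)),
                    c("s1", "s1", "s1", "s2"))
  m3 <- metadiet:::count_matrix(average_replicates(tb3), id_col = "sample_id")
  expect_equal(unname(m3["s1", ]), c(mean(c(1, 0.5, 0.2)), mean(c(0, 0.5, 0.8))))
})

test_that("dw is zero iff a replicate equals its sample mean profile", {
  set.seed(3)
  counts <- matrix(rpois(8 * 4, 20), nrow = 8,
                   dimnames = list(paste0("r", 1:8), paste0("m", 1:4)))
  counts[2, ] <- counts[1, ]  # sample s1's replicates identical
  tb <- make_table(counts, rep(paste0("s", 1:4), each = 2))
  d <- replicate_distances(replicate_profiles(tb))
  prof <- metadiet:::count_matrix(replicate_profiles(tb), id_col = "replicate_id")
  means <- metadiet:::sample_mean_profiles(replicate_profiles(tb))
  for (i in seq_len(nrow(d$dw))) {
    eq <- isTRUE(all.equal(prof[i, ], means[d$dw$sample_id[i], ], tolerance = 1e-12))
    expect_equal(d$dw$dw[i] < 1e-12, eq)
  }
})
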
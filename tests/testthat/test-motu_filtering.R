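test_that("filter_global enforces the length and total-read boundaries", {
  counts <- rbind(r1 = c(5L, 6L, 4L, 20L), r2 = c(5L, 5L, 5L, 20L))
  colnames(counts) <- c("at10", "at11", "short", "ok")
  tb <- make_table(counts, c("s1", "s2"))
  recs <- make_records(colnames(counts), seq_length = c(10, 10, 9, 10))
  out <- filter_global(tb, recs)
  kept <- metadiet:::motu_cols(out)
  expect_false("at10" %in% kept)   # total exactly 10 reads: removed
  expect_true("at11" %in% kept)    # 11 reads: kept
  expect_false("short" %in% kept)  # 9 bp: removed
  expect_true("ok" %in% kept)      # 10 bp boundary: kept

  # idempotent and order-independent in its two criteria
  expect_equal(filter_global(out, recs), out)
  by_len <- filter_global(filter_global(tb, recs, min_total_reads = -1), recs, min_len = 0)
  by_reads <- filter_global(filter_global(tb, recs, min_len = 0), recs, min_total_reads = -1)
  expect_equal(by_len, by_reads)

  # empty table passes through
  empty <- tb[, metadiet:::meta_cols()]
  expect_equal(filter_global(empty, recs), empty)
})

test_that("filter_min_proportion zeroes, drops, renormalizes", {
  m <- rbind(s1 = c(0.005, 0.495, 0.50), s2 = c(0.2, 0.3, 0.5))
  colnames(m) <- paste0("m", 1:3)
  out <- filter_min_proportion(make_sample_table(m))
  om <- metadiet:::count_matrix(out, id_col = "sample_id")
  expect_equal(unname(om["s1", ]), c(0, 0.495 / 0.995, 0.5 / 0.995),
               tolerance = 1e-12)
  expect_true(all(abs(rowSums(om) - 1) < 1e-12))

  # column below threshold everywhere is dropped
  m2 <- rbind(s1 = c(0.005, 0.995), s2 = c(0.008, 0.992))
  colnames(m2) <- c("rare", "common")
  out2 <- filter_min_proportion(make_sample_table(m2))
  expect_equal(metadiet:::motu_cols(out2), "common")

  # all entries at or above threshold: unchanged within 1e-12
  m3 <- rbind(s1 = c(0.4, 0.6), s2 = c(0.25, 0.75))
  colnames(m3) <- c("m1", "m2")
  out3 <- filter_min_proportion(make_sample_table(m3))
  expect_equal(metadiet:::count_matrix(out3, id_col = "sample_id"), m3,
               tolerance = 1e-12)
})

test_that("filter_min_proportion is idempotent and leaves no sub-threshold entries", {
  set.seed(5)
  m <- metadiet:::row_normalize(matrix(rexp(10 * 30), nrow = 10,
                                       dimnames = list(paste0("s", 1:10),
                                                       paste0("m", 1:30))))
  once <- filter_min_proportion(make_sample_table(m))
  twice <- filter_min_proportion(once)
  expect_equal(metadiet:::count_matrix(twice, id_col = "sample_id"),
               metadiet:::count_matrix(once, id_col = "sample_id"),
               tolerance = 1e-12)
  om <- metadiet:::count_matrix(once, id_col = "sample_id")
  expect_true(all(om[om > 0] >= 0.01))
  expect_lte(sum(om > 0), sum(m > 0))
})

test_that("taxonomic scope keeps only lineages containing a target clade", {
  counts <- rbind(r1 = c(3L, 4L, 5L), r2 = c(1L, 2L, 3L))
  colnames(counts) <- c("plant1", "fungus1", "nolineage")
  tb <- make_table(counts, c("s1", "s2"))
  recs <- dplyr::bind_rows(
    make_records("plant1", phylum = "Spermatophyta"),
    make_records("fungus1", dietary_category = "mushroom", phylum = "Basidiomycota") |>
      dplyr::mutate(class = "Agaricomycetes", domain = NA_character_),
    make_records("nolineage", dietary_category = "other", phylum = NA_character_) |>
      dplyr::mutate(domain = NA_character_)
  )
  sper <- marker_spec("sper01", "Spermatophyta", "plant")
  out <- filter_taxonomic_scope(tb, recs, sper)
  expect_equal(metadiet:::motu_cols(out), "plant1")
  expect_setequal(attr(out, "out_of_scope"), c("fungus1", "nolineage"))
  # mushrooms stay in scope for the fungal marker
  fung <- marker_spec("fung01", c("Agaricomycetes", "Lecanoromycetes"),
                      c("mushroom", "lichen"))
  expect_equal(metadiet:::motu_cols(filter_taxonomic_scope(tb, recs, fung)), "fungus1")
  # a table already in scope is unchanged
  tb_in <- make_table(counts[, "plant1", drop = FALSE], c("s1", "s2"))
  expect_equal(metadiet:::count_matrix(filter_taxonomic_scope(tb_in, recs, sper)),
               metadiet:::count_matrix(tb_in))
})

test_that("screen_controls reports recovery failures and leaks", {
  counts <- rbind(r1 = c(100L, 2L, 0L), r2 = c(80L, 0L, 0L),
                  neg = c(3L, 0L, 0L), pos = c(0L, 0L, 500L))
  colnames(counts) <- c("diet1", "diet2", "ctrl")
  tb <- make_table(counts, c("s1", "s2", "NEG", "POS"),
                   flags = c("none", "none", "pcr_negative", "pcr_positive"))
  recs <- dplyr::bind_rows(
    make_records(c("diet1", "diet2")),
    make_records("ctrl", dietary_category = "other") |>
      dplyr::mutate(is_control = TRUE, functional_group = "none")
  )
  rep <- screen_controls(tb, recs)
  # dietary MOTU carrying 100% of the negative control is flagged
  expect_true(any(rep$negatives$flagged[rep$negatives$motu_id == "diet1"]))
  expect_true(rep$positive_recovered$recovered)
  expect_length(rep$control_failures, 0L)
  expect_equal(rep$leak_rate, 0)

  # positive-control MOTU absent from the positive replicate -> failure
  counts2 <- counts; counts2["pos", "ctrl"] <- 0L
  tb2 <- make_table(counts2, c("s1", "s2", "NEG", "POS"),
                    flags = c("none", "none", "pcr_negative", "pcr_positive"))
  rep2 <- screen_controls(tb2, recs)
  expect_true("ctrl" %in% rep2$control_failures)

  # no controls at all: empty report with a warning
  tb3 <- make_table(counts[1:2, ], c("s1", "s2"))
  expect_warning(rep3 <- screen_controls(tb3, recs), "no control")
  expect_equal(nrow(rep3$negatives), 0L)
})

test_that("simulated tag jumps leak positive-control reads at the configured rate", {
  cfg <- sim_config(species = "bank", n_per_cell = 13, markers = "sper01",
                    tag_jump_rate = 0.02, outlier_replicate_rate = 0,
                    replicate_failure_rate = 0, marker_bias_sd = 0, seed = 202)
  sim <- simulate_study(cfg)
  rep <- screen_controls(sim$tables$sper01, sim$records)
  expect_gt(rep$leak_rate, 0.01)
  expect_lt(rep$leak_rate, 0.03)
})
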
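test_that("hellinger gives square roots of proportions with unit row norms", {
  m <- rbind(s1 = c(0.25, 0.75), s2 = c(0.5, 0.5))
  colnames(m) <- c("a", "b")
  h <- hellinger(make_sample_table(m))
  hm <- metadiet:::count_matrix(h, id_col = "sample_id")
  expect_equal(unname(hm["s1", ]), c(0.5, sqrt(0.75)), tolerance = 1e-12)
  expect_equal(unname(sqrt(rowSums(hm^2))), c(1, 1), tolerance = 1e-12)
  # identical rows at distance 0; disjoint compositions at sqrt(2)
  m2 <- rbind(s1 = c(1, 0), s2 = c(1, 0), s3 = c(0, 1))
  colnames(m2) <- c("a", "b")
  d <- dist(hellinger(m2))
  expect_equal(as.matrix(d)["s1", "s2"], 0)
  expect_equal(as.matrix(d)["s1", "s3"], sqrt(2), tolerance = 1e-12)
  expect_error(hellinger(rbind(c(-0.1, 1.1))), "negative")
})

perm_fixture <- function() {
  m <- rbind(a1 = c(1, 0), a2 = c(0.9, 0.1), a3 = c(0.8, 0.2),
             b1 = c(0, 1), b2 = c(0.1, 0.9), b3 = c(0.2, 0.8))
  colnames(m) <- c("x", "y")
  m
}

test_that("permanova Monte-Carlo p matches complete enumeration", {
  m <- perm_fixture()
  groups <- rep(c("A", "B"), each = 3)
  p_enum <- permanova_p_enum(m, groups)
  expect_equal(p_enum, 1 / 10)   # 2 of the 20 label splits reach the observed F
  design <- tibble::tibble(sample_id = rownames(m), grp = groups)
  fit <- permanova(make_sample_table(m), design, ~ grp, n_perm = 9999, seed = 1)
  p_mc <- fit$table$p_value[fit$table$term == "grp"]
  se3 <- 3 * sqrt(p_enum * (1 - p_enum) / 9999)
  expect_lt(abs(p_mc - p_enum), se3)
  # observed pseudo-F agrees with the brute-force formula
  expect_equal(fit$table$statistic[1], permanova_F_oracle(dist(m), groups),
               tolerance = 1e-10)
})

test_that("permanova validates terms and flags degenerate input", {
  m <- perm_fixture()
  design <- tibble::tibble(sample_id = rownames(m), grp = "same")
  expect_error(permanova(make_sample_table(m), design, ~ grp), "single level")
  m0 <- m; m0[] <- 0.5
  design2 <- tibble::tibble(sample_id = rownames(m0),
                            grp = rep(c("A", "B"), each = 3))
  fit <- permanova(make_sample_table(m0), design2, ~ grp, n_perm = 99)
  expect_true(fit$degenerate)
  # deterministic under a fixed seed
  design3 <- tibble::tibble(sample_id = rownames(m),
                            grp = rep(c("A", "B"), each = 3))
  f1 <- permanova(make_sample_table(m), design3, ~ grp, n_perm = 199, seed = 9)
  f2 <- permanova(make_sample_table(m), design3, ~ grp, n_perm = 199, seed = 9)
  expect_identical(f1$table, f2$table)
})

test_that("pca explains rank-1 data on one axis and conserves variance", {
  m <- outer(c(1, 2, 3, 4), c(0.5, 1, 1.5))
  rownames(m) <- paste0("s", 1:4); colnames(m) <- paste0("t", 1:3)
  ord <- pca_ordination(m)
  expect_equal(ord$percent_explained[1], 100, tolerance = 1e-8)
  # eigenvalue sum equals total variance
  set.seed(12)
  m2 <- matrix(rnorm(8 * 5), nrow = 8,
               dimnames = list(paste0("s", 1:8), paste0("t", 1:5)))
  ord2 <- pca_ordination(m2)
  expect_equal(sum(ord2$eigenvalues), sum(apply(m2, 2, var)), tolerance = 1e-10)
  # constant matrix flagged degenerate
  m3 <- matrix(1, 4, 3, dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  expect_true(pca_ordination(m3)$degenerate)
})

test_that("rda constrained eigenvalues match the regression-then-PCA oracle", {
  # 6 samples x 3 taxa, one 2-level factor
  m <- rbind(s1 = c(5, 1, 2), s2 = c(6, 2, 1), s3 = c(5.5, 1.5, 1.5),
             s4 = c(1, 4, 3), s5 = c(2, 5, 4), s6 = c(1.5, 4.5, 3.5))
  colnames(m) <- paste0("t", 1:3)
  grp <- rep(c("A", "B"), each = 3)
  design <- tibble::tibble(sample_id = rownames(m), grp = grp)
  ord <- rda_ordination(make_sample_table(m), design, ~ grp)
  # oracle: center, fit group means, decompose the fitted matrix
  yc <- scale(m, scale = FALSE)
  fitted <- apply(yc, 2, function(col) ave(col, grp))
  eig_oracle <- svd(fitted)$d^2 / (nrow(m) - 1)
  eig_oracle <- eig_oracle[eig_oracle > 1e-10]
  expect_equal(ord$eigenvalues, eig_oracle, tolerance = 1e-8)
  # R2 oracle and Ezekiel adjustment with one coded column
  r2_oracle <- sum(fitted^2) / sum(yc^2)
  expect_equal(ord$R2, r2_oracle, tolerance = 1e-10)
  expect_equal(ord$adjusted_R2, 1 - (1 - r2_oracle) * (6 - 1) / (6 - 1 - 1),
               tolerance = 1e-10)
})

test_that("rda handles null, saturated and intercept-only designs", {
  set.seed(44)
  m <- matrix(rnorm(10 * 4), nrow = 10,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:4)))
  # predictor orthogonal to everything: R2 near 0, adjusted <= 0
  design <- tibble::tibble(sample_id = rownames(m), grp = rep(c("A", "B"), 5))
  m_orth <- m
  for (t in colnames(m_orth)) {
    m_orth[, t] <- m_orth[, t] - ave(m_orth[, t], design$grp) + mean(m_orth[, t])
  }
  ord0 <- rda_ordination(m_orth, design, ~ grp)
  expect_lt(ord0$R2, 1e-10)
  expect_lte(ord0$adjusted_R2, 0)
  # response exactly determined by the factor: R2 = 1, one constrained axis
  m_sat <- apply(m, 2, function(col) ave(col, design$grp))
  rownames(m_sat) <- rownames(m)
  ord1 <- suppressWarnings(rda_ordination(m_sat, design, ~ grp))
  expect_equal(ord1$R2, 1, tolerance = 1e-10)
  expect_equal(ord1$percent_explained[1], 100, tolerance = 1e-8)
  # R2 invariant to relabeling factor levels
  design2 <- design
  design2$grp <- ifelse(design$grp == "A", "Z", "Q")
  expect_equal(rda_ordination(m, design, ~ grp)$R2,
               rda_ordination(m, design2, ~ grp)$R2, tolerance = 1e-12)
})

test_that("rda with an intercept-only model reproduces pca of the centered matrix", {
  set.seed(55)
  m <- matrix(rexp(12 * 5), nrow = 12,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:5)))
  pca <- pca_ordination(m)
  fit <- vegan::rda(m ~ 1)
  expect_equal(unname(fit$CA$eig), pca$eigenvalues, tolerance = 1e-10)
})

test_that("permutation_anova matches anova(lm) F and detects strong effects", {
  set.seed(66)
  design <- tibble::tibble(grp = rep(c("A", "B"), each = 20),
                           sex = rep(c("m", "f"), 20))
  y <- rnorm(40) + 3 * (design$grp == "B")
  fit <- permutation_anova(y, design, ~ grp + sex, n_perm = 999, seed = 2)
  ref <- anova(lm(y ~ grp + sex, data = design))
  expect_equal(fit$table$statistic[1:2], ref$`F value`[1:2], tolerance = 1e-10)
  expect_equal(fit$table$sum_of_squares, c(ref$`Sum Sq`), tolerance = 1e-10)
  # delta = 3 SD with n = 20/group: decisive at 999 permutations
  expect_lte(fit$table$p_value[1], 0.01)
  # constant response: all p = 1, flagged
  fit0 <- permutation_anova(rep(2, 40), design, ~ grp + sex, n_perm = 99)
  expect_true(fit0$degenerate)
  expect_true(all(fit0$table$p_value[1:2] == 1))
  # deterministic under seed
  f1 <- permutation_anova(y, design, ~ grp * sex, n_perm = 199, seed = 5)
  f2 <- permutation_anova(y, design, ~ grp * sex, n_perm = 199, seed = 5)
  expect_identical(f1$table, f2$table)
})

test_that("tidiers return well-formed tibbles", {
  m <- perm_fixture()
  design <- tibble::tibble(sample_id = rownames(m),
                           grp = rep(c("A", "B"), each = 3))
  fit <- permanova(make_sample_table(m), design, ~ grp, n_perm = 99, seed = 1)
  expect_named(tidy(fit),
               c("term", "df", "sum_of_squares", "R2", "statistic", "p_value"))
  expect_equal(nrow(glance(fit)), 1L)
  # R2 components sum to 1
  expect_equal(sum(tidy(fit)$R2), 1, tolerance = 1e-9)
  ord <- pca_ordination(m)
  expect_named(tidy(ord), c("axis", "eigenvalue", "percent_explained"))
  expect_false(glance(ord)$constrained)
})
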
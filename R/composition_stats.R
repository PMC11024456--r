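# Composition and diversity statistics. PERMANOVA and ordination lean on
# vegan (adonis2, rda, RsquareAdj); the permutation ANOVA for scalar
# responses (diversity ~ phase x season) is computed here directly via
# QR-projection sequential sums of squares, with significance by permuting
# the response.

#' Hellinger transform
#'
#' Square roots of row-normalized relative abundances. Euclidean distance on
#' transformed rows equals the Hellinger distance, bounded by sqrt(2); each
#' non-empty row has unit Euclidean norm. Down-weights dominant taxa without
#' inflating rare ones, which is what makes it the standard pre-transform
#' for linear ordination of compositions.
#'
#' @param x Sample-by-taxon tibble (`sample_id` + numeric columns) or matrix.
#' @return Same shape, transformed. Negative entries are an error.
#' @export
hellinger <- function(x) {
  m <- if (is.matrix(x)) x else count_matrix(x, id_col = "sample_id")
  if (any(m < 0)) stop("hellinger: negative entries", call. = FALSE)
  nz <- rowSums(m) > 0
  out <- m
  if (any(nz)) {
    out[nz, ] <- as.matrix(vegan::decostand(m[nz, , drop = FALSE], "hellinger"))
  }
  if (is.matrix(x)) return(out)
  dplyr::bind_cols(x[, "sample_id"], tibble::as_tibble(out, .name_repair = "minimal"))
}

align_design <- function(x, design) {
  m <- if (is.matrix(x)) x else count_matrix(x, id_col = "sample_id")
  design <- tibble::as_tibble(design)
  if ("sample_id" %in% names(design) && !is.null(rownames(m))) {
    idx <- match(rownames(m), design$sample_id)
    if (anyNA(idx)) {
      stop(sprintf("sample(s) missing from design: %s",
                   paste(rownames(m)[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
    design <- design[idx, ]
  } else if (nrow(design) != nrow(m)) {
    stop("design rows do not match data rows", call. = FALSE)
  }
  list(m = m, design = design)
}

check_term_levels <- function(formula, design) {
  vars <- all.vars(formula)
  for (v in vars) {
    if (!v %in% names(design)) stop(sprintf("term variable '%s' not in design", v), call. = FALSE)
    if (length(unique(design[[v]])) < 2) {
      stop(sprintf("term '%s' has a single level", v), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Permutational multivariate ANOVA (PERMANOVA)
#'
#' Partitions Euclidean sums of squares of `x` (typically
#' Hellinger-transformed RRA) by the model terms, with sequential (Type I)
#' sums of squares, and tests each pseudo-F by permuting sample labels.
#' P-values use the add-one estimator p = (1 + #\{F* >= F\}) / (1 + n_perm).
#' Permutations can be restricted within `strata`. Deterministic under a
#' fixed `seed`.
#'
#' @param x Sample-by-taxon tibble or matrix (already transformed).
#' @param design Tibble of sample covariates; matched to `x` by `sample_id`
#'   when present, by row order otherwise.
#' @param formula RHS-only formula of terms, e.g. `~ phase + season`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @param strata Optional column name in `design`; permutations are then
#'   restricted within its levels.
#' @return A `permanova_fit`: list with `table` (term, df, sum_of_squares,
#'   R2, statistic, p_value), `n_perm`, `seed`, `degenerate`.
#' @export
permanova <- function(x, design, formula, n_perm = 999, seed = NULL, strata = NULL) {
  stopifnot(n_perm >= 1)
  al <- align_design(x, design)
  check_term_levels(formula, al$design)
  d <- dist(al$m)
  if (max(d) == 0) {
    # all rows identical: no variance to partition
    return(structure(list(table = tibble::tibble(), n_perm = n_perm,
                          seed = seed, degenerate = TRUE),
                     class = "permanova_fit"))
  }
  if (!is.null(seed)) set.seed(seed)
  dat <- as.data.frame(al$design)
  str_arg <- if (!is.null(strata)) dat[[strata]] else NULL
  f <- stats::as.formula(paste("d ~", as.character(formula)[2]))
  fit <- vegan::adonis2(f, data = dat, permutations = n_perm, by = "terms",
                        strata = str_arg)
  tab <- tibble::tibble(
    term = rownames(fit),
    df = fit$Df,
    sum_of_squares = fit$SumOfSqs,
    R2 = fit$R2,
    statistic = fit$F,
    p_value = fit$`Pr(>F)`
  ) |>
    dplyr::filter(.data$term != "Total")   # term + residual rows partition SS
  structure(list(table = tab, n_perm = n_perm, seed = seed, degenerate = FALSE),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<permanova_fit> degenerate: no between-sample variance\n")
    return(invisible(x))
  }
  cat(sprintf("<permanova_fit> %d permutations\n", x$n_perm))
  print(as.data.frame(x$table))
  invisible(x)
}

ordination_result <- function(fit, m, constrained, adjusted_R2 = NA_real_,
                              R2 = NA_real_, degenerate = FALSE) {
  if (degenerate) {
    return(structure(list(eigenvalues = numeric(), percent_explained = numeric(),
                          site_scores = tibble::tibble(), loadings = tibble::tibble(),
                          constrained = constrained, adjusted_R2 = adjusted_R2,
                          R2 = R2, degenerate = TRUE, fit = NULL),
                     class = "ordination"))
  }
  comp <- if (constrained) fit$CCA else fit$CA
  eig <- comp$eig
  total <- fit$tot.chi
  if (length(eig) == 0) {
    sc <- matrix(numeric(), nrow = nrow(m), ncol = 0,
                 dimnames = list(rownames(m), NULL))
    ld <- matrix(numeric(), nrow = ncol(m), ncol = 0,
                 dimnames = list(colnames(m), NULL))
  } else {
    sc <- vegan::scores(fit, display = "sites",
                        choices = seq_along(eig), scaling = 1)
    ld <- vegan::scores(fit, display = "species",
                        choices = seq_along(eig), scaling = 1)
  }
  structure(list(
    eigenvalues = unname(eig),
    percent_explained = unname(100 * eig / total),
    site_scores = dplyr::bind_cols(tibble::tibble(sample_id = rownames(sc)),
                                   tibble::as_tibble(sc, .name_repair = "minimal")),
    loadings = dplyr::bind_cols(tibble::tibble(taxon = rownames(ld)),
                                tibble::as_tibble(ld, .name_repair = "minimal")),
    constrained = constrained, adjusted_R2 = adjusted_R2, R2 = R2,
    degenerate = FALSE, fit = fit
  ), class = "ordination")
}

#' Principal component analysis of a composition matrix
#'
#' Column-centered singular decomposition (no scaling); eigenvalues are
#' squared singular values / (n - 1) and sum to the total variance.
#'
#' @param x Sample-by-taxon tibble or matrix (typically Hellinger-transformed).
#' @return An `ordination` object (unconstrained).
#' @export
pca_ordination <- function(x) {
  m <- if (is.matrix(x)) x else count_matrix(x, id_col = "sample_id")
  if (nrow(m) < 2) stop("pca needs at least 2 rows", call. = FALSE)
  if (sum(scale(m, scale = FALSE)^2) < 1e-12) {
    return(ordination_result(NULL, m, constrained = FALSE, degenerate = TRUE))
  }
  fit <- vegan::rda(m)
  ordination_result(fit, m, constrained = FALSE)
}

#' Redundancy analysis (constrained ordination)
#'
#' Non-scaled RDA: the part of the (column-centered) composition matrix
#' explained by the dummy-coded predictors is extracted by regression and
#' decomposed by singular decomposition. Optional `condition` variables are
#' partialled out first (partial RDA). The adjusted R2 follows Ezekiel's
#' formula 1 - (1 - R2)(n - 1)/(n - m - 1) with m coded predictor columns.
#'
#' @param x Sample-by-taxon tibble or matrix.
#' @param design Tibble of sample covariates (matched as in [permanova()]).
#' @param formula RHS-only formula of predictors, e.g. `~ phase + season` or
#'   `~ phase_season` for an interaction coded as one factor.
#' @param condition Optional character vector of covariate columns to
#'   partial out (e.g. a sampling grid).
#' @return An `ordination` object with `constrained = TRUE`, `R2` and
#'   `adjusted_R2`.
#' @export
rda_ordination <- function(x, design, formula, condition = NULL) {
  al <- align_design(x, design)
  check_term_levels(formula, al$design)
  dat <- as.data.frame(al$design)
  rhs <- as.character(formula)[2]
  if (!is.null(condition)) {
    rhs <- paste(rhs, "+", sprintf("Condition(%s)", paste(condition, collapse = " + ")))
  }
  m <- al$m
  f <- stats::as.formula(paste("m ~", rhs))
  fit <- vegan::rda(f, data = dat)
  r2 <- vegan::RsquareAdj(fit)
  ordination_result(fit, m, constrained = TRUE,
                    adjusted_R2 = r2$adj.r.squared %||% NA_real_,
                    R2 = r2$r.squared %||% NA_real_)
}

#' @export
print.ordination <- function(x, ...) {
  kind <- if (x$constrained) "RDA" else "PCA"
  if (x$degenerate) {
    cat(sprintf("<ordination> %s degenerate: constant matrix\n", kind))
    return(invisible(x))
  }
  cat(sprintf("<ordination> %s, %d axes\n", kind, length(x$eigenvalues)))
  cat("  % explained:", paste(sprintf("%.1f", head(x$percent_explained, 5)), collapse = ", "),
      if (length(x$percent_explained) > 5) "..." else "", "\n")
  if (x$constrained) cat(sprintf("  R2 = %.4f, adjusted R2 = %.4f\n", x$R2, x$adjusted_R2))
  invisible(x)
}

# cumulative QR projections for sequential (Type I) sums of squares
sequential_qr <- function(X, assign) {
  ks <- sort(unique(assign))
  lapply(ks, function(k) {
    Xi <- X[, assign <= k, drop = FALSE]
    q <- qr(Xi)
    list(Q = qr.Q(q)[, seq_len(q$rank), drop = FALSE], rank = q$rank)
  })
}

#' Permutation ANOVA for a scalar response
#'
#' Fits `y ~ terms` by least squares, computes sequential (Type I) sums of
#' squares per term, and obtains p-values by recomputing the F statistics
#' under random permutations of `y` (add-one estimator). Dummy coding uses
#' treatment contrasts with the alphabetically first level as reference.
#'
#' @param y Numeric response, one value per sample (e.g. Hill diversity).
#' @param design Tibble of covariates, same order as `y` (or carrying
#'   `sample_id` matched against `names(y)`).
#' @param formula RHS-only formula, e.g. `~ phase * season`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A `perm_anova`: list with `table` (term, df, sum_of_squares,
#'   mean_square, statistic, p_value; last row = residual), `n_perm`,
#'   `seed`, `degenerate`.
#' @export
permutation_anova <- function(y, design, formula, n_perm = 999, seed = NULL) {
  stopifnot(n_perm >= 1)
  design <- tibble::as_tibble(design)
  if (!is.null(names(y)) && "sample_id" %in% names(design)) {
    design <- design[match(names(y), design$sample_id), ]
  }
  n <- length(y)
  stopifnot(nrow(design) == n)
  dat <- as.data.frame(lapply(design, function(col) {
    if (is.character(col)) factor(col, levels = sort(unique(col))) else col
  }))
  X <- model.matrix(formula, dat)
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(formula), "term.labels")
  ss_total <- sum((y - mean(y))^2)
  if (ss_total < 1e-12) {
    tab <- tibble::tibble(term = c(labels, "residual"),
                          df = NA_integer_, sum_of_squares = 0,
                          mean_square = 0, statistic = NA_real_,
                          p_value = c(rep(1, length(labels)), NA_real_))
    return(structure(list(table = tab, n_perm = n_perm, seed = seed,
                          degenerate = TRUE), class = "perm_anova"))
  }
  qrs <- sequential_qr(X, assign)
  ranks <- vapply(qrs, `[[`, integer(1), "rank")
  df_terms <- diff(ranks)                    # first entry of ranks = intercept rank
  df_res <- n - ranks[length(ranks)]

  fstats <- function(yy) {
    # model SS after each cumulative block, for all columns of yy at once
    css <- vapply(qrs, function(qq) colSums(crossprod(qq$Q, yy)^2),
                  numeric(ncol(yy)))
    if (ncol(yy) == 1) css <- matrix(css, nrow = 1)
    ss_term <- css[, -1, drop = FALSE] - css[, -ncol(css), drop = FALSE]
    tot <- colSums(yy^2) - css[, 1]
    ss_res <- tot - rowSums(ss_term)
    F <- sweep(ss_term, 2, df_terms, "/") / (ss_res / df_res)
    list(F = F, ss_term = ss_term, ss_res = ss_res)
  }
  obs <- fstats(matrix(y, ncol = 1))
  if (!is.null(seed)) set.seed(seed)
  perm_y <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
  perm <- fstats(perm_y)
  exceed <- colSums(sweep(perm$F, 2, obs$F[1, ], ">=") * 1)
  p <- (1 + exceed) / (1 + n_perm)
  tab <- tibble::tibble(
    term = c(labels, "residual"),
    df = c(df_terms, df_res),
    sum_of_squares = c(obs$ss_term[1, ], obs$ss_res[1]),
    mean_square = c(obs$ss_term[1, ] / df_terms, obs$ss_res[1] / df_res),
    statistic = c(obs$F[1, ], NA_real_),
    p_value = c(p, NA_real_)
  )
  structure(list(table = tab, n_perm = n_perm, seed = seed, degenerate = FALSE),
            class = "perm_anova")
}

#' @export
print.perm_anova <- function(x, ...) {
  cat(sprintf("<perm_anova> %d permutations%s\n", x$n_perm,
              if (x$degenerate) " (degenerate: constant response)" else ""))
  print(as.data.frame(x$table))
  invisible(x)
}
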
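# broom-style tidiers for the package's fitted objects.

#' Tidy a PERMANOVA fit
#'
#' @param x A `permanova_fit` from [permanova()].
#' @param ... Unused.
#' @return Tibble with one row per term: term, df, sum_of_squares, R2,
#'   statistic, p_value.
#' @export
tidy.permanova_fit <- function(x, ...) {
  x$table
}

#' @rdname tidy.permanova_fit
#' @return For `glance()`: a one-row tibble with n_perm, degenerate, and the
#'   first tested term's statistic and p-value.
#' @export
glance.permanova_fit <- function(x, ...) {
  if (x$degenerate || nrow(x$table) == 0) {
    return(tibble::tibble(n_perm = x$n_perm, degenerate = TRUE,
                          statistic = NA_real_, p_value = NA_real_))
  }
  first <- x$table[1, ]
  tibble::tibble(n_perm = x$n_perm, degenerate = FALSE,
                 statistic = first$statistic, p_value = first$p_value)
}

#' Tidy an ordination
#'
#' @param x An `ordination` from [pca_ordination()] or [rda_ordination()].
#' @param ... Unused.
#' @return Tibble with one row per axis: axis, eigenvalue, percent_explained.
#' @export
tidy.ordination <- function(x, ...) {
  if (x$degenerate) {
    return(tibble::tibble(axis = integer(), eigenvalue = double(),
                          percent_explained = double()))
  }
  tibble::tibble(axis = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 percent_explained = x$percent_explained)
}

#' @rdname tidy.ordination
#' @export
glance.ordination <- function(x, ...) {
  tibble::tibble(constrained = x$constrained,
                 n_axes = length(x$eigenvalues),
                 R2 = x$R2, adjusted_R2 = x$adjusted_R2,
                 degenerate = x$degenerate)
}

#' Tidy a permutation ANOVA
#'
#' @param x A `perm_anova` from [permutation_anova()].
#' @param ... Unused.
#' @return The per-term table (last row is the residual).
#' @export
tidy.perm_anova <- function(x, ...) {
  x$table
}

#' @rdname tidy.perm_anova
#' @export
glance.perm_anova <- function(x, ...) {
  res <- x$table[x$table$term == "residual", ]
  tot <- sum(x$table$sum_of_squares, na.rm = TRUE)
  tibble::tibble(n_perm = x$n_perm, degenerate = x$degenerate,
                 residual_share = if (x$degenerate || tot == 0) NA_real_
                                  else res$sum_of_squares / tot)
}

#' Tidy a replicate QC report
#'
#' @param x A `qc_report` from [filter_replicates_iterative()].
#' @param ... Unused.
#' @return The removal table: iteration, replicate_id, sample_id, dw,
#'   threshold.
#' @export
tidy.qc_report <- function(x, ...) {
  x$removed
}

#' @rdname tidy.qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(n_iterations = x$n_iterations, converged = x$converged,
                 n_removed = nrow(x$removed),
                 n_failed = length(x$failed_replicates),
                 n_samples_dropped = length(x$samples_dropped))
}

#' Tidy a recovery report
#'
#' @param x A `recovery_report` from [run_recovery_experiment()].
#' @param ... Unused.
#' @return The per-study metrics tibble.
#' @export
tidy.recovery_report <- function(x, ...) {
  x$per_study
}

#' @rdname tidy.recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  ps <- x$per_study
  tibble::tibble(n_studies = nrow(ps),
                 sensitivity = mean(ps$sensitivity, na.rm = TRUE),
                 false_removal = mean(ps$false_removal, na.rm = TRUE),
                 spearman_truth = mean(ps$spearman_truth, na.rm = TRUE),
                 diversity_bias = mean(ps$diversity_bias, na.rm = TRUE))
}
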
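# Diet metrics: relative read abundance (RRA), weighted percent of
# occurrence (wPOO), Hill-number diversity, and aggregation to coarser
# taxonomic or functional groupings.

#' Relative read abundance
#'
#' Divides each row (sample or replicate) by its total, so rows sum to 1.
#' Idempotent. All-zero rows are left at zero and flagged in the
#' `"empty_rows"` attribute.
#'
#' @param x Tibble with an id column (`sample_id` or `replicate_id`) and
#'   numeric columns, or a plain numeric matrix.
#' @return Same shape, rows normalized.
#' @export
rra <- function(x) {
  if (is.matrix(x)) return(row_normalize(x))
  motus <- motu_cols(x)
  m <- row_normalize(as.matrix(x[, motus, drop = FALSE]))
  out <- dplyr::bind_cols(x[, setdiff(names(x), motus), drop = FALSE],
                          tibble::as_tibble(m, .name_repair = "minimal"))
  attr(out, "marker_id") <- attr(x, "marker_id")
  attr(out, "taxa") <- attr(x, "taxa")
  attr(out, "empty_rows") <- which(rowSums(m) == 0)
  class(out) <- class(x)
  out
}

#' Weighted percent of occurrence (wPOO)
#'
#' Each occurrence of a taxon in a sample is down-weighted by the number of
#' taxa occurring in that sample: a sample containing exactly taxa A, B and
#' C contributes one third to each, not one. wPOO(t) is the mean of these
#' quotients across samples, so taxa are weighted by how exclusive their
#' occurrences are. Samples with zero occurrences are excluded from the mean
#' and reported. Over taxa, wPOO sums to 1 whenever every included sample
#' has at least one occurrence.
#'
#' @param occurrences Binary sample-by-taxon tibble (`sample_id` + 0/1
#'   columns), e.g. from [occurrence_union()].
#' @return Tibble: `taxon`, `wpoo`, `n_samples` (samples with occurrences).
#'   Attribute `"excluded_samples"` lists zero-occurrence samples.
#' @export
wpoo <- function(occurrences) {
  m <- count_matrix(occurrences, id_col = "sample_id")
  if (any(!m %in% c(0, 1))) stop("occurrences must be binary", call. = FALSE)
  k <- rowSums(m)
  excluded <- occurrences$sample_id[k == 0]
  m <- m[k > 0, , drop = FALSE]
  k <- k[k > 0]
  w <- if (nrow(m) == 0) rep(NA_real_, ncol(m)) else colMeans(m / k)
  out <- tibble::tibble(taxon = colnames(m), wpoo = unname(w),
                        n_samples = nrow(m))
  attr(out, "excluded_samples") <- excluded
  out
}

hill_number <- function(p, q) {
  if (any(p < 0)) stop("negative abundance in profile", call. = FALSE)
  p <- p[p > 0]
  if (length(p) == 0) return(NA_real_)
  p <- p / sum(p)
  if (abs(q - 1) < 1e-10) {
    exp(-sum(p * log(p)))        # q -> 1 limit: exponential of Shannon entropy
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

#' Hill-number diversity per sample
#'
#' The effective number of equally abundant taxa at order q:
#' \deqn{{}^qD = (\sum_i p_i^q)^{1/(1-q)}}{^qD = (sum p_i^q)^(1/(1-q))}
#' with the analytic limit \eqn{{}^1D = \exp(-\sum_i p_i \ln p_i)} at q = 1.
#' q = 0 gives taxon richness; \eqn{{}^qD} is non-increasing in q. Zero
#' entries are ignored; empty rows give `NA`.
#'
#' @param profile Sample-by-taxon tibble of relative abundances, or a
#'   numeric vector (one profile).
#' @param q Diversity order(s), each >= 0.
#' @return Tibble: `sample_id`, `q`, `diversity`.
#' @export
hill_diversity <- function(profile, q = 1) {
  stopifnot(all(q >= 0))
  if (is.numeric(profile) && is.null(dim(profile))) {
    profile <- dplyr::bind_cols(tibble::tibble(sample_id = "profile"),
                                tibble::as_tibble(as.list(setNames(profile,
                                  paste0("t", seq_along(profile))))))
  }
  m <- count_matrix(profile, id_col = "sample_id")
  tidyr::expand_grid(sample_id = profile$sample_id, q = q) |>
    dplyr::mutate(diversity = purrr::map2_dbl(.data$sample_id, .data$q,
      function(s, qq) hill_number(m[s, ], qq)))
}

#' Aggregate a profile to coarser groups
#'
#' Sums member proportions by an annotation key: a lineage rank (e.g.
#' `"genus"`, `"family"`), `"dietary_category"` or `"functional_group"`.
#' Taxa lacking the annotation are pooled into `"other"`. Aggregation
#' commutes with [rra()].
#'
#' @param profile Sample-by-taxon tibble; for a `diet_profile` the `"taxa"`
#'   attribute supplies annotations unless `annotations` is given.
#' @param by Annotation column to group by.
#' @param annotations Optional tibble with `taxon` (or `motu_id`) and the
#'   `by` column.
#' @return Sample-by-group tibble; rows sum as in the input.
#' @export
aggregate_profile <- function(profile, by, annotations = NULL) {
  ann <- annotations %||% attr(profile, "taxa")
  if (is.null(ann)) stop("no annotations available for aggregation", call. = FALSE)
  ann <- tibble::as_tibble(ann)
  if (!"taxon" %in% names(ann) && "motu_id" %in% names(ann)) {
    ann <- dplyr::rename(ann, taxon = "motu_id")
  }
  if (!by %in% names(ann)) {
    stop(sprintf("annotation column '%s' not found", by), call. = FALSE)
  }
  taxa <- motu_cols(profile)
  key <- as.character(ann[[by]][match(taxa, ann$taxon)])
  key[is.na(key) | key == "none"] <- "other"
  m <- count_matrix(profile, id_col = "sample_id")
  agg <- t(rowsum(t(m), group = key))
  dplyr::bind_cols(tibble::tibble(sample_id = profile$sample_id),
                   tibble::as_tibble(agg, .name_repair = "minimal"))
}
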
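# Global and per-sample MOTU filters, taxonomic-scope restriction, and
# screening of PCR controls. The per-sample 1% rule is the tag-jump filter:
# index switching between libraries deposits small numbers of reads in the
# wrong replicate, so within-sample proportions below 1% are zeroed.

#' Global MOTU filter on sequence length and dataset-wide reads
#'
#' Drops MOTUs whose sequence is shorter than `min_len` base pairs or whose
#' total read count over the whole table is less than or equal to
#' `min_total_reads` (boundary semantics: exactly `min_total_reads` reads is
#' removed; exactly `min_len` bp is kept). The two criteria commute and the
#' filter is idempotent.
#'
#' @param table A `replicate_table`.
#' @param records MOTU records covering every MOTU column (see
#'   [validate_motu_records()]).
#' @param min_len Minimum sequence length in bp (default 10).
#' @param min_total_reads Reads threshold; MOTUs at or below it are dropped
#'   (default 10).
#' @return The filtered `replicate_table`.
#' @export
filter_global <- function(table, records, min_len = 10, min_total_reads = 10) {
  motus <- motu_cols(table)
  if (length(motus) == 0) return(table)
  missing <- setdiff(motus, records$motu_id)
  if (length(missing) > 0) {
    stop(sprintf("MOTU(s) without records: %s", paste(head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  len <- records$seq_length[match(motus, records$motu_id)]
  tot <- colSums(count_matrix(table))
  drop <- len < min_len | tot <= min_total_reads
  out <- table[, c(meta_cols(), motus[!drop]), drop = FALSE]
  class(out) <- c("replicate_table", setdiff(class(out), "replicate_table"))
  out
}

#' Per-sample minimum-proportion (tag-jump) filter
#'
#' Within each sample, entries with proportion strictly below `threshold`
#' are set to zero; MOTU columns that become all-zero are dropped and rows
#' are renormalized to sum to 1. Rows emptied entirely are kept (as zeros)
#' and flagged in the `"empty_samples"` attribute so downstream sample
#' bookkeeping stays honest. Idempotent, and never increases the number of
#' nonzero entries.
#'
#' @param table Sample-by-MOTU tibble of relative abundances (`sample_id` +
#'   numeric columns), e.g. from [average_replicates()].
#' @param threshold Proportion below which entries are zeroed (default 0.01).
#' @return The filtered sample table, rows renormalized.
#' @export
filter_min_proportion <- function(table, threshold = 0.01) {
  motus <- motu_cols(table)
  if (length(motus) == 0 || nrow(table) == 0) return(table)
  m <- count_matrix(table, id_col = "sample_id")
  m <- row_normalize(m)
  m[m < threshold] <- 0
  keep <- colSums(m) > 0
  m <- row_normalize(m[, keep, drop = FALSE])
  empty <- table$sample_id[rowSums(m) == 0]
  out <- dplyr::bind_cols(table[, "sample_id"],
                          tibble::as_tibble(m, .name_repair = "minimal"))
  attr(out, "marker_id") <- attr(table, "marker_id")
  attr(out, "empty_samples") <- union(attr(table, "empty_samples"), empty)
  out
}

#' Restrict a table to a marker's taxonomic scope
#'
#' Keeps MOTUs whose lineage contains at least one of the marker's target
#' clades (any rank). MOTUs lacking any lineage information are treated as
#' out of scope and listed in the `"out_of_scope"` attribute together with
#' the other removals.
#'
#' @param table A `replicate_table` or sample-by-MOTU tibble.
#' @param records MOTU records with lineage rank columns.
#' @param marker A [marker_spec()].
#' @return The table restricted to in-scope MOTUs; attribute
#'   `"out_of_scope"` lists dropped MOTU ids.
#' @export
filter_taxonomic_scope <- function(table, records, marker) {
  motus <- motu_cols(table)
  if (length(motus) == 0) return(table)
  records <- validate_motu_records(records)
  idx <- match(motus, records$motu_id)
  lin <- as.matrix(records[idx, lineage_ranks()])
  in_scope <- apply(lin, 1, function(r) any(r %in% marker$target_clades))
  in_scope[is.na(in_scope)] <- FALSE
  dropped <- motus[!in_scope]
  keep_cols <- c(intersect(names(table), c(meta_cols(), "sample_id")), motus[in_scope])
  out <- table[, keep_cols, drop = FALSE]
  class(out) <- class(table)
  attr(out, "marker_id") <- attr(table, "marker_id")
  attr(out, "empty_samples") <- attr(table, "empty_samples")
  attr(out, "out_of_scope") <- dropped
  out
}

#' Screen PCR control replicates
#'
#' Advisory report on the controls: per MOTU, its read share inside negative
#' controls (flagging dietary MOTUs above `flag_threshold` relative abundance
#' in any negative control), and a recovery check that every
#' positive-control MOTU (records with `is_control = TRUE`) was actually
#' retrieved in a positive-control replicate. Also estimates the tag-jump
#' leak rate as the share of positive-control reads found outside positive
#' controls. Nothing is subtracted from the data.
#'
#' @param table A `replicate_table` with `control_flag` set.
#' @param records MOTU records (`is_control` column marks positive-control
#'   sequences).
#' @param flag_threshold Relative abundance above which a dietary MOTU inside
#'   a negative control is flagged (default 0.01).
#' @return A `control_report`: list with `negatives` (per-MOTU share in each
#'   negative control, flagged), `positive_recovered` (per positive-control
#'   MOTU), `control_failures` (character), `leak_rate` (numeric or NA).
#' @export
screen_controls <- function(table, records, flag_threshold = 0.01) {
  records <- validate_motu_records(records)
  has_controls <- any(table$control_flag != "none")
  if (!has_controls) {
    warning("no control replicates present; empty control report")
    return(structure(list(negatives = tibble::tibble(), positive_recovered = tibble::tibble(),
                          control_failures = character(), leak_rate = NA_real_),
                     class = "control_report"))
  }
  m <- count_matrix(table)
  motus <- colnames(m)
  cat_of <- records$dietary_category[match(motus, records$motu_id)]

  neg_idx <- which(table$control_flag %in% c("pcr_negative", "extraction_negative"))
  negatives <- tibble::tibble()
  if (length(neg_idx) > 0) {
    nm <- row_normalize(m[neg_idx, , drop = FALSE])
    negatives <- tibble::tibble(
      replicate_id = rep(table$replicate_id[neg_idx], each = length(motus)),
      motu_id = rep(motus, times = length(neg_idx)),
      share = as.vector(t(nm)),
      dietary = rep(cat_of %in% dietary_categories(), times = length(neg_idx))
    ) |>
      dplyr::filter(.data$share > 0) |>
      dplyr::mutate(flagged = .data$dietary & .data$share > flag_threshold)
  }

  pos_motus <- records$motu_id[records$is_control]
  pos_idx <- which(table$control_flag == "pcr_positive")
  positive_recovered <- tibble::tibble()
  control_failures <- character()
  leak_rate <- NA_real_
  if (length(pos_motus) > 0) {
    present <- intersect(pos_motus, motus)
    rec <- vapply(present, function(mo) {
      length(pos_idx) > 0 && sum(m[pos_idx, mo]) > 0
    }, logical(1))
    positive_recovered <- tibble::tibble(motu_id = present, recovered = unname(rec))
    control_failures <- c(setdiff(pos_motus, motus), present[!rec])
    if (length(present) > 0) {
      tot <- sum(m[, present])
      outside <- sum(m[setdiff(seq_len(nrow(m)), pos_idx), present])
      if (tot > 0) leak_rate <- outside / tot
    }
  }
  structure(list(negatives = negatives, positive_recovered = positive_recovered,
                 control_failures = control_failures, leak_rate = leak_rate),
            class = "control_report")
}

#' @export
print.control_report <- function(x, ...) {
  n_flag <- if (nrow(x$negatives) > 0) sum(x$negatives$flagged) else 0L
  cat(sprintf("<control_report> %d flagged negative-control entr%s; %d control failure(s); leak rate %s\n",
              n_flag, if (n_flag == 1) "y" else "ies",
              length(x$control_failures),
              ifelse(is.na(x$leak_rate), "NA", format(x$leak_rate, digits = 3))))
  invisible(x)
}
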
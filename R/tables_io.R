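# Reading, validating and writing the pipeline's tabular formats. On disk,
# MOTU count tables are MOTU-by-replicate (the layout demultiplexers emit);
# in memory every table is a wide tibble with replicates (or samples) as rows.

#' Build a replicate count table from components
#'
#' @param counts Numeric matrix, replicates x MOTUs, with dimnames, or a data
#'   frame of counts with MOTU columns.
#' @param replicate_to_sample Named character vector or two-column data frame
#'   (`replicate_id`, `sample_id`) mapping every replicate to its sample.
#' @param marker_id Marker short name.
#' @param run_id Optional per-replicate run label (recycled if length 1).
#' @param control_flags Optional per-replicate flag: one of `"none"`,
#'   `"pcr_negative"`, `"extraction_negative"`, `"pcr_positive"`.
#'
#' @return A `replicate_table` tibble: columns `marker_id`, `run_id`,
#'   `replicate_id`, `sample_id`, `control_flag`, then one integer-valued
#'   column per MOTU.
#' @export
replicate_table <- function(counts, replicate_to_sample, marker_id,
                            run_id = NA_character_, control_flags = "none") {
  m <- as.matrix(counts)
  if (is.null(rownames(m))) stop("counts must have replicate ids as rownames", call. = FALSE)
  if (is.null(colnames(m))) stop("counts must have MOTU ids as colnames", call. = FALSE)
  validate_counts(m)
  map <- normalize_map(replicate_to_sample)
  orphan <- setdiff(rownames(m), map$replicate_id)
  if (length(orphan) > 0) {
    stop(sprintf("replicate(s) missing from the replicate-to-sample map: %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop(sprintf("duplicate MOTU id(s): %s",
                 paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")),
         call. = FALSE)
  }
  ok_flags <- c("none", "pcr_negative", "extraction_negative", "pcr_positive")
  control_flags <- rep_len(control_flags, nrow(m))
  if (!all(control_flags %in% ok_flags)) {
    stop("control_flags must be one of: ", paste(ok_flags, collapse = ", "), call. = FALSE)
  }
  meta <- tibble::tibble(
    marker_id = marker_id,
    run_id = rep_len(run_id, nrow(m)),
    replicate_id = rownames(m),
    sample_id = map$sample_id[match(rownames(m), map$replicate_id)],
    control_flag = control_flags
  )
  out <- matrix_to_table(m, meta)
  class(out) <- c("replicate_table", class(out))
  out
}

validate_counts <- function(m) {
  if (!is.numeric(m)) stop("counts must be numeric", call. = FALSE)
  if (anyNA(m)) stop("counts contain unparseable or missing cells", call. = FALSE)
  if (any(m < 0)) stop("counts contain negative values", call. = FALSE)
  if (any(m != floor(m))) stop("counts must be integers", call. = FALSE)
  invisible(m)
}

normalize_map <- function(map) {
  if (is.data.frame(map)) {
    assert_tbl(map, c("replicate_id", "sample_id"), "replicate-to-sample map")
    map <- tibble::as_tibble(map[, c("replicate_id", "sample_id")])
  } else {
    map <- tibble::tibble(replicate_id = names(map), sample_id = unname(map))
  }
  if (anyDuplicated(map$replicate_id)) {
    stop("replicate mapped to more than one sample", call. = FALSE)
  }
  map
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Read a MOTU count table and its replicate-to-sample map
#'
#' Expects the file layout produced after demultiplexing: first column MOTU
#' ids, remaining columns one per PCR replicate, tab- or comma-separated. A
#' companion map file links replicate ids to sample ids; when `map` is
#' `NULL`, replicate names of the form `<sample>_R<k>` are split on the last
#' `"_R"`.
#'
#' @param path Count table path (TSV or CSV).
#' @param marker_id Marker short name recorded on every replicate.
#' @param map Path to a two-column TSV/CSV (`replicate_id`, `sample_id`), a
#'   data frame, a named vector, or `NULL` to derive samples from names.
#' @param run_id Optional run label.
#' @param control_flags Optional named vector replicate -> flag; unnamed
#'   replicates get `"none"`.
#'
#' @return A `replicate_table` tibble (see [replicate_table()]).
#' @export
read_replicate_table <- function(path, marker_id, map = NULL,
                                 run_id = NA_character_, control_flags = NULL) {
  raw <- read_delim_auto(path)
  motu_ids <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, function(col) as.numeric(as.character(col)),
                                 numeric(nrow(vals))))
  if (nrow(vals) == 1) num <- matrix(num, nrow = 1)
  bad <- is.na(num) & !is.na(as.matrix(vals))
  if (any(bad)) {
    stop(sprintf("unparseable count cell(s) in %s (e.g. '%s')", path,
                 as.matrix(vals)[which(bad)[1]]), call. = FALSE)
  }
  m <- t(num)                       # replicates x MOTUs
  rownames(m) <- colnames(vals)
  colnames(m) <- motu_ids
  if (is.null(map)) {
    reps <- rownames(m)
    if (!all(grepl("_R[0-9]+$", reps))) {
      stop("no map given and replicate names do not follow <sample>_R<k>", call. = FALSE)
    }
    map <- tibble::tibble(replicate_id = reps,
                          sample_id = sub("_R[0-9]+$", "", reps))
  } else if (is.character(map) && length(map) == 1 && file.exists(map)) {
    map <- read_delim_auto(map)
  }
  flags <- rep("none", nrow(m))
  if (!is.null(control_flags)) {
    hit <- match(rownames(m), names(control_flags))
    flags[!is.na(hit)] <- control_flags[hit[!is.na(hit)]]
  }
  replicate_table(m, map, marker_id = marker_id, run_id = run_id,
                  control_flags = flags)
}

#' Merge the count tables of two sequencing runs
#'
#' Element-wise sum over the union of replicates and MOTUs; a cell absent
#' from one run contributes zero. Replicate ids must identify the same
#' physical PCR in both runs. Merging is commutative and associative.
#'
#' @param a,b `replicate_table` tibbles for the same marker.
#' @return A merged `replicate_table`.
#' @export
merge_runs <- function(a, b) {
  ma <- unique(a$marker_id); mb <- unique(b$marker_id)
  if (nrow(a) > 0 && nrow(b) > 0 && !identical(ma, mb)) {
    stop(sprintf("marker mismatch: '%s' vs '%s'", ma, mb), call. = FALSE)
  }
  if (nrow(a) == 0) return(b)
  if (nrow(b) == 0) return(a)
  motus <- union(motu_cols(a), motu_cols(b))
  reps <- union(a$replicate_id, b$replicate_id)
  acc <- matrix(0, nrow = length(reps), ncol = length(motus),
                dimnames = list(reps, motus))
  for (tb in list(a, b)) {
    m <- count_matrix(tb)
    acc[rownames(m), colnames(m)] <- acc[rownames(m), colnames(m)] + m
  }
  meta <- dplyr::bind_rows(a[, meta_cols()], b[, meta_cols()]) |>
    dplyr::distinct(.data$replicate_id, .keep_all = TRUE)
  meta <- meta[match(reps, meta$replicate_id), ]
  meta$run_id <- NA_character_     # runs merged; per-run identity no longer meaningful
  out <- matrix_to_table(acc, meta)
  class(out) <- c("replicate_table", class(out))
  out
}

#' Write a diet profile to disk
#'
#' Writes the profile wide (samples as rows) as TSV, with a sidecar
#' `<path>.taxa.tsv` holding per-taxon annotations (dietary category,
#' functional group, source marker) when present. Non-finite values are
#' refused.
#'
#' @param profile A `diet_profile` (or any sample-by-taxon tibble).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_diet_profile <- function(profile, path) {
  m <- count_matrix(profile, id_col = "sample_id")
  if (nrow(m) > 0 && any(!is.finite(m))) {
    stop("profile contains non-finite values; refusing to write", call. = FALSE)
  }
  out <- dplyr::bind_cols(tibble::tibble(sample_id = profile$sample_id),
                          tibble::as_tibble(m, .name_repair = "minimal"))
  readr::write_tsv(out, path, progress = FALSE)
  taxa <- attr(profile, "taxa")
  if (!is.null(taxa)) {
    readr::write_tsv(taxa, paste0(path, ".taxa.tsv"), progress = FALSE)
  }
  invisible(path)
}

#' Read a diet profile written by [write_diet_profile()]
#'
#' @param path TSV path; a sidecar `<path>.taxa.tsv` is picked up if present.
#' @return A `diet_profile` tibble.
#' @export
read_diet_profile <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(sample_id = readr::col_character(),
                                               .default = readr::col_double()))
  x <- tibble::as_tibble(x)
  sidecar <- paste0(path, ".taxa.tsv")
  if (file.exists(sidecar)) {
    attr(x, "taxa") <- readr::read_tsv(sidecar, show_col_types = FALSE, progress = FALSE)
  }
  class(x) <- c("diet_profile", class(x))
  x
}

#' Read per-sample metadata
#'
#' Validates the categorical design fields against their allowed levels:
#' `vole_species` in bank/tundra, `season` in summer/winter, `phase` in
#' increase_peak/crash_low.
#'
#' @param path TSV/CSV with at least `sample_id`; design columns optional.
#' @return A validated tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- read_delim_auto(path)
  validate_sample_metadata(md)
}

#' @rdname read_sample_metadata
#' @param metadata A data frame to validate in place of a file.
#' @export
validate_sample_metadata <- function(metadata) {
  md <- tibble::as_tibble(metadata)
  assert_tbl(md, "sample_id", "sample metadata")
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata", call. = FALSE)
  levels <- list(vole_species = c("bank", "tundra"),
                 season = c("summer", "winter"),
                 phase = c("increase_peak", "crash_low"))
  for (col in names(levels)) {
    if (col %in% names(md)) {
      bad <- setdiff(unique(stats::na.omit(md[[col]])), levels[[col]])
      if (length(bad) > 0) {
        stop(sprintf("invalid %s level(s): %s", col, paste(bad, collapse = ", ")),
             call. = FALSE)
      }
    }
  }
  md
}

#' Read a MOTU annotation table
#'
#' @param path TSV/CSV with one row per MOTU; lineage as one rank per column.
#' @return A validated tibble (see [validate_motu_records()]).
#' @export
read_motu_records <- function(path) {
  validate_motu_records(read_delim_auto(path))
}
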
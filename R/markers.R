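#' Describe a metabarcoding primer set
#'
#' A marker specification names the primer set, the taxonomic clade(s) whose
#' members it is trusted to amplify (used by [filter_taxonomic_scope()]), and
#' the dietary categories it covers (used by [fuse_markers()]).
#'
#' @param marker_id Short unique name, e.g. `"sper01"`.
#' @param target_clades Character vector of clade names; a MOTU is in scope if
#'   any rank of its lineage matches one of these.
#' @param categories Dietary categories the marker covers; subset of
#'   `"plant"`, `"bryophyte"`, `"arthropod"`, `"lichen"`, `"mushroom"`.
#' @param gene_region Free-text description of the amplified region.
#'
#' @return A `marker_spec` object (a named list).
#' @export
#' @examples
#' marker_spec("sper01", "Spermatophyta", "plant", "trnL P6 loop")
marker_spec <- function(marker_id, target_clades, categories, gene_region = "") {
  stopifnot(is.character(marker_id), length(marker_id) == 1, nzchar(marker_id))
  if (length(target_clades) == 0 || any(!nzchar(target_clades))) {
    stop("target_clades must be non-empty", call. = FALSE)
  }
  bad <- setdiff(categories, dietary_categories())
  if (length(bad) > 0) {
    stop(sprintf("unknown dietary categor%s: %s",
                 if (length(bad) > 1) "ies" else "y",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(marker_id = marker_id, target_clades = as.character(target_clades),
         categories = as.character(categories), gene_region = gene_region),
    class = "marker_spec"
  )
}

#' @export
print.marker_spec <- function(x, ...) {
  cat(sprintf("<marker_spec> %s (%s)\n  scope: %s\n  categories: %s\n",
              x$marker_id, x$gene_region,
              paste(x$target_clades, collapse = ", "),
              paste(x$categories, collapse = ", ")))
  invisible(x)
}

#' Default diet-marker panel
#'
#' The five complementary primer sets used for full-spectrum herbivore diet
#' analysis: a seed-plant trnL marker, a bryophyte trnL marker, a fungal ITS1
#' marker covering mushrooms (Agaricomycetes) and lichens (Lecanoromycetes),
#' an arthropod COI marker, and a broad eukaryote 18S marker that serves as
#' the fusion scaffold.
#'
#' @return Named list of [marker_spec()] objects.
#' @export
default_markers <- function() {
  list(
    sper01 = marker_spec("sper01", "Spermatophyta", "plant", "trnL P6 loop"),
    bryo01 = marker_spec("bryo01", "Bryophyta", "bryophyte", "trnL P6 loop"),
    fung01 = marker_spec("fung01", c("Agaricomycetes", "Lecanoromycetes"),
                         c("mushroom", "lichen"), "ITS1"),
    arth01 = marker_spec("arth01", "Arthropoda", "arthropod", "COI Folmer region"),
    euka02 = marker_spec("euka02", "Eukaryota", dietary_categories(), "18S V7")
  )
}

#' Validate a MOTU record table
#'
#' MOTU records carry, per MOTU: the source marker, sequence length, lineage
#' (one column per rank: domain, kingdom, phylum, class, order, family,
#' genus), best assignment rank, dietary category and plant functional group.
#'
#' @param records A data frame with at least `motu_id`, `marker_id`,
#'   `seq_length`, `dietary_category`, `functional_group`. Missing lineage
#'   rank columns are added as `NA`.
#' @return A validated tibble.
#' @export
validate_motu_records <- function(records) {
  records <- tibble::as_tibble(records)
  assert_tbl(records, c("motu_id", "marker_id", "seq_length",
                        "dietary_category", "functional_group"), "MOTU records")
  dup <- records |>
    dplyr::count(.data$marker_id, .data$motu_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(sprintf("duplicate motu_id within marker: %s",
                 paste(dup$motu_id, collapse = ", ")), call. = FALSE)
  }
  if (any(records$seq_length < 0 | records$seq_length != floor(records$seq_length))) {
    stop("seq_length must be a non-negative integer", call. = FALSE)
  }
  ok_cat <- c(dietary_categories(), "other")
  bad <- setdiff(unique(records$dietary_category), ok_cat)
  if (length(bad) > 0) {
    stop(sprintf("unknown dietary_category: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  bad_fg <- records$functional_group != "none" & records$dietary_category != "plant"
  if (any(bad_fg)) {
    stop("functional_group other than 'none' requires dietary_category 'plant'",
         call. = FALSE)
  }
  for (r in lineage_ranks()) {
    if (!r %in% names(records)) records[[r]] <- NA_character_
  }
  if (!"is_control" %in% names(records)) records$is_control <- FALSE
  records
}
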
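# Fusing the five marker datasets into one diet profile per sample. The
# broad eukaryote marker sees all dietary categories at coarse taxonomic
# resolution and provides the category-level scaffold; each specialized
# marker then resolves the taxa *within* its categories, and its
# within-category relative read abundances are substituted into the
# scaffold proportions.

#' Dietary-category proportions from the eukaryote marker
#'
#' Aggregates a filtered, averaged eukaryote sample table to the five
#' dietary categories (plus `other`) using each MOTU's annotation.
#'
#' @param euka Sample-by-MOTU tibble (relative abundances) from the
#'   eukaryote marker.
#' @param records MOTU records carrying `dietary_category`.
#' @return Tibble: `sample_id`, `plant`, `bryophyte`, `arthropod`, `lichen`,
#'   `mushroom`, `other`; rows sum to 1.
#' @export
category_proportions <- function(euka, records) {
  records <- validate_motu_records(records)
  motus <- motu_cols(euka)
  cats <- records$dietary_category[match(motus, records$motu_id)]
  cats[is.na(cats)] <- "other"
  m <- count_matrix(euka, id_col = "sample_id")
  m <- row_normalize(m)
  agg <- t(rowsum(t(m), group = cats))
  all_cats <- c(dietary_categories(), "other")
  out <- matrix(0, nrow = nrow(m), ncol = length(all_cats),
                dimnames = list(rownames(m), all_cats))
  out[, colnames(agg)] <- agg
  dplyr::bind_cols(tibble::tibble(sample_id = euka$sample_id),
                   tibble::as_tibble(out, .name_repair = "minimal"))
}

#' Fuse specialized marker tables onto the eukaryote scaffold
#'
#' For each sample and dietary category with scaffold proportion p > 0, the
#' category's taxa receive p times their within-marker relative read
#' abundance (renormalized over that category's in-scope taxa). Categories
#' with p > 0 but no usable specialized data keep p on a placeholder taxon
#' `<category>_unresolved`. The `other` share of the scaffold is removed and
#' the five dietary categories are renormalized first, so each fused row
#' sums to 1 and, within each category, to the scaffold proportion (mass
#' conservation). Detections by a specialized marker in a category whose
#' scaffold proportion is zero contribute no fused mass; they are logged in
#' the `"occurrence_only"` attribute (they still count for occurrence-based
#' metrics via [occurrence_union()]).
#'
#' @param cat_props Output of [category_proportions()].
#' @param marker_tables Named list, dietary category -> sample-by-MOTU tibble
#'   from the specialized marker resolving that category (a table may be
#'   shared by several categories, e.g. a fungal marker for both `mushroom`
#'   and `lichen`; it is restricted to each category via `records`).
#' @param records MOTU records for all specialized-marker MOTUs.
#' @return A `diet_profile`: tibble `sample_id` + taxon columns, rows
#'   summing to 1; attributes `"taxa"` (taxon, dietary_category,
#'   functional_group, source_marker), `"occurrence_only"`,
#'   `"unfused_samples"`.
#' @export
fuse_markers <- function(cat_props, marker_tables, records) {
  records <- validate_motu_records(records)
  cats <- dietary_categories()
  cp <- as.matrix(cat_props[, cats])
  rownames(cp) <- cat_props$sample_id
  diet_tot <- rowSums(cp)
  unfused <- cat_props$sample_id[diet_tot == 0]
  keep <- diet_tot > 0
  cp <- cp[keep, , drop = FALSE] / diet_tot[keep]
  samples <- rownames(cp)

  blocks <- list()
  taxa_ann <- list()
  occ_only <- list()
  for (cat in cats) {
    tb <- marker_tables[[cat]]
    placeholder <- paste0(cat, "_unresolved")
    p <- cp[, cat]
    block <- matrix(0, nrow = length(samples), ncol = 0, dimnames = list(samples, NULL))
    if (!is.null(tb) && nrow(tb) > 0 && length(motu_cols(tb)) > 0) {
      motus <- motu_cols(tb)
      in_cat <- motus[records$dietary_category[match(motus, records$motu_id)] == cat]
      if (length(in_cat) > 0) {
        m <- count_matrix(tb[, c("sample_id", in_cat)], id_col = "sample_id")
        m <- m[intersect(rownames(m), samples), , drop = FALSE]
        mm <- matrix(0, nrow = length(samples), ncol = length(in_cat),
                     dimnames = list(samples, in_cat))
        mm[rownames(m), ] <- row_normalize(m)
        # specialized detections with zero scaffold support: occurrence only
        lost <- rownames(m)[rowSums(m) > 0 & p[rownames(m)] == 0]
        if (length(lost) > 0) {
          occ_only[[cat]] <- tibble::tibble(sample_id = lost, category = cat)
        }
        block <- mm * p
        taxa_ann[[cat]] <- tibble::tibble(
          taxon = in_cat, dietary_category = cat,
          functional_group = records$functional_group[match(in_cat, records$motu_id)],
          source_marker = attr(tb, "marker_id") %||% NA_character_
        )
      }
    }
    # residual scaffold mass not resolved by a specialized marker
    resolved <- if (ncol(block) > 0) rowSums(block) else rep(0, length(samples))
    residual <- p - resolved
    residual[abs(residual) < 1e-12] <- 0
    if (any(residual > 0)) {
      block <- cbind(block, matrix(residual, ncol = 1, dimnames = list(samples, placeholder)))
      taxa_ann[[paste0(cat, "_ph")]] <- tibble::tibble(
        taxon = placeholder, dietary_category = cat,
        functional_group = "none", source_marker = "euka_scaffold"
      )
    }
    blocks[[cat]] <- block
  }
  fused <- do.call(cbind, blocks)
  colnames(fused) <- unlist(lapply(blocks, colnames))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = samples),
                          tibble::as_tibble(fused, .name_repair = "minimal"))
  attr(out, "taxa") <- dplyr::bind_rows(taxa_ann)
  attr(out, "occurrence_only") <- if (length(occ_only)) dplyr::bind_rows(occ_only) else tibble::tibble()
  attr(out, "unfused_samples") <- unfused
  class(out) <- c("diet_profile", class(out))
  out
}

#' Occurrence union across markers
#'
#' A taxon occurs in a sample when its within-marker relative read abundance
#' is strictly above `threshold`; occurrences are unioned over markers so
#' that detections without eukaryote-scaffold support still count. Feeds
#' [wpoo()].
#'
#' @param marker_tables List of sample-by-MOTU tibbles (relative abundances).
#' @param threshold Strict occurrence threshold (default 0.01).
#' @return Binary tibble: `sample_id` + one 0/1 column per taxon, over the
#'   union of samples and taxa.
#' @export
occurrence_union <- function(marker_tables, threshold = 0.01) {
  marker_tables <- Filter(function(tb) !is.null(tb) && nrow(tb) > 0, marker_tables)
  if (length(marker_tables) == 0) return(tibble::tibble(sample_id = character()))
  samples <- sort(unique(unlist(lapply(marker_tables, function(tb) tb$sample_id))))
  taxa <- unique(unlist(lapply(marker_tables, motu_cols)))
  occ <- matrix(0, nrow = length(samples), ncol = length(taxa),
                dimnames = list(samples, taxa))
  for (tb in marker_tables) {
    if (length(motu_cols(tb)) == 0) next
    m <- row_normalize(count_matrix(tb, id_col = "sample_id"))
    hit <- (m > threshold) * 1
    occ[rownames(hit), colnames(hit)] <- pmax(occ[rownames(hit), colnames(hit), drop = FALSE], hit)
  }
  dplyr::bind_cols(tibble::tibble(sample_id = samples),
                   tibble::as_tibble(occ, .name_repair = "minimal"))
}
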
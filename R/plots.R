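# ggplot2 graphics for the main result types.

#' Plot the dw/db distance distributions and threshold
#'
#' Density curves of the within-sample (dw) and between-sample (db)
#' distance distributions with the estimated rejection threshold; the
#' diagnostic to inspect before trusting the replicate filter.
#'
#' @param d A `replicate_distances` object.
#' @param threshold Optional threshold to draw; defaults to
#'   [estimate_threshold()] of `d`.
#' @return A ggplot object.
#' @export
plot_replicate_qc <- function(d, threshold = estimate_threshold(d)) {
  df <- dplyr::bind_rows(
    tibble::tibble(distance = d$dw$dw, which = "dw (replicate vs own sample mean)"),
    tibble::tibble(distance = d$db, which = "db (between sample means)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, fill = .data$which)) +
    ggplot2::geom_density(alpha = 0.4, adjust = 1) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "Euclidean distance", y = "density", fill = NULL,
                  title = "Replicate dissimilarity distributions",
                  subtitle = sprintf("threshold = %.3f", threshold)) +
    ggplot2::theme_minimal()
}

#' Stacked diet composition per sample
#'
#' @param profile A `diet_profile` (or sample-by-taxon tibble with a
#'   `"taxa"` attribute).
#' @param metadata Optional sample metadata to facet by `phase`/`season`.
#' @param by Annotation used for the fill: `"dietary_category"` (default) or
#'   `"functional_group"`.
#' @return A ggplot object.
#' @export
plot_diet_composition <- function(profile, metadata = NULL, by = "dietary_category") {
  agg <- aggregate_profile(profile, by = by)
  long <- tidyr::pivot_longer(agg, -"sample_id", names_to = by,
                              values_to = "proportion")
  if (!is.null(metadata)) {
    long <- dplyr::left_join(long, metadata, by = "sample_id")
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                          y = .data$proportion,
                                          fill = .data[[by]])) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "relative read abundance", fill = by) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(metadata) && all(c("phase", "season") %in% names(long))) {
    p <- p + ggplot2::facet_grid(~ .data$phase + .data$season,
                                 scales = "free_x", space = "free_x")
  }
  p
}

#' Ordination biplot
#'
#' Sample scores on the first two axes, labelled by percent of explained
#' variation; taxon loadings above `min_loading` drawn as arrows.
#'
#' @param object An `ordination`.
#' @param colour Optional vector (or metadata column values) colouring the
#'   samples.
#' @param min_loading Hide taxa whose loading length on the first two axes
#'   is below this (default 0.1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ordination <- function(object, colour = NULL, min_loading = 0.1, ...) {
  if (object$degenerate) stop("cannot plot a degenerate ordination", call. = FALSE)
  sc <- object$site_scores
  ax <- names(sc)[2:3]
  df <- tibble::tibble(x = sc[[ax[1]]], y = sc[[ax[2]]],
                       sample_id = sc$sample_id)
  if (!is.null(colour)) df$colour <- colour
  ld <- object$loadings
  ldf <- tibble::tibble(x = ld[[ax[1]]], y = ld[[ax[2]]], taxon = ld$taxon)
  ldf <- ldf[sqrt(ldf$x^2 + ldf$y^2) >= min_loading, ]
  lab <- sprintf("%s (%.1f%%)", ax, object$percent_explained[1:2])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    (if (is.null(colour)) ggplot2::geom_point(colour = "grey40")
     else ggplot2::geom_point(ggplot2::aes(colour = .data$colour))) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = lab[1], y = lab[2], colour = NULL,
                  title = if (object$constrained) "RDA" else "PCA") +
    ggplot2::theme_minimal()
  if (nrow(ldf) > 0) {
    p <- p +
      ggplot2::geom_segment(data = ldf,
        ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
        colour = "steelblue") +
      ggplot2::geom_text(data = ldf,
        ggplot2::aes(x = .data$x, y = .data$y, label = .data$taxon),
        size = 3, vjust = -0.5, colour = "steelblue")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
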
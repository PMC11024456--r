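# PCR-replicate outlier removal. Each replicate's relative-abundance profile
# is compared with the mean profile of its own sample (distance dw); the dw
# distribution is compared against the distribution of pairwise distances
# between sample mean profiles (db). Replicates are expected to resemble
# their own sample more than any two samples resemble each other (dw < db);
# replicates beyond the intersection of the two distributions are discarded,
# iteratively, until a fixpoint.

#' Relative-abundance profiles of PCR replicates
#'
#' Divides each replicate's counts by its total reads. Replicates with zero
#' total reads cannot be normalized; they are excluded and recorded in the
#' `"excluded"` attribute rather than divided by zero.
#'
#' @param table A `replicate_table`.
#' @return Tibble with `replicate_id`, `sample_id` and one column per MOTU;
#'   every row sums to 1. Attribute `"excluded"`: replicate ids with zero reads.
#' @export
replicate_profiles <- function(table) {
  m <- count_matrix(table)
  tot <- rowSums(m)
  keep <- tot > 0
  prof <- row_normalize(m[keep, , drop = FALSE])
  out <- dplyr::bind_cols(
    table[keep, c("replicate_id", "sample_id")],
    tibble::as_tibble(prof, .name_repair = "minimal")
  )
  attr(out, "excluded") <- table$replicate_id[!keep]
  out
}

sample_mean_profiles <- function(profiles) {
  m <- count_matrix(profiles, id_col = "replicate_id")
  sm <- rowsum(m, group = profiles$sample_id) /
    as.vector(table(profiles$sample_id)[sort(unique(profiles$sample_id))])
  sm[sort(unique(profiles$sample_id)), , drop = FALSE]
}

#' Within-sample (dw) and between-sample (db) distance distributions
#'
#' `dw[i]` is the Euclidean distance between replicate i's profile and the
#' unweighted mean profile of its own sample's replicates (the replicate
#' itself included); `db` holds all pairwise Euclidean distances between
#' sample mean profiles.
#'
#' @param profiles Output of [replicate_profiles()], or any tibble with
#'   `replicate_id`, `sample_id` and numeric profile columns.
#' @return A `replicate_distances` object: list with `dw` (tibble:
#'   `replicate_id`, `sample_id`, `dw`), `db` (numeric vector of length
#'   S(S-1)/2), and `threshold` (`NA` until [estimate_threshold()] is run).
#' @export
replicate_distances <- function(profiles) {
  assert_tbl(profiles, c("replicate_id", "sample_id"), "profiles")
  samples <- sort(unique(profiles$sample_id))
  if (length(samples) < 2) {
    stop("replicate_distances needs at least 2 samples (db is undefined otherwise)",
         call. = FALSE)
  }
  m <- count_matrix(profiles, id_col = "replicate_id")
  means <- sample_mean_profiles(profiles)
  dw <- sqrt(rowSums((m - means[profiles$sample_id, , drop = FALSE])^2))
  db <- as.vector(dist(means))
  structure(
    list(dw = tibble::tibble(replicate_id = profiles$replicate_id,
                             sample_id = profiles$sample_id, dw = unname(dw)),
         db = db, threshold = NA_real_),
    class = "replicate_distances"
  )
}

#' @export
print.replicate_distances <- function(x, ...) {
  cat(sprintf("<replicate_distances> %d replicates, %d sample pairs\n",
              nrow(x$dw), length(x$db)))
  cat(sprintf("  dw: [%.4g, %.4g]  db: [%.4g, %.4g]  threshold: %s\n",
              min(x$dw$dw), max(x$dw$dw), min(x$db), max(x$db),
              ifelse(is.na(x$threshold), "unset", format(x$threshold, digits = 4))))
  invisible(x)
}

#' Estimate the dw/db dissimilarity threshold
#'
#' The rejection threshold is the intersection of the dw and db
#' distributions, estimated as the smallest point where a Gaussian
#' kernel-density estimate of dw (Silverman's rule-of-thumb bandwidth,
#' 512-point grid on \[0, max(db)\]) falls below that of db, searched to the
#' right of the dw mode. When the densities do not cross (dw entirely below
#' db) the midpoint of max(dw) and min(db) is returned; when dw is degenerate
#' (all values equal) the threshold is that value plus half the distance to
#' min(db).
#'
#' @param d A `replicate_distances` object, or a list with numeric `dw`, `db`.
#' @return The threshold (non-negative scalar).
#' @export
estimate_threshold <- function(d) {
  dw <- if (is.data.frame(d$dw)) d$dw$dw else d$dw
  db <- d$db
  if (length(dw) == 0 || length(db) == 0) {
    stop("estimate_threshold: dw and db must be non-empty", call. = FALSE)
  }
  if (max(dw) < min(db)) {
    # separated (or degenerate-dw) case: split the gap
    return((max(dw) + min(db)) / 2)
  }
  if (sd(dw) == 0) {
    # degenerate dw overlapping db's range: step half-way toward db
    return(dw[1] + (min(db) - dw[1]) / 2)
  }
  grid_max <- max(db)
  fd <- density(dw, bw = "nrd0", n = 512, from = 0, to = grid_max)
  fb <- if (sd(db) == 0) {
    # point-mass db: treat as a spike at its value
    y <- rep(0, 512)
    y[which.min(abs(fd$x - db[1]))] <- Inf
    list(x = fd$x, y = y)
  } else {
    density(db, bw = "nrd0", n = 512, from = 0, to = grid_max)
  }
  mode_i <- which.max(fd$y)
  below <- which(fd$y < fb$y)
  below <- below[below > mode_i]
  if (length(below) == 0) {
    return((max(dw) + min(db)) / 2)
  }
  fd$x[below[1]]
}

#' Iteratively remove outlier PCR replicates
#'
#' On each iteration: recompute replicate profiles, dw/db distances and the
#' dissimilarity threshold, then drop every replicate with dw strictly above
#' the threshold (ties kept). Stops when an iteration removes nothing or
#' `max_iter` is reached; on convergence the result is a fixpoint. Control
#' replicates (flag other than `"none"`) and zero-read replicates take no
#' part in the procedure; the latter are dropped up front and reported.
#'
#' @param table A `replicate_table`.
#' @param max_iter Maximum number of iterations (default 20).
#' @return List with `table` (the filtered `replicate_table`, controls
#'   retained) and `report` (a `qc_report`: `removed` tibble with iteration,
#'   replicate_id, sample_id, dw, threshold; `thresholds` per iteration;
#'   `n_iterations`; `converged`; `samples_dropped`; `failed_replicates`).
#' @export
filter_replicates_iterative <- function(table, max_iter = 20) {
  stopifnot(max_iter >= 1)
  is_control <- table$control_flag != "none"
  controls <- table[is_control, ]
  work <- table[!is_control, ]

  tot <- rowSums(count_matrix(work))
  failed <- work$replicate_id[tot == 0]
  work <- work[tot > 0, ]

  removed <- tibble::tibble(iteration = integer(), replicate_id = character(),
                            sample_id = character(), dw = double(),
                            threshold = double())
  thresholds <- double()
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    if (length(unique(work$sample_id)) < 2 || nrow(work) < 2) {
      converged <- TRUE
      it <- it - 1L
      break
    }
    prof <- replicate_profiles(work)
    d <- replicate_distances(prof)
    thr <- estimate_threshold(d)
    thresholds <- c(thresholds, thr)
    out <- d$dw[d$dw$dw > thr, ]
    if (nrow(out) == 0) {
      converged <- TRUE
      break
    }
    removed <- dplyr::bind_rows(removed,
      tibble::tibble(iteration = it, replicate_id = out$replicate_id,
                     sample_id = out$sample_id, dw = out$dw, threshold = thr))
    work <- work[!work$replicate_id %in% out$replicate_id, ]
  }
  all_samples <- unique(table$sample_id[!is_control])
  samples_dropped <- setdiff(all_samples, unique(work$sample_id))
  kept <- dplyr::bind_rows(work, controls)
  class(kept) <- c("replicate_table", setdiff(class(kept), "replicate_table"))
  report <- structure(
    list(removed = removed, thresholds = thresholds,
         n_iterations = max(it, 1L), converged = converged,
         samples_dropped = samples_dropped, failed_replicates = failed),
    class = "qc_report"
  )
  list(table = kept, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d iteration(s)%s; %d replicate(s) removed, %d failed, %d sample(s) dropped\n",
              x$n_iterations, if (x$converged) " (converged)" else "",
              nrow(x$removed), length(x$failed_replicates),
              length(x$samples_dropped)))
  invisible(x)
}

#' Average surviving PCR replicates per sample
#'
#' Each sample's profile is the unweighted mean of its replicates'
#' relative-abundance profiles, giving equal weight to each replicate
#' regardless of sequencing depth. Control and zero-read replicates are
#' excluded; samples left with no usable replicate are excluded and reported
#' in the `"empty_samples"` attribute.
#'
#' @param table A `replicate_table`.
#' @return A sample-by-MOTU tibble (`sample_id` + MOTU columns); every row
#'   sums to 1. Attributes: `"marker_id"`, `"empty_samples"`.
#' @export
average_replicates <- function(table) {
  work <- table[table$control_flag == "none", ]
  prof <- replicate_profiles(work)
  excluded <- attr(prof, "excluded")
  if (nrow(prof) == 0) {
    out <- tibble::tibble(sample_id = character())
    attr(out, "empty_samples") <- unique(work$sample_id)
    attr(out, "marker_id") <- unique(table$marker_id)
    return(out)
  }
  means <- sample_mean_profiles(prof)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(means)),
                          tibble::as_tibble(means, .name_repair = "minimal"))
  attr(out, "empty_samples") <-
    setdiff(unique(work$sample_id), out$sample_id)
  attr(out, "marker_id") <- unique(table$marker_id)
  out
}
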
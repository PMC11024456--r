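# End-to-end orchestration: merge_runs -> filter_global -> replicate_qc ->
# filter_min_proportion -> filter_taxonomic_scope -> fusion -> metrics ->
# statistics, from a config list or YAML file, writing every intermediate
# and final table plus a machine-readable manifest.

pipeline_stages <- function() {
  c("merge_runs", "filter_global", "replicate_qc", "filter_min_proportion",
    "filter_taxonomic_scope", "fusion", "metrics", "statistics")
}

default_pipeline_options <- function() {
  list(min_len = 10, min_total_reads = 10, qc_max_iter = 20,
       min_prop = 0.01, occ_threshold = 0.01,
       min_prop_before_averaging = FALSE)
}

stage_error <- function(stage, e) {
  stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE)
}

#' Run the pipeline core on in-memory tables
#'
#' The computation shared by [run_pipeline()] and
#' [run_recovery_experiment()]: per marker, global MOTU filtering, iterative
#' replicate QC, replicate averaging, the per-sample minimum-proportion
#' filter and taxonomic-scope restriction; then eukaryote-scaffold fusion,
#' the occurrence union, Hill diversity and wPOO. No files are touched.
#'
#' @param tables Named list of `replicate_table`s, one per marker.
#' @param records MOTU records covering all markers.
#' @param metadata Sample metadata tibble.
#' @param markers Marker panel (named list of [marker_spec()]); defaults to
#'   [default_markers()].
#' @param options Filter settings overriding the defaults: `min_len`,
#'   `min_total_reads`, `qc_max_iter`, `min_prop`, `occ_threshold`,
#'   `min_prop_before_averaging`.
#' @return List with `qc_reports`, `averaged`, `scoped` (per marker),
#'   `cat_props`, `fused`, `occurrence`, `diversity`, `wpoo`, `log`,
#'   `options`.
#' @export
process_study <- function(tables, records, metadata, markers = default_markers(),
                          options = list()) {
  opts <- modifyList(default_pipeline_options(), options)
  records <- validate_motu_records(records)
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- c(log[[stage]] %||% character(), sprintf(...))
  }

  panel <- markers                    # declared panel, tables present or not
  markers <- markers[intersect(names(markers), names(tables))]
  qc_reports <- list()
  averaged <- list()
  scoped <- list()
  for (mk_id in names(markers)) {
    mk <- markers[[mk_id]]
    tb <- tables[[mk_id]]
    tb <- tryCatch(filter_global(tb, records, opts$min_len, opts$min_total_reads),
                   error = function(e) stage_error("filter_global", e))
    note("filter_global", "%s: %d MOTUs retained", mk_id, length(motu_cols(tb)))

    qc <- tryCatch(filter_replicates_iterative(tb, max_iter = opts$qc_max_iter),
                   error = function(e) stage_error("replicate_qc", e))
    qc_reports[[mk_id]] <- qc$report
    note("replicate_qc", "%s: %d replicate(s) removed in %d iteration(s)",
         mk_id, nrow(qc$report$removed), qc$report$n_iterations)

    avg <- average_replicates(qc$table)
    if (opts$min_prop_before_averaging) {
      # alternative ordering: zero sub-threshold entries per replicate first
      reps <- rra(qc$table[qc$table$control_flag == "none", ])
      reps_f <- filter_min_proportion(
        dplyr::rename(reps[, c("replicate_id", motu_cols(reps))], sample_id = "replicate_id"),
        opts$min_prop)
      reps_f <- dplyr::rename(reps_f, replicate_id = "sample_id")
      back <- dplyr::left_join(qc$table[qc$table$control_flag == "none", meta_cols()],
                               reps_f, by = "replicate_id")
      avg <- average_replicates(replicate_table_from_profiles(back))
      filt <- avg
    } else {
      filt <- tryCatch(filter_min_proportion(avg, opts$min_prop),
                       error = function(e) stage_error("filter_min_proportion", e))
    }
    note("filter_min_proportion", "%s: %d MOTUs after %.2g filter",
         mk_id, length(motu_cols(filt)), opts$min_prop)

    sc <- tryCatch(filter_taxonomic_scope(filt, records, mk),
                   error = function(e) stage_error("filter_taxonomic_scope", e))
    sc <- rra(sc)   # renormalize after scope restriction
    note("filter_taxonomic_scope", "%s: %d in-scope MOTUs (%d dropped)",
         mk_id, length(motu_cols(sc)), length(attr(sc, "out_of_scope") %||% character()))
    averaged[[mk_id]] <- avg
    scoped[[mk_id]] <- sc
  }

  # fusion: eukaryote scaffold + one specialized table per category
  fused <- NULL; cat_props <- NULL; occurrence <- NULL
  tryCatch({
    if (!"euka02" %in% names(scoped)) {
      stop("no eukaryote scaffold table (euka02) available", call. = FALSE)
    }
    cat_props <- category_proportions(scoped[["euka02"]], records)
    cat_tables <- list()
    for (mk_id in setdiff(names(markers), "euka02")) {
      for (cat in markers[[mk_id]]$categories) {
        if (!is.null(cat_tables[[cat]])) {
          stop(sprintf("two markers declared for category '%s'", cat), call. = FALSE)
        }
        cat_tables[[cat]] <- scoped[[mk_id]]
      }
    }
    declared <- unique(unlist(lapply(panel[setdiff(names(panel), "euka02")],
                                     `[[`, "categories")))
    missing <- declared[!declared %in% names(cat_tables)]
    if (length(missing) > 0) {
      stop(sprintf("no marker table for declared category: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    fused <- fuse_markers(cat_props, cat_tables, records)
    occurrence <- occurrence_union(scoped, threshold = opts$occ_threshold)
    note("fusion", "%d samples fused over %d taxa; %d unfused",
         nrow(fused), length(motu_cols(fused)),
         length(attr(fused, "unfused_samples")))
  }, error = function(e) stage_error("fusion", e))

  # metrics
  diversity <- NULL; wpoo_tab <- NULL
  tryCatch({
    diversity <- hill_diversity(fused, q = 1) |>
      dplyr::left_join(metadata, by = "sample_id")
    wpoo_tab <- wpoo(occurrence)
    note("metrics", "Hill q=1 over %d samples; wPOO over %d taxa",
         nrow(diversity), nrow(wpoo_tab))
  }, error = function(e) stage_error("metrics", e))

  list(qc_reports = qc_reports, averaged = averaged, scoped = scoped,
       cat_props = cat_props, fused = fused, occurrence = occurrence,
       diversity = diversity, wpoo = wpoo_tab, log = log, options = opts)
}

# rebuild a replicate_table from profile rows (used by the alternative
# filter-before-averaging ordering; profiles are scaled to integer pseudo-counts)
replicate_table_from_profiles <- function(x) {
  motus <- motu_cols(x)
  m <- round(as.matrix(x[, motus]) * 1e6)
  rownames(m) <- x$replicate_id
  replicate_table(m, x[, c("replicate_id", "sample_id")],
                  marker_id = unique(x$marker_id),
                  control_flags = x$control_flag)
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (!is.null(config$seed)) args$seed <- config$seed
    sim <- simulate_study(do.call(sim_config, args))
    return(list(tables = sim$tables, records = sim$records,
                metadata = sim$metadata, truth = sim$truth,
                markers = default_markers()[names(sim$tables)]))
  }
  if (is.null(config$markers)) {
    stop("config must declare either 'simulate' or 'markers'", call. = FALSE)
  }
  specs <- default_markers()
  tables <- list()
  for (mk_id in names(config$markers)) {
    entry <- config$markers[[mk_id]]
    paths <- entry$runs %||% entry$table
    if (is.null(paths)) {
      stop(sprintf("marker '%s' declares no count table", mk_id), call. = FALSE)
    }
    runs <- lapply(paths, read_replicate_table, marker_id = mk_id,
                   map = entry$map %||% NULL)
    tables[[mk_id]] <- Reduce(merge_runs, runs)
  }
  list(tables = tables,
       records = read_motu_records(config$records),
       metadata = read_sample_metadata(config$metadata),
       truth = NULL, markers = specs[names(tables)])
}

run_group_statistics <- function(fused, diversity, metadata, stats_cfg) {
  terms <- stats_cfg$terms %||% "phase + season"
  n_perm <- stats_cfg$n_perm %||% 999
  seed <- stats_cfg$seed %||% 1
  condition <- stats_cfg$condition %||% NULL
  f <- stats::as.formula(paste("~", terms))
  hel <- hellinger(fused)
  groups <- if ("vole_species" %in% names(metadata) &&
                length(unique(metadata$vole_species)) > 1) {
    split(metadata$sample_id, metadata$vole_species)
  } else {
    list(all = metadata$sample_id)
  }
  out <- list()
  for (g in names(groups)) {
    ids <- intersect(groups[[g]], hel$sample_id)
    sub <- hel[match(ids, hel$sample_id), ]
    md <- metadata[match(ids, metadata$sample_id), ]
    usable <- tryCatch({ check_term_levels(f, md); TRUE },
                       error = function(e) FALSE)
    if (length(ids) < 5 || !usable) next
    div <- diversity$diversity[match(ids, diversity$sample_id)]
    out[[g]] <- list(
      permanova = permanova(sub, md, f, n_perm = n_perm, seed = seed),
      pca = pca_ordination(sub),
      rda = rda_ordination(sub, md, f, condition = condition),
      diversity_anova = permutation_anova(div, md, f, n_perm = n_perm, seed = seed)
    )
  }
  out
}

#' Run the full diet-analysis pipeline
#'
#' Executes all stages on either simulated data (`config$simulate`) or
#' tables read from disk (`config$markers`, `config$metadata`,
#' `config$records`), writes every intermediate and final table under
#' `out_dir`, and records thresholds, seeds and stage-by-stage survivor
#' counts in `manifest.json`. Identical config + seed give byte-identical
#' numeric outputs. Any stage error halts with a stage-named message;
#' partial outputs are retained.
#'
#' @param config A config list or path to a YAML file. Keys: `simulate`
#'   (arguments to [sim_config()]) or `markers`/`metadata`/`records`
#'   (paths); `filters` (min_len, min_total_reads, min_prop, occ_threshold,
#'   qc_max_iter, min_prop_before_averaging); `statistics` (terms, n_perm,
#'   seed, condition); `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of in-memory results from the run.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_pipeline_inputs(config)

  res <- process_study(inputs$tables, inputs$records, inputs$metadata,
                       markers = inputs$markers,
                       options = config$filters %||% list())
  res$log$merge_runs <- sprintf("%d marker table(s) loaded", length(inputs$tables))

  stats_res <- tryCatch(
    run_group_statistics(res$fused, res$diversity, inputs$metadata,
                         config$statistics %||% list()),
    error = function(e) stage_error("statistics", e))
  res$statistics <- stats_res
  res$log$statistics <- sprintf("%d group(s) analysed", length(stats_res))

  # ---- write outputs -------------------------------------------------------
  w <- function(x, name) readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  readr::write_tsv(inputs$metadata, file.path(out_dir, "metadata.tsv"), progress = FALSE)
  for (mk_id in names(res$qc_reports)) {
    rep <- res$qc_reports[[mk_id]]
    w(rep$removed, sprintf("qc_removed_%s.tsv", mk_id))
    w(res$scoped[[mk_id]], sprintf("sample_table_%s.tsv", mk_id))
  }
  qc_summary <- lapply(res$qc_reports, function(r) {
    list(n_iterations = r$n_iterations, converged = r$converged,
         n_removed = nrow(r$removed), thresholds = r$thresholds,
         samples_dropped = r$samples_dropped,
         failed_replicates = r$failed_replicates)
  })
  jsonlite::write_json(qc_summary, file.path(out_dir, "qc_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_diet_profile(res$fused, file.path(out_dir, "diet_profile.tsv"))
  w(res$cat_props, "category_proportions.tsv")
  w(res$occurrence, "occurrence.tsv")
  w(res$diversity, "diversity.tsv")
  w(res$wpoo, "wpoo.tsv")
  for (g in names(stats_res)) {
    w(tidy(stats_res[[g]]$permanova), sprintf("permanova_%s.tsv", g))
    w(tidy(stats_res[[g]]$rda), sprintf("rda_axes_%s.tsv", g))
    w(stats_res[[g]]$rda$site_scores, sprintf("rda_scores_%s.tsv", g))
    w(tidy(stats_res[[g]]$diversity_anova), sprintf("diversity_anova_%s.tsv", g))
  }

  manifest <- list(
    package = "metadiet",
    version = as.character(packageVersion("metadiet")),
    seed = config$seed %||% (config$simulate$seed %||% NA),
    options = res$options,
    statistics = config$statistics %||% list(),
    stages = lapply(setNames(nm = pipeline_stages()), function(s) {
      as.list(res$log[[s]] %||% "no-op")
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(truth = inputs$truth, out_dir = out_dir)))
}

#' Summary tables for the standard diet figures
#'
#' From a completed run directory: per-taxon mean and standard error of RRA
#' and wPOO across samples, keeping taxa that contributed more than
#' `rra_threshold` of the reads in at least one sample and were detected in
#' more than `min_sample_frac` of the samples; plus plant functional-group
#' mean proportions by cycle phase and by season.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param rra_threshold Within-sample RRA defining a detection (default 0.01).
#' @param min_sample_frac Minimum fraction of samples with a detection for a
#'   taxon to be summarized (default 0.05, strict).
#' @return List with `taxa_summary` and `functional_groups` tibbles.
#' @export
summarize_figures <- function(run_dir, rra_threshold = 0.01, min_sample_frac = 0.05) {
  prof_path <- file.path(run_dir, "diet_profile.tsv")
  if (!file.exists(prof_path)) {
    warning("no diet profile found in ", run_dir, "; empty summaries")
    return(list(taxa_summary = tibble::tibble(), functional_groups = tibble::tibble()))
  }
  profile <- read_diet_profile(prof_path)
  metadata <- readr::read_tsv(file.path(run_dir, "metadata.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  wpoo_tab <- readr::read_tsv(file.path(run_dir, "wpoo.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  m <- count_matrix(profile, id_col = "sample_id")
  se <- function(v) sd(v) / sqrt(length(v))
  detected_frac <- colMeans(m > rra_threshold)
  keep <- names(detected_frac)[detected_frac > min_sample_frac]
  taxa_summary <- tibble::tibble(
    taxon = keep,
    rra_mean = colMeans(m[, keep, drop = FALSE]),
    rra_se = apply(m[, keep, drop = FALSE], 2, se),
    detected_frac = detected_frac[keep]
  ) |>
    dplyr::left_join(wpoo_tab, by = "taxon") |>
    dplyr::arrange(dplyr::desc(.data$rra_mean))

  fg <- tryCatch(aggregate_profile(profile, by = "functional_group"),
                 error = function(e) NULL)
  functional_groups <- tibble::tibble()
  if (!is.null(fg)) {
    long <- tidyr::pivot_longer(fg, -"sample_id", names_to = "functional_group",
                                values_to = "proportion") |>
      dplyr::left_join(metadata, by = "sample_id")
    by_vars <- intersect(c("phase", "season"), names(long))
    functional_groups <- dplyr::bind_rows(lapply(by_vars, function(v) {
      long |>
        dplyr::group_by(.data$functional_group, level = .data[[v]]) |>
        dplyr::summarise(mean = mean(.data$proportion),
                         se = se(.data$proportion), .groups = "drop") |>
        dplyr::mutate(variable = v, .before = 1)
    }))
  }
  list(taxa_summary = taxa_summary, functional_groups = functional_groups)
}
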
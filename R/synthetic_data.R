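# Simulator for multi-marker metabarcoding diet studies with known ground
# truth. Emulates the post-demultiplexing stage: per-marker replicate count
# tables with Dirichlet-multinomial replicate noise, tag-jump
# cross-contamination, failed and outlier replicates, per-marker taxonomic
# scopes and detection bias, plus PCR controls.

#' Simulation configuration
#'
#' Defaults emulate a two-species cyclic-vole diet study: unbalanced
#' phase-by-season sample cells, a taxon pool dominated by seed plants with
#' the three functional groups, sparse Dirichlet diets, triplicate PCRs for
#' the plant and eukaryote markers and duplicates for the rest, and
#' realistic artifact rates.
#'
#' @param species Species to simulate (subset of `"bank"`, `"tundra"`).
#' @param n_per_cell `NULL` for the default unbalanced phase-by-season cell
#'   sizes, or a single integer used for every cell.
#' @param n_taxa Named integer vector: taxon pool size per dietary category.
#' @param category_weights Named list per species: expected diet share per
#'   dietary category.
#' @param breadth_alpha Within-category Dirichlet concentration controlling
#'   diet breadth (small = few dominant taxa).
#' @param sample_concentration Dirichlet concentration of sample truths
#'   around their cell mean (larger = more homogeneous samples).
#' @param replicate_concentration Dirichlet-multinomial overdispersion of
#'   PCR replicates around the sample truth (smaller = noisier replicates).
#' @param reads_mean,reads_dispersion Negative-binomial mean and size for
#'   per-replicate sequencing depth.
#' @param replicates_per_marker Named integer vector: PCR replicates per
#'   sample for each marker.
#' @param tag_jump_rate Per-read probability of landing in another replicate.
#' @param outlier_replicate_rate Fraction of replicates spiked with a
#'   different sample's truth; the realized number is
#'   `round(rate * n_replicates)` distinct replicates, so the denominator of
#'   recovery statistics is deterministic.
#' @param replicate_failure_rate Per-replicate probability of total failure
#'   (zero reads).
#' @param phase_effect,season_effect Lists `list(multiplier, frac_taxa)`:
#'   multiplicative shift applied to a fraction of plant taxa in the
#'   crash-low phase / winter season before renormalization.
#' @param marker_bias_sd Log-normal SD of fixed per-taxon, per-marker
#'   detection bias multipliers (0 = unbiased).
#' @param markers Marker ids to simulate (subset of [default_markers()]).
#' @param exact_counts If `TRUE`, replicates carry rounded expected counts
#'   (the zero-noise limit) instead of Dirichlet-multinomial draws.
#' @param controls Append one PCR negative and one PCR positive replicate
#'   per marker.
#' @param seed Integer seed; the whole study is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(species = c("bank", "tundra"),
                       n_per_cell = NULL,
                       n_taxa = c(plant = 60, bryophyte = 12, arthropod = 12,
                                  lichen = 10, mushroom = 8),
                       category_weights = list(
                         bank = c(plant = 0.70, bryophyte = 0.08, arthropod = 0.05,
                                  lichen = 0.12, mushroom = 0.05),
                         tundra = c(plant = 0.90, bryophyte = 0.04, arthropod = 0.04,
                                    lichen = 0.01, mushroom = 0.01)),
                       breadth_alpha = 0.08,
                       sample_concentration = 50,
                       replicate_concentration = 200,
                       reads_mean = 2000, reads_dispersion = 5,
                       replicates_per_marker = c(sper01 = 3, bryo01 = 2, fung01 = 2,
                                                 arth01 = 2, euka02 = 3),
                       tag_jump_rate = 0.02,
                       outlier_replicate_rate = 0.02,
                       replicate_failure_rate = 0.02,
                       phase_effect = list(multiplier = 2, frac_taxa = 0.2),
                       season_effect = list(multiplier = 1.5, frac_taxa = 0.2),
                       marker_bias_sd = 0.3,
                       markers = names(default_markers()),
                       exact_counts = FALSE,
                       controls = TRUE,
                       seed = 20170801) {
  species <- match.arg(species, c("bank", "tundra"), several.ok = TRUE)
  rates <- c(tag_jump_rate, outlier_replicate_rate, replicate_failure_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (breadth_alpha <= 0 || sample_concentration <= 0 || replicate_concentration <= 0) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (reads_mean < 0) stop("reads_mean must be non-negative", call. = FALSE)
  if (any(n_taxa[dietary_categories()] <= 0 | is.na(n_taxa[dietary_categories()]))) {
    stop("every dietary category needs at least one taxon", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

# default unbalanced phase x season cell sizes per species
default_cells <- function(species, n_per_cell = NULL) {
  cells <- dplyr::bind_rows(
    tibble::tibble(vole_species = "bank",
                   phase = c("increase_peak", "increase_peak", "crash_low", "crash_low"),
                   season = c("summer", "winter", "summer", "winter"),
                   n = c(13, 26, 61, 26)),
    tibble::tibble(vole_species = "tundra",
                   phase = c("increase_peak", "increase_peak", "crash_low", "crash_low"),
                   season = c("summer", "winter", "summer", "winter"),
                   n = c(6, 14, 44, 4))
  )
  cells <- cells[cells$vole_species %in% species, ]
  if (!is.null(n_per_cell)) cells$n <- n_per_cell
  cells
}

category_lineage <- function(cat) {
  switch(cat,
    plant = c(kingdom = "Viridiplantae", phylum = "Spermatophyta", class = NA),
    bryophyte = c(kingdom = "Viridiplantae", phylum = "Bryophyta", class = NA),
    arthropod = c(kingdom = "Metazoa", phylum = "Arthropoda", class = NA),
    lichen = c(kingdom = "Fungi", phylum = "Ascomycota", class = "Lecanoromycetes"),
    mushroom = c(kingdom = "Fungi", phylum = "Basidiomycota", class = "Agaricomycetes")
  )
}

build_taxa_pool <- function(config) {
  recs <- list()
  for (cat in dietary_categories()) {
    n <- config$n_taxa[[cat]]
    ids <- sprintf("%s_%02d", cat, seq_len(n))
    fg <- rep("none", n)
    if (cat == "plant") {
      # 1/4 graminoids, ~2/5 forbs, rest shrubs
      n_gr <- max(1, round(n * 0.25)); n_fo <- max(1, round(n * 0.42))
      fg <- rep(c("graminoid", "forb", "shrub"),
                c(n_gr, n_fo, n - n_gr - n_fo))
    }
    lin <- category_lineage(cat)
    recs[[cat]] <- tibble::tibble(
      motu_id = ids, marker_id = cat, seq_length = sample(15:120, n, replace = TRUE),
      best_rank = "genus", dietary_category = cat, functional_group = fg,
      domain = "Eukaryota", kingdom = lin[["kingdom"]], phylum = lin[["phylum"]],
      class = lin[["class"]], order = NA_character_, family = NA_character_,
      genus = sprintf("%s_gen_%02d", cat, ceiling(seq_len(n) / 2)),
      is_control = FALSE
    )
  }
  dplyr::bind_rows(recs)
}

# per-read reassignment to a uniformly chosen other replicate (same MOTU)
apply_tag_jumps <- function(m, rate) {
  if (rate == 0 || nrow(m) < 2) {
    return(list(m = m, n_jumped = 0, n_total = sum(m)))
  }
  total <- sum(m)
  jumps <- matrix(rbinom(length(m), as.vector(m), rate), nrow = nrow(m))
  m2 <- m - jumps
  idx <- which(jumps > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    dest <- setdiff(seq_len(nrow(m)), i)
    add <- rmultinom(1, jumps[i, j], rep(1, length(dest)))
    m2[dest, j] <- m2[dest, j] + add[, 1]
  }
  list(m = m2, n_jumped = sum(jumps), n_total = total)
}

#' Simulate a multi-marker metabarcoding diet study
#'
#' Draws per-sample diet truths from Dirichlet distributions around
#' species-by-phase-by-season cell means (effects applied multiplicatively
#' to selected plant taxa, then renormalized), restricts and biases the
#' truth per marker, and generates Dirichlet-multinomial replicate counts
#' with failed replicates, spiked outlier replicates, tag jumps and PCR
#' controls. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `tables` (named list marker -> `replicate_table`),
#'   `metadata` (sample metadata tibble), `records` (MOTU records for all
#'   markers and controls), and `truth` (a `sim_truth`: `diet` sample-level
#'   truth over all dietary taxa, `outliers`, `tag_jumps`, `effect_taxa`,
#'   `marker_scopes`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  markers <- default_markers()[config$markers]

  cells <- default_cells(config$species, config$n_per_cell)
  metadata <- cells |>
    dplyr::mutate(cell = dplyr::row_number()) |>
    tidyr::uncount(.data$n, .id = "k") |>
    dplyr::mutate(
      sample_id = sprintf("%s_%03d", .data$vole_species,
                          stats::ave(seq_along(.data$cell), .data$vole_species,
                                     FUN = seq_along)),
      site_id = sprintf("%s_grid%d", .data$vole_species, 1 + (.data$k %% 3L))) |>
    dplyr::select("sample_id", "vole_species", "season", "phase", "site_id")

  records <- build_taxa_pool(config)
  taxa <- records$motu_id
  n_tax <- length(taxa)

  # species base diets: category weights x within-category Dirichlet
  base <- list()
  for (sp in config$species) {
    w <- config$category_weights[[sp]][dietary_categories()]
    v <- numeric(n_tax)
    for (cat in dietary_categories()) {
      sel <- records$dietary_category == cat
      v[sel] <- w[[cat]] * rdirichlet(1, rep(config$breadth_alpha, sum(sel)))[1, ]
    }
    base[[sp]] <- v / sum(v)
  }

  # effect taxa: disjoint slices of a random plant ordering
  plants <- which(records$dietary_category == "plant")
  ord <- sample(plants)
  n_eff_p <- round(config$phase_effect$frac_taxa * length(plants))
  n_eff_s <- round(config$season_effect$frac_taxa * length(plants))
  phase_taxa <- ord[seq_len(n_eff_p)]
  season_taxa <- ord[n_eff_p + seq_len(min(n_eff_s, length(plants) - n_eff_p))]

  truth <- matrix(0, nrow = nrow(metadata), ncol = n_tax,
                  dimnames = list(metadata$sample_id, taxa))
  for (i in seq_len(nrow(metadata))) {
    mu <- base[[metadata$vole_species[i]]]
    if (metadata$phase[i] == "crash_low") {
      mu[phase_taxa] <- mu[phase_taxa] * config$phase_effect$multiplier
    }
    if (metadata$season[i] == "winter") {
      mu[season_taxa] <- mu[season_taxa] * config$season_effect$multiplier
    }
    mu <- mu / sum(mu)
    truth[i, ] <- rdirichlet(1, config$sample_concentration * mu)[1, ]
  }

  # fixed per-marker detection biases
  biases <- lapply(markers, function(mk) {
    if (config$marker_bias_sd == 0) rep(1, n_tax)
    else exp(stats::rnorm(n_tax, 0, config$marker_bias_sd))
  })

  tables <- list()
  outliers <- list()
  tag_jumps <- list()
  all_records <- records
  for (mk_id in names(markers)) {
    mk <- markers[[mk_id]]
    in_scope <- records$dietary_category %in% mk$categories
    mtax <- taxa[in_scope]
    mtruth <- row_normalize(truth[, in_scope, drop = FALSE] *
                              rep(biases[[mk_id]][in_scope], each = nrow(truth)))
    n_rep <- config$replicates_per_marker[[mk_id]]
    rep_meta <- tidyr::expand_grid(sample_id = metadata$sample_id, k = seq_len(n_rep)) |>
      dplyr::mutate(replicate_id = sprintf("%s_%s_R%d", .data$sample_id, mk_id, .data$k))
    n_reps <- nrow(rep_meta)

    # exact number of spiked outliers, donors from compositionally distinct samples
    n_out <- round(config$outlier_replicate_rate * n_reps)
    spiked <- if (n_out > 0) sort(sample.int(n_reps, n_out)) else integer()
    donors <- character()
    depth <- rnbinom(n_reps, mu = config$reads_mean, size = config$reads_dispersion)
    failed <- runif(n_reps) < config$replicate_failure_rate
    depth[failed] <- 0

    ctrl_id <- paste0("ctrl_", mk_id)
    cols <- c(mtax, if (config$controls) ctrl_id)
    cnt <- matrix(0L, nrow = n_reps, ncol = length(cols),
                  dimnames = list(rep_meta$replicate_id, cols))
    for (r in seq_len(n_reps)) {
      s <- rep_meta$sample_id[r]
      p <- mtruth[s, ]
      if (r %in% spiked) {
        # a compositionally distinct donor: above-median distance from the host
        dd <- sqrt(rowSums((mtruth - rep(p, each = nrow(mtruth)))^2))
        dd <- dd[setdiff(names(dd), s)]
        cand <- names(dd)[dd > stats::median(dd)]
        donor <- if (length(cand) > 0) sample(cand, 1) else names(which.max(dd))
        donors <- c(donors, donor)
        p <- mtruth[donor, ]
      }
      if (depth[r] == 0 || sum(p) == 0) next
      if (config$exact_counts) {
        cnt[r, mtax] <- round(depth[r] * p)
      } else {
        supp <- which(p > 0)
        pp <- rdirichlet(1, config$replicate_concentration * p[supp])[1, ]
        cnt[r, mtax[supp]] <- rmultinom(1, depth[r], pp)[, 1]
      }
    }
    map <- rep_meta[, c("replicate_id", "sample_id")]
    flags <- rep("none", n_reps)
    if (config$controls) {
      neg_id <- sprintf("%s_NEG_R1", mk_id); pos_id <- sprintf("%s_POS_R1", mk_id)
      cnt <- rbind(cnt, matrix(0L, nrow = 2, ncol = ncol(cnt),
                               dimnames = list(c(neg_id, pos_id), cols)))
      cnt[pos_id, ctrl_id] <- config$reads_mean
      map <- dplyr::bind_rows(map, tibble::tibble(
        replicate_id = c(neg_id, pos_id),
        sample_id = c(sprintf("%s_NEG", mk_id), sprintf("%s_POS", mk_id))))
      flags <- c(flags, "pcr_negative", "pcr_positive")
      all_records <- dplyr::bind_rows(all_records, tibble::tibble(
        motu_id = ctrl_id, marker_id = mk_id, seq_length = 50L,
        best_rank = "species", dietary_category = "other",
        functional_group = "none", domain = NA_character_,
        kingdom = NA_character_, phylum = NA_character_, class = NA_character_,
        order = NA_character_, family = NA_character_, genus = NA_character_,
        is_control = TRUE))
    }
    tj <- apply_tag_jumps(cnt, config$tag_jump_rate)
    tables[[mk_id]] <- replicate_table(tj$m, map, marker_id = mk_id,
                                       control_flags = flags)
    outliers[[mk_id]] <- tibble::tibble(
      marker_id = mk_id,
      replicate_id = rep_meta$replicate_id[spiked],
      sample_id = rep_meta$sample_id[spiked],
      donor_sample = donors)
    tag_jumps[[mk_id]] <- tibble::tibble(
      marker_id = mk_id, n_jumped = tj$n_jumped, n_total = tj$n_total,
      rate_realized = ifelse(tj$n_total > 0, tj$n_jumped / tj$n_total, NA_real_))
  }

  diet <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(truth)),
                           tibble::as_tibble(truth, .name_repair = "minimal"))
  truth_obj <- structure(list(
    diet = diet,
    outliers = dplyr::bind_rows(outliers),
    tag_jumps = dplyr::bind_rows(tag_jumps),
    effect_taxa = list(phase = taxa[phase_taxa], season = taxa[season_taxa]),
    marker_scopes = lapply(markers, `[[`, "categories")
  ), class = "sim_truth")

  list(tables = tables, metadata = validate_sample_metadata(metadata),
       records = validate_motu_records(all_records), truth = truth_obj,
       config = config)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d samples x %d taxa; %d spiked outlier(s)\n",
              nrow(x$diet), length(motu_cols(x$diet)), nrow(x$outliers)))
  invisible(x)
}
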
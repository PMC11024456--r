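# Shared fixture builders and independent oracles.

# counts matrix -> replicate_table with a simple map
make_table <- function(counts, samples, marker_id = "sper01", flags = "none") {
  map <- tibble::tibble(replicate_id = rownames(counts), sample_id = samples)
  replicate_table(counts, map, marker_id = marker_id, control_flags = flags)
}

# MOTU records for plain plant MOTUs
make_records <- function(motu_ids, seq_length = 50, marker_id = "sper01",
                         dietary_category = "plant", functional_group = "forb",
                         phylum = "Spermatophyta", genus = NULL) {
  n <- length(motu_ids)
  fg <- rep_len(functional_group, n)
  fg[rep_len(dietary_category, n) != "plant"] <- "none"
  tibble::tibble(
    motu_id = motu_ids, marker_id = marker_id,
    seq_length = rep_len(seq_length, n), best_rank = "genus",
    dietary_category = rep_len(dietary_category, n), functional_group = fg,
    domain = "Eukaryota", kingdom = NA_character_,
    phylum = rep_len(phylum, n), class = NA_character_,
    order = NA_character_, family = NA_character_,
    genus = genus %||% paste0("gen_", motu_ids), is_control = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample-by-MOTU tibble from a matrix
make_sample_table <- function(m, marker_id = "sper01") {
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m) %||% character(0)),
                          tibble::as_tibble(m, .name_repair = "minimal"))
  attr(out, "marker_id") <- marker_id
  out
}

# all permutations of 1..n (n small), one per row
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# brute-force PERMANOVA pseudo-F from a distance matrix and group labels
permanova_F_oracle <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  a <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# complete-enumeration PERMANOVA p-value
permanova_p_enum <- function(m, groups) {
  d <- dist(m)
  f_obs <- permanova_F_oracle(d, groups)
  perms <- all_perms(length(groups))
  f_all <- apply(perms, 1, function(p) permanova_F_oracle(d, groups[p]))
  mean(f_all >= f_obs - 1e-12)
}

# hand 3-samples x 2-replicates distance fixture (2 MOTUs, depth 10)
qc_hand_fixture <- function() {
  counts <- rbind(
    r1 = c(10L, 0L), r2 = c(8L, 2L),
    r3 = c(5L, 5L), r4 = c(3L, 7L),
    r5 = c(0L, 10L), r6 = c(2L, 8L)
  )
  colnames(counts) <- c("m1", "m2")
  make_table(counts, samples = rep(c("s1", "s2", "s3"), each = 2))
}
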
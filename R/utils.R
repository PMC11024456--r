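# Internal helpers shared across modules. All user-facing tables are wide
# tibbles: replicate tables carry the meta columns marker_id, run_id,
# replicate_id, sample_id, control_flag followed by one numeric column per
# MOTU; sample tables carry sample_id followed by MOTU columns.

motu_cols <- function(x) {
  setdiff(names(x), c(meta_cols(), "sample_id"))
}

# numeric matrix of the MOTU columns, rownames = replicate or sample ids
count_matrix <- function(x, id_col = NULL) {
  mc <- motu_cols(x)
  m <- as.matrix(x[, mc, drop = FALSE])
  if (is.null(id_col)) {
    id_col <- if ("replicate_id" %in% names(x)) "replicate_id" else "sample_id"
  }
  rownames(m) <- as.character(x[[id_col]])
  storage.mode(m) <- "double"
  m
}

# rebuild a wide tibble from a matrix plus metadata columns
matrix_to_table <- function(m, meta) {
  dplyr::bind_cols(meta, tibble::as_tibble(m, .name_repair = "minimal"))
}

row_normalize <- function(m) {
  rs <- rowSums(m)
  out <- m
  nz <- rs > 0
  out[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  out
}

assert_tbl <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dietary_categories <- function() c("plant", "bryophyte", "arthropod", "lichen", "mushroom")

functional_groups <- function() c("graminoid", "forb", "shrub", "none")

lineage_ranks <- function() c("domain", "kingdom", "phylum", "class", "order", "family", "genus")

# Dirichlet sampler via gamma draws; rows of `alpha` can be a vector
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = alpha, rate = 1), nrow = n, byrow = TRUE)
  rs <- rowSums(g)
  # guard against all-zero gamma draws at tiny concentrations
  bad <- rs == 0
  if (any(bad)) {
    idx <- sample.int(k, sum(bad), replace = TRUE)
    g[cbind(which(bad), idx)] <- 1
    rs <- rowSums(g)
  }
  g / rs
}
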
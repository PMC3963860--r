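# Shared fixtures, built in code at test time.

units_to_ct <- function(u) ifelse(u > 0, -log2(u / 1e12), 40)

# Locale-proof canonical form of a partition (list of character vectors).
canonical_partition <- function(parts) {
  sort(vapply(parts, function(p) paste(sort(p), collapse = "|"), character(1)))
}

expect_same_partition <- function(got, want) {
  expect_identical(canonical_partition(got), canonical_partition(want))
}

# Expression profile over the published proteomics grid (units -> Ct).
study_grid_profiles <- function() {
  sp <- study_proteomics()
  as_expression_profile(tibble::tibble(
    gene_symbol = sp$gene_symbol,
    cell_type = sp$cell_type,
    ct = units_to_ct(sp$units),
    all_sentinel = sp$units == 0
  ))
}

# Small well-formed Ct + catalog TSV pair; returns the two paths.
write_small_ct_files <- function(dir, ct_lines = NULL) {
  ct_path <- file.path(dir, "ct.tsv")
  cat_path <- file.path(dir, "catalog.tsv")
  if (is.null(ct_lines)) {
    ct_lines <- c(
      "assay_id\tgene_symbol\tcell_type\treplicate\tct",
      "a1\tGENE1\tTG1\t1\t23.8",
      "a1\tGENE1\tTG1\t2\t24.2",
      "a2\tGENE2\tTG1\t1\tUndetermined"
    )
  }
  writeLines(ct_lines, ct_path)
  writeLines(c(
    "assay_id\tgene_symbol\tcategory",
    "a1\tGENE1\tGPCR",
    "a2\tGENE2\tGPCR",
    "a3\tRPLP0\thousekeeping"
  ), cat_path)
  list(ct = ct_path, catalog = cat_path)
}

# mean_ct-shaped tibble from a gene x cell-type matrix of mean Ct values.
mean_ct_from_matrix <- function(mat, all_sentinel = NULL) {
  genes <- rownames(mat)
  cells <- colnames(mat)
  df <- tidyr::expand_grid(gene_symbol = genes, cell_type = cells)
  df$mean_ct <- unname(mapply(function(g, cc) mat[g, cc],
                              df$gene_symbol, df$cell_type))
  df$assay_id <- paste0("assay-", df$gene_symbol)
  df$sd_ct <- 0
  df$n_replicates <- 2L
  df$all_sentinel <- if (is.null(all_sentinel)) FALSE else
    unname(mapply(function(g, cc) all_sentinel[g, cc],
                  df$gene_symbol, df$cell_type))
  df$mixed_detection <- FALSE
  df
}
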
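test_that("simulate_ct_dataset honours the zero-noise and sentinel contracts", {
  cfg0 <- sim_config(n_gpcr_assays = 30, n_housekeeping = 4,
                     ct_noise_sd = 0, rng_seed = 2)
  sim0 <- simulate_ct_dataset(cfg0)
  obs <- sim0$dataset$observations
  truth <- sim0$truth$true_ct
  merged <- merge(obs, truth, by = c("gene_symbol", "cell_type"))
  # zero noise: every replicate equals the true Ct
  expect_true(all(merged$ct[!merged$absent] == merged$true_ct[!merged$absent]))
  # absent genes are sentinel in all replicates, never partially
  absent_genes <- unique(truth$gene_symbol[truth$absent])
  expect_gt(length(absent_genes), 0)
  ab <- obs[obs$gene_symbol %in% absent_genes, ]
  expect_true(all(ab$ct == 40) && all(ab$is_sentinel))

  # fixed seed: bit-identical reruns
  again <- simulate_ct_dataset(cfg0)
  expect_identical(sim0, again)

  # config validation
  expect_error(sim_config(n_gpcr_assays = 0), class = "receptoire_parameter_error")
  expect_error(sim_config(cell_types = c("A", "A")),
               class = "receptoire_parameter_error")
  expect_error(sim_config(ct_noise_sd = -1), class = "receptoire_parameter_error")
})

test_that("replicate means concentrate around the true Ct (normal theory)", {
  cfg <- sim_config(n_gpcr_assays = 200, n_housekeeping = 4,
                    replicates = 4, ct_noise_sd = 0.3, rng_seed = 12)
  sim <- simulate_ct_dataset(cfg)
  m <- merge_replicates(sim$dataset)
  cmp <- merge(m, sim$truth$true_ct, by = c("gene_symbol", "cell_type"))
  cmp <- cmp[!cmp$absent, ]
  # |mean - true| < 3 * sd/sqrt(4) for >= 99% of (gene, cell) entries
  frac <- mean(abs(cmp$mean_ct - cmp$true_ct) < 3 * 0.3 / 2)
  expect_gte(frac, 0.99)
})

test_that("planted specificity groups satisfy their separation rule exactly before noise", {
  cfg <- sim_config(planted_groups = list(
    list(cells = c("TG1", "OB1"), direction = "over", n_genes = 4,
         fold_separation = 4),
    list(cells = c("HA", "U87"), direction = "under", n_genes = 3,
         fold_separation = 4)
  ), ct_noise_sd = 0, rng_seed = 3)
  sim <- simulate_ct_dataset(cfg)
  truth <- sim$truth$true_ct
  for (i in seq_len(nrow(sim$truth$groups))) {
    g <- sim$truth$groups[i, ]
    cells_in <- strsplit(g$cells, ",")[[1]]
    tt <- truth[truth$gene_symbol == g$gene_symbol, ]
    inside <- tt$true_ct[tt$cell_type %in% cells_in]
    outside <- tt$true_ct[!tt$cell_type %in% cells_in]
    gap <- if (g$direction == "over") min(outside) - max(inside) else
      min(inside) - max(outside)
    expect_equal(gap, log2(4), tolerance = 1e-12)
  }
  # zero noise: classification recovers every planted membership
  prof <- normalize_expression(merge_replicates(sim$dataset),
                               build_reference_model(merge_replicates(sim$dataset)))
  cls <- classify_specificity(prof)
  hit <- merge(sim$truth$groups, cls, by = c("gene_symbol", "direction"))
  expect_equal(nrow(hit), nrow(sim$truth$groups))
  expect_true(all(hit$cells.x == hit$cells.y))
})

test_that("simulate_proteins tiles topology and is deterministic", {
  sim <- simulate_proteins(5, seed = 4)
  for (r in sim$records) {
    topo <- r$topology
    expect_equal(topo$start[1], 1L)
    expect_equal(topo$end[nrow(topo)], nchar(r$sequence))
    expect_true(all(topo$start[-1] == topo$end[-nrow(topo)] + 1L))
  }
  expect_identical(simulate_proteins(5, seed = 4), sim)
  expect_error(simulate_proteins(0), class = "receptoire_parameter_error")
})

test_that("spectral counts follow the stated rate model", {
  # zero expected peptides: always nd
  rec0 <- protein_record("Z0", "ACDEFG",
                         tibble::tibble(start = 1, end = 6,
                                        label = "TRANSMEMBRANE"))
  dig0 <- count_expected_peptides(rec0)
  prof0 <- as_expression_profile(tibble::tibble(
    gene_symbol = "Z0", cell_type = c("A", "B", "C"), ct = 15))
  tab0 <- simulate_spectral_counts(prof0, list(Z0 = dig0), seed = 1)
  expect_true(all(!tab0$detected))

  # 10x unit ratio -> mean spectrum-count ratio ~ 10 over many draws
  seqs <- "ACDEFGHILKWWYYFFMMNKTTSSPPVVGGHHRACDEFGHIWK"
  rec <- protein_record("R1", seqs,
                        tibble::tibble(start = 1, end = nchar(seqs),
                                       label = "CYTOPLASMIC"))
  dig <- count_expected_peptides(rec)
  draws <- paste0("d", 1:1000)
  prof <- as_expression_profile(tibble::tibble(
    gene_symbol = rep(c("HI", "LO"), each = 1000),
    cell_type = rep(draws, 2),
    ct = rep(units_to_ct(c(3e5, 3e4)), each = 1000)
  ))
  digs <- list(HI = dig, LO = dig)
  # use an expected count > 5 so the detectability rule is passed on both
  digs$HI$expected_count <- digs$LO$expected_count <- 8
  tab <- simulate_spectral_counts(prof, digs, seed = 5)
  mean_hi <- mean(tab$spectra[tab$accession == "HI"], na.rm = TRUE)
  mean_lo <- mean(tab$spectra[tab$accession == "LO"], na.rm = TRUE)
  expect_equal(mean_hi / mean_lo, 10, tolerance = 0.1)

  # determinism and key checking
  expect_identical(simulate_spectral_counts(prof, digs, seed = 5), tab)
  expect_error(simulate_spectral_counts(prof, digs["HI"], seed = 5),
               class = "receptoire_key_error")
})

test_that("synthetic_expression_table plants the printed summary structure for any seed", {
  for (s in c(1, 77)) {
    tab <- synthetic_expression_table(seed = s)
    prof <- as_expression_profile(tab)
    flt <- filter_expressed(prof)
    counts <- setNames(flt$counts$n_retained, flt$counts$cell_type)
    expect_equal(counts[c("OB1", "TG1", "f-NSC", "HA", "U87")],
                 c(OB1 = 90L, TG1 = 83L, `f-NSC` = 77L, HA = 61L, U87 = 57L))
    expect_length(flt$union, 138)
    expect_length(core_set(prof), 26)
    # planted membership patterns are recovered exactly (designed margins)
    gt <- attr(tab, "ground_truth")
    cls <- classify_specificity(prof)
    over <- cls[cls$direction == "over", ]
    planted <- gt[gt$pattern != "" &
                    lengths(strsplit(gt$pattern, ",")) < 5, ]
    hit <- merge(planted, over, by = "gene_symbol")
    expect_equal(nrow(hit), nrow(planted))
    expect_true(all(vapply(seq_len(nrow(hit)), function(i) {
      setequal(strsplit(hit$pattern[i], ",")[[1]],
               strsplit(hit$cells[i], ",")[[1]])
    }, logical(1))))
  }
})
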
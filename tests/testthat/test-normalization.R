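test_that("reference_stability matches a manual pairwise-sd calculation", {
  # two candidates offset by a constant: perfectly stable pair, M = 0
  mat <- rbind(A = c(X = 20, Y = 22, Z = 24),
               B = c(X = 21, Y = 23, Z = 25))
  st <- reference_stability(mean_ct_from_matrix(mat), c("A", "B"))
  expect_equal(st$m_value, c(0, 0))

  # three candidates, two cell types: spreadsheet-style oracle
  mat3 <- rbind(A = c(X = 20, Y = 21),
                B = c(X = 22, Y = 24),
                C = c(X = 25, Y = 25.5))
  st3 <- reference_stability(mean_ct_from_matrix(mat3), c("A", "B", "C"))
  v_ab <- sd(c(22 - 20, 24 - 21))
  v_ac <- sd(c(25 - 20, 25.5 - 21))
  v_bc <- sd(c(25 - 22, 25.5 - 24))
  manual <- c(A = mean(c(v_ab, v_ac)), B = mean(c(v_ab, v_bc)),
              C = mean(c(v_ac, v_bc)))
  got <- setNames(st3$m_value, st3$gene_symbol)
  expect_equal(got[names(manual)], manual)

  # permuting cell-type order leaves M unchanged
  st3p <- reference_stability(mean_ct_from_matrix(mat3[, c("Y", "X")]),
                              c("A", "B", "C"))
  expect_equal(st3p$m_value, st3$m_value)

  expect_error(reference_stability(mean_ct_from_matrix(mat3), "A"),
               class = "receptoire_parameter_error")
})

test_that("normalize_expression reproduces the published delta-Ct arithmetic", {
  cells <- c("TG1", "OB1")
  mat <- rbind(RPLP0 = c(TG1 = 21.12, OB1 = 21.12),
               LPHN2 = c(TG1 = 24.00, OB1 = 30),
               F2R = c(TG1 = 30, OB1 = 24.30),
               SAME = c(TG1 = 21.12, OB1 = 21.12))
  ref <- build_reference_model(mean_ct_from_matrix(mat), "RPLP0")
  expect_equal(ref$grand_mean_ct, 21.12)
  prof <- normalize_expression(mean_ct_from_matrix(mat), ref)

  lphn2 <- prof[prof$gene_symbol == "LPHN2" & prof$cell_type == "TG1", ]
  expect_equal(lphn2$delta_ct, 2.88)
  expect_equal(round(lphn2$fold_below_ref, 2), 7.36)

  f2r <- prof[prof$gene_symbol == "F2R" & prof$cell_type == "OB1", ]
  expect_equal(f2r$delta_ct, 3.18)
  expect_equal(round(f2r$fold_below_ref, 2), 9.06)

  same <- prof[prof$gene_symbol == "SAME" & prof$cell_type == "TG1", ]
  expect_equal(same$delta_ct, 0)
  expect_equal(same$fold_below_ref, 1)
  expect_equal(same$ratio_over_ref, 1)
})

test_that("normalization aligns cell types to the reference anchor and inverts exactly", {
  # reference drifts by +0.5 in OB1: gene Ct must be shifted back by 0.5
  mat <- rbind(RPLP0 = c(TG1 = 21.0, OB1 = 21.5),
               G1 = c(TG1 = 25, OB1 = 25.5))
  ref <- build_reference_model(mean_ct_from_matrix(mat), "RPLP0")
  expect_equal(ref$grand_mean_ct, 21.25)
  prof <- normalize_expression(mean_ct_from_matrix(mat), ref)
  g1 <- prof[prof$gene_symbol == "G1", ]
  expect_equal(g1$ct[g1$cell_type == "TG1"], 25.25)  # 25 - (21.0 - 21.25)
  expect_equal(g1$ct[g1$cell_type == "OB1"], 25.25)  # 25.5 - (21.5 - 21.25)
  # un-normalize: adding the shift back recovers the raw Ct
  shift <- ref$per_cell_ct[g1$cell_type] - ref$grand_mean_ct
  expect_equal(unname(g1$ct + shift), c(25, 25.5))

  # sentinel genes keep Ct 40 and are below cutoff
  sent <- matrix(FALSE, 2, 2, dimnames = dimnames(mat))
  mat2 <- mat; mat2["G1", "OB1"] <- 40; sent["G1", "OB1"] <- TRUE
  prof2 <- normalize_expression(mean_ct_from_matrix(mat2, sent), ref)
  s <- prof2[prof2$gene_symbol == "G1" & prof2$cell_type == "OB1", ]
  expect_equal(s$ct, 40)
  expect_equal(s$units, expression_units(40))
  expect_false(s$above_cutoff)

  # reference sentinel in any cell type is unusable
  sent3 <- matrix(FALSE, 2, 2, dimnames = dimnames(mat))
  sent3["RPLP0", "OB1"] <- TRUE
  expect_error(build_reference_model(mean_ct_from_matrix(mat, sent3), "RPLP0"),
               class = "receptoire_reference_error")
})

test_that("fold identities and unit monotonicity hold across random profiles", {
  set.seed(1)
  for (i in 1:20) {
    d <- runif(50, -10, 19)
    expect_true(all(abs(fold_below_reference(d) * ratio_over_reference(d) - 1) < 1e-12))
  }
  ct <- sort(runif(100, 15, 40))
  expect_true(all(diff(expression_units(ct)) < 0))  # strictly decreasing
  expect_equal(round(expression_units(31.5)), 329)
  expect_equal(relative_fold_over_cutoff(31.5), 1)
  expect_equal(relative_fold_over_cutoff(21.12), 2^10.38)
  expect_lt(relative_fold_over_cutoff(40), 1)
})

test_that("filter_expressed applies the inclusive cutoff and union semantics", {
  prof <- as_expression_profile(tibble::tibble(
    gene_symbol = c("G1", "G2", "G3", "G1", "G2", "G3"),
    cell_type = rep(c("TG1", "OB1"), each = 3),
    ct = c(31.5, 31.51, 25, 33, 31.49, 25)
  ))
  flt <- filter_expressed(prof)
  expect_true("G1" %in% flt$retained$TG1)    # exactly at cutoff: retained
  expect_false("G2" %in% flt$retained$TG1)
  expect_true("G2" %in% flt$retained$OB1)
  expect_setequal(flt$union, c("G1", "G2", "G3"))
  expect_equal(flt$counts$n_retained[flt$counts$cell_type == "TG1"], 2L)

  # published example: 78 units (below 329) is not retained
  grid <- study_grid_profiles()
  flt2 <- filter_expressed(grid)
  expect_false("BDKRB2" %in% flt2$retained$OB1)
  expect_true("BDKRB2" %in% flt2$retained$U87)

  # everything sentinel: empty union
  empty <- as_expression_profile(tibble::tibble(
    gene_symbol = c("G1", "G1"), cell_type = c("TG1", "OB1"),
    ct = c(40, 40), all_sentinel = TRUE
  ))
  expect_length(filter_expressed(empty)$union, 0)
})

test_that("stability ranking recovers the planted reference on simulated data", {
  sim <- simulate_ct_dataset(sim_config(rng_seed = 3))
  m <- merge_replicates(sim$dataset)
  hk <- unique(sim$dataset$catalog$gene_symbol[
    sim$dataset$catalog$category == "housekeeping"])
  st <- reference_stability(m, hk)
  expect_equal(st$gene_symbol[1], "RPLP0")
})
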
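#' Configuration for the synthetic Ct-dataset generator
#'
#' Defaults are the conditions of the original assay: a 356-GPCR +
#' 14-housekeeping TaqMan low-density-array panel across five cell types
#' (TG1, OB1, f-NSC, HA, U87), triplicate measurements for f-NSC and
#' duplicates elsewhere, additive Gaussian replicate noise of 0.3 cycles on
#' the Ct scale, and a sentinel Ct of 40 for assays that never amplify.
#'
#' @param n_gpcr_assays Number of GPCR assays (default 356).
#' @param n_housekeeping Number of housekeeping assays (default 14); the
#'   first is the stable reference gene `RPLP0`.
#' @param cell_types Cell-type labels (default the study's five).
#' @param replicates Replicates per cell type: a single count or a named
#'   vector; the default gives f-NSC 3 and every other cell type 2.
#' @param ct_noise_sd Replicate noise sd in cycles (default 0.3).
#' @param sentinel_ct Sentinel Ct for absent genes (default 40).
#' @param planted_groups List of planted specificity groups, each a list with
#'   `cells` (subset of `cell_types`), `direction` (`"over"`/`"under"`),
#'   `n_genes`, and `fold_separation` (> 1). Groups claim disjoint gene sets.
#' @param prop_expressed,prop_low Proportions of the non-planted GPCRs that
#'   are ubiquitously expressed (true Ct 23-30) and low-expressed (true Ct
#'   33-38); the remainder never amplify (sentinel).
#' @param rng_seed Integer seed; fixed seed gives bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_gpcr_assays = 356, n_housekeeping = 14,
                       cell_types = c("TG1", "OB1", "f-NSC", "HA", "U87"),
                       replicates = NULL, ct_noise_sd = 0.3, sentinel_ct = 40,
                       planted_groups = list(),
                       prop_expressed = 0.35, prop_low = 0.35,
                       rng_seed = 1L) {
  if (n_gpcr_assays < 1 || n_housekeeping < 2) {
    rlang::abort("Counts must be positive (and >= 2 housekeeping genes)",
                 class = "receptoire_parameter_error")
  }
  if (anyDuplicated(cell_types)) {
    rlang::abort("Duplicate cell-type labels", class = "receptoire_parameter_error")
  }
  if (ct_noise_sd < 0) {
    rlang::abort("ct_noise_sd must be >= 0", class = "receptoire_parameter_error")
  }
  if (is.null(replicates)) {
    replicates <- stats::setNames(ifelse(cell_types == "f-NSC", 3L, 2L), cell_types)
  } else if (length(replicates) == 1 && is.null(names(replicates))) {
    replicates <- stats::setNames(rep(as.integer(replicates), length(cell_types)),
                                  cell_types)
  }
  stopifnot(setequal(names(replicates), cell_types), all(replicates >= 1))
  for (g in planted_groups) {
    stopifnot(all(g$cells %in% cell_types),
              length(g$cells) < length(cell_types),
              g$direction %in% c("over", "under"),
              g$n_genes >= 1, g$fold_separation > 1)
  }
  n_planted <- sum(vapply(planted_groups, function(g) g$n_genes, numeric(1)))
  if (n_planted > n_gpcr_assays) {
    rlang::abort("Planted groups claim more genes than available",
                 class = "receptoire_parameter_error")
  }
  structure(
    list(n_gpcr_assays = n_gpcr_assays, n_housekeeping = n_housekeeping,
         cell_types = cell_types, replicates = replicates,
         ct_noise_sd = ct_noise_sd, sentinel_ct = sentinel_ct,
         planted_groups = planted_groups, prop_expressed = prop_expressed,
         prop_low = prop_low, rng_seed = as.integer(rng_seed)),
    class = "sim_config"
  )
}

#' Simulate a replicate-level Ct dataset with known ground truth
#'
#' Draws a true mean Ct per (gene, cell type) and emits replicate observations
#' as true Ct plus independent Gaussian noise on the cycle scale. Absent genes
#' are sentinel in every replicate (never partially). Housekeeping genes have
#' low between-cell-type variance; the reference gene (`RPLP0`, true Ct 21.12)
#' is the most stable by construction. Planted specificity groups place their
#' member genes symmetrically around the 31.5-cycle cutoff: inside cells at
#' cutoff - s/2 and outside cells at cutoff + s/2 (s = log2 fold separation),
#' so the separation rule holds exactly before noise.
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (a `ct_dataset`) and `truth`, a list holding
#'   `true_ct` (tibble gene x cell type), `groups` (tibble of planted
#'   memberships), and `reference_gene`.
#' @export
simulate_ct_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  cells <- config$cell_types
  cutoff <- 31.5

  hk_names <- c("RPLP0",
                sprintf("HK%02d", seq_len(config$n_housekeeping - 1)))
  gpcr_names <- sprintf("GPCR%03d", seq_len(config$n_gpcr_assays))

  # --- housekeeping truth. The reference is near-constant across cell types
  # (jitter sd 0.05 cycles). Every other control gets a fixed per-cell-type
  # offset pattern with a guaranteed realized spread of 0.8-1.5 cycles:
  # between-cell-type expression differences of imperfect controls are
  # reproducible biology, not resampling noise. The pattern matrix is
  # double-centered (its panel-consensus component removed) so no unstable
  # control can mimic stability by co-varying with the rest of the panel;
  # this plants the reference as unambiguously the most stable gene.
  hk_base <- c(21.12, stats::runif(config$n_housekeeping - 1, 18, 28))
  n_other <- config$n_housekeeping - 1
  hk_spread <- stats::runif(n_other, 0.8, 1.5)
  pat <- matrix(stats::rnorm(n_other * length(cells)), n_other, length(cells))
  pat <- sweep(pat, 2, colMeans(pat))
  pat <- sweep(pat, 1, rowMeans(pat))
  pat <- sweep(pat, 1, apply(pat, 1, stats::sd), "/") * hk_spread
  hk_true <- do.call(rbind, lapply(seq_along(hk_names), function(i) {
    offset <- if (i == 1) stats::rnorm(length(cells), 0, 0.05) else pat[i - 1, ]
    tibble::tibble(
      gene_symbol = hk_names[i], cell_type = cells,
      true_ct = hk_base[i] + offset,
      absent = FALSE
    )
  }))

  # --- planted specificity groups
  planted_rows <- list()
  group_rows <- list()
  gene_cursor <- 0L
  for (gi in seq_along(config$planted_groups)) {
    g <- config$planted_groups[[gi]]
    s <- log2(g$fold_separation)
    genes <- gpcr_names[gene_cursor + seq_len(g$n_genes)]
    gene_cursor <- gene_cursor + g$n_genes
    jitter <- stats::runif(g$n_genes, -0.1, 0.1)
    for (k in seq_along(genes)) {
      inside_ct <- cutoff - s / 2 + jitter[k]
      outside_ct <- inside_ct + s
      if (g$direction == "under") {
        tmp <- inside_ct; inside_ct <- outside_ct; outside_ct <- tmp
      }
      planted_rows[[length(planted_rows) + 1]] <- tibble::tibble(
        gene_symbol = genes[k], cell_type = cells,
        true_ct = ifelse(cells %in% g$cells, inside_ct, outside_ct),
        absent = FALSE
      )
      group_rows[[length(group_rows) + 1]] <- tibble::tibble(
        gene_symbol = genes[k],
        cells = paste(sort(g$cells), collapse = ","),
        direction = g$direction, fold_separation = g$fold_separation
      )
    }
  }

  # --- background GPCRs: ubiquitous / low / absent
  bg_names <- gpcr_names[setdiff(seq_len(config$n_gpcr_assays),
                                 seq_len(gene_cursor))]
  n_bg <- length(bg_names)
  n_expr <- round(config$prop_expressed * n_bg)
  n_low <- round(config$prop_low * n_bg)
  kind <- rep("absent", n_bg)
  if (n_expr > 0) kind[seq_len(n_expr)] <- "expressed"
  if (n_low > 0) kind[n_expr + seq_len(min(n_low, n_bg - n_expr))] <- "low"
  bg_true <- do.call(rbind, lapply(seq_len(n_bg), function(i) {
    if (kind[i] == "absent") {
      tibble::tibble(gene_symbol = bg_names[i], cell_type = cells,
                     true_ct = config$sentinel_ct, absent = TRUE)
    } else {
      base <- if (kind[i] == "expressed") stats::runif(1, 23, 30) else
        stats::runif(1, 33, 38)
      tibble::tibble(gene_symbol = bg_names[i], cell_type = cells,
                     true_ct = base + stats::runif(length(cells), -0.3, 0.3),
                     absent = FALSE)
    }
  }))

  true_ct <- dplyr::bind_rows(hk_true, do.call(rbind, planted_rows), bg_true)

  # --- replicate observations
  obs <- true_ct |>
    dplyr::rowwise() |>
    dplyr::mutate(n_rep = config$replicates[[.data$cell_type]]) |>
    dplyr::ungroup()
  obs <- obs[rep(seq_len(nrow(obs)), obs$n_rep), ]
  obs <- obs |>
    dplyr::group_by(.data$gene_symbol, .data$cell_type) |>
    dplyr::mutate(replicate = dplyr::row_number()) |>
    dplyr::ungroup()
  noise <- stats::rnorm(nrow(obs), 0, config$ct_noise_sd)
  observations <- tibble::tibble(
    assay_id = paste0("assay-", obs$gene_symbol),
    gene_symbol = obs$gene_symbol,
    cell_type = obs$cell_type,
    replicate = obs$replicate,
    ct = ifelse(obs$absent, config$sentinel_ct, obs$true_ct + noise),
    is_sentinel = obs$absent
  )
  catalog <- tibble::tibble(
    assay_id = paste0("assay-", c(hk_names, gpcr_names)),
    gene_symbol = c(hk_names, gpcr_names),
    category = c(rep("housekeeping", length(hk_names)),
                 rep("GPCR", length(gpcr_names)))
  )
  truth <- list(
    true_ct = true_ct,
    groups = if (length(group_rows) > 0) dplyr::bind_rows(group_rows) else
      tibble::tibble(gene_symbol = character(), cells = character(),
                     direction = character(), fold_separation = numeric()),
    reference_gene = "RPLP0"
  )
  list(dataset = new_ct_dataset(observations, catalog, config$sentinel_ct),
       truth = truth)
}
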
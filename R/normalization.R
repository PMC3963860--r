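#' Expression units from a cycle threshold
#'
#' The study's arbitrary expression scale: `u = 2^-Ct * 10^12`. It is strictly
#' decreasing in Ct; the Ct 31.5 expression cutoff corresponds to 329 units
#' (to rounding).
#'
#' @param ct Cycle threshold, in cycles.
#' @return Expression level in arbitrary units.
#' @export
expression_units <- function(ct) 2^(-ct) * 1e12

#' Fold by which a gene sits below the reference gene
#'
#' `2^dCt` where `dCt = Ct_gene - Ct_reference`. This is the convention of the
#' study's top-expressed table: e.g. dCt 2.88 prints as fold 7.36. Its
#' reciprocal, [ratio_over_reference()], is the abundance ratio of the gene
#' over the reference.
#'
#' @param delta_ct Ct difference gene minus reference, in cycles.
#' @return Dimensionless fold.
#' @export
fold_below_reference <- function(delta_ct) 2^delta_ct

#' Abundance ratio of a gene over the reference gene
#'
#' `2^-dCt`, the sign-correct relative abundance (abundance is proportional to
#' `2^-Ct`).
#'
#' @inheritParams fold_below_reference
#' @return Dimensionless ratio.
#' @export
ratio_over_reference <- function(delta_ct) 2^(-delta_ct)

#' Fold change relative to the expression cutoff
#'
#' `2^(cutoff_ct - ct)`: how many fold a gene sits above the Ct 31.5
#' expression cutoff (below-cutoff genes give values < 1).
#'
#' @param ct Normalized cycle threshold, in cycles.
#' @param cutoff_ct Cutoff Ct (default 31.5).
#' @return Dimensionless fold.
#' @export
relative_fold_over_cutoff <- function(ct, cutoff_ct = 31.5) 2^(cutoff_ct - ct)

#' geNorm-style reference-gene stability score M
#'
#' For each candidate control gene j, computes over every other candidate k
#' the per-cell-type log2 expression ratio (using `2^-Ct` as the quantity, so
#' the ratio is `Ct_k - Ct_j`), takes its standard deviation `V_jk` across
#' cell types, and averages over k: `M_j = mean_k(V_jk)`. Lower M means more
#' stable. Sentinel-flagged (non-amplified) entries are excluded pairwise.
#'
#' @param matrix A `mean_ct` tibble from [merge_replicates()] (or any tibble
#'   with `gene_symbol`, `cell_type`, `mean_ct` and optionally `all_sentinel`).
#' @param candidates Character vector of candidate gene symbols (>= 2).
#' @return Tibble with `gene_symbol` and `m_value`, sorted by increasing M.
#' @export
reference_stability <- function(matrix, candidates) {
  if (length(candidates) < 2) {
    rlang::abort("Need at least 2 candidate reference genes",
                 class = "receptoire_parameter_error")
  }
  df <- tibble::as_tibble(matrix)
  if (!"all_sentinel" %in% names(df)) df$all_sentinel <- FALSE
  df <- df[df$gene_symbol %in% candidates & !df$all_sentinel, ]
  wide <- tidyr::pivot_wider(df[c("gene_symbol", "cell_type", "mean_ct")],
                             names_from = "cell_type", values_from = "mean_ct")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$gene_symbol
  usable <- rowSums(!is.na(mat)) >= 2
  if (!all(candidates %in% rownames(mat)[usable])) {
    rlang::abort(
      "Every candidate must be measured (non-sentinel) in at least 2 cell types",
      class = "receptoire_parameter_error"
    )
  }
  m <- vapply(candidates, function(j) {
    v <- vapply(setdiff(candidates, j), function(k) {
      ratio <- mat[k, ] - mat[j, ]  # log2(q_j / q_k) with q = 2^-Ct
      stats::sd(ratio, na.rm = TRUE)
    }, numeric(1))
    mean(v)
  }, numeric(1))
  tibble::tibble(gene_symbol = candidates, m_value = unname(m)) |>
    dplyr::arrange(.data$m_value)
}

#' Build the reference model used for cross-sample alignment
#'
#' Captures the reference gene's Ct in each cell type and its grand mean. The
#' grand mean (21.12 cycles for RPLP0 in the original study) is the single
#' anchor to which all cell types are aligned: each cell type's Ct values are
#' shifted so that its reference Ct equals the grand mean.
#'
#' @param matrix A `mean_ct` tibble.
#' @param reference_gene Reference gene symbol (default `"RPLP0"`).
#' @param grand_mean_ct Optional override of the grand-mean reference Ct (for
#'   example to reuse a previously fitted anchor); defaults to the mean of the
#'   per-cell-type reference Ct values.
#' @return A `reference_model`: list with `reference_gene`, `grand_mean_ct`
#'   and `per_cell_ct` (named numeric vector).
#' @export
build_reference_model <- function(matrix, reference_gene = "RPLP0",
                                  grand_mean_ct = NULL) {
  df <- tibble::as_tibble(matrix)
  ref <- df[df$gene_symbol == reference_gene, ]
  if (nrow(ref) == 0) {
    rlang::abort(paste0("Reference gene ", reference_gene, " not measured"),
                 class = "receptoire_reference_error")
  }
  if (!"all_sentinel" %in% names(ref)) ref$all_sentinel <- FALSE
  if (any(ref$all_sentinel)) {
    rlang::abort(
      paste0("Reference gene ", reference_gene,
             " did not amplify in cell type(s): ",
             paste(ref$cell_type[ref$all_sentinel], collapse = ", ")),
      class = "receptoire_reference_error"
    )
  }
  per_cell <- stats::setNames(ref$mean_ct, ref$cell_type)
  structure(
    list(
      reference_gene = reference_gene,
      grand_mean_ct = if (is.null(grand_mean_ct)) mean(per_cell) else grand_mean_ct,
      per_cell_ct = per_cell
    ),
    class = "reference_model"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  cat("<reference_model>", x$reference_gene,
      "grand-mean Ct", round(x$grand_mean_ct, 2), "over",
      length(x$per_cell_ct), "cell types\n")
  invisible(x)
}

#' Normalize mean Ct values against the reference gene
#'
#' Aligns every cell type to the reference anchor (normalized Ct = raw mean Ct
#' minus the cell type's reference offset from the grand mean), then derives
#' the quantities of the expression profile: dCt relative to the reference,
#' the fold below the reference (`2^dCt`, the study's printed convention), the
#' abundance ratio over the reference (`2^-dCt`), expression units
#' (`2^-Ct * 10^12`) and the above-cutoff flag (Ct <= cutoff, inclusive).
#' Genes that did not amplify keep the sentinel Ct of 40 un-shifted: their
#' units derive from Ct 40 and they are never above cutoff.
#'
#' @param matrix A `mean_ct` tibble from [merge_replicates()], or any tibble
#'   with `gene_symbol`, `cell_type`, `mean_ct` (plus optional `assay_id`,
#'   `all_sentinel`).
#' @param ref A `reference_model` from [build_reference_model()].
#' @param cutoff_ct Expression cutoff in cycles (default 31.5).
#' @return An `expression_profile` tibble: `gene_symbol`, `cell_type`, `ct`
#'   (normalized), `delta_ct`, `fold_below_ref`, `ratio_over_ref`, `units`,
#'   `above_cutoff`, with attributes `reference_gene`, `grand_mean_ct`,
#'   `cutoff_ct`.
#' @export
normalize_expression <- function(matrix, ref, cutoff_ct = 31.5) {
  stopifnot(inherits(ref, "reference_model"))
  df <- tibble::as_tibble(matrix)
  if (!"all_sentinel" %in% names(df)) df$all_sentinel <- FALSE
  missing_cells <- setdiff(unique(df$cell_type), names(ref$per_cell_ct))
  if (length(missing_cells) > 0) {
    rlang::abort(
      paste0("Reference model has no Ct for cell type(s): ",
             paste(missing_cells, collapse = ", ")),
      class = "receptoire_reference_error"
    )
  }
  shift <- ref$per_cell_ct[df$cell_type] - ref$grand_mean_ct
  norm_ct <- ifelse(df$all_sentinel, df$mean_ct, df$mean_ct - shift)
  delta <- norm_ct - ref$grand_mean_ct
  out <- tibble::tibble(
    gene_symbol = df$gene_symbol,
    cell_type = df$cell_type,
    ct = norm_ct,
    delta_ct = delta,
    fold_below_ref = fold_below_reference(delta),
    ratio_over_ref = ratio_over_reference(delta),
    units = expression_units(norm_ct),
    above_cutoff = !df$all_sentinel & norm_ct <= cutoff_ct,
    all_sentinel = df$all_sentinel
  )
  attr(out, "reference_gene") <- ref$reference_gene
  attr(out, "grand_mean_ct") <- ref$grand_mean_ct
  attr(out, "cutoff_ct") <- cutoff_ct
  class(out) <- c("expression_profile", class(out))
  out
}

#' Build an expression profile directly from normalized Ct values
#'
#' Convenience constructor for data that is already reference-normalized (for
#' example a published per-gene, per-cell-type Ct table): derives units, folds
#' and the cutoff flag without re-aligning samples.
#'
#' @param df Tibble with `gene_symbol`, `cell_type` and `ct` (normalized
#'   cycles); an optional `all_sentinel` column marks non-amplified entries.
#' @param reference_ct The reference gene's anchor Ct (default 21.12 cycles).
#' @param cutoff_ct Expression cutoff in cycles (default 31.5).
#' @inherit normalize_expression return
#' @export
as_expression_profile <- function(df, reference_ct = 21.12, cutoff_ct = 31.5) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("gene_symbol", "cell_type", "ct") %in% names(df)))
  if (!"all_sentinel" %in% names(df)) df$all_sentinel <- FALSE
  delta <- df$ct - reference_ct
  out <- tibble::tibble(
    gene_symbol = df$gene_symbol,
    cell_type = df$cell_type,
    ct = df$ct,
    delta_ct = delta,
    fold_below_ref = fold_below_reference(delta),
    ratio_over_ref = ratio_over_reference(delta),
    units = expression_units(df$ct),
    above_cutoff = !df$all_sentinel & df$ct <= cutoff_ct,
    all_sentinel = df$all_sentinel
  )
  attr(out, "reference_gene") <- "(pre-normalized)"
  attr(out, "grand_mean_ct") <- reference_ct
  attr(out, "cutoff_ct") <- cutoff_ct
  class(out) <- c("expression_profile", class(out))
  out
}

#' Filter genes by the expression cutoff
#'
#' A gene is retained in a cell type iff its normalized Ct is at or below the
#' cutoff (inclusive). The union set collects genes retained in at least one
#' cell type — the study's criterion for keeping a receptor in the comparative
#' analysis.
#'
#' @param profiles An `expression_profile` tibble.
#' @param ct_cutoff Cutoff in cycles (default 31.5).
#' @return An `expressed_filter`: list with `retained` (named list of gene
#'   sets per cell type), `union` (character vector), and `counts` (tibble of
#'   per-cell-type retained counts).
#' @export
filter_expressed <- function(profiles, ct_cutoff = 31.5) {
  df <- tibble::as_tibble(profiles)
  keep <- !df$all_sentinel & df$ct <= ct_cutoff
  retained <- split(df$gene_symbol[keep], df$cell_type[keep])
  cells <- sort(unique(df$cell_type))
  retained <- lapply(stats::setNames(cells, cells), function(ct_lab) {
    sort(unique(retained[[ct_lab]]))
  })
  union_set <- sort(unique(unlist(retained, use.names = FALSE)))
  counts <- tibble::tibble(
    cell_type = cells,
    n_retained = unname(vapply(retained, length, integer(1)))
  )
  structure(
    list(retained = retained, union = union_set, counts = counts,
         ct_cutoff = ct_cutoff),
    class = "expressed_filter"
  )
}

#' @export
print.expressed_filter <- function(x, ...) {
  cat("<expressed_filter> Ct <=", x$ct_cutoff, ":",
      length(x$union), "genes in union\n")
  print(x$counts)
  invisible(x)
}
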
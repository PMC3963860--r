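#' Rank concordance between transcript levels and spectral counts
#'
#' Kendall tau-b (tie-corrected) between a protein's transcript expression
#' units and its spectral (or peptide) counts across cell types. Cells where
#' the protein was not detected (`NA` counts) are mapped to 0 by default —
#' absence is informative — or excluded with `nd_as = "exclude"`.
#'
#' @param transcript_units Numeric vector of expression units per cell type.
#' @param counts Numeric vector of spectral counts, `NA` for not-detected.
#' @param nd_as `0` (default) or `"exclude"`.
#' @return Kendall tau-b in `[-1, 1]`.
#' @export
rank_concordance <- function(transcript_units, counts, nd_as = 0) {
  stopifnot(length(transcript_units) == length(counts))
  if (identical(nd_as, "exclude")) {
    keep <- !is.na(counts)
    transcript_units <- transcript_units[keep]
    counts <- counts[keep]
  } else {
    counts[is.na(counts)] <- nd_as
  }
  if (length(counts) < 3) {
    rlang::abort("Need at least 3 cell types with transcript values",
                 class = "receptoire_parameter_error")
  }
  if (stats::sd(transcript_units) == 0 || stats::sd(counts) == 0) {
    rlang::abort("All values tied on one side: tau undefined",
                 class = "receptoire_degenerate_error")
  }
  suppressWarnings(stats::cor(transcript_units, counts, method = "kendall"))
}

#' Cross-tabulate predicted vs observed MS detection
#'
#' Joins the observed detected/not-detected grid with the
#' [predict_detectable()] predictions on (accession, cell type) keys and
#' returns the confusion counts and accuracy.
#'
#' @param table Tibble with `accession`, `cell_type`, `detected` (logical).
#' @param predictions Tibble with `accession`, `cell_type`, `predicted`
#'   (logical).
#' @return List with `confusion` (named counts TP, FP, FN, TN), `accuracy`,
#'   and `cells` (the joined per-cell tibble).
#' @export
detection_agreement <- function(table, predictions) {
  table <- tibble::as_tibble(table)
  predictions <- tibble::as_tibble(predictions)
  joined <- dplyr::inner_join(table, predictions,
                              by = c("accession", "cell_type"))
  if (nrow(joined) != nrow(table) || nrow(joined) != nrow(predictions)) {
    rlang::abort("Observed and predicted grids do not share identical keys",
                 class = "receptoire_key_error")
  }
  tp <- sum(joined$detected & joined$predicted)
  fp <- sum(!joined$detected & joined$predicted)
  fn <- sum(joined$detected & !joined$predicted)
  tn <- sum(!joined$detected & !joined$predicted)
  list(
    confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
    accuracy = (tp + tn) / nrow(joined),
    cells = joined
  )
}

#' Read a spectral-count TSV
#'
#' @param path TSV with columns `accession`, `cell_type`, `peptides`,
#'   `spectra`; empty count fields mean not detected.
#' @return Tibble with a logical `detected` column (`nd` iff both counts
#'   absent).
#' @export
read_spectral_counts <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    accession = readr::col_character(), cell_type = readr::col_character(),
    peptides = readr::col_integer(), spectra = readr::col_integer()
  ))
  if (any(xor(is.na(df$peptides), is.na(df$spectra)))) {
    rlang::abort("Not-detected rows must have both counts absent",
                 class = "receptoire_format_error")
  }
  df$detected <- !is.na(df$peptides)
  df
}
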
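#' Published top-expressed Ct table
#'
#' The study's table of GPCRs with normalized Ct at or below 25 cycles in each
#' of the five cell types, as printed: mean Ct +/- sd, delta-Ct against the
#' RPLP0 reference (grand-mean Ct 21.12), and the printed fold
#' (`2^delta_ct`). Two f-NSC rows (FZD3, GPRC5B) print folds computed from
#' unrounded Ct values and so disagree slightly with `2^(printed delta_ct)`;
#' they are shipped as printed.
#'
#' @return Tibble `cell_type`, `gene_symbol`, `ct`, `ct_sd`, `delta_ct`,
#'   `delta_ct_sd`, `fold`, `fold_sd`.
#' @export
study_top_expressed <- function() {
  path <- system.file("extdata", "study_top_expressed.tsv",
                      package = "receptoire", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    cell_type = readr::col_character(), gene_symbol = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' Published proteomics comparison grid
#'
#' The study's 15-receptor x 5-cell-type grid: transcript expression units
#' (`2^-Ct * 10^12`), the in-silico expected-detectable peptide count per
#' receptor, and the observed unique-peptide and spectrum counts (absent =
#' not detected at 1% FDR).
#'
#' @return Tibble `gene_symbol`, `accession`, `mw_kda`, `expected_peptides`,
#'   `cell_type`, `units`, `peptides`, `spectra`, `detected`.
#' @export
study_proteomics <- function() {
  path <- system.file("extdata", "study_proteomics.tsv",
                      package = "receptoire", mustWork = TRUE)
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_symbol = readr::col_character(),
    accession = readr::col_character(),
    mw_kda = readr::col_double(),
    expected_peptides = readr::col_integer(),
    cell_type = readr::col_character(),
    units = readr::col_double(),
    peptides = readr::col_integer(),
    spectra = readr::col_integer()
  ))
  df$detected <- !is.na(df$peptides)
  df
}
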
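#' Read a long-format Ct table with its gene catalog
#'
#' Reads replicate-level cycle-threshold (Ct) observations exported from a
#' TaqMan low-density-array run, one observation per row, together with a
#' catalog classifying every assay on the card (GPCR, housekeeping, LANCL or
#' other). Wells that did not amplify are exported as an empty Ct field or the
#' token `"Undetermined"`; these become sentinel observations carrying the
#' sentinel Ct (40 cycles by convention).
#'
#' The expected dialect is UTF-8 TSV with a header. Ct table columns:
#' `assay_id`, `gene_symbol`, `cell_type`, `replicate`, `ct`. Catalog columns:
#' `assay_id`, `gene_symbol`, `category`.
#'
#' @param path Path to the Ct TSV.
#' @param catalog_path Path to the gene-catalog TSV.
#' @param sentinel_ct Ct value assigned to non-amplified wells (default 40).
#' @return A `ct_dataset`: list with `observations` (tibble with columns
#'   `assay_id`, `gene_symbol`, `cell_type`, `replicate`, `ct`, `is_sentinel`),
#'   `catalog`, and `sentinel_ct`.
#' @seealso [merge_replicates()], [write_ct_table()]
#' @export
read_ct_table <- function(path, catalog_path, sentinel_ct = 40) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("assay_id", "gene_symbol", "cell_type", "replicate", "ct")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("Ct table is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "receptoire_format_error"
    )
  }
  catalog <- read_gene_catalog(catalog_path)

  ct_chr <- raw$ct
  undetermined <- is.na(ct_chr) | trimws(ct_chr) == "" |
    tolower(trimws(ct_chr)) == "undetermined"
  ct_num <- suppressWarnings(as.numeric(ct_chr))
  bad <- !undetermined & is.na(ct_num)
  if (any(bad)) {
    rlang::abort(
      paste0("Non-numeric Ct value(s) other than 'Undetermined': ",
             paste(utils::head(unique(ct_chr[bad]), 5), collapse = ", ")),
      class = "receptoire_parse_error"
    )
  }

  obs <- tibble::tibble(
    assay_id = raw$assay_id,
    gene_symbol = raw$gene_symbol,
    cell_type = raw$cell_type,
    replicate = as.integer(raw$replicate),
    ct = ifelse(undetermined, sentinel_ct, ct_num),
    is_sentinel = undetermined
  )

  unknown <- setdiff(obs$assay_id, catalog$assay_id)
  if (length(unknown) > 0) {
    rlang::abort(
      paste0("Assay id(s) absent from the catalog: ",
             paste(utils::head(unknown, 5), collapse = ", ")),
      class = "receptoire_catalog_error"
    )
  }
  key <- paste(obs$assay_id, obs$cell_type, obs$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    rlang::abort(
      "Duplicated (assay_id, cell_type, replicate) observation(s) in Ct table",
      class = "receptoire_format_error"
    )
  }
  new_ct_dataset(obs, catalog, sentinel_ct)
}

#' Read a gene catalog TSV
#'
#' @param path TSV with columns `assay_id`, `gene_symbol`, `category`;
#'   categories are `GPCR`, `housekeeping`, `LANCL` or `other`.
#' @return Tibble catalog with unique assay ids.
#' @export
read_gene_catalog <- function(path) {
  catalog <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("assay_id", "gene_symbol", "category")
  missing_cols <- setdiff(required, names(catalog))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("Catalog is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "receptoire_format_error"
    )
  }
  if (anyDuplicated(catalog$assay_id)) {
    rlang::abort("Catalog assay ids must be unique",
                 class = "receptoire_catalog_error")
  }
  allowed <- c("GPCR", "housekeeping", "LANCL", "other")
  if (!all(catalog$category %in% allowed)) {
    rlang::abort(
      paste0("Catalog categories must be one of: ", paste(allowed, collapse = ", ")),
      class = "receptoire_catalog_error"
    )
  }
  tibble::as_tibble(catalog[required])
}

new_ct_dataset <- function(observations, catalog, sentinel_ct) {
  stopifnot(all(observations$ct > 0))
  structure(
    list(observations = observations, catalog = catalog, sentinel_ct = sentinel_ct),
    class = "ct_dataset"
  )
}

#' @export
print.ct_dataset <- function(x, ...) {
  cat("<ct_dataset>", nrow(x$observations), "observations,",
      nrow(x$catalog), "assays,",
      length(unique(x$observations$cell_type)), "cell types; sentinel Ct",
      x$sentinel_ct, "\n")
  invisible(x)
}

#' Write a ct_dataset back to the canonical TSV pair
#'
#' Sentinel observations are written with the `"Undetermined"` token so that a
#' write/read round trip reproduces the dataset exactly.
#'
#' @param dataset A `ct_dataset`.
#' @param path Output path for the Ct TSV.
#' @param catalog_path Output path for the catalog TSV (optional).
#' @return `dataset`, invisibly.
#' @export
write_ct_table <- function(dataset, path, catalog_path = NULL) {
  stopifnot(inherits(dataset, "ct_dataset"))
  out <- dataset$observations
  out$ct <- ifelse(out$is_sentinel, "Undetermined", format(out$ct, digits = 15))
  readr::write_tsv(out[c("assay_id", "gene_symbol", "cell_type", "replicate", "ct")], path)
  if (!is.null(catalog_path)) readr::write_tsv(dataset$catalog, catalog_path)
  invisible(dataset)
}

#' Aggregate replicate Ct observations into per-(gene, cell type) means
#'
#' Computes the arithmetic mean and sample standard deviation of the replicate
#' Ct values on the cycle (log-abundance) scale, the scale on which qPCR
#' replicate noise is approximately Gaussian. Sentinel (non-amplified)
#' replicates are excluded from the mean; a gene whose replicates are all
#' sentinel in a cell type keeps the sentinel value and is flagged
#' `all_sentinel`. Mixed sentinel/numeric replicate sets are flagged
#' `mixed_detection`. A single usable replicate yields sd 0.
#'
#' @param dataset A `ct_dataset`.
#' @return A `mean_ct` tibble with columns `assay_id`, `gene_symbol`,
#'   `cell_type`, `mean_ct`, `sd_ct`, `n_replicates`, `all_sentinel`,
#'   `mixed_detection`; the sentinel Ct is kept as attribute `sentinel_ct`.
#' @export
merge_replicates <- function(dataset) {
  stopifnot(inherits(dataset, "ct_dataset"))
  obs <- dataset$observations
  if (nrow(obs) == 0) {
    rlang::abort("Empty Ct dataset", class = "receptoire_format_error")
  }
  sentinel <- dataset$sentinel_ct
  res <- obs |>
    dplyr::group_by(.data$assay_id, .data$gene_symbol, .data$cell_type) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      all_sentinel = all(.data$is_sentinel),
      mixed_detection = any(.data$is_sentinel) && !all(.data$is_sentinel),
      mean_ct = if (all(.data$is_sentinel)) sentinel else mean(.data$ct[!.data$is_sentinel]),
      sd_ct = if (all(.data$is_sentinel)) 0 else {
        usable <- .data$ct[!.data$is_sentinel]
        if (length(usable) < 2) 0 else stats::sd(usable)
      },
      .groups = "drop"
    ) |>
    dplyr::select("assay_id", "gene_symbol", "cell_type", "mean_ct", "sd_ct",
                  "n_replicates", "all_sentinel", "mixed_detection")
  attr(res, "sentinel_ct") <- sentinel
  attr(res, "catalog") <- dataset$catalog
  class(res) <- c("mean_ct", class(res))
  res
}
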
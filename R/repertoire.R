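#' Most highly expressed genes per cell type
#'
#' Lists, per cell type, the genes with normalized Ct at or below a display
#' threshold (default 25 cycles, the study's "most highly expressed" bar),
#' sorted by ascending Ct.
#'
#' @param profiles An `expression_profile` tibble.
#' @param ct_max Display threshold in cycles (default 25).
#' @return Tibble `cell_type`, `gene_symbol`, `ct`, `delta_ct`,
#'   `fold_below_ref`, sorted by cell type then ascending Ct.
#' @export
top_expressed <- function(profiles, ct_max = 25) {
  df <- tibble::as_tibble(profiles)
  df[!df$all_sentinel & df$ct <= ct_max,
     c("cell_type", "gene_symbol", "ct", "delta_ct", "fold_below_ref")] |>
    dplyr::arrange(.data$cell_type, .data$ct)
}

#' Genes expressed above cutoff in every cell type
#'
#' The "common core" of the repertoire: genes whose normalized Ct is at or
#' below the cutoff in all cell types present in the profile.
#'
#' @param profiles An `expression_profile` tibble.
#' @param cutoff Cutoff Ct in cycles (default 31.5).
#' @return Character vector of gene symbols.
#' @export
core_set <- function(profiles, cutoff = 31.5) {
  df <- tibble::as_tibble(profiles)
  n_cells <- length(unique(df$cell_type))
  df$pass <- !df$all_sentinel & df$ct <= cutoff
  tab <- df |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(n_pass = sum(.data$pass), n_seen = dplyr::n(), .groups = "drop")
  sort(tab$gene_symbol[tab$n_pass == n_cells & tab$n_seen == n_cells])
}

# Single-letter codes for the study's five cell types; unknown labels fall
# back to their first character.
.cell_code_letter <- function(cell) {
  map <- c("TG1" = "T", "OB1" = "O", "U87" = "U", "U-87" = "U",
           "f-NSC" = "N", "NSC" = "N", "HA" = "H")
  out <- unname(map[cell])
  out[is.na(out)] <- toupper(substr(cell[is.na(out)], 1, 1))
  out
}

.code_string <- function(cells) {
  letters_ <- .cell_code_letter(cells)
  ord <- c("N", "T", "O", "U", "H")  # the study's printed letter order
  paste(letters_[order(match(letters_, ord, nomatch = 99L), letters_)],
        collapse = "")
}

#' Evaluate the cell-type specificity rule for one gene
#'
#' The primitive behind [classify_specificity()]: decides whether a gene's
#' expression pattern satisfies the (cutoff, fold-margin) rule for a given
#' cell-type subset. Over direction: above cutoff in every subset cell, and
#' either every complement cell below cutoff or minimum subset units at least
#' `f`-fold the maximum complement units; under direction is the mirror
#' image. For a fixed subset, satisfaction is anti-monotone in `f`.
#'
#' @param units Named numeric vector of expression units per cell type.
#' @param above Named logical vector: above-cutoff flag per cell type.
#' @param subset Character vector, a proper non-empty subset of the cell
#'   types.
#' @param f Fold margin (> 1).
#' @param direction `"over"` or `"under"`.
#' @return List with `ok` (logical) and `ratio` (the inside/outside
#'   separation used for tie-breaking; `NA` when the cutoff pattern already
#'   fails).
#' @export
specificity_rule <- function(units, above, subset, f, direction) {
  inside <- subset
  outside <- setdiff(names(units), subset)
  if (direction == "over") {
    if (!all(above[inside])) return(list(ok = FALSE, ratio = NA_real_))
    lo_in <- min(units[inside])
    hi_out <- max(units[outside])
    ok <- all(!above[outside]) || lo_in >= f * hi_out
    list(ok = ok, ratio = lo_in / hi_out)
  } else {
    if (!all(above[outside])) return(list(ok = FALSE, ratio = NA_real_))
    hi_in <- max(units[inside])
    lo_out <- min(units[outside])
    ok <- all(!above[inside]) || hi_in * f <= lo_out
    list(ok = ok, ratio = lo_out / hi_in)
  }
}

#' Classify genes into cell-type specificity groups
#'
#' Formalizes the study's qualitative subgroup assignments with a
#' deterministic rule. A gene is assigned the over-direction code S (a proper
#' subset of the cell types) iff (a) it is above cutoff in every cell type of
#' S, and (b) either every cell type outside S is below cutoff, or its minimum
#' units over S are at least `f`-fold its maximum units over the complement.
#' The under-direction rule is the mirror image. Each gene receives at most
#' one maximal code per direction: the largest satisfying S, ties broken by
#' the higher inside/outside unit ratio. A gene assigned both an over- and an
#' under-code is kept only if the two codes are disjoint; otherwise both
#' assignments are rejected.
#'
#' @param profiles An `expression_profile` tibble.
#' @param f Fold margin (> 1; default 3).
#' @param cutoff Cutoff Ct in cycles (default 31.5).
#' @return Tibble `code` (letter code, e.g. `"TO"`), `cells` (comma-joined
#'   cell types), `direction` (`"over"`/`"under"`), `gene_symbol`, `ratio`
#'   (inside/outside separation).
#' @export
classify_specificity <- function(profiles, f = 3.0, cutoff = 31.5) {
  if (f <= 1) {
    rlang::abort("Fold margin f must be > 1", class = "receptoire_parameter_error")
  }
  df <- tibble::as_tibble(profiles)
  cells <- sort(unique(df$cell_type))
  if (length(cells) < 2) {
    rlang::abort("Need at least 2 cell types", class = "receptoire_parameter_error")
  }
  wide_u <- tidyr::pivot_wider(df[c("gene_symbol", "cell_type", "units")],
                               names_from = "cell_type", values_from = "units")
  wide_a <- tidyr::pivot_wider(
    dplyr::mutate(df, pass = !.data$all_sentinel & .data$ct <= cutoff)[
      c("gene_symbol", "cell_type", "pass")],
    names_from = "cell_type", values_from = "pass")

  # all proper non-empty subsets, largest first
  subsets <- unlist(lapply(seq_len(length(cells) - 1), function(k) {
    utils::combn(cells, k, simplify = FALSE)
  }), recursive = FALSE)
  subsets <- subsets[order(-vapply(subsets, length, integer(1)))]

  assign_one <- function(units, above, direction) {
    best <- NULL
    best_size <- -1L
    for (s in subsets) {
      if (length(s) < best_size) break
      r <- specificity_rule(units, above, s, f, direction)
      if (r$ok) {
        if (length(s) > best_size ||
            (length(s) == best_size && isTRUE(r$ratio > best$ratio))) {
          best <- list(cells = s, ratio = r$ratio)
          best_size <- length(s)
        }
      }
    }
    best
  }

  rows <- list()
  for (i in seq_len(nrow(wide_u))) {
    gene <- wide_u$gene_symbol[i]
    units <- unlist(wide_u[i, cells])
    above <- unlist(wide_a[i, cells])
    if (anyNA(units) || anyNA(above)) next
    if (!any(above)) next  # nothing expressed: no specificity to report
    over <- assign_one(units, above, "over")
    under <- assign_one(units, above, "under")
    if (!is.null(over) && !is.null(under) &&
        length(intersect(over$cells, under$cells)) > 0) {
      over <- NULL
      under <- NULL
    }
    for (d in c("over", "under")) {
      hit <- if (d == "over") over else under
      if (!is.null(hit)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          code = .code_string(hit$cells),
          cells = paste(sort(hit$cells), collapse = ","),
          direction = d,
          gene_symbol = gene,
          ratio = hit$ratio
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(code = character(), cells = character(),
                          direction = character(), gene_symbol = character(),
                          ratio = numeric()))
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$direction, .data$code, .data$gene_symbol)
}

#' Single-cell-type marker genes
#'
#' [classify_specificity()] restricted to singleton codes: genes specific to
#' exactly one cell type.
#'
#' @inheritParams classify_specificity
#' @return Named list (one element per cell type) of over-direction marker
#'   gene sets.
#' @export
cell_markers <- function(profiles, f = 3.0, cutoff = 31.5) {
  groups <- classify_specificity(profiles, f = f, cutoff = cutoff)
  cells <- sort(unique(tibble::as_tibble(profiles)$cell_type))
  singles <- groups[groups$direction == "over" & !grepl(",", groups$cells), ]
  lapply(stats::setNames(cells, cells), function(ct_lab) {
    sort(singles$gene_symbol[singles$cells == ct_lab])
  })
}
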
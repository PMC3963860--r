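# Monoisotopic residue masses (Da) for the 20 standard amino acids, plus the
# mass of water added on hydrolysis.
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
.WATER_MASS <- 18.010565

.check_residues <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(.RESIDUE_MASS))
  if (length(bad) > 0) {
    rlang::abort(
      paste0("Non-standard residue(s): ", paste(bad, collapse = ", ")),
      class = "receptoire_residue_error"
    )
  }
  chars
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) except when the next
#' residue is proline (the Keil rule). With `missed_cleavages = m`, also emits
#' every concatenation of up to `m + 1` adjacent fully-cleaved fragments. At
#' `m = 0` the fragments tile the sequence exactly.
#'
#' @param sequence Protein sequence over the 20 standard one-letter residues.
#' @param missed_cleavages Maximum number of internal uncut K/R sites per
#'   peptide (default 0).
#' @return Tibble `peptide`, `start`, `end` (1-based inclusive), `n_missed`.
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0) {
  stopifnot(nchar(sequence) > 0)
  chars <- .check_residues(sequence)
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  base <- tibble::tibble(
    peptide = substring(sequence, starts, ends),
    start = starts, end = ends, n_missed = 0L
  )
  if (missed_cleavages == 0) return(base)
  out <- list(base)
  for (m in seq_len(missed_cleavages)) {
    if (m + 1 > length(starts)) break
    i <- seq_len(length(starts) - m)
    out[[m + 1]] <- tibble::tibble(
      peptide = substring(sequence, starts[i], ends[i + m]),
      start = starts[i], end = ends[i + m], n_missed = m
    )
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$start, .data$end)
}

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water (18.010565 Da). The
#' empty sequence returns the bare water mass.
#'
#' @param sequence Peptide sequence over the 20 standard residues.
#' @return Mass in Da.
#' @export
peptide_mass <- function(sequence) {
  if (nchar(sequence) == 0) return(.WATER_MASS)
  chars <- .check_residues(sequence)
  sum(.RESIDUE_MASS[chars]) + .WATER_MASS
}

#' Construct a protein record
#'
#' @param accession Accession string.
#' @param sequence Residue string.
#' @param topology Tibble/data.frame with `start`, `end` (1-based inclusive)
#'   and `label` in EXTRACELLULAR / TRANSMEMBRANE / CYTOPLASMIC; segments must
#'   not overlap and must lie within the sequence. Residues not covered by any
#'   segment are treated as unlocalized (and fail the compartment filter).
#' @param modified_positions Integer positions carrying post-translational
#'   modifications (e.g. glycosylation sites).
#' @return A `protein_record` list.
#' @export
protein_record <- function(accession, sequence, topology = NULL,
                           modified_positions = integer()) {
  .check_residues(sequence)
  n <- nchar(sequence)
  if (is.null(topology)) {
    topology <- tibble::tibble(start = integer(), end = integer(),
                               label = character())
  }
  topology <- tibble::as_tibble(topology)
  allowed <- c("EXTRACELLULAR", "TRANSMEMBRANE", "CYTOPLASMIC")
  if (nrow(topology) > 0) {
    stopifnot(all(topology$label %in% allowed),
              all(topology$start >= 1), all(topology$end <= n),
              all(topology$start <= topology$end))
    covered <- unlist(Map(seq.int, topology$start, topology$end))
    if (anyDuplicated(covered)) {
      rlang::abort("Topology segments overlap",
                   class = "receptoire_topology_error")
    }
  }
  stopifnot(all(modified_positions >= 1), all(modified_positions <= n))
  structure(
    list(accession = accession, sequence = sequence, topology = topology,
         modified_positions = as.integer(modified_positions)),
    class = "protein_record"
  )
}

# label covering [start, end] entirely within one segment, else NA
.peptide_compartment <- function(topology, start, end) {
  if (nrow(topology) == 0) return(NA_character_)
  hit <- topology$start <= start & topology$end >= end
  if (!any(hit)) return(NA_character_)
  topology$label[which(hit)[1]]
}

#' Count MS-detectable tryptic peptides for a protein
#'
#' Applies the study's four detectability criteria to the fully-cleaved
#' (0 missed cleavage) tryptic peptides: (i) monoisotopic mass within
#' `mass_range` (inclusive); (ii) the peptide lies entirely inside a single
#' extracellular or cytoplasmic segment (transmembrane or unlocalized
#' residues fail — only compartments exposed to trypsin digestion count);
#' (iii) no annotated modified residue inside the peptide; (iv) unique —
#' by default distinct within the parent protein, and additionally absent
#' from every sequence of `uniqueness_db` when one is supplied.
#'
#' @param record A `protein_record`.
#' @param mass_range Numeric length-2, Da (default `c(1000, 3000)`).
#' @param uniqueness_db Optional character vector of background protein
#'   sequences (the parent itself is ignored if present).
#' @return A `digest_report`: list with `accession`, `candidates` (tibble with
#'   per-peptide filter flags), `expected_count`, and `tallies` (named counts
#'   of candidates failing each criterion; a peptide may fail several).
#' @export
count_expected_peptides <- function(record, mass_range = c(1000, 3000),
                                    uniqueness_db = NULL) {
  stopifnot(inherits(record, "protein_record"),
            length(mass_range) == 2, mass_range[1] <= mass_range[2])
  pep <- tryptic_digest(record$sequence, missed_cleavages = 0)
  pep$mass <- vapply(pep$peptide, peptide_mass, numeric(1), USE.NAMES = FALSE)
  pep$compartment <- vapply(seq_len(nrow(pep)), function(i) {
    .peptide_compartment(record$topology, pep$start[i], pep$end[i])
  }, character(1))
  pep$pass_mass <- pep$mass >= mass_range[1] & pep$mass <= mass_range[2]
  pep$pass_compartment <- !is.na(pep$compartment) &
    pep$compartment %in% c("EXTRACELLULAR", "CYTOPLASMIC")
  mods <- record$modified_positions
  pep$pass_modification <- vapply(seq_len(nrow(pep)), function(i) {
    !any(mods >= pep$start[i] & mods <= pep$end[i])
  }, logical(1))
  dup <- duplicated(pep$peptide) | duplicated(pep$peptide, fromLast = TRUE)
  pep$pass_unique <- !dup
  if (!is.null(uniqueness_db)) {
    bg <- setdiff(uniqueness_db, record$sequence)
    if (length(bg) > 0) {
      in_bg <- vapply(pep$peptide, function(p) {
        any(grepl(p, bg, fixed = TRUE))
      }, logical(1), USE.NAMES = FALSE)
      pep$pass_unique <- pep$pass_unique & !in_bg
    }
  }
  pep$expected <- pep$pass_mass & pep$pass_compartment &
    pep$pass_modification & pep$pass_unique
  structure(
    list(
      accession = record$accession,
      candidates = pep,
      expected_count = sum(pep$expected),
      tallies = c(
        failed_mass = sum(!pep$pass_mass),
        failed_compartment = sum(!pep$pass_compartment),
        failed_modification = sum(!pep$pass_modification),
        failed_uniqueness = sum(!pep$pass_unique),
        total_candidates = nrow(pep)
      )
    ),
    class = "digest_report"
  )
}

#' @export
print.digest_report <- function(x, ...) {
  cat("<digest_report>", x$accession, ":", x$expected_count,
      "expected peptide(s) of", nrow(x$candidates), "candidates\n")
  invisible(x)
}

#' Joint transcript/peptide detectability prediction
#'
#' A protein is predicted MS-detectable iff it has strictly more than
#' `min_peptides` expected peptides and strictly more than `min_units`
#' transcript expression units (the study's "more than 5 peptides and over
#' 20000 units" rule).
#'
#' @param expected_count Expected-peptide count(s).
#' @param transcript_units Transcript expression units (same length or
#'   recyclable).
#' @param min_peptides Strict lower bound on peptides (default 5).
#' @param min_units Strict lower bound on units (default 20000).
#' @return Logical vector.
#' @export
predict_detectable <- function(expected_count, transcript_units,
                               min_peptides = 5, min_units = 20000) {
  if (any(expected_count < 0) || any(transcript_units < 0)) {
    rlang::abort("Counts and units must be non-negative",
                 class = "receptoire_parameter_error")
  }
  expected_count > min_peptides & transcript_units > min_units
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences; the accession is the first
#'   whitespace-delimited token of each header.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    rlang::abort("Biostrings is required to read FASTA files")
  }
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  out
}

#' Read a topology annotation TSV
#'
#' @param path TSV with columns `accession`, `start`, `end`, `label`
#'   (1-based inclusive coordinates).
#' @return Tibble.
#' @export
read_topology <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    accession = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), label = readr::col_character()
  ))
}

#' Read a modified-positions TSV
#'
#' @param path TSV with columns `accession`, `position`.
#' @return Tibble.
#' @export
read_modifications <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    accession = readr::col_character(), position = readr::col_integer()
  ))
}
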
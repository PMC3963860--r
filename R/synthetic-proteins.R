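# Independent brute-force digest oracle.
#
# Deliberately shares no code with the digest-predictor module: the cleavage
# scan is an explicit residue-by-residue loop, the mass table is derived at
# load time from monoisotopic elemental compositions, and the compartment and
# modification checks are re-implemented with loops. Used as ground truth for
# the synthetic protein set.
.ORACLE_ATOM <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, S = 31.97207069)
.ORACLE_COMPOSITION <- list(
  G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1), L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1), N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3), Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1), E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1), H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1), R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2), W = c(C = 11, H = 10, N = 2, O = 1)
)
.ORACLE_RESIDUE_MASS <- vapply(.ORACLE_COMPOSITION, function(comp) {
  sum(.ORACLE_ATOM[names(comp)] * comp)
}, numeric(1))
.ORACLE_WATER <- 2 * .ORACLE_ATOM[["H"]] + .ORACLE_ATOM[["O"]]

.oracle_peptides <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  frags <- list()
  start <- 1L
  for (i in seq_len(n)) {
    is_site <- chars[i] %in% c("K", "R") && i < n && chars[i + 1] != "P"
    if (is_site || i == n) {
      frags[[length(frags) + 1]] <- c(start, i)
      start <- i + 1L
    }
  }
  frags
}

.oracle_mass <- function(chars, from, to) {
  total <- .ORACLE_WATER
  for (i in from:to) total <- total + .ORACLE_RESIDUE_MASS[[chars[i]]]
  total
}

.oracle_expected_count <- function(record, mass_range = c(1000, 3000)) {
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  frags <- .oracle_peptides(record$sequence)
  seqs <- vapply(frags, function(fr) {
    paste(chars[fr[1]:fr[2]], collapse = "")
  }, character(1))
  counts <- table(seqs)
  keep <- logical(length(frags))
  for (k in seq_along(frags)) {
    fr <- frags[[k]]
    m <- .oracle_mass(chars, fr[1], fr[2])
    if (m < mass_range[1] || m > mass_range[2]) next
    ok_compartment <- FALSE
    topo <- record$topology
    if (nrow(topo) > 0) {
      for (t in seq_len(nrow(topo))) {
        if (topo$start[t] <= fr[1] && topo$end[t] >= fr[2] &&
            topo$label[t] %in% c("EXTRACELLULAR", "CYTOPLASMIC")) {
          ok_compartment <- TRUE
          break
        }
      }
    }
    if (!ok_compartment) next
    has_mod <- FALSE
    for (p in record$modified_positions) {
      if (p >= fr[1] && p <= fr[2]) { has_mod <- TRUE; break }
    }
    if (has_mod) next
    if (counts[[seqs[k]]] > 1) next
    keep[k] <- TRUE
  }
  sum(keep)
}

#' Generate synthetic membrane-protein records with digest ground truth
#'
#' Sequences are drawn over the 20 standard residues with a controlled
#' combined K/R density (default 8%, typical of membrane receptors). Topology
#' segments tile each sequence in the 7-transmembrane pattern (extracellular
#' and cytoplasmic loops of 15-80 residues alternating with 19-24-residue
#' transmembrane helices); a small fraction of residues carry planted
#' modifications. The expected-detectable peptide count of every record is
#' computed by an independent brute-force digest (no code shared with
#' [count_expected_peptides()]) and returned as ground truth.
#'
#' @param n Number of records (>= 1).
#' @param seed Integer seed.
#' @param length_range Sequence length range (default 300-800 residues).
#' @param kr_prob Combined sampling probability of K and R (default 0.08).
#' @param mod_prob Per-residue modification probability (default 0.02).
#' @return List with `records` (list of `protein_record`) and `truth` (tibble
#'   `accession`, `oracle_expected`).
#' @export
simulate_proteins <- function(n, seed = 1L, length_range = c(300, 800),
                              kr_prob = 0.08, mod_prob = 0.02) {
  if (n < 1) {
    rlang::abort("n must be >= 1", class = "receptoire_parameter_error")
  }
  set.seed(as.integer(seed))
  residues <- names(.ORACLE_COMPOSITION)
  weights <- stats::setNames(rep((1 - kr_prob) / 18, 20), residues)
  weights[c("K", "R")] <- kr_prob / 2
  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(length_range[1]:length_range[2], 1)
    seq_chars <- sample(residues, len, replace = TRUE, prob = weights)
    sequence <- paste(seq_chars, collapse = "")
    # tile topology: loop / TM / loop / TM ... starting extracellular
    labels <- c("EXTRACELLULAR", "TRANSMEMBRANE", "CYTOPLASMIC", "TRANSMEMBRANE")
    segs <- list()
    pos <- 1L
    li <- 0L
    while (pos <= len) {
      lab <- labels[(li %% 4) + 1]
      w <- if (lab == "TRANSMEMBRANE") sample(19:24, 1) else sample(15:80, 1)
      end <- min(pos + w - 1L, len)
      segs[[length(segs) + 1]] <- tibble::tibble(start = pos, end = end,
                                                 label = lab)
      pos <- end + 1L
      li <- li + 1L
    }
    topology <- dplyr::bind_rows(segs)
    mods <- which(stats::runif(len) < mod_prob)
    acc <- sprintf("SYNP%04d", i)
    rec <- protein_record(acc, sequence, topology, mods)
    records[[i]] <- rec
    truth[[i]] <- tibble::tibble(accession = acc,
                                 oracle_expected = .oracle_expected_count(rec))
  }
  list(records = records, truth = dplyr::bind_rows(truth))
}

#' Simulate a spectral-count table from expression and digest reports
#'
#' Spectrum counts are Poisson with mean proportional to transcript units
#' times expected-detectable peptides (rate `rate` per unit-peptide); the
#' unique-peptide count is the occupancy of the expected peptides when the
#' spectra are spread uniformly over them. Proteins failing the
#' detectability rule ([predict_detectable()]) are reported not-detected with
#' probability `nd_miss_prob`; a zero draw is also not-detected.
#'
#' @param profiles An `expression_profile` tibble whose `gene_symbol` values
#'   key into `digests`.
#' @param digests Named list of `digest_report` objects (names = gene
#'   symbols/accessions shared with `profiles`).
#' @param seed Integer seed.
#' @param rate Expected spectra per (unit x peptide) (default 2e-5: the most
#'   abundant receptors, at ~1e5 units and ~15 peptides, yield a few dozen
#'   spectra, matching typical membrane-proteome depth).
#' @param nd_miss_prob Probability that a rule-failing protein is dropped
#'   outright (default 0.95).
#' @return Tibble `accession`, `cell_type`, `peptides`, `spectra`, `detected`
#'   (`NA` counts when not detected).
#' @export
simulate_spectral_counts <- function(profiles, digests, seed = 1L,
                                     rate = 2e-5, nd_miss_prob = 0.95) {
  df <- tibble::as_tibble(profiles)
  missing_keys <- setdiff(unique(df$gene_symbol), names(digests))
  if (length(missing_keys) > 0) {
    rlang::abort(paste0("No digest report for: ",
                        paste(utils::head(missing_keys, 5), collapse = ", ")),
                 class = "receptoire_key_error")
  }
  set.seed(as.integer(seed))
  expected <- vapply(digests, function(d) d$expected_count, numeric(1))
  out <- df[c("gene_symbol", "cell_type", "units")]
  out$expected <- expected[out$gene_symbol]
  n <- nrow(out)
  lambda <- out$units * out$expected * rate
  spectra <- stats::rpois(n, lambda)
  rule_ok <- predict_detectable(out$expected, out$units)
  dropped <- !rule_ok & stats::runif(n) < nd_miss_prob
  spectra[dropped] <- 0L
  peptides <- integer(n)
  for (i in seq_len(n)) {
    if (spectra[i] > 0) {
      peptides[i] <- length(unique(sample.int(out$expected[i], spectra[i],
                                              replace = TRUE)))
    }
  }
  detected <- spectra > 0
  tibble::tibble(
    accession = out$gene_symbol,
    cell_type = out$cell_type,
    peptides = ifelse(detected, peptides, NA_integer_),
    spectra = ifelse(detected, spectra, NA_integer_),
    detected = detected
  )
}
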
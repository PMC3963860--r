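# Independent residue-mass oracle for tests: monoisotopic masses assembled
# from elemental compositions, not from the package's residue table.
.test_atom <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                O = 15.9949146221, S = 31.97207069)
.test_formula <- list(
  G = "C2H3N1O1", A = "C3H5N1O1", S = "C3H5N1O2", P = "C5H7N1O1",
  V = "C5H9N1O1", T = "C4H7N1O2", C = "C3H5N1O1S1", L = "C6H11N1O1",
  I = "C6H11N1O1", N = "C4H6N2O2", D = "C4H5N1O3", Q = "C5H8N2O2",
  K = "C6H12N2O1", E = "C5H7N1O3", M = "C5H9N1O1S1", H = "C6H7N3O1",
  F = "C9H9N1O1", R = "C6H12N4O1", Y = "C9H9N1O2", W = "C11H10N2O1"
)
.test_residue_mass <- vapply(.test_formula, function(f) {
  m <- regmatches(f, gregexpr("[A-Z][0-9]+", f))[[1]]
  sum(vapply(m, function(tok) {
    .test_atom[[substr(tok, 1, 1)]] * as.numeric(substring(tok, 2))
  }, numeric(1)))
}, numeric(1))
.test_mass <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  sum(.test_residue_mass[chars]) + 2 * .test_atom[["H"]] + .test_atom[["O"]]
}

test_that("tryptic_digest applies the Keil rule and tiles the sequence", {
  expect_equal(tryptic_digest("AKRPGKR")$peptide, c("AK", "RPGK", "R"))
  expect_equal(tryptic_digest("ACDEFG")$peptide, "ACDEFG")  # no K/R
  expect_error(tryptic_digest("ABZ"), class = "receptoire_residue_error")

  # one missed cleavage adds the adjacent concatenations
  m1 <- tryptic_digest("AKRPGKR", missed_cleavages = 1)
  expect_setequal(m1$peptide[m1$n_missed == 1], c("AKRPGK", "RPGKR"))

  # tiling invariant on random sequences
  set.seed(5)
  residues <- names(.test_residue_mass)
  for (i in 1:200) {
    s <- paste(sample(residues, sample(5:80, 1), replace = TRUE), collapse = "")
    pep <- tryptic_digest(s)
    expect_identical(paste(pep$peptide, collapse = ""), s)
    expect_identical(pep$start[1], 1L)
    expect_identical(pep$end[nrow(pep)], nchar(s))
  }
})

test_that("peptide_mass matches the elemental-composition oracle", {
  expect_equal(peptide_mass("GGGGG"), 5 * 57.02146 + 18.010565, tolerance = 1e-6)
  expect_equal(peptide_mass("GGGGG"), 303.118, tolerance = 1e-3)
  expect_equal(peptide_mass(""), 18.010565, tolerance = 1e-6)
  set.seed(6)
  residues <- names(.test_residue_mass)
  for (i in 1:50) {
    s <- paste(sample(residues, 12, replace = TRUE), collapse = "")
    expect_equal(peptide_mass(s), .test_mass(s), tolerance = 1e-6)
  }
})

test_that("count_expected_peptides applies the four detectability filters", {
  # fully transmembrane protein: nothing is exposed to trypsin
  seq <- paste(rep("ACDEFGHILK", 10), collapse = "")
  tm <- protein_record("P1", seq,
                       tibble::tibble(start = 1, end = nchar(seq),
                                      label = "TRANSMEMBRANE"))
  expect_equal(count_expected_peptides(tm)$expected_count, 0)

  # three distinct exposed in-range peptides; the modification filter then
  # removes all of them
  seq2 <- "ACDEFGHILKWWYYFFMMNKTTSSPPVVGGHHR"
  topo <- tibble::tibble(start = 1, end = nchar(seq2), label = "EXTRACELLULAR")
  open <- protein_record("P2", seq2, topo)
  rep_open <- count_expected_peptides(open)
  expect_equal(rep_open$expected_count, 3)
  modded <- protein_record("P3", seq2, topo,
                           modified_positions = seq(1, nchar(seq2), 2))
  expect_equal(count_expected_peptides(modded)$expected_count, 0)

  # uniqueness: repeated fragment inside the parent never counts; background
  # sequences knock out shared peptides
  dup_seq <- "ACDEFGHILKACDEFGHILKWWYYFFMMNK"
  dup <- protein_record("P4", dup_seq,
                        tibble::tibble(start = 1, end = nchar(dup_seq),
                                       label = "CYTOPLASMIC"))
  rep_dup <- count_expected_peptides(dup)
  expect_equal(rep_dup$expected_count, 1)  # only the WWYYFFMMNK fragment
  rep_bg <- count_expected_peptides(dup, uniqueness_db = "XWWYYFFMMNKX")
  expect_equal(rep_bg$expected_count, 0)

  # tallies are consistent with the candidate table
  expect_equal(rep_dup$tallies[["total_candidates"]], nrow(rep_dup$candidates))
  expect_equal(rep_dup$expected_count, sum(rep_dup$candidates$expected))
})

test_that("digest engine equals the independent brute-force oracle", {
  sim <- simulate_proteins(30, seed = 8)
  counts <- vapply(sim$records, function(r) {
    count_expected_peptides(r)$expected_count
  }, numeric(1))
  expect_equal(counts, sim$truth$oracle_expected)
})

test_that("expected count is monotone in the mass window", {
  sim <- simulate_proteins(15, seed = 9)
  for (r in sim$records) {
    narrow <- count_expected_peptides(r, mass_range = c(1000, 3000))$expected_count
    wide <- count_expected_peptides(r, mass_range = c(800, 3500))$expected_count
    expect_gte(wide, narrow)
  }
})

test_that("predict_detectable uses strict thresholds on both axes", {
  expect_true(predict_detectable(14, 42820))   # GPR56 in OB1: detected
  expect_false(predict_detectable(2, 29644))   # CXCR4 in OB1: too few peptides
  expect_false(predict_detectable(50, 2338))   # LPHN2 in f-NSC: too few units
  expect_false(predict_detectable(5, 20000))   # boundaries are strict
  expect_error(predict_detectable(-1, 5),
               class = "receptoire_parameter_error")
})
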
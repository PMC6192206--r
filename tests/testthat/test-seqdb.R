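test_that("FASTA round-trip keeps identifiers, descriptions and sequences", {
  db <- tinyProteinDb()
  path <- tempfile(fileext = ".fasta")
  writeFastaDb(db, path)
  back <- readFasta(path)
  expect_equal(names(back@sequences), c("p1", "p2", "p3"))
  expect_equal(as.character(back@sequences), as.character(db@sequences),
               ignore_attr = TRUE)
  expect_equal(back@description, c("first", "second", "third"))

  # identifier is the first whitespace-delimited header token
  p2 <- tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description here", "PEPK"), p2)
  one <- readFasta(p2)
  expect_equal(names(one@sequences), "p1")
  expect_equal(as.character(one@sequences), "PEPK", ignore_attr = TRUE)
})

test_that("FASTA reader rejects empty files and empty records", {
  p <- tempfile(fileext = ".fasta")
  writeLines(character(0), p)
  expect_error(readFasta(p))
  p2 <- tempfile(fileext = ".fasta")
  writeLines(c(">ok", "PEPTIDEK", ">empty1", ">tail", "AAK"), p2)
  expect_error(readFasta(p2), "empty1")
})

test_that("decoy generation doubles the database with reversed sequences", {
  db <- generateDecoys(tinyProteinDb(), prefix = "Rev_")
  expect_length(db@sequences, 6L)
  expect_equal(sum(db@isDecoy), 3L)
  expect_equal(as.character(db@sequences[["Rev_p1"]]),
               paste(rev(strsplit("MKRAGKPEPTIDEK", "")[[1]]), collapse = ""))
  # involution: reversing a decoy recovers its target
  for (id in c("p1", "p2", "p3")) {
    rev_seq <- as.character(db@sequences[[paste0("Rev_", id)]])
    expect_equal(paste(rev(strsplit(rev_seq, "")[[1]]), collapse = ""),
                 as.character(db@sequences[[id]]))
  }
  # palindromic sequence still yields a (flagged) decoy
  pal <- generateDecoys(newProteinDb("q1", "ABA"))
  expect_equal(as.character(pal@sequences[["Rev_q1"]]), "ABA")
  expect_true(isDecoy(pal)[["Rev_q1"]])
  # prefix collision is refused
  expect_error(generateDecoys(newProteinDb("Rev_x", "PEPK"), prefix = "Rev_"),
               "collide")
})

test_that("tryptic digestion honours K/R-not-before-P with missed cleavages", {
  d <- digestProtein("MKRAGK", max_missed = 1L, length_range = c(1L, 60L))
  got <- setNames(d$missed_cleavages, d$sequence)
  expect_mapequal(as.list(got),
                  list(MK = 0L, MKR = 1L, R = 0L, RAGK = 1L, AGK = 0L))
  # K before P blocks cleavage
  expect_equal(digestProtein("AAKPAA", length_range = c(1L, 60L))$sequence,
               "AAKPAA")
  # no cleavage site: whole protein, length permitting
  expect_equal(digestProtein("AAAA", length_range = c(1L, 60L))$sequence, "AAAA")
  expect_equal(nrow(digestProtein("AAAA", length_range = c(6L, 60L))), 0L)
})

test_that("zero-missed-cleavage peptides re-concatenate to the protein", {
  set.seed(11)
  aa <- names(psmEnsemble:::.RESIDUE_MASS)
  for (k in 1:20) {
    w <- ifelse(aa %in% c("K", "R"), 4, 1)
    prot <- paste(sample(aa, sample(30:120, 1), replace = TRUE, prob = w),
                  collapse = "")
    d <- digestProtein(prot, max_missed = 0L, length_range = c(1L, 10000L))
    expect_equal(paste(d$sequence, collapse = ""), prot)
    expect_true(all(d$missed_cleavages == 0L))
  }
})

test_that("peptide masses follow the monoisotopic residue table plus water", {
  expect_equal(peptideMass("G", fixed_mods = NULL), 75.03203, tolerance = 1e-6)
  expect_equal(peptideMass("PEPTIDE", fixed_mods = NULL), 799.35994,
               tolerance = 1e-6)
  # carbamidomethyl C applied as fixed modification by default
  expect_equal(peptideMass("C") - peptideMass("C", fixed_mods = NULL),
               57.02146, tolerance = 1e-9)
  expect_error(peptideMass(""), "empty")
  expect_error(peptideMass("PEBTIDE"), "B")
})

test_that("mass-index queries equal a brute-force linear scan", {
  db <- generateDecoys(tinyProteinDb())
  index <- buildMassIndex(db, length_range = c(2L, 60L))
  tab <- peptideTable(index)
  expect_false(is.unsorted(tab$mass))
  expect_equal(anyDuplicated(tab$sequence), 0L)

  # shared target/decoy peptides count as target
  expect_true(all(!tab$is_decoy[vapply(tab$parents, function(p)
    any(!startsWith(p, "Rev_")), TRUE)]))

  set.seed(42)
  queries <- c(runif(80, min(tab$mass), max(tab$mass)), tab$mass[1:10])
  for (q in queries) {
    for (tol in c(0.5, 5)) {
      got <- queryCandidates(index, q, tol, "Da")$sequence
      want <- tab$sequence[abs(tab$mass - q) <= tol]
      expect_setequal(got, want)
    }
    got_ppm <- queryCandidates(index, q, 20, "ppm")$sequence
    expect_setequal(got_ppm, tab$sequence[abs(tab$mass - q) <= q * 20e-6])
  }
  # containment and empty-window cases (K6 precedes P, so the tryptic
  # peptide from p1 runs through to the terminus)
  expect_true("AGKPEPTIDEK" %in%
    queryCandidates(index, peptideMass("AGKPEPTIDEK"), 0.5, "Da")$sequence)
  expect_equal(nrow(queryCandidates(index, 1e6, 0.5, "Da")), 0L)
})

test_that("larger random peptide sets agree between index and linear scan", {
  set.seed(7)
  aa <- names(psmEnsemble:::.RESIDUE_MASS)
  seqs <- unique(vapply(1:1000, function(i)
    paste(sample(aa, sample(6:20, 1), replace = TRUE), collapse = ""), ""))
  db <- newProteinDb(sprintf("x%04d", seq_along(seqs)), seqs)
  index <- buildMassIndex(db, max_missed = 3L, length_range = c(6L, 60L))
  tab <- peptideTable(index)
  qs <- runif(100, min(tab$mass) - 1, max(tab$mass) + 1)
  for (q in qs) {
    got <- sort(queryCandidates(index, q, 10, "ppm")$sequence)
    want <- sort(tab$sequence[abs(tab$mass - q) <= q * 1e-5])
    expect_identical(got, want)
  }
})
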
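test_that("theoretical b/y fragments match hand-computed values", {
  fr <- theoreticalFragments("PEPTIDE", precursor_charge = 2L,
                             fixed_mods = NULL)
  b2 <- fr$mz[fr$ion_type == "b" & fr$index == 2 & fr$charge == 1]
  y1 <- fr$mz[fr$ion_type == "y" & fr$index == 1 & fr$charge == 1]
  expect_equal(b2, 227.10262, tolerance = 1e-5)
  expect_equal(y1, 148.06043, tolerance = 1e-5)
  # 1+ only for 2+ precursors; 2+ fragments appear from 3+ precursors
  expect_setequal(unique(fr$charge), 1L)
  fr3 <- theoreticalFragments("PEPTIDE", precursor_charge = 3L)
  expect_setequal(unique(fr3$charge), c(1L, 2L))

  # b/y complementarity: b_i + y_(n-i) neutral masses sum to peptide mass
  n <- nchar("PEPTIDE")
  proton <- massConstants()[["proton"]]
  for (i in seq_len(n - 1)) {
    b <- fr$mz[fr$ion_type == "b" & fr$index == i] - proton
    y <- fr$mz[fr$ion_type == "y" & fr$index == n - i] - proton
    expect_equal(b + y, peptideMass("PEPTIDE", fixed_mods = NULL),
                 tolerance = 1e-9)
  }
  expect_error(theoreticalFragments("A"), "length")
})

test_that("MVH score equals exhaustive multivariate-hypergeometric enumeration", {
  # independent oracle: enumerate all draws of n bins out of N and count
  # the configurations with the observed per-class composition
  enum_mvh <- function(class_sizes, n_bins, x, x_empty) {
    labels <- c(rep(seq_along(class_sizes), class_sizes),
                rep(0L, n_bins - sum(class_sizes)))
    n_draw <- sum(x) + x_empty
    combos <- utils::combn(length(labels), n_draw)
    want <- c(x_empty, x)
    hits <- sum(apply(combos, 2, function(cols)
      identical(tabulate(labels[cols] + 1L, nbins = length(x) + 1L), want)))
    -log(hits / ncol(combos))
  }
  set.seed(21)
  n_checked <- 0
  while (n_checked < 20) {
    n_peaks <- sample(4:9, 1)
    mz <- sort(sample(seq(100, 100 + 19) + 0.3, n_peaks))
    sp <- newSpectrum("e", 600, 2L, mz = mz,
                      intensity = sample(10:99, n_peaks))
    classed <- preprocessMvh(sp)
    pep <- paste(sample(c("A", "G", "S", "P", "V", "K"), sample(3:5, 1),
                        replace = TRUE), collapse = "")
    frags <- theoreticalFragments(pep, 2L)
    got <- scoreMvh(classed, frags, tol = 0.5)
    m <- psmEnsemble:::.matchFragments(frags$mz, classed$mz, 0.5)
    x <- tabulate(classed$class[m[!is.na(m)]],
                  nbins = length(classed$class_sizes))
    n_bins <- max(classed$n_bins, length(classed$mz) + nrow(frags))
    if (n_bins > 22) next   # keep enumeration tractable
    want <- enum_mvh(classed$class_sizes, n_bins, x, sum(is.na(m)))
    expect_equal(got, want, tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
})

test_that("MVH rewards matches into rarer high-intensity classes", {
  # 10 retained peaks -> classes of sizes 1, 2, 7; peaks spread widely so
  # the candidate-bin universe dwarfs the peak count, as for real spectra
  sp <- newSpectrum("c", 900, 2L, mz = seq(100.3, by = 50, length.out = 10),
                    intensity = 10:1)
  classed <- preprocessMvh(sp)
  score_for <- function(target_mz) {
    frags <- data.frame(ion_type = "b", index = 1, charge = 1, mz = target_mz)
    scoreMvh(classed, frags, tol = 0.4)
  }
  s_class1 <- score_for(classed$mz[classed$class == 1L][1])
  s_class3 <- score_for(classed$mz[classed$class == 3L][1])
  s_none <- score_for(5000)
  expect_gt(s_class1, s_class3)
  expect_gt(s_class3, s_none)
  # zero matches equal the all-empty-bin draw probability
  n_bins <- classed$n_bins
  expect_equal(s_none, -(lchoose(n_bins - 10, 1) - lchoose(n_bins, 1)))
  expect_error(scoreMvh(classed, data.frame()[0, ]), "fragments")
})

test_that("fast Xcorr equals the naive shifted-dot-product definition", {
  set.seed(31)
  peptides <- vapply(1:20, function(i)
    paste(sample(names(psmEnsemble:::.RESIDUE_MASS), sample(6:12, 1),
                 replace = TRUE), collapse = ""), "")
  for (pep in peptides) {
    sp <- randomSpectrum(80, charge = 2L, mz_range = c(150, 1200))
    sp@precursorMz <- (peptideMass(pep) + 2 * massConstants()[["proton"]]) / 2
    arr <- preprocessXcorr(sp)
    frags <- theoreticalFragments(pep, 2L)
    got <- scoreXcorr(arr, frags)
    # naive: rebuild the binned/normalized vector independently, apply the
    # O(n * w) windowed-mean subtraction, and take the scaled dot product
    bins <- unique(as.integer(frags$mz / arr$bin_width + 1 - arr$bin_offset))
    bins <- bins[bins >= 1 & bins <= length(arr$y)]
    y <- rebinNormalized(sp, arr)
    got_naive <- sum(naiveXcorrTransform(y)[bins]) * 0.005
    expect_equal(got, got_naive, tolerance = 1e-6)
  }
})

test_that("Xcorr of an all-zero array is zero", {
  sp0 <- newSpectrum("z", 500, 2L, mz = numeric(0), intensity = numeric(0))
  arr <- preprocessXcorr(sp0)
  expect_equal(scoreXcorr(arr, theoreticalFragments("PEPTIDEK", 2L)), 0)
})

test_that("a planted spectrum outscores random same-mass peptides on Xcorr", {
  set.seed(41)
  aa <- names(psmEnsemble:::.RESIDUE_MASS)
  pep <- "GASPVLKTEIR"
  sp <- perfectSpectrum(pep, charge = 2L)
  arr <- preprocessXcorr(sp)
  s_true <- scoreXcorr(arr, theoreticalFragments(pep, 2L))
  perm_scores <- vapply(1:100, function(i) {
    perm <- paste(sample(strsplit(pep, "")[[1]]), collapse = "")
    scoreXcorr(arr, theoreticalFragments(perm, 2L))
  }, 0.0)
  expect_true(all(s_true >= perm_scores))
  expect_gt(s_true, stats::quantile(perm_scores, 0.99))
})

test_that("WDP follows its closed form and monotonicity", {
  pep <- "SAMPLEK"
  fr <- theoreticalFragments(pep, 2L)
  sp <- perfectSpectrum(pep, charge = 2L)
  n_peaks <- nrow(peaks(sp))
  # perfect match, equal intensities: sum of w * sqrt(1/n_peaks)
  expect_equal(scoreWdp(sp, fr), nrow(fr) * sqrt(1 / n_peaks),
               tolerance = 1e-9)
  # no matches -> 0
  far <- newSpectrum("f", 500, 2L, mz = c(3000, 3100), intensity = c(1, 1))
  expect_equal(scoreWdp(far, fr), 0)
  # halving one matched peak's intensity strictly decreases the score
  pk <- peaks(sp)
  pk[1, 2] <- pk[1, 2] / 2
  sp_half <- newSpectrum("h", precursorMz(sp), 2L, pk[, 1], pk[, 2])
  expect_lt(scoreWdp(sp_half, fr), scoreWdp(sp, fr))
  # direct-formula recomputation on a jittered spectrum
  set.seed(3)
  mz <- fr$mz + runif(nrow(fr), -0.3, 0.3)
  inten <- runif(nrow(fr), 1, 100)
  spj <- newSpectrum("j", precursorMz(sp), 2L, mz, inten)
  m <- psmEnsemble:::.matchFragments(fr$mz, peaks(spj)[, 1], 0.5)
  ok <- !is.na(m)
  want <- sum(sqrt(peaks(spj)[m[ok], 2] / sum(inten)) *
                (1 - abs(fr$mz[ok] - peaks(spj)[m[ok], 1]) / 0.5))
  expect_equal(scoreWdp(spj, fr), want, tolerance = 1e-12)
})

test_that("two-tier search recovers a planted peptide at rank 1 everywhere", {
  run <- cachedPipelineRun()
  db <- run$db; index <- run$index
  pep <- peptideTable(index)$sequence[
    !peptideTable(index)$is_decoy & nchar(peptideTable(index)$sequence) == 12][1]
  sp <- perfectSpectrum(pep, charge = 2L, scan = "planted")
  out <- ensembleSearch(list(sp), index)
  top <- out[out$sequence == pep, ]
  expect_equal(nrow(top), 1L)
  expect_equal(top$rank_mvh, 1L)
  expect_equal(top$rank_xcorr, 1L)
  expect_equal(top$rank_wdp, 1L)
  # no-candidate spectrum yields an empty result
  none <- newSpectrum("none", 9999, 2L, mz = c(100, 200), intensity = c(1, 1))
  expect_equal(nrow(ensembleSearch(list(none), index)), 0L)
})

test_that("search results are invariant to batch size and worker count", {
  run <- cachedPipelineRun()
  sp <- run$spectra[1:40]
  base <- ensembleSearch(sp, run$index, searchConfig(batch_size = 20000L))
  small <- ensembleSearch(sp, run$index, searchConfig(batch_size = 10L))
  par4 <- ensembleSearch(sp, run$index,
                         searchConfig(batch_size = 50L, n_workers = 4L))
  expect_equal(small, base)
  expect_equal(par4, base)
})

test_that("two-tier output equals exhaustive three-scorer scoring when <= 50 candidates", {
  run <- cachedPipelineRun()
  cfg <- searchConfig()
  checked <- 0L
  for (sp in run$spectra) {
    cand <- queryCandidates(run$index, precursorNeutralMass(sp),
                            cfg$precursor_tolerance, cfg$precursor_unit)
    if (nrow(cand) < 2L || nrow(cand) > 50L) next
    got <- ensembleSearch(list(sp), run$index, cfg)
    # exhaustive reference: every candidate scored by all three functions
    classed <- preprocessMvh(sp)
    arr <- preprocessXcorr(sp)
    frags <- lapply(cand$sequence, theoreticalFragments,
                    precursor_charge = precursorCharge(sp))
    mvh <- vapply(frags, function(f) scoreMvh(classed, f, 0.5), 0.0)
    xc <- vapply(frags, function(f) scoreXcorr(arr, f), 0.0)
    wd <- vapply(frags, function(f) scoreWdp(sp, f, 0.5), 0.0)
    ord <- function(s) order(-s, cand$sequence, cand$is_decoy)
    topk <- function(s) cand$sequence[ord(s)][seq_len(min(5L, nrow(cand)))]
    want_set <- sort(unique(c(topk(mvh), topk(xc), topk(wd))))
    expect_identical(sort(got$sequence), want_set)
    sel <- match(got$sequence, cand$sequence)
    expect_equal(got$mvh, mvh[sel], tolerance = 1e-12)
    expect_equal(got$xcorr, xc[sel], tolerance = 1e-12)
    expect_equal(got$wdp, wd[sel], tolerance = 1e-12)
    checked <- checked + 1L
    if (checked >= 25L) break
  }
  expect_gte(checked, 10L)
})
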
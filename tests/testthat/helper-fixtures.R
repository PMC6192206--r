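# Shared fixtures, built in code. The heavier synthetic runs used by the
# acceptance tests are cached per test session.

# tiny three-protein target database exercising tryptic edge cases
tinyProteinDb <- function() {
  newProteinDb(
    ids = c("p1", "p2", "p3"),
    sequences = c("MKRAGKPEPTIDEK", "AAKPAAGELVISK", "SAMPLERPEPTIDEK"),
    description = c("first", "second", "third")
  )
}

# a spectrum synthesized exactly from a peptide's b/y ions (no jitter)
perfectSpectrum <- function(sequence, charge = 2L, scan = "s1",
                            intensity = 100) {
  fr <- theoreticalFragments(sequence, precursor_charge = charge)
  newSpectrum(scan, .perfectPrecursorMz(sequence, charge), charge,
              mz = fr$mz, intensity = rep(intensity, nrow(fr)))
}

.perfectPrecursorMz <- function(sequence, charge) {
  peptideMass(sequence) / charge + massConstants()[["proton"]]
}

# naive windowed-mean background subtraction (independent of the cumsum
# fast path in preprocessXcorr)
naiveXcorrTransform <- function(y, w = 75L) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    y[i] - (sum(y[lo:hi]) - y[i]) / (2 * w)
  }, 0.0)
}

# independent re-binning + regional normalization (pre-subtraction stage),
# written with explicit loops rather than the package's vectorized path
rebinNormalized <- function(sp, arr) {
  pk <- peaks(sp)
  y <- numeric(length(arr$y))
  if (nrow(pk) == 0) return(y)
  bins <- as.integer(pk[, 1] / arr$bin_width + 1 - arr$bin_offset)
  for (i in seq_len(nrow(pk))) {
    b <- bins[i]
    if (b >= 1 && b <= length(y) && pk[i, 2] > 0)
      y[b] <- max(y[b], sqrt(pk[i, 2]))
  }
  hi <- max(bins[bins <= length(y)])
  rs <- ceiling(hi / 10)
  for (r in 1:10) {
    idx <- which(pmin((seq_along(y) - 1) %/% rs + 1, 10) == r & y > 0)
    if (length(idx)) y[idx] <- y[idx] / max(y[idx]) * 50
  }
  y
}

# random peaked spectrum for property tests
randomSpectrum <- function(n_peaks, scan = "r1", charge = 2L,
                           mz_range = c(150, 1800)) {
  mz <- sort(runif(n_peaks, mz_range[1], mz_range[2]))
  newSpectrum(scan, 700, charge, mz = mz,
              intensity = rlnorm(n_peaks, 5, 1))
}

# one full-pipeline synthetic run, cached so several tests can share it
.pipeline_cache <- new.env(parent = emptyenv())

cachedPipelineRun <- function(seed = 7L, n_spectra = 300L, n_proteins = 300L) {
  key <- paste0("run_", seed, "_", n_spectra, "_", n_proteins)
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  ds <- generateDataset(
    syntheticConfig(seed = seed, n_spectra = n_spectra,
                    n_proteins = n_proteins),
    dir = file.path(tempdir(), paste0("pipe_", key)))
  db <- generateDecoys(readFasta(ds$fasta))
  index <- buildMassIndex(db)
  spectra <- readMgf(ds$mgf)
  psms <- ensembleSearch(spectra, index)
  res <- suppressWarnings(suppressMessages(runFilter(psms, db, index)))
  out <- list(ds = ds, db = db, index = index, spectra = spectra,
              psms = psms, res = res)
  .pipeline_cache[[key]] <- out
  out
}
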
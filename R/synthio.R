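## Synthetic fixture generator: FASTA + MGF pairs with ground-truth labels
## emulating the metaproteomics regime of an incomplete database, where a
## substantial fraction of spectra come from peptides absent from the
## searched database ("foreign" spectra).

#' Synthetic dataset configuration
#'
#' Defaults emulate a soil-like metaproteomics regime at desk scale: 500
#' proteins of 100-400 residues, 1000 spectra of which 30% are foreign
#' (their true peptide is not in the database), 20 uniform noise peaks per
#' spectrum, Gaussian fragment m/z jitter with sigma 0.05 Da, and
#' log-normal fragment intensities. Foreign peptides are independent random
#' tryptic-like sequences, length-matched to the database pool and
#' rejection-sampled until their mass lands within `foreign_mass_tol` of a
#' database peptide mass, so they fall into real precursor search windows
#' as hard negatives while staying uncorrelated with any particular
#' database peptide; junk matches then split evenhandedly between targets
#' and decoys, as for real out-of-database spectra.
#'
#' @param n_proteins number of target proteins.
#' @param protein_length_range integer two-vector of protein lengths.
#' @param n_spectra number of MS2 spectra.
#' @param fraction_foreign fraction of spectra from non-database peptides.
#' @param noise_peaks_per_spectrum number of uniform noise peaks.
#' @param fragment_mz_jitter Gaussian sigma on fragment m/z, in Da.
#' @param intensity_meanlog,intensity_sdlog log-normal fragment intensity
#'   parameters.
#' @param kr_frequency per-residue frequency of each of K and R (controls
#'   tryptic site density).
#' @param peptide_length_range lengths of peptides selected to generate
#'   spectra.
#' @param distinct_fraction fraction of in-database spectra drawing a new
#'   distinct peptide (the remainder re-sample already-used peptides,
#'   giving multi-spectrum peptides).
#' @param charges precursor charge states sampled uniformly.
#' @param foreign_mass_tol mass window (Da) within which a foreign peptide
#'   must match some database peptide mass.
#' @param seed integer seed; identical seeds give identical outputs.
#' @return Named list (class `SyntheticConfig`).
#' @export
syntheticConfig <- function(n_proteins = 500L,
                            protein_length_range = c(100L, 400L),
                            n_spectra = 1000L,
                            fraction_foreign = 0.3,
                            noise_peaks_per_spectrum = 20L,
                            fragment_mz_jitter = 0.05,
                            intensity_meanlog = 7, intensity_sdlog = 0.6,
                            kr_frequency = 0.055,
                            peptide_length_range = c(8L, 25L),
                            distinct_fraction = 0.7,
                            charges = c(2L, 3L),
                            foreign_mass_tol = 0.05,
                            seed = 1L) {
  if (fraction_foreign < 0 || fraction_foreign > 1)
    stop("fraction_foreign must lie in [0, 1]")
  if (n_proteins < 1L || n_spectra < 0L || noise_peaks_per_spectrum < 0L)
    stop("counts must be non-negative (and n_proteins >= 1)")
  structure(as.list(environment()), class = "SyntheticConfig")
}

## random protein sequences with boosted K/R frequency
.randomProteins <- function(n, length_range, kr_freq) {
  aa <- names(.RESIDUE_MASS)
  p <- rep((1 - 2 * kr_freq) / 18, 20)
  names(p) <- aa
  p[c("K", "R")] <- kr_freq
  lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(aa, L, replace = TRUE, prob = p), collapse = ""), "")
}

## random tryptic-like peptide (C-terminal K/R) whose mass lands within
## `tol` of some database peptide mass, so its spectrum falls into real
## precursor search windows; rejection-sampled. Independence from any
## particular database peptide keeps junk matches unbiased between targets
## and decoys, as for real out-of-database spectra.
.randomForeignPeptide <- function(length_range, kr_freq, db_masses, tol,
                                  forbidden, max_tries = 500L) {
  aa <- names(.RESIDUE_MASS)
  p <- rep((1 - 2 * kr_freq) / 18, 20)
  names(p) <- aa
  p[c("K", "R")] <- kr_freq
  n_mass <- length(db_masses)
  for (k in seq_len(max_tries)) {
    L <- sample(length_range[1L]:length_range[2L], 1L)
    cand <- paste(c(sample(aa, L - 1L, replace = TRUE, prob = p),
                    sample(c("K", "R"), 1L)), collapse = "")
    m <- peptideMass(cand)
    j <- findInterval(m, db_masses)
    d <- min(abs(m - db_masses[max(j, 1L)]),
             abs(m - db_masses[min(j + 1L, n_mass)]))
    if (d <= tol && !(cand %in% forbidden)) return(cand)
  }
  NA_character_
}

## synthesize one spectrum's peak list from a peptide
.synthesizeSpectrum <- function(sequence, charge, cfg) {
  fr <- theoreticalFragments(sequence, precursor_charge = charge,
                             fixed_mods = defaultFixedMods())
  mz <- fr$mz + rnorm(nrow(fr), 0, cfg$fragment_mz_jitter)
  inten <- rlnorm(nrow(fr), cfg$intensity_meanlog, cfg$intensity_sdlog)
  n_noise <- cfg$noise_peaks_per_spectrum
  if (n_noise > 0L) {
    noise_mz <- runif(n_noise, 100, max(fr$mz) + 50)
    noise_in <- rlnorm(n_noise, cfg$intensity_meanlog - 1, cfg$intensity_sdlog)
    mz <- c(mz, noise_mz)
    inten <- c(inten, noise_in)
  }
  keep <- mz > 0
  list(mz = mz[keep], intensity = inten[keep])
}

#' Generate a synthetic FASTA + MGF dataset with ground truth
#'
#' Draws random proteins, digests them with the default tryptic rule,
#' samples database peptides for the in-database spectra and mass-matched
#' random foreign peptides for the rest,
#' and synthesizes centroided b/y spectra with log-normal intensities,
#' Gaussian m/z jitter and uniform noise peaks. Writes standard FASTA and
#' MGF files plus a truth table mapping every scan to its true peptide
#' (`origin = "database"` or `"foreign"`).
#'
#' @param config a [syntheticConfig()].
#' @param dir output directory (created if needed).
#' @param basename file stem for the three outputs.
#' @return List with paths `fasta`, `mgf`, `truth`, the `truth`
#'   `data.frame` (`scan`, `peptide`, `origin`, `source_protein`, `charge`)
#'   and the target [ProteinDb-class].
#' @export
generateDataset <- function(config = syntheticConfig(), dir = tempfile("synth"),
                            basename = "synthetic") {
  cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  seqs <- .randomProteins(cfg$n_proteins, cfg$protein_length_range,
                          cfg$kr_frequency)
  ids <- sprintf("prot%04d", seq_len(cfg$n_proteins))
  db <- newProteinDb(ids, seqs)
  ## peptide pool: tryptic peptides in the spectral length range
  occ <- .digestDb(db, max_missed = 1L,
                   length_range = cfg$peptide_length_range)
  if (!nrow(occ)) stop("no tryptic peptides in the configured length range")
  pool <- occ[!duplicated(occ$sequence), ]
  db_pep_set <- unique(occ$sequence)
  n_foreign <- round(cfg$n_spectra * cfg$fraction_foreign)
  n_indb <- cfg$n_spectra - n_foreign
  n_distinct <- max(1L, ceiling(n_indb * cfg$distinct_fraction))
  if (n_indb > 0L && n_distinct > nrow(pool))
    stop("config demands ", n_distinct, " distinct peptides but the database yields only ",
         nrow(pool))
  truth <- NULL
  if (n_indb > 0L) {
    chosen <- sample(nrow(pool), n_distinct)
    draw <- c(chosen, sample(chosen, n_indb - n_distinct, replace = TRUE))
    draw <- sample(draw)  # interleave repeats
    truth <- data.frame(
      peptide = pool$sequence[draw],
      origin = "database",
      source_protein = pool$protein[draw]
    )
  }
  if (n_foreign > 0L) {
    ## anchor foreign masses on the searched (target + reversed-decoy)
    ## peptide space so junk matches are unbiased between the two species
    decoy_db <- newProteinDb(paste0("d", ids),
                             as.character(Biostrings::reverse(db@sequences)))
    occ_d <- .digestDb(decoy_db, max_missed = 1L,
                       length_range = cfg$peptide_length_range)
    db_masses <- sort(peptideMass(unique(c(pool$sequence, occ_d$sequence))))
    forbidden <- unique(c(db_pep_set, occ_d$sequence))
    foreign <- vapply(seq_len(n_foreign), function(i)
      .randomForeignPeptide(cfg$peptide_length_range, cfg$kr_frequency,
                            db_masses, cfg$foreign_mass_tol, forbidden), "")
    ok <- !is.na(foreign)
    truth <- rbind(truth, data.frame(
      peptide = foreign[ok],
      origin = "foreign",
      source_protein = NA_character_
    ))
  }
  if (is.null(truth))
    truth <- data.frame(peptide = character(), origin = character(),
                        source_protein = character())
  truth <- truth[sample(nrow(truth)), , drop = FALSE]
  truth$scan <- sprintf("scan%05d", seq_len(nrow(truth)))
  truth$charge <- sample(cfg$charges, nrow(truth), replace = TRUE)
  rownames(truth) <- NULL
  truth <- truth[, c("scan", "peptide", "origin", "source_protein", "charge")]
  ## synthesize and write MGF
  mgf_path <- file.path(dir, paste0(basename, ".mgf"))
  con <- file(mgf_path, "w")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(truth))) {
    pk <- .synthesizeSpectrum(truth$peptide[i], truth$charge[i], cfg)
    o <- order(pk$mz)
    mass <- peptideMass(truth$peptide[i])
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", truth$scan[i]),
      sprintf("PEPMASS=%.6f", .massToMz(mass, truth$charge[i])),
      sprintf("CHARGE=%d+", truth$charge[i]),
      sprintf("%.5f %.2f", pk$mz[o], pk$intensity[o]),
      "END IONS"
    ), con)
  }
  fasta_path <- file.path(dir, paste0(basename, ".fasta"))
  writeFastaDb(db, fasta_path)
  truth_path <- file.path(dir, paste0(basename, "_truth.tsv"))
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta_path, mgf = mgf_path, truth_path = truth_path,
       truth = truth, db = db)
}

#' Evaluate accepted PSMs against the ground truth
#'
#' True FDR is the fraction of accepted PSMs whose peptide differs from the
#' truth table's peptide for that scan; recall is the number of correctly
#' accepted PSMs divided by the number of in-database spectra. Only target
#' PSMs count as identifications: rows flagged decoy (if an `is_decoy`
#' column is present) serve the FDR bookkeeping and are dropped before
#' evaluation.
#'
#' @param accepted accepted PSM table with `scan` and `sequence` columns.
#' @param truth truth `data.frame` from [generateDataset()].
#' @return List with `true_fdr`, `recall`, `n_accepted`, `n_correct`,
#'   `n_in_database`, and `empty` flag.
#' @export
evaluateAgainstTruth <- function(accepted, truth) {
  n_indb <- sum(truth$origin == "database")
  if ("is_decoy" %in% names(accepted))
    accepted <- accepted[!accepted$is_decoy, , drop = FALSE]
  if (nrow(accepted) == 0L)
    return(list(true_fdr = 0, recall = 0, n_accepted = 0L, n_correct = 0L,
                n_in_database = n_indb, empty = TRUE))
  m <- match(accepted$scan, truth$scan)
  if (anyNA(m))
    stop("accepted PSMs contain scan ids absent from the truth table: ",
         paste(head(accepted$scan[is.na(m)]), collapse = ", "))
  correct <- accepted$sequence == truth$peptide[m]
  list(true_fdr = mean(!correct),
       recall = sum(correct) / n_indb,
       n_accepted = nrow(accepted),
       n_correct = sum(correct),
       n_in_database = n_indb,
       empty = FALSE)
}
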
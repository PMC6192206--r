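## Sequence-database side of the search engine: FASTA in, reversed decoys,
## tryptic digestion, monoisotopic masses, precursor-window candidate lookup.

#' Read a protein FASTA file
#'
#' The identifier of each entry is the first whitespace-delimited token of
#' the header line; the remainder is kept as the description. Sequences are
#' uppercased and trailing stop characters (`*`) stripped.
#'
#' @param path path to a FASTA file.
#' @param decoy_prefix identifier prefix that flags an entry as a reversed
#'   decoy (default `"Rev_"`). Entries already carrying the prefix are
#'   loaded as decoys, so databases with pre-generated decoys round-trip.
#' @return A [ProteinDb-class].
#' @export
readFasta <- function(path, decoy_prefix = "Rev_") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("FASTA file contains no records: ", path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("\\*", "", as.character(aa)))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("FASTA record with empty sequence: ", paste(ids[empty], collapse = ", "))
  is_decoy <- startsWith(ids, decoy_prefix)
  newProteinDb(ids, seqs, description = desc, is_decoy = is_decoy,
               decoy_prefix = decoy_prefix)
}

#' Construct a ProteinDb from vectors
#'
#' @param ids,sequences,description parallel character vectors.
#' @param is_decoy logical decoy flags.
#' @param decoy_split split assignment; defaults to `"not_applicable"` for
#'   targets and is only meaningful for decoys.
#' @param decoy_prefix decoy identifier prefix.
#' @return A [ProteinDb-class].
#' @export
newProteinDb <- function(ids, sequences, description = rep("", length(ids)),
                         is_decoy = rep(FALSE, length(ids)),
                         decoy_split = ifelse(is_decoy, "train", "not_applicable"),
                         decoy_prefix = "Rev_") {
  aa <- Biostrings::AAStringSet(sequences)
  names(aa) <- ids
  new("ProteinDb", sequences = aa, description = description,
      isDecoy = is_decoy, decoySplit = decoy_split, decoyPrefix = decoy_prefix)
}

#' Append reversed-sequence decoys to a target database
#'
#' One decoy per target, made by reversing the full protein sequence; the
#' decoy identifier is the target identifier with `prefix` prepended.
#' Reversal is an involution, so reversing a decoy recovers its target.
#'
#' @param db [ProteinDb-class] of target proteins.
#' @param prefix decoy identifier prefix (must not collide with any target
#'   identifier).
#' @return A [ProteinDb-class] with `2 *` the input entries.
#' @export
generateDecoys <- function(db, prefix = db@decoyPrefix) {
  stopifnot(is(db, "ProteinDb"))
  if (any(db@isDecoy)) stop("database already contains decoys")
  ids <- names(db@sequences)
  if (any(startsWith(ids, prefix)))
    stop("target identifiers collide with decoy prefix '", prefix, "'")
  rev_seqs <- as.character(Biostrings::reverse(db@sequences))
  newProteinDb(
    ids = c(ids, paste0(prefix, ids)),
    sequences = c(as.character(db@sequences), rev_seqs),
    description = c(db@description, rep("reversed decoy", length(ids))),
    is_decoy = c(rep(FALSE, length(ids)), rep(TRUE, length(ids))),
    decoy_split = c(rep("not_applicable", length(ids)), rep("train", length(ids))),
    decoy_prefix = prefix
  )
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, plus any fixed
#' modification deltas. Vectorized over sequences.
#'
#' @param sequence character vector of peptide sequences (uppercase,
#'   standard residues).
#' @param fixed_mods named numeric vector of per-residue mass deltas in Da
#'   (default: carbamidomethyl C).
#' @return Neutral monoisotopic mass(es) in Da.
#' @export
peptideMass <- function(sequence, fixed_mods = defaultFixedMods()) {
  if (any(!nzchar(sequence))) stop("empty peptide sequence")
  tbl <- .RESIDUE_MASS
  if (length(fixed_mods)) {
    bad <- setdiff(names(fixed_mods), names(tbl))
    if (length(bad)) stop("fixed modification on unknown residue: ",
                          paste(bad, collapse = ", "))
    tbl[names(fixed_mods)] <- tbl[names(fixed_mods)] + fixed_mods
  }
  chars <- strsplit(sequence, "", fixed = TRUE)
  all_ch <- unlist(chars, use.names = FALSE)
  m <- tbl[all_ch]
  if (anyNA(m)) {
    bad <- unique(all_ch[is.na(m)])
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  }
  lens <- lengths(chars)
  as.numeric(rowsum(m, rep.int(seq_along(sequence), lens))) + .WATER_MASS
}

## 0-based cleavage cut points for trypsin (after K/R, not before P),
## excluding the protein termini.
.trypticSites <- function(sequence) {
  hits <- gregexpr("[KR](?!P)", sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' In-silico tryptic digestion of one protein
#'
#' Fully tryptic peptides (cleavage C-terminal to K/R except before P) with
#' up to `max_missed` internal missed cleavage sites, filtered to the given
#' length range. Peptides at the protein termini are included; a protein
#' with no cleavage site yields itself (length permitting).
#'
#' @param sequence protein sequence (single string).
#' @param max_missed maximum internal missed cleavage sites (default 3).
#' @param length_range integer two-vector `c(min, max)` peptide length
#'   (default `c(6, 60)`).
#' @return `data.frame` with columns `sequence` and `missed_cleavages`.
#' @export
digestProtein <- function(sequence, max_missed = 3L, length_range = c(6L, 60L)) {
  cuts <- .trypticSites(sequence)
  n <- nchar(sequence)
  bounds <- c(0L, cuts[cuts < n], n)        # segment boundaries
  nseg <- length(bounds) - 1L
  out_seq <- character(0)
  out_mc <- integer(0)
  for (i in seq_len(nseg)) {
    jmax <- min(nseg, i + max_missed)
    for (j in i:jmax) {
      len <- bounds[j + 1L] - bounds[i]
      if (len < length_range[1L]) next
      if (len > length_range[2L]) break
      out_seq <- c(out_seq, substr(sequence, bounds[i] + 1L, bounds[j + 1L]))
      out_mc <- c(out_mc, j - i)
    }
  }
  data.frame(sequence = out_seq, missed_cleavages = out_mc)
}

## Digest every protein in a db; returns a data.table with one row per
## (protein, peptide) occurrence.
.digestDb <- function(db, max_missed = 3L, length_range = c(6L, 60L)) {
  seqs <- as.character(db@sequences)
  ids <- names(db@sequences)
  res <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    d <- digestProtein(seqs[k], max_missed, length_range)
    if (nrow(d)) {
      d$protein <- ids[k]
      d$protein_decoy <- db@isDecoy[k]
      res[[k]] <- d
    }
  }
  data.table::rbindlist(res)
}

#' Digest a database and build the precursor-mass index
#'
#' Digests every protein, computes monoisotopic peptide masses, merges
#' duplicate sequences (union of parent proteins; decoy only if all parents
#' are decoys) and sorts by mass.
#'
#' @param db a [ProteinDb-class] (targets plus decoys).
#' @param max_missed,length_range digestion parameters, see
#'   [digestProtein()].
#' @param fixed_mods fixed modifications, see [peptideMass()].
#' @return A [MassIndex-class].
#' @export
buildMassIndex <- function(db, max_missed = 3L, length_range = c(6L, 60L),
                           fixed_mods = defaultFixedMods()) {
  occ <- .digestDb(db, max_missed, length_range)
  if (!nrow(occ)) {
    return(new("MassIndex",
               peptides = data.frame(sequence = character(), mass = numeric(),
                                     missed_cleavages = integer(),
                                     is_decoy = logical(),
                                     parents = I(list())),
               fixedMods = fixed_mods))
  }
  sequence <- missed_cleavages <- protein_decoy <- NULL  # NSE
  pep <- occ[, list(missed_cleavages = missed_cleavages[1L],
                    is_decoy = all(protein_decoy),
                    parents = list(unique(protein))),
             by = sequence]
  pep$mass <- peptideMass(pep$sequence, fixed_mods)
  data.table::setorder(pep, mass, sequence)
  data.table::setcolorder(pep, c("sequence", "mass", "missed_cleavages",
                                 "is_decoy", "parents"))
  new("MassIndex", peptides = pep, fixedMods = fixed_mods)
}

#' Candidate peptides within a precursor mass window
#'
#' Binary search over the mass-sorted index; returns exactly the peptides
#' whose neutral mass lies within the tolerance of the query mass.
#'
#' @param index a [MassIndex-class].
#' @param neutral_mass precursor neutral mass (Da).
#' @param tolerance numeric tolerance value (> 0).
#' @param unit `"Da"` or `"ppm"`.
#' @return Subset of the peptide table (possibly zero rows).
#' @export
queryCandidates <- function(index, neutral_mass, tolerance, unit = c("Da", "ppm")) {
  stopifnot(is(index, "MassIndex"), tolerance > 0)
  unit <- match.arg(unit)
  tol <- if (unit == "ppm") neutral_mass * tolerance * 1e-6 else tolerance
  p <- index@peptides
  lo <- findInterval(neutral_mass - tol, p$mass, left.open = TRUE) + 1L
  hi <- findInterval(neutral_mass + tol, p$mass)
  if (hi < lo) p[0L, ] else p[lo:hi, ]
}
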
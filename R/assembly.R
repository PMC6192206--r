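## Assembly of accepted PSMs into peptide and protein-group
## identifications, with level-specific decoy-split FDR counts.

#' Assemble accepted PSMs into peptide identifications
#'
#' One record per distinct peptide sequence, pooling all charge states and
#' modification forms. A peptide is a decoy only if all of its parent
#' proteins are decoys.
#'
#' @param accepted accepted PSM table (rows of a feature/selection table).
#' @return `data.frame` with columns `sequence`, `spectrum_count`,
#'   `is_decoy`, `proteins`, `best_parent`, `decoy_split`, `scans`.
#' @export
assemblePeptides <- function(accepted) {
  if (nrow(accepted) == 0L) {
    return(data.frame(sequence = character(), spectrum_count = integer(),
                      is_decoy = logical(), proteins = character(),
                      best_parent = character(), decoy_split = character(),
                      scans = character()))
  }
  dt <- data.table::as.data.table(accepted)
  has_split <- "decoy_split" %in% names(dt)
  sequence <- NULL
  out <- dt[, list(
    spectrum_count = .N,
    is_decoy = is_decoy[1L],
    proteins = proteins[1L],
    best_parent = if ("best_parent" %in% names(dt)) best_parent[1L] else NA_character_,
    decoy_split = if (has_split) decoy_split[1L] else NA_character_,
    scans = paste(scan, collapse = ";")
  ), by = sequence]
  data.table::setorder(out, sequence)
  as.data.frame(out)
}

#' Infer protein groups from accepted peptides
#'
#' Proteins whose accepted-peptide sets are identical are aggregated into
#' one protein group ("indistinguishable" proteins). A peptide is unique if
#' it maps to exactly one group (`unique_scope = "group"`, the default) or
#' exactly one protein (`unique_scope = "protein"`). A group is identified
#' if it has at least `min_unique` unique accepted peptides. Subset
#' proteins are not subsumed: only exact peptide-set equality groups.
#'
#' @param peptides output of [assemblePeptides()].
#' @param index the [MassIndex-class] used for the search (provides the
#'   full peptide-to-protein map).
#' @param min_unique minimum unique peptides per group (default 1).
#' @param unique_scope `"group"` or `"protein"`.
#' @param decoy_prefix identifier prefix marking decoy proteins.
#' @return `data.frame` with one row per identified group: `group_id`,
#'   `members`, `n_members`, `peptides`, `unique_peptides`,
#'   `n_unique_peptides`, `spectrum_count`, `is_decoy`, `decoy_split`.
#' @export
inferProteins <- function(peptides, index, min_unique = 1L,
                          unique_scope = c("group", "protein"),
                          decoy_prefix = "Rev_") {
  unique_scope <- match.arg(unique_scope)
  empty <- data.frame(group_id = character(), members = character(),
                      n_members = integer(), peptides = character(),
                      unique_peptides = character(),
                      n_unique_peptides = integer(),
                      spectrum_count = integer(), is_decoy = logical(),
                      decoy_split = character())
  if (nrow(peptides) == 0L) return(empty)
  ptab <- peptideTable(index)
  parents <- ptab$parents[match(peptides$sequence, ptab$sequence)]
  ## protein -> accepted peptide sets
  long <- data.frame(
    protein = unlist(parents),
    sequence = rep(peptides$sequence, lengths(parents)),
    count = rep(peptides$spectrum_count, lengths(parents))
  )
  pepset <- vapply(split(long$sequence, long$protein),
                   function(s) paste(sort(unique(s)), collapse = ";"), "")
  groups <- split(names(pepset), pepset)
  group_of_protein <- setNames(rep(seq_along(groups), lengths(groups)),
                               unlist(groups))
  ## uniqueness of each accepted peptide
  n_owners <- vapply(parents, function(pr) {
    if (unique_scope == "protein") length(unique(pr))
    else length(unique(group_of_protein[pr]))
  }, 0L)
  is_unique <- n_owners == 1L
  rows <- lapply(seq_along(groups), function(g) {
    members <- sort(groups[[g]])
    seqs <- sort(unique(long$sequence[long$protein %in% members]))
    uniq <- seqs[seqs %in% peptides$sequence[is_unique] &
                   seqs %in% long$sequence[long$protein %in% members]]
    sel <- match(seqs, peptides$sequence)
    data.frame(
      group_id = paste(members, collapse = ";"),
      members = paste(members, collapse = ";"),
      n_members = length(members),
      peptides = paste(seqs, collapse = ";"),
      unique_peptides = paste(uniq, collapse = ";"),
      n_unique_peptides = length(uniq),
      spectrum_count = sum(peptides$spectrum_count[sel]),
      is_decoy = NA,
      decoy_split = NA_character_
    )
  })
  out <- do.call(rbind, rows)
  ## a group is decoy iff all member proteins are decoys (decoy identifiers
  ## carry the decoy prefix, a ProteinDb invariant)
  out$is_decoy <- vapply(strsplit(out$members, ";", fixed = TRUE),
                         function(m) all(startsWith(m, decoy_prefix)), TRUE)
  out <- out[out$n_unique_peptides >= min_unique, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attribute decoy identifications to the decoy split
#'
#' Assigns each decoy peptide or protein-group identification to the
#' train/test split of its representative decoy protein (for peptides, the
#' best parent; for groups, the first member), then applies the
#' decoy-split FDR estimator.
#'
#' @param ids peptide table from [assemblePeptides()] or group table from
#'   [inferProteins()].
#' @param db split [ProteinDb-class].
#' @param alpha realized test-split fraction.
#' @return An [estimateFdr()] record.
#' @export
levelFdrCounts <- function(ids, db, alpha) {
  if (nrow(ids) == 0L) return(estimateFdr(0L, 0L, alpha))
  split_map <- setNames(db@decoySplit, names(db@sequences))
  rep_protein <- if ("members" %in% names(ids)) {
    vapply(strsplit(ids$members, ";", fixed = TRUE), `[`, "", 1L)
  } else if ("best_parent" %in% names(ids) && !anyNA(ids$best_parent)) {
    ids$best_parent
  } else {
    vapply(strsplit(ids$proteins, ";", fixed = TRUE), `[`, "", 1L)
  }
  sp <- split_map[rep_protein]
  n_target <- sum(!ids$is_decoy)
  n_test_decoy <- sum(ids$is_decoy & !is.na(sp) & sp == "test")
  estimateFdr(n_target, n_test_decoy, alpha)
}
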
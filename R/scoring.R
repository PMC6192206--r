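## Theoretical b/y fragmentation and the three scoring functions (MVH,
## Xcorr, WDP), orchestrated as the two-tier ensemble search: all
## precursor-window candidates are scored by MVH, the MVH top-50 are
## rescored by Xcorr and WDP, and the union of the top-5 per scorer is
## reported.

#' Theoretical b/y fragment ions of a peptide
#'
#' Singly charged b and y ions are always generated; doubly charged
#' fragments are added for precursors of charge 3 or higher. For a peptide
#' of length n, ions are indexed 1..n-1 in each series.
#'
#' @param sequence peptide sequence (length >= 2).
#' @param precursor_charge precursor charge state.
#' @param fixed_mods fixed modifications, see [peptideMass()].
#' @return `data.frame` with columns `ion_type` ("b"/"y"), `index`,
#'   `charge`, `mz`.
#' @export
theoreticalFragments <- function(sequence, precursor_charge = 2L,
                                 fixed_mods = defaultFixedMods()) {
  n <- nchar(sequence)
  if (n < 2L) stop("peptide must have length >= 2")
  tbl <- .RESIDUE_MASS
  if (length(fixed_mods))
    tbl[names(fixed_mods)] <- tbl[names(fixed_mods)] + fixed_mods
  res <- tbl[strsplit(sequence, "", fixed = TRUE)[[1]]]
  if (anyNA(res)) stop("unknown residue in peptide ", sequence)
  b_neutral <- cumsum(res)[-n]                       # b_i, i = 1..n-1
  y_neutral <- rev(cumsum(rev(res))[-n]) + .WATER_MASS  # y_i indexed n-1..1
  idx <- seq_len(n - 1L)
  charges <- if (precursor_charge >= 3L) c(1L, 2L) else 1L
  out <- lapply(charges, function(z) {
    data.frame(
      ion_type = rep(c("b", "y"), each = n - 1L),
      index = c(idx, rev(idx)),
      charge = z,
      mz = c(b_neutral / z + .PROTON_MASS, y_neutral / z + .PROTON_MASS)
    )
  })
  do.call(rbind, out)
}

## Greedy fragment-to-peak matching: fragments in ascending m/z order each
## claim the nearest unclaimed peak within tolerance. Returns the peak index
## per fragment (NA if unmatched). Deterministic.
.matchFragments <- function(frag_mz, peak_mz, tol) {
  m <- rep(NA_integer_, length(frag_mz))
  if (!length(peak_mz)) return(m)
  claimed <- logical(length(peak_mz))
  ord <- order(frag_mz)
  for (f in ord) {
    d <- abs(peak_mz - frag_mz[f])
    d[claimed] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) {
      m[f] <- j
      claimed[j] <- TRUE
    }
  }
  m
}

#' Multivariate hypergeometric (MVH) score
#'
#' Each predicted fragment is matched to at most one retained peak within
#' the fragment tolerance. The score is the negative log probability of
#' drawing the observed per-class match counts (intensity classes 1..C plus
#' the empty-bin class) when drawing one bin per predicted fragment,
#' without replacement, from the candidate-bin universe:
#' \deqn{-\ln P = \ln\binom{N}{n} - \sum_k \ln\binom{K_k}{x_k}}
#' where N is the universe size, n the number of predicted fragments,
#' K_k the class occupancies (the empty class holding N minus the retained
#' peaks) and x_k the match counts. Higher is better; matches into more
#' intense classes are rarer and score higher.
#'
#' @param classed an `MvhClassedPeaks` from [preprocessMvh()].
#' @param fragments a fragment table from [theoreticalFragments()].
#' @param tol fragment match tolerance in Da (default 0.5).
#' @return Numeric score (>= 0 up to floating error).
#' @export
scoreMvh <- function(classed, fragments, tol = 0.5) {
  n_frag <- nrow(fragments)
  if (n_frag == 0L) stop("no predicted fragments to score")
  n_classes <- length(classed$class_sizes)
  t_total <- length(classed$mz)
  ## universe must be able to absorb all draws
  n_bins <- max(classed$n_bins, t_total + n_frag)
  m <- .matchFragments(fragments$mz, classed$mz, tol)
  x <- tabulate(classed$class[m[!is.na(m)]], nbins = n_classes)
  x_empty <- n_frag - sum(x)
  k_empty <- n_bins - t_total
  -(sum(lchoose(classed$class_sizes, x)) + lchoose(k_empty, x_empty) -
      lchoose(n_bins, n_frag))
}

#' Fast cross-correlation (Xcorr) score
#'
#' Scaled dot product of the unit-intensity binned theoretical spectrum
#' with the background-subtracted observed array from
#' [preprocessXcorr()]; equivalent to the cross-correlation at zero lag
#' minus the mean cross-correlation over the +/- 75-bin lag window.
#'
#' @param arr an `XcorrArray`.
#' @param fragments fragment table from [theoreticalFragments()].
#' @param scale final score scale factor (default 0.005).
#' @return Numeric score.
#' @export
scoreXcorr <- function(arr, fragments, scale = 0.005) {
  bins <- unique(.xcorrBin(fragments$mz, arr$bin_width, arr$bin_offset))
  bins <- bins[bins >= 1L & bins <= length(arr$y)]
  if (!length(bins)) return(0)
  sum(arr$y[bins]) * scale
}

#' Weighted dot product (WDP) score
#'
#' Sum over predicted fragments matched within the fragment tolerance of
#' `w_type * sqrt(I_obs / I_total) * (1 - |dmz| / tol)`, where `I_total` is
#' the spectrum's total ion intensity and `w_type` an ion-series weight
#' (b and y both 1 by default). Unmatched fragments contribute zero.
#'
#' @param spectrum a [Spectrum-class].
#' @param fragments fragment table from [theoreticalFragments()].
#' @param tol fragment match tolerance in Da (default 0.5).
#' @param weights named numeric ion-series weights.
#' @return Numeric score (>= 0).
#' @export
scoreWdp <- function(spectrum, fragments, tol = 0.5, weights = c(b = 1, y = 1)) {
  pk <- spectrum@peaks
  if (nrow(pk) == 0L) return(0)
  i_total <- sum(pk[, 2L])
  if (i_total <= 0) return(0)
  m <- .matchFragments(fragments$mz, pk[, 1L], tol)
  ok <- !is.na(m)
  if (!any(ok)) return(0)
  dmz <- abs(fragments$mz[ok] - pk[m[ok], 1L])
  sum(weights[fragments$ion_type[ok]] * sqrt(pk[m[ok], 2L] / i_total) *
        (1 - dmz / tol))
}

#' Default search configuration
#'
#' All tunables of the ensemble search with their defaults: precursor
#' tolerance 0.05 Da, fragment tolerance 0.5 Da for MVH/WDP (Xcorr uses its
#' own binning), trypsin digestion with up to 3 missed cleavages and
#' peptide length 6-60, carbamidomethyl C fixed, MVH with 3 intensity
#' classes, Comet-convention Xcorr constants, tier-2 depth 50 and output
#' depth 5, batches of 20000 PSMs.
#'
#' @param ... name = value overrides of any default; unknown names are an
#'   error.
#' @return Named list of configuration values.
#' @export
searchConfig <- function(...) {
  cfg <- list(
    precursor_tolerance = 0.05, precursor_unit = "Da",
    fragment_tolerance = 0.5,
    max_missed = 3L, length_range = c(6L, 60L),
    fixed_mods = defaultFixedMods(),
    decoy_prefix = "Rev_",
    assumed_charges = c(2L, 3L),
    mvh_classes = 3L,
    xcorr_bin_width = 1.0005079, xcorr_bin_offset = 0.4,
    xcorr_regions = 10L, xcorr_norm_max = 50, xcorr_halfwidth = 75L,
    xcorr_scale = 0.005,
    wdp_weights = c(b = 1, y = 1),
    tier2_depth = 50L, output_depth = 5L,
    batch_size = 20000L, n_workers = 1L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  modifyList(cfg, ov)
}

## deterministic candidate ordering: higher score, then lexicographically
## smaller peptide, then target before decoy
.scoreOrder <- function(score, sequence, is_decoy) {
  order(-score, sequence, is_decoy)
}

## Score one spectrum against its candidate table; returns the reported PSM
## rows (union of top-5 per scorer) or NULL.
.searchOneSpectrum <- function(spectrum, cand, cfg) {
  nc <- nrow(cand)
  if (nc == 0L) return(NULL)
  classed <- preprocessMvh(spectrum, n_classes = cfg$mvh_classes)
  frags <- lapply(cand$sequence, theoreticalFragments,
                  precursor_charge = spectrum@precursorCharge,
                  fixed_mods = cfg$fixed_mods)
  mvh <- vapply(frags, function(f) scoreMvh(classed, f, cfg$fragment_tolerance), 0.0)
  ord1 <- .scoreOrder(mvh, cand$sequence, cand$is_decoy)
  rank_mvh <- integer(nc)
  rank_mvh[ord1] <- seq_len(nc)
  tier2 <- ord1[seq_len(min(cfg$tier2_depth, nc))]
  arr <- preprocessXcorr(spectrum, cfg$xcorr_bin_width, cfg$xcorr_bin_offset,
                         cfg$xcorr_regions, cfg$xcorr_norm_max,
                         cfg$xcorr_halfwidth)
  xcorr <- vapply(frags[tier2], function(f) scoreXcorr(arr, f, cfg$xcorr_scale), 0.0)
  wdp <- vapply(frags[tier2], function(f)
    scoreWdp(spectrum, f, cfg$fragment_tolerance, cfg$wdp_weights), 0.0)
  n2 <- length(tier2)
  ord_x <- .scoreOrder(xcorr, cand$sequence[tier2], cand$is_decoy[tier2])
  ord_w <- .scoreOrder(wdp, cand$sequence[tier2], cand$is_decoy[tier2])
  rank_x <- integer(n2); rank_x[ord_x] <- seq_len(n2)
  rank_w <- integer(n2); rank_w[ord_w] <- seq_len(n2)
  depth <- min(cfg$output_depth, n2)
  keep2 <- sort(unique(c(seq_len(depth),              # top-5 MVH (tier2 is MVH-ordered)
                         ord_x[seq_len(depth)], ord_w[seq_len(depth)])))
  sel <- tier2[keep2]
  data.frame(
    scan = spectrum@scanId,
    charge = spectrum@precursorCharge,
    sequence = cand$sequence[sel],
    proteins = vapply(cand$parents[sel], paste, "", collapse = ";"),
    is_decoy = cand$is_decoy[sel],
    missed_cleavages = cand$missed_cleavages[sel],
    calc_mass = cand$mass[sel],
    meas_mass = precursorNeutralMass(spectrum),
    mvh = mvh[sel],
    xcorr = xcorr[keep2],
    wdp = wdp[keep2],
    rank_mvh = rank_mvh[sel],
    rank_xcorr = rank_x[keep2],
    rank_wdp = rank_w[keep2],
    row.names = NULL
  )
}

#' Two-tier ensemble search
#'
#' For every spectrum: peptide candidates are fetched from the precursor
#' mass window, all are scored by MVH, the top-50 candidates ranked by MVH
#' are rescored by Xcorr and WDP, and the union of the top-5 peptides per
#' scorer is reported with all three scores and per-scorer ranks (MVH rank
#' among all scored candidates, Xcorr/WDP ranks within the tier-2 set).
#' Spectra with no candidates yield no rows.
#'
#' When the input contains several assumed charge states of the same scan,
#' each is searched separately and the best row per (scan, peptide) by MVH
#' is kept.
#'
#' Work is partitioned into batches of approximately `batch_size` PSMs that
#' are processed independently (optionally on `n_workers` forked workers)
#' and merged in spectrum order, so results are invariant to batch size and
#' worker count.
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param index a [MassIndex-class].
#' @param config a [searchConfig()] list.
#' @return `data.frame` of reported PSMs, one row per (scan, peptide).
#' @export
ensembleSearch <- function(spectra, index, config = searchConfig()) {
  cfg <- config
  cand_list <- lapply(spectra, function(sp)
    queryCandidates(index, precursorNeutralMass(sp),
                    cfg$precursor_tolerance, cfg$precursor_unit))
  n_cand <- vapply(cand_list, nrow, 0L)
  ## batch spectra so each batch holds ~batch_size candidate scorings
  batch_id <- cumsum(n_cand)
  batch_id <- if (length(batch_id)) (batch_id - 1L) %/% max(cfg$batch_size, 1L) else integer(0)
  run_batch <- function(idx) {
    rows <- lapply(idx, function(i)
      .searchOneSpectrum(spectra[[i]], cand_list[[i]], cfg))
    data.table::rbindlist(rows)
  }
  batches <- split(seq_along(spectra), batch_id)
  res <- if (cfg$n_workers > 1L) {
    parallel::mclapply(batches, run_batch, mc.cores = cfg$n_workers)
  } else {
    lapply(batches, run_batch)
  }
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0L) {
    return(data.frame(scan = character(), charge = integer(),
                      sequence = character(), proteins = character(),
                      is_decoy = logical(), missed_cleavages = integer(),
                      calc_mass = numeric(), meas_mass = numeric(),
                      mvh = numeric(), xcorr = numeric(), wdp = numeric(),
                      rank_mvh = integer(), rank_xcorr = integer(),
                      rank_wdp = integer()))
  }
  ## merge assumed-charge duplicates: keep best MVH per (scan, peptide)
  data.table::setorder(out, scan, sequence, -mvh, -xcorr)
  out <- out[!duplicated(out[, c("scan", "sequence")]), ]
  data.table::setorder(out, scan, rank_mvh, sequence)
  as.data.frame(out)
}
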
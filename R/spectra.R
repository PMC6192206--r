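## MS2 spectra: MGF reading and the per-scorer preprocessed representations.
## The Xcorr path follows the binned fast-cross-correlation conventions of
## SEQUEST-family engines; the MVH path follows MyriMatch-style intensity
## classing.

#' Construct a Spectrum
#'
#' @param scan_id scan identifier.
#' @param precursor_mz precursor m/z in Th.
#' @param precursor_charge assumed positive charge.
#' @param mz,intensity parallel numeric peak vectors (any order; sorted by
#'   m/z on construction).
#' @return A [Spectrum-class].
#' @export
newSpectrum <- function(scan_id, precursor_mz, precursor_charge, mz, intensity) {
  o <- order(mz)
  pk <- cbind(mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o])
  new("Spectrum", scanId = as.character(scan_id),
      precursorMz = as.numeric(precursor_mz),
      precursorCharge = as.integer(precursor_charge), peaks = pk)
}

#' Read an MGF file
#'
#' One [Spectrum-class] per `BEGIN IONS`/`END IONS` block. `PEPMASS` is
#' required. When `CHARGE` is absent the block is expanded into one
#' spectrum per assumed charge state (default 2+ and 3+), matching common
#' engine behaviour for charge-undetermined precursors. Blocks with zero
#' peaks are retained (they simply score nothing).
#'
#' @param path path to an MGF file.
#' @param assumed_charges integer vector of charges to assume when a block
#'   has no `CHARGE` line.
#' @return List of [Spectrum-class] objects.
#' @export
readMgf <- function(path, assumed_charges = c(2L, 3L)) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end) || any(end < begin))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
  out <- vector("list", length(begin))
  for (b in seq_along(begin)) {
    block <- lines[(begin[b] + 1L):(end[b] - 1L)]
    block <- block[nzchar(block)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      paste0("index=", b)
    if (!"PEPMASS" %in% keys)
      stop("malformed MGF block ", b, ": missing PEPMASS")
    pepmass <- as.numeric(strsplit(vals[match("PEPMASS", keys)], "\\s+")[[1]][1])
    if (!is.finite(pepmass))
      stop("malformed MGF block ", b, ": unreadable PEPMASS")
    charges <- if ("CHARGE" %in% keys) {
      ch <- as.integer(gsub("[^0-9]", "", vals[match("CHARGE", keys)]))
      if (!is.finite(ch) || ch < 1L)
        stop("malformed MGF block ", b, ": unreadable CHARGE")
      ch
    } else as.integer(assumed_charges)
    pk_lines <- block[!is_kv]
    if (length(pk_lines)) {
      parts <- strsplit(trimws(pk_lines), "[ \t]+")
      mz <- as.numeric(vapply(parts, `[`, "", 1L))
      it <- as.numeric(vapply(parts, `[`, "", 2L))
      if (anyNA(mz) || anyNA(it))
        stop("malformed MGF block ", b, ": unreadable peak line")
    } else {
      mz <- numeric(0); it <- numeric(0)
    }
    out[[b]] <- lapply(charges, function(z)
      newSpectrum(title, pepmass, z, mz, it))
  }
  unlist(out, recursive = FALSE)
}

## --- Xcorr preprocessing ---------------------------------------------------

## Comet-style m/z binning: bin index for an m/z value.
.xcorrBin <- function(mz, bin_width, bin_offset) {
  as.integer(mz / bin_width + 1 - bin_offset)
}

#' Xcorr-preprocessed binned spectrum
#'
#' Prepares a spectrum for fast cross-correlation scoring: intensities are
#' square-rooted, peaks are accumulated into m/z bins (max per bin), the
#' binned range is split into `n_regions` regions each max-normalized to
#' `norm_max`, and the fast-Xcorr background subtraction is applied:
#' `y'[i] = y[i] - mean(y[i-w .. i+w] excluding i)` with the mean divisor
#' fixed at `2w` (zero-padded beyond the array), so that a dot product of a
#' theoretical spectrum with `y'` equals the full cross-correlation
#' `R(0) - mean(R(tau), |tau| <= w, tau != 0)`.
#'
#' @param spectrum a [Spectrum-class].
#' @param bin_width bin width in Da (default 1.0005079, the average spacing
#'   of peptide isotopic clusters).
#' @param bin_offset fractional bin offset (default 0.4).
#' @param n_regions number of normalization regions (default 10).
#' @param norm_max per-region maximum after normalization (default 50).
#' @param offset_halfwidth background window half-width in bins (default 75).
#' @return Object of class `XcorrArray`: list with the transformed vector
#'   `y` (index 1 = bin 1), and the binning constants.
#' @export
preprocessXcorr <- function(spectrum, bin_width = 1.0005079, bin_offset = 0.4,
                            n_regions = 10L, norm_max = 50,
                            offset_halfwidth = 75L) {
  pk <- spectrum@peaks
  ## array spans up to the precursor neutral mass + a margin, as fragment
  ## bins can slightly exceed the largest observed peak
  max_mz <- max(precursorNeutralMass(spectrum) + .PROTON_MASS,
                if (nrow(pk)) max(pk[, 1L]) else 0)
  nbins <- max(.xcorrBin(max_mz, bin_width, bin_offset) + offset_halfwidth + 1L,
               2L * offset_halfwidth + 2L)
  y <- numeric(nbins)
  if (nrow(pk) && any(pk[, 2L] > 0)) {
    bins <- .xcorrBin(pk[, 1L], bin_width, bin_offset)
    keep <- bins >= 1L & bins <= nbins & pk[, 2L] > 0
    bins <- bins[keep]
    inten <- sqrt(pk[keep, 2L])
    ## max intensity per bin
    if (length(bins)) {
      o <- order(bins, -inten)
      first <- !duplicated(bins[o])
      y[bins[o][first]] <- inten[o][first]
      ## regional max-normalization over the occupied range
      hi_bin <- max(bins)
      region_size <- ceiling(hi_bin / n_regions)
      reg <- pmin((seq_len(nbins) - 1L) %/% region_size + 1L, n_regions)
      for (r in seq_len(n_regions)) {
        idx <- which(reg == r & y > 0)
        if (length(idx)) y[idx] <- y[idx] / max(y[idx]) * norm_max
      }
    }
  }
  ## fast background subtraction via cumulative sums
  w <- offset_halfwidth
  cs <- cumsum(c(0, y))
  i <- seq_len(nbins)
  win_sum <- cs[pmin(i + w, nbins) + 1L] - cs[pmax(i - w, 1L)]
  yp <- y - (win_sum - y) / (2 * w)
  structure(list(y = yp, bin_width = bin_width, bin_offset = bin_offset,
                 offset_halfwidth = w),
            class = "XcorrArray")
}

## --- MVH preprocessing -----------------------------------------------------

#' Intensity-classed peaks for MVH scoring
#'
#' MyriMatch-style preparation for the multivariate hypergeometric score:
#' the spectrum is first peak-filtered (most intense peak per 1 Da window),
#' surviving peaks are sorted by descending intensity (ties broken by
#' ascending m/z) and partitioned into `n_classes` intensity classes whose
#' sizes follow the geometric proportion 1:2:4:... with the remainder
#' assigned to the last (weakest) class. The size of the candidate-bin
#' universe (total 1 Da bins in the scored m/z range) is recorded; bins not
#' occupied by a retained peak form the "empty" class from which unmatched
#' fragment predictions are drawn.
#'
#' @param spectrum a [Spectrum-class].
#' @param n_classes number of intensity classes (default 3).
#' @param window_da peak-filter window width in Da (default 1.0).
#' @return Object of class `MvhClassedPeaks`: list with `mz`, `class`
#'   (per retained peak), `class_sizes`, and `n_bins` (universe size).
#' @export
preprocessMvh <- function(spectrum, n_classes = 3L, window_da = 1.0) {
  pk <- spectrum@peaks
  pk <- pk[pk[, 2L] > 0, , drop = FALSE]
  if (nrow(pk) == 0L) {
    return(structure(list(mz = numeric(0), class = integer(0),
                          class_sizes = integer(n_classes), n_bins = 0L),
                     class = "MvhClassedPeaks"))
  }
  ## retain the most intense peak per window
  win <- floor(pk[, 1L] / window_da)
  o <- order(win, -pk[, 2L], pk[, 1L])
  keep <- o[!duplicated(win[o])]
  pk <- pk[sort(keep), , drop = FALSE]
  ## rank by descending intensity, ties by ascending m/z
  o <- order(-pk[, 2L], pk[, 1L])
  t_total <- nrow(pk)
  sizes <- .geometricClassSizes(t_total, n_classes)
  cls <- integer(t_total)
  cls[o] <- rep.int(seq_len(n_classes), sizes)
  n_bins <- as.integer(floor(max(pk[, 1L]) / window_da) -
                         floor(min(pk[, 1L]) / window_da) + 1L)
  structure(list(mz = pk[, 1L], class = cls, class_sizes = sizes,
                 n_bins = max(n_bins, t_total)),
            class = "MvhClassedPeaks")
}

## class sizes 1:2:4:..., unit = floor(T / (2^C - 1)) clamped to >= 1, the
## remainder going to the last class; degenerately small spectra fill
## classes in order.
.geometricClassSizes <- function(t_total, n_classes) {
  unit <- max(1L, t_total %/% (2L^n_classes - 1L))
  sizes <- integer(n_classes)
  remaining <- t_total
  for (k in seq_len(n_classes - 1L)) {
    sizes[k] <- min(unit * 2L^(k - 1L), remaining)
    remaining <- remaining - sizes[k]
  }
  sizes[n_classes] <- remaining
  sizes
}
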
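#' @import methods
NULL

#' Protein database with reversed decoys
#'
#' An S4 container for a target/decoy protein database. Sequences are held
#' as a [Biostrings::AAStringSet]; per-protein metadata (description, decoy
#' flag, decoy train/test split assignment) live in parallel slots.
#'
#' The decoy split assignment is `"not_applicable"` for every target protein
#' and, after [splitDecoyProteins()], `"train"` or `"test"` for each decoy.
#'
#' @slot sequences [Biostrings::AAStringSet] of protein sequences, named by
#'   protein identifier.
#' @slot description character vector of FASTA descriptions (may be empty
#'   strings).
#' @slot isDecoy logical vector, `TRUE` for reversed-decoy entries.
#' @slot decoySplit character vector in
#'   `c("train", "test", "not_applicable")`.
#' @slot decoyPrefix single string: the identifier prefix marking decoys.
#' @exportClass ProteinDb
setClass("ProteinDb",
  slots = c(
    sequences = "AAStringSet",
    description = "character",
    isDecoy = "logical",
    decoySplit = "character",
    decoyPrefix = "character"
  )
)

setValidity("ProteinDb", function(object) {
  n <- length(object@sequences)
  msgs <- character()
  if (length(object@description) != n || length(object@isDecoy) != n ||
      length(object@decoySplit) != n)
    msgs <- c(msgs, "metadata slots must parallel the sequence set")
  if (any(Biostrings::width(object@sequences) == 0))
    msgs <- c(msgs, "empty protein sequences are not allowed")
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    msgs <- c(msgs, "sequences must have unique identifiers")
  if (!all(object@decoySplit %in% c("train", "test", "not_applicable")))
    msgs <- c(msgs, "decoySplit must be train/test/not_applicable")
  if (any(!object@isDecoy & object@decoySplit != "not_applicable"))
    msgs <- c(msgs, "target proteins cannot carry a decoy split assignment")
  if (length(object@decoyPrefix) != 1L || !nzchar(object@decoyPrefix))
    msgs <- c(msgs, "decoyPrefix must be a non-empty string")
  if (any(object@isDecoy & !startsWith(names(object@sequences), object@decoyPrefix)))
    msgs <- c(msgs, "decoy identifiers must carry the decoy prefix")
  if (length(msgs)) msgs else TRUE
})

#' Precursor-mass peptide index
#'
#' Result of in-silico digestion of a [ProteinDb-class], sorted by neutral
#' monoisotopic peptide mass for fast precursor-window candidate lookup.
#' Duplicate peptide sequences arising from different proteins are merged
#' into a single candidate holding the union of parent proteins; a peptide
#' is flagged decoy only if *all* of its parents are decoys, so peptides
#' shared between targets and decoys count as target.
#'
#' @slot peptides a `data.table` with columns `sequence`, `mass` (neutral,
#'   Da, ascending), `missed_cleavages`, `is_decoy`, and list column
#'   `parents` (character vectors of protein identifiers).
#' @slot fixedMods named numeric vector of fixed modifications used for the
#'   mass computation.
#' @exportClass MassIndex
setClass("MassIndex",
  slots = c(peptides = "data.frame", fixedMods = "numeric")
)

setValidity("MassIndex", function(object) {
  p <- object@peptides
  need <- c("sequence", "mass", "missed_cleavages", "is_decoy", "parents")
  if (!all(need %in% names(p)))
    return(paste("peptides table must have columns:", paste(need, collapse = ", ")))
  if (is.unsorted(p$mass)) return("peptides must be sorted by mass")
  if (nrow(p) && any(p$mass <= 0)) return("peptide masses must be positive")
  if (anyDuplicated(p$sequence)) return("peptide sequences must be unique")
  TRUE
})

#' A single MS2 spectrum
#'
#' Centroided fragment spectrum of one selected precursor. Peaks are stored
#' as a two-column matrix (`mz`, `intensity`) sorted by m/z. The neutral
#' precursor mass is derived as `(precursor m/z - proton) * charge`.
#'
#' @slot scanId single string identifying the scan.
#' @slot precursorMz precursor m/z (Th).
#' @slot precursorCharge assumed positive charge state.
#' @slot peaks numeric matrix with columns `mz` and `intensity`.
#' @exportClass Spectrum
setClass("Spectrum",
  slots = c(
    scanId = "character",
    precursorMz = "numeric",
    precursorCharge = "integer",
    peaks = "matrix"
  )
)

setValidity("Spectrum", function(object) {
  pk <- object@peaks
  msgs <- character()
  if (ncol(pk) != 2L) msgs <- c(msgs, "peaks must be an (mz, intensity) matrix")
  if (nrow(pk)) {
    if (is.unsorted(pk[, 1L])) msgs <- c(msgs, "peaks must be sorted by m/z")
    if (any(!is.finite(pk)) || any(pk[, 2L] < 0))
      msgs <- c(msgs, "intensities must be finite and non-negative")
  }
  if (object@precursorCharge < 1L) msgs <- c(msgs, "charge must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Trained supervised PSM filter
#'
#' A binary classifier separating confident from spurious PSMs in the
#' 10-feature space (three scores, three score differentials, precursor
#' mass error, missed cleavages, peptide and protein spectrum counts).
#' Positive training data are unanimous target PSMs; negative training data
#' are decoy PSMs from the training split of reversed proteins. Features are
#' standardized with training-set means and standard deviations before
#' fitting.
#'
#' @slot modelKind one of `"logistic_regression"`, `"random_forest"`,
#'   `"adaboost"`.
#' @slot fit fitted model object (class depends on `modelKind`).
#' @slot featureNames character vector of features used (constant features
#'   are dropped at training time).
#' @slot center,scale named numeric standardization constants.
#' @slot alpha realized fraction of decoy proteins assigned to the test
#'   split, used in FDR estimation.
#' @exportClass TrainedPsmFilter
setClass("TrainedPsmFilter",
  slots = c(
    modelKind = "character",
    fit = "ANY",
    featureNames = "character",
    center = "numeric",
    scale = "numeric",
    alpha = "numeric"
  )
)

setValidity("TrainedPsmFilter", function(object) {
  msgs <- character()
  if (!object@modelKind %in% c("logistic_regression", "random_forest", "adaboost"))
    msgs <- c(msgs, "unknown modelKind")
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    msgs <- c(msgs, "alpha must lie in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ProteinDb", function(object) {
  n <- length(object@sequences)
  nd <- sum(object@isDecoy)
  cat(sprintf("ProteinDb: %d proteins (%d targets, %d decoys, prefix '%s')\n",
              n, n - nd, nd, object@decoyPrefix))
  if (nd && any(object@decoySplit != "not_applicable"))
    cat(sprintf("  decoy split: %d train / %d test\n",
                sum(object@decoySplit == "train"),
                sum(object@decoySplit == "test")))
})

setMethod("show", "MassIndex", function(object) {
  p <- object@peptides
  cat(sprintf("MassIndex: %d peptides (%d decoy-only), mass %.2f-%.2f Da\n",
              nrow(p), sum(p$is_decoy),
              if (nrow(p)) min(p$mass) else NA_real_,
              if (nrow(p)) max(p$mass) else NA_real_))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum %s: precursor %.4f Th (%d+), %d peaks\n",
              object@scanId, object@precursorMz, object@precursorCharge,
              nrow(object@peaks)))
})

setMethod("show", "TrainedPsmFilter", function(object) {
  cat(sprintf("TrainedPsmFilter: %s on %d features (test-split alpha %.3f)\n",
              object@modelKind, length(object@featureNames), object@alpha))
})

#' Accessors for core containers
#'
#' @param x a [ProteinDb-class], [MassIndex-class] or [Spectrum-class].
#' @return `isDecoy` returns the logical decoy flags; `decoySplit` the
#'   per-protein split assignment; `peptideTable` the peptide candidate
#'   table of a [MassIndex-class]; `peaks` the peak matrix; `scanId`,
#'   `precursorMz`, `precursorCharge` the corresponding spectrum fields;
#'   `precursorNeutralMass` the derived neutral mass in Da.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("isDecoy", function(x) standardGeneric("isDecoy"))
#' @rdname accessors
#' @export
setMethod("isDecoy", "ProteinDb", function(x) setNames(x@isDecoy, names(x@sequences)))

#' @rdname accessors
#' @export
setGeneric("decoySplit", function(x) standardGeneric("decoySplit"))
#' @rdname accessors
#' @export
setMethod("decoySplit", "ProteinDb", function(x) setNames(x@decoySplit, names(x@sequences)))

#' @rdname accessors
#' @export
setGeneric("peptideTable", function(x) standardGeneric("peptideTable"))
#' @rdname accessors
#' @export
setMethod("peptideTable", "MassIndex", function(x) x@peptides)

#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname accessors
#' @export
setMethod("peaks", "Spectrum", function(x) x@peaks)

#' @rdname accessors
#' @export
setGeneric("scanId", function(x) standardGeneric("scanId"))
#' @rdname accessors
#' @export
setMethod("scanId", "Spectrum", function(x) x@scanId)

#' @rdname accessors
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))
#' @rdname accessors
#' @export
setMethod("precursorMz", "Spectrum", function(x) x@precursorMz)

#' @rdname accessors
#' @export
setGeneric("precursorCharge", function(x) standardGeneric("precursorCharge"))
#' @rdname accessors
#' @export
setMethod("precursorCharge", "Spectrum", function(x) x@precursorCharge)

#' @rdname accessors
#' @export
setGeneric("precursorNeutralMass", function(x) standardGeneric("precursorNeutralMass"))
#' @rdname accessors
#' @export
setMethod("precursorNeutralMass", "Spectrum", function(x)
  .mzToMass(x@precursorMz, x@precursorCharge))
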
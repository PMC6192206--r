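## Monoisotopic residue masses and physical constants used throughout.
## Residue masses are the standard amino-acid residue (not free amino acid)
## monoisotopic masses; I and L are distinct entries with identical mass.

#' @importFrom methods new validObject is slot
#' @importFrom stats predict quantile rbinom rlnorm rnorm runif sd setNames
#' @importFrom utils head modifyList
NULL

## data.table syntax is used inside this package
.datatable.aware <- TRUE

.PROTON_MASS <- 1.00727646677
.WATER_MASS <- 18.0105646863

.RESIDUE_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Default fixed modifications
#'
#' Carbamidomethylation of cysteine (+57.02146 Da) is applied as the sole
#' fixed modification by default, the near-universal setting for
#' iodoacetamide-alkylated samples. Variable modifications are out of scope
#' for this version; the `fixed_mods` argument of the relevant functions is
#' the configuration hook.
#'
#' @return Named numeric vector of residue mass deltas in Da.
#' @export
defaultFixedMods <- function() c(C = 57.02146)

#' Proton and water monoisotopic masses
#'
#' Constants used for m/z to neutral-mass conversion and peptide mass
#' computation.
#' @return A named numeric vector with elements `proton` and `water` (Da).
#' @export
massConstants <- function() c(proton = .PROTON_MASS, water = .WATER_MASS)

## m/z of an ion of given neutral mass and positive charge
.massToMz <- function(neutral_mass, charge) neutral_mass / charge + .PROTON_MASS

## neutral mass from observed m/z and charge
.mzToMass <- function(mz, charge) (mz - .PROTON_MASS) * charge
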
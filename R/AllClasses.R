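#' @include hrfp-package.R
NULL

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA3 <- setNames(names(AA1), AA1)
VALID_CODES <- c(unname(AA1), "X")

#' ProteinStructure: atomic coordinates for SASA and annotation
#'
#' Holds the non-hydrogen, non-water, non-hetero atoms of a single model of a
#' protein structure. The `atoms` slot is a data.frame with columns `chain`,
#' `resno` (1-based residue sequence number), `code` (one-letter amino-acid
#' code, `"X"` for nonstandard), `name` (atom name, e.g. `"CA"`), `element`,
#' `x`, `y`, `z` (angstrom), and `occ`.
#'
#' @slot atoms data.frame of atoms as described above.
#' @seealso [readStructure()], [makeFixtureStructure()], [shrakeRupley()]
#' @export
setClass("ProteinStructure", representation(atoms = "data.frame"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "code", "name", "element", "x", "y", "z", "occ")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0) return("structure contains no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (any(a$resno < 1)) return("residue numbers must be >= 1")
  if (!all(a$code %in% VALID_CODES))
    return("residue codes must be one-letter amino-acid codes or 'X'")
  TRUE
})

#' @describeIn ProteinStructure number of atoms
#' @param x,object a `ProteinStructure`
#' @export
setMethod("length", "ProteinStructure", function(x) nrow(x@atoms))

setMethod("show", "ProteinStructure", function(object) {
  sq <- residueSequence(object)
  cat("ProteinStructure:", nrow(object@atoms), "atoms,",
      nrow(sq), "residues,",
      length(unique(sq$chain)), "chain(s)",
      paste0("[", paste(unique(sq$chain), collapse = ","), "]"), "\n")
})

#' Atom table of a structure
#' @param x a `ProteinStructure`
#' @return data.frame of atoms (see [ProteinStructure-class]).
#' @export
atoms <- function(x) {
  stopifnot(is(x, "ProteinStructure"))
  x@atoms
}

#' Per-chain ordered residue list of a structure
#' @param x a `ProteinStructure`
#' @param chain optional chain label to restrict to.
#' @return data.frame with columns `chain`, `resno`, `code`, ordered by
#'   chain then residue number.
#' @export
residueSequence <- function(x, chain = NULL) {
  a <- atoms(x)
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  key <- !duplicated(paste(a$chain, a$resno))
  out <- a[key, c("chain", "resno", "code")]
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' RateConstant: a fitted pseudo-first-order oxidation rate
#'
#' Result of fitting the dose-response of the unmodified fraction,
#' Y = Y0 * exp(-k t), for one oxidized species at one site.
#'
#' @slot k first-order rate constant in 1/s (>= 0).
#' @slot y0 fitted amplitude, the unmodified fraction at t = 0; in (0, 1.05].
#' @slot sdK standard deviation of `k` from the fit covariance (NA if the
#'   fit sat on a boundary).
#' @slot nPoints number of data points in the pooled fit.
#' @slot nReplicates number of replicates pooled.
#' @slot rss residual sum of squares.
#' @seealso [fitFirstOrder()]
#' @export
setClass("RateConstant",
         representation(k = "numeric", y0 = "numeric", sdK = "numeric",
                        nPoints = "integer", nReplicates = "integer",
                        rss = "numeric"))

setValidity("RateConstant", function(object) {
  if (object@k < 0) return("k must be >= 0")
  if (object@y0 <= 0 || object@y0 > 1.05) return("y0 must be in (0, 1.05]")
  if (!is.na(object@sdK) && object@sdK < 0) return("sdK must be >= 0")
  TRUE
})

setMethod("show", "RateConstant", function(object) {
  cat(sprintf("RateConstant: k = %.4g /s (sd %.3g), Y0 = %.3f, %d points, %d replicate(s)\n",
              object@k, object@sdK, object@y0, object@nPoints,
              object@nReplicates))
})

#' Rate constant accessors
#' @param x a [RateConstant-class]
#' @return `rateK` the rate in 1/s; `rateSd` its standard deviation; `rateY0`
#'   the fitted amplitude.
#' @export
rateK <- function(x) { stopifnot(is(x, "RateConstant")); x@k }

#' @rdname rateK
#' @export
rateSd <- function(x) { stopifnot(is(x, "RateConstant")); x@sdK }

#' @rdname rateK
#' @export
rateY0 <- function(x) { stopifnot(is(x, "RateConstant")); x@y0 }

#' CalibrationModel: linear ln PF versus fSASA relation
#'
#' Ordinary least squares model `lnPF = intercept + slope * fSASA` fitted on a
#' reference (free) state, together with the Pearson correlation of the pairs.
#' For footprinting data the slope is negative: protection rises as solvent
#' exposure falls.
#'
#' @slot slope regression slope (b).
#' @slot intercept regression intercept (a).
#' @slot r Pearson correlation coefficient of the (fSASA, lnPF) pairs.
#' @slot n number of points.
#' @slot sigma residual standard error.
#' @seealso [calibrate()], [predictBoundFsasa()]
#' @export
setClass("CalibrationModel",
         representation(slope = "numeric", intercept = "numeric",
                        r = "numeric", n = "integer", sigma = "numeric"))

setValidity("CalibrationModel", function(object) {
  if (object@n < 3) return("calibration needs at least 3 points")
  if (abs(object@r) > 1 + 1e-12) return("|R| must be <= 1")
  TRUE
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: lnPF = %.4f %+.4f * fSASA  (Pearson R = %.3f, n = %d, sigma = %.3f)\n",
              object@intercept, object@slope, object@r, object@n,
              object@sigma))
})

#' Calibration model accessors
#' @param x a [CalibrationModel-class]
#' @return `calSlope`/`calIntercept` the line parameters; `pearsonR` the
#'   correlation coefficient; `calN` the number of points.
#' @export
calSlope <- function(x) { stopifnot(is(x, "CalibrationModel")); x@slope }

#' @rdname calSlope
#' @export
calIntercept <- function(x) { stopifnot(is(x, "CalibrationModel")); x@intercept }

#' @rdname calSlope
#' @export
pearsonR <- function(x) { stopifnot(is(x, "CalibrationModel")); x@r }

#' @rdname calSlope
#' @export
calN <- function(x) { stopifnot(is(x, "CalibrationModel")); x@n }

#' PotencyEstimate: four-parameter logistic dose-response fit
#'
#' @slot pec50 -log10(EC50 in M).
#' @slot emax fitted top minus bottom (response amplitude).
#' @slot hill Hill slope.
#' @slot bottom,top fitted asymptotes.
#' @slot se named numeric of standard errors (`pec50`, `emax`, `hill`).
#' @slot extrapolated TRUE if the fitted EC50 lies outside the tested
#'   concentration range.
#' @seealso [fitDoseResponse()]
#' @export
setClass("PotencyEstimate",
         representation(pec50 = "numeric", emax = "numeric", hill = "numeric",
                        bottom = "numeric", top = "numeric", se = "numeric",
                        extrapolated = "logical"))

setValidity("PotencyEstimate", function(object) {
  if (!is.finite(object@emax)) return("Emax must be finite")
  TRUE
})

setMethod("show", "PotencyEstimate", function(object) {
  cat(sprintf("PotencyEstimate: pEC50 = %.2f (EC50 = %.3g M), Emax = %.3g, Hill = %.2f%s\n",
              object@pec50, 10^(-object@pec50), object@emax, object@hill,
              if (object@extrapolated) " [EC50 outside tested range]" else ""))
})

#' Potency accessors
#' @param x a [PotencyEstimate-class]
#' @return `pEC50` the -log10 molar potency; `eMax` the response amplitude;
#'   `hillSlope` the Hill coefficient.
#' @export
pEC50 <- function(x) { stopifnot(is(x, "PotencyEstimate")); x@pec50 }

#' @rdname pEC50
#' @export
eMax <- function(x) { stopifnot(is(x, "PotencyEstimate")); x@emax }

#' @rdname pEC50
#' @export
hillSlope <- function(x) { stopifnot(is(x, "PotencyEstimate")); x@hill }
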
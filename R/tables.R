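#' @include AllClasses.R
NULL

extdataPath <- function(file) {
  p <- system.file("extdata", file, package = "hrfp")
  if (!nzchar(p)) {
    # during development (pkgload) inst/ may not be installed yet
    p <- system.file("inst", "extdata", file, package = "hrfp")
  }
  if (!nzchar(p)) stop("bundled table not found: ", file)
  p
}

#' Load a residue intrinsic-reactivity table
#'
#' Intrinsic reactivities quantify the propensity of each amino-acid side
#' chain for hydroxyl-radical oxidation and are used to normalise measured
#' oxidation rates into protection factors (PF = sum(R_i) / k). Residues
#' absent from the table are treated as non-oxidizable.
#'
#' The bundled `"default"` table is derived from published radiolysis
#' second-order rate constants of free amino-acid side chains, rescaled to a
#' relative scale commensurate with per-second footprinting rates. Because
#' protection factors are homogeneous of degree 1 in the reactivity scale,
#' the calibration slope and Pearson R are invariant to the overall scale of
#' this table; it is configuration, not a constant of the method.
#'
#' @param source `"default"` for the bundled table, or a path to a CSV/TSV
#'   file with columns `residue` (one-letter code) and `reactivity` (> 0).
#' @return named numeric vector of reactivities keyed by one-letter residue
#'   code, with a `"provenance"` attribute.
#' @examples
#' r <- loadReactivityTable()
#' r[["W"]]
#' @export
loadReactivityTable <- function(source = "default") {
  if (identical(source, "default")) {
    path <- extdataPath("reactivity_default.csv")
    prov <- "bundled default (radiolysis rate-constant scale)"
  } else {
    path <- source
    prov <- source
  }
  tab <- readTable(path, schema = tableSchema(
    required = c(residue = "character", reactivity = "numeric")))
  if (any(duplicated(tab$residue)))
    stop("duplicate residue entries in reactivity table")
  if (any(tab$reactivity <= 0))
    stop("reactivity values must be > 0 (non-oxidizable residues are omitted, not zeroed)")
  bad <- setdiff(tab$residue, VALID_CODES)
  if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  out <- setNames(tab$reactivity, tab$residue)
  attr(out, "provenance") <- prov
  out
}

#' Load a residue reference-SASA table
#'
#' Residue-specific maximum (standard-state) accessible surface areas used to
#' normalise observed SASA into fractional SASA. The bundled table carries a
#' `total` column (theoretical maximum ASA of residue X in an extended
#' Gly-X-Gly context) and a `side_chain` column (side-chain atoms only, the
#' default used for footprinting since backbone atoms are not oxidation
#' targets). Glycine has no side-chain reference.
#'
#' @param source `"default"` or a path to a CSV/TSV with columns `residue`
#'   and either `side_chain`/`total` or a single `sasa_ref` column.
#' @param mode `"side_chain"` (default) or `"total"`.
#' @return named numeric vector of reference areas in square angstrom.
#' @export
loadSasaRefTable <- function(source = "default",
                             mode = c("side_chain", "total")) {
  mode <- match.arg(mode)
  path <- if (identical(source, "default")) extdataPath("sasa_ref_default.csv") else source
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"residue" %in% names(raw)) stop("reference-SASA table needs a 'residue' column")
  col <- if (mode %in% names(raw)) mode else if ("sasa_ref" %in% names(raw)) "sasa_ref"
  else stop("reference-SASA table needs a '", mode, "' or 'sasa_ref' column")
  vals <- as.numeric(raw[[col]])
  keep <- !is.na(vals)
  if (any(vals[keep] <= 0)) stop("reference areas must be > 0")
  setNames(vals[keep], raw$residue[keep])
}

#' Load a van der Waals radius table
#'
#' Element radii (angstrom) for SASA computation. The probe radius is a
#' separate argument of [shrakeRupley()] (default 1.4, a water molecule).
#'
#' @param source `"default"` or path to a CSV/TSV with columns `element`,
#'   `radius`.
#' @return named numeric vector of radii keyed by element symbol.
#' @export
loadRadiusTable <- function(source = "default") {
  path <- if (identical(source, "default")) extdataPath("vdw_radii_default.csv") else source
  tab <- readTable(path, schema = tableSchema(
    required = c(element = "character", radius = "numeric")))
  if (any(tab$radius <= 0)) stop("radii must be > 0")
  setNames(tab$radius, toupper(tab$element))
}

# monoisotopic residue masses (Da); fixed physical constants, not config
MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
WATER_MASS <- 18.010565
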
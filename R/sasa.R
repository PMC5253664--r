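#' @include AllClasses.R
NULL

# deterministic quasi-uniform golden-spiral lattice on the unit sphere
sphereLattice <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * (pi * (3 - sqrt(5)))  # golden angle
  cbind(r * cos(phi), r * sin(phi), z)
}

# canonical pose: principal axes of the atom cloud with deterministic
# orientation, so that any rigid transform of the input maps to (numerically)
# identical coordinates and hence identical lattice occlusion counts
canonicalFrame <- function(xyz) {
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  if (nrow(xc) < 2) return(xc)
  e <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  v <- e$vectors
  proj <- xc %*% v
  for (j in 1:2) {
    s <- sum(proj[, j]^3)
    if (abs(s) < 1e-9) s <- sum(proj[, j] * abs(proj[, j]))
    if (s < 0) v[, j] <- -v[, j]
  }
  v[, 3] <- crossprodVec(v[, 1], v[, 2])  # right-handed frame
  xc %*% v
}

crossprodVec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA: each atom's van der Waals sphere is expanded by the probe
#' radius and sampled with a deterministic golden-spiral point lattice; the
#' accessible area is the expanded-sphere area times the fraction of test
#' points not buried inside any neighbouring expanded sphere.
#'
#' With `frame = "canonical"` (default) coordinates are first moved to a
#' deterministic principal-axes pose, which makes the result invariant to
#' rigid rotation/translation of the input to near machine precision. With
#' `frame = "input"` the lattice is fixed in the input frame, which makes
#' occlusion strictly monotone under atom addition.
#'
#' @param structure a [ProteinStructure-class].
#' @param radii named element radius vector, see [loadRadiusTable()].
#' @param probe probe radius in angstrom (default 1.4, water).
#' @param nPoints test points per atom (>= 92; default 960).
#' @param frame `"canonical"` or `"input"` (see above).
#' @return numeric vector of per-atom SASA in square angstrom, one per row of
#'   `atoms(structure)`.
#' @examples
#' s <- makeFixtureStructure("helix", 10, seed = 1)
#' sum(shrakeRupley(s))
#' @export
shrakeRupley <- function(structure, radii = loadRadiusTable(), probe = 1.4,
                         nPoints = 960, frame = c("canonical", "input")) {
  frame <- match.arg(frame)
  stopifnot(nPoints >= 92, probe >= 0)
  a <- atoms(structure)
  unknown <- setdiff(unique(a$element), names(radii))
  if (length(unknown))
    stop("unknown element(s) not in radius table: ",
         paste(unknown, collapse = ", "))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (frame == "canonical" && nrow(xyz) > 2) xyz <- canonicalFrame(xyz)
  rExp <- unname(radii[a$element]) + probe
  lat <- sphereLattice(nPoints)
  n <- nrow(xyz)
  out <- numeric(n)
  # neighbour search on squared distances
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rExp + rExp[i])^2 & seq_len(n) != i)
    if (!length(nb)) {
      out[i] <- 4 * pi * rExp[i]^2
      next
    }
    pts <- sweep(lat * rExp[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(free)) break
      dj <- (pts[free, 1] - xyz[j, 1])^2 + (pts[free, 2] - xyz[j, 2])^2 +
        (pts[free, 3] - xyz[j, 3])^2
      free[free] <- dj >= rExp[j]^2
    }
    out[i] <- 4 * pi * rExp[i]^2 * sum(free) / nPoints
  }
  out
}

#' Per-residue SASA
#'
#' Sums atomic SASA over each residue. The default counts side-chain atoms
#' only (backbone N, CA, C, O and OXT excluded), since backbone atoms are not
#' hydroxyl-radical oxidation targets and the protection calibration uses
#' fractional side-chain accessibility.
#'
#' @inheritParams shrakeRupley
#' @param sideChainOnly exclude backbone atoms (default TRUE).
#' @return data.frame with `chain`, `resno`, `code`, `sasa`.
#' @export
perResidueSasa <- function(structure, radii = loadRadiusTable(), probe = 1.4,
                           nPoints = 960, sideChainOnly = TRUE,
                           frame = c("canonical", "input")) {
  frame <- match.arg(frame)
  a <- atoms(structure)
  atomSasa <- shrakeRupley(structure, radii, probe, nPoints, frame)
  if (sideChainOnly)
    atomSasa[a$name %in% c("N", "CA", "C", "O", "OXT")] <- 0
  key <- paste(a$chain, a$resno, sep = ":")
  agg <- tapply(atomSasa, key, sum)
  sq <- residueSequence(structure)
  sq$sasa <- as.numeric(agg[paste(sq$chain, sq$resno, sep = ":")])
  sq$sasa[is.na(sq$sasa)] <- 0
  sq
}

#' Reactivity-weighted SASA of a peptide or multi-residue site
#'
#' When an oxidation rate is measured at peptide (or two-residue) resolution,
#' the SASA entering the calibration is a weighted mean over the oxidizable
#' residues, with weights proportional to intrinsic reactivity
#' (w_i = R_i / sum(R_j)): the measured rate is dominated by the most
#' reactive side chains. A single-residue input returns its SASA unchanged.
#'
#' @param sasa numeric vector of per-residue SASA values.
#' @param codes one-letter residue codes matching `sasa`.
#' @param reactivities named reactivity vector.
#' @param uniform use uniform weights over oxidizable residues instead of
#'   reactivity weights (alternative weighting behind a switch).
#' @return weighted SASA (square angstrom).
#' @examples
#' weightedPeptideSasa(c(100, 50), c("W", "Y"), c(W = 10, Y = 10)) # 75
#' @export
weightedPeptideSasa <- function(sasa, codes, reactivities, uniform = FALSE) {
  stopifnot(length(sasa) == length(codes))
  ok <- codes %in% names(reactivities)
  if (!any(ok)) stop("undefined weighting: no oxidizable residue in peptide")
  w <- if (uniform) as.numeric(ok) else
    ifelse(ok, unname(reactivities[codes]), 0)
  sum(w * sasa) / sum(w)
}

#' Fractional SASA of a site
#'
#' fSASA is the ratio of the observed (reactivity-weighted) SASA to the
#' residue-specific standard reference area, with the same weights in the
#' numerator and denominator:
#' fSASA = sum(w_i SASA_i) / sum(w_i SASA_REF_i). Values above 1 are
#' physically possible for extended conformations and are flagged, not
#' rejected.
#'
#' @param sasa per-residue SASA values of the site's residues.
#' @param codes one-letter residue codes matching `sasa`.
#' @param sasaRef named reference-area vector, see [loadSasaRefTable()].
#' @param reactivities named reactivity vector (weights).
#' @param uniform see [weightedPeptideSasa()].
#' @return list with `fsasa`, `sasa_w`, `sasa_ref_w`, `flagged`
#'   (TRUE if fSASA > 1).
#' @examples
#' fractionalSasa(50, "W", c(W = 200), c(W = 10))$fsasa # 0.25
#' @export
fractionalSasa <- function(sasa, codes, sasaRef, reactivities,
                           uniform = FALSE) {
  ok <- codes %in% names(reactivities)
  if (!any(ok)) stop("undefined weighting: no oxidizable residue")
  missing <- setdiff(codes[ok], names(sasaRef))
  if (length(missing))
    stop("no reference area for residue(s): ", paste(missing, collapse = ", "))
  w <- if (uniform) as.numeric(ok) else ifelse(ok, unname(reactivities[codes]), 0)
  sw <- sum(w * sasa) / sum(w)
  refw <- sum(w * ifelse(ok, unname(sasaRef[codes]), 0)) / sum(w)
  f <- sw / refw
  list(fsasa = f, sasa_w = sw, sasa_ref_w = refw, flagged = f > 1)
}

#' Site-level accessibility table for a protection table
#'
#' Computes per-residue SASA of a structure once, then the weighted fSASA of
#' every site of a protection (or rate) table, joining on the site's chain
#' and residue numbers.
#'
#' @param sites data.frame with `site` and `residues` columns (e.g. from
#'   [protectionTable()]).
#' @param structure a [ProteinStructure-class].
#' @param sasaRef named reference-area vector.
#' @param reactivities named reactivity vector.
#' @param ... passed to [perResidueSasa()].
#' @return data.frame `site`, `residues`, `sasa_w`, `sasa_ref_w`, `fsasa`,
#'   `flagged`.
#' @export
siteAccessibility <- function(sites, structure, sasaRef, reactivities, ...) {
  prs <- perResidueSasa(structure, ...)
  ps <- parseSite(sites$site)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    sel <- prs$chain == ps$chain[i] & prs$resno %in% ps$resno[[i]]
    if (!any(sel))
      stop("site not present in structure: ", sites$site[i])
    fr <- fractionalSasa(prs$sasa[sel], prs$code[sel], sasaRef, reactivities)
    data.frame(site = sites$site[i],
               residues = paste(prs$code[sel], collapse = ""),
               sasa_w = fr$sasa_w, sasa_ref_w = fr$sasa_ref_w,
               fsasa = fr$fsasa, flagged = fr$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
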
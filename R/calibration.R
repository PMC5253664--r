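#' @include AllClasses.R
NULL

#' Calibrate the ln PF versus fSASA relation
#'
#' Ordinary least squares of log protection factor on fractional SASA over a
#' reference (free) state, with the Pearson correlation coefficient of the
#' pairs. For footprinting data the correlation is negative: buried residues
#' oxidize slowly and carry high protection factors.
#'
#' @param fsasa fractional SASA values (predictor).
#' @param lnPf natural-log protection factors (response), same length.
#' @param inverse regress fSASA on lnPF instead and report the line in
#'   (intercept, slope) form of lnPF on fSASA by algebraic inversion
#'   (inverse-regression alternative).
#' @return a [CalibrationModel-class].
#' @examples
#' f <- c(0.1, 0.4, 0.9)
#' m <- calibrate(f, 5 - 4 * f)  # exact line: a = 5, b = -4, R = -1
#' @export
calibrate <- function(fsasa, lnPf, inverse = FALSE) {
  stopifnot(length(fsasa) == length(lnPf))
  keep <- is.finite(fsasa) & is.finite(lnPf)
  fsasa <- fsasa[keep]; lnPf <- lnPf[keep]
  if (length(fsasa) < 3) stop("calibration needs at least 3 pairs")
  if (stats::sd(fsasa) == 0)
    stop("rank deficiency: fSASA values are all identical")
  if (inverse) {
    fit <- stats::lm(fsasa ~ lnPf)
    b <- 1 / unname(coef(fit)[2])
    a <- -unname(coef(fit)[1]) * b
    sig <- suppressWarnings(summary(fit)$sigma) * abs(b)
  } else {
    fit <- stats::lm(lnPf ~ fsasa)
    a <- unname(coef(fit)[1])
    b <- unname(coef(fit)[2])
    sig <- suppressWarnings(summary(fit)$sigma)
  }
  r <- stats::cor(fsasa, lnPf)
  new("CalibrationModel", slope = b, intercept = a, r = r,
      n = length(fsasa), sigma = sig)
}

#' Predict bound-state fractional SASA from ln PF
#'
#' Inverts the calibration line: fSASA = (lnPF - a) / b. Because fractional
#' accessibility is physically bounded, predictions are clamped to \[0, 1\]
#' by default with the raw value retained alongside.
#'
#' @param lnPf vector of bound-state log protection factors.
#' @param model a [CalibrationModel-class].
#' @param clip clamp predictions to \[0, 1\] (default TRUE).
#' @param sasaRefW optional vector of weighted reference areas (same length
#'   or length 1); when given, predicted absolute SASA is also returned.
#' @return data.frame with `ln_pf`, `fsasa_raw`, `fsasa`, `clipped`, and
#'   `sasa_pred` when `sasaRefW` is supplied.
#' @export
predictBoundFsasa <- function(lnPf, model, clip = TRUE, sasaRefW = NULL) {
  stopifnot(is(model, "CalibrationModel"))
  if (calSlope(model) == 0) stop("non-invertible calibration: slope is zero")
  raw <- (lnPf - calIntercept(model)) / calSlope(model)
  f <- if (clip) pmin(pmax(raw, 0), 1) else raw
  out <- data.frame(ln_pf = lnPf, fsasa_raw = raw, fsasa = f,
                    clipped = clip & (raw < 0 | raw > 1))
  if (!is.null(sasaRefW)) out$sasa_pred <- f * sasaRefW
  out
}

#' Ligand-induced burial change per site
#'
#' Joins free-state accessibility with predicted bound-state accessibility by
#' site key and reports delta = fSASA_free - fSASA_bound, ranked from the
#' largest burial change down. Unmatched sites on either side raise an error
#' listing the orphans.
#'
#' @param free data.frame with `site` and `fsasa` (free state).
#' @param bound data.frame with `site` and `fsasa` (predicted bound state).
#' @return data.frame `site`, `fsasa_free`, `fsasa_bound`, `delta`, `rank`,
#'   ordered by decreasing `delta`.
#' @export
deltaAccessibility <- function(free, bound) {
  orphansFree <- setdiff(free$site, bound$site)
  orphansBound <- setdiff(bound$site, free$site)
  if (length(orphansFree) || length(orphansBound))
    stop("join error, unmatched site(s): ",
         paste(c(orphansFree, orphansBound), collapse = ", "))
  m <- merge(free[, c("site", "fsasa")], bound[, c("site", "fsasa")],
             by = "site", suffixes = c("_free", "_bound"))
  m$delta <- m$fsasa_free - m$fsasa_bound
  m <- m[order(-m$delta), , drop = FALSE]
  m$rank <- seq_len(nrow(m))
  names(m)[names(m) == "fsasa_free"] <- "fsasa_free"
  rownames(m) <- NULL
  m
}
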
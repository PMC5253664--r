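#' @include AllClasses.R
NULL

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits y = bottom + (top - bottom) / (1 + 10^((log10 EC50 - log10 x) * h))
#' to ligand concentration versus response (e.g. BRET ratio) data by bounded
#' nonlinear least squares. Emax is reported as top - bottom (the response
#' difference between zero and saturating ligand) and potency as
#' pEC50 = -log10(EC50 in M). Zero-dose wells anchor the bottom asymptote:
#' they are included as pseudo-concentration points three log-units below the
#' lowest tested dose (a fit-stability device, since log 0 is undefined).
#'
#' @param conc molar ligand concentrations (0 allowed for baseline wells).
#' @param response responses matching `conc`.
#' @param hillBounds bounds for the free Hill slope (default \[0.3, 5\]).
#' @return a [PotencyEstimate-class]. If the fitted EC50 lies outside the
#'   tested concentration range an extrapolation warning is raised and the
#'   estimate is flagged.
#' @examples
#' x <- 10^seq(-10, -6.5, by = 0.5)
#' y <- 1 / (1 + 10^((log10(8.5e-9) - log10(x))))
#' pEC50(fitDoseResponse(x, y))  # ~8.07
#' @export
fitDoseResponse <- function(conc, response, hillBounds = c(0.3, 5)) {
  stopifnot(length(conc) == length(response), all(conc >= 0))
  pos <- conc > 0
  if (length(unique(conc[pos])) < 4)
    stop("need at least 4 distinct positive concentrations")
  lx <- log10(conc)
  lx[!pos] <- min(log10(conc[pos])) - 3
  dat <- data.frame(lx = lx, y = response)
  rng <- range(response)
  if (diff(rng) <= 0) {
    # flat curve: no response amplitude, EC50 undefined
    warning("flat dose-response curve: Emax ~ 0, fitted EC50 outside the tested range")
    return(new("PotencyEstimate", pec50 = -(max(log10(conc[pos])) + 3),
               emax = 0, hill = 1, bottom = rng[1], top = rng[1],
               se = c(pec50 = NA_real_, emax = NA_real_, hill = NA_real_),
               extrapolated = TRUE))
  }
  start <- list(bottom = rng[1], top = rng[2],
                lec50 = stats::median(log10(conc[pos])), h = 1)
  span <- max(rng[2] - rng[1], 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^((lec50 - lx) * h)),
      data = dat, start = start,
      lower = c(bottom = rng[1] - span, top = rng[1] - span,
                lec50 = min(lx) - 3, h = hillBounds[1]),
      upper = c(bottom = rng[2] + span, top = rng[2] + span,
                lec50 = max(lx) + 3, h = hillBounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop("dose-response fit failure: ",
                             conditionMessage(e), " [n=", length(conc), "]"))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(cf)))
  extrap <- cf[["lec50"]] < min(log10(conc[pos])) ||
    cf[["lec50"]] > max(log10(conc[pos]))
  if (extrap)
    warning("fitted EC50 outside the tested concentration range")
  new("PotencyEstimate",
      pec50 = -unname(cf[["lec50"]]),
      emax = unname(cf[["top"]] - cf[["bottom"]]),
      hill = unname(cf[["h"]]),
      bottom = unname(cf[["bottom"]]), top = unname(cf[["top"]]),
      se = c(pec50 = unname(se[["lec50"]]),
             emax = sqrt(sum(se[c("top", "bottom")]^2, na.rm = TRUE)),
             hill = unname(se[["h"]])),
      extrapolated = extrap)
}

#' Normalize a mutant potency estimate to same-day wild type
#'
#' Mutant responses are interpreted against wild-type measurements from the
#' same experimental session: delta-pEC50 = pEC50_mut - pEC50_WT and
#' %Emax = Emax_mut / Emax_WT * 100.
#'
#' @param mutant,wtSameDay [PotencyEstimate-class] objects from the same
#'   session.
#' @return list with `dpec50` and `pct_emax`.
#' @export
normalizeToWt <- function(mutant, wtSameDay) {
  stopifnot(is(mutant, "PotencyEstimate"), is(wtSameDay, "PotencyEstimate"))
  if (eMax(wtSameDay) == 0)
    stop("undefined normalization: wild-type Emax is zero")
  list(dpec50 = pEC50(mutant) - pEC50(wtSameDay),
       pct_emax = eMax(mutant) / eMax(wtSameDay) * 100)
}

#' Potency fold difference between two ligands
#'
#' EC50 ratio of ligand A over ligand B, with a rounded-fold convenience
#' value for statements like "fourfold lower potency".
#'
#' @param a,b [PotencyEstimate-class] objects, or EC50 values in M.
#' @return list with `fold` (EC50_a / EC50_b) and `fold_rounded`.
#' @examples
#' foldPotency(33e-9, 8.5e-9) # 3.88, rounds to 4
#' @export
foldPotency <- function(a, b) {
  ec <- function(x) if (is(x, "PotencyEstimate")) 10^(-pEC50(x)) else x
  ea <- ec(a); eb <- ec(b)
  stopifnot(ea > 0, eb > 0)
  f <- ea / eb
  list(fold = f, fold_rounded = round(f))
}

#' Fit every (ligand, construct, session) group of a BRET table
#'
#' Applies [fitDoseResponse()] to each curve of a dose-response table in the
#' [bretTableSchema()] layout (replicates pooled), then derives per-session
#' mutant-versus-WT normalizations where a `WT` construct is present.
#'
#' @param bret data.frame in the BRET table schema.
#' @param wtLabel construct label identifying wild type (default "WT").
#' @return data.frame `construct`, `ligand`, `session`, `pec50`, `se_pec50`,
#'   `emax`, `se_emax`, `hill`, `dpec50`, `pct_emax`.
#' @export
fitBretTable <- function(bret, wtLabel = "WT") {
  grp <- interaction(bret$ligand, bret$construct, bret$session, drop = TRUE)
  est <- lapply(split(bret, grp), function(d) {
    pe <- fitDoseResponse(d$conc_M, d$response)
    data.frame(construct = d$construct[1], ligand = d$ligand[1],
               session = d$session[1], pec50 = pEC50(pe),
               se_pec50 = unname(pe@se[["pec50"]]), emax = eMax(pe),
               se_emax = unname(pe@se[["emax"]]), hill = hillSlope(pe),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, est)
  out$dpec50 <- NA_real_
  out$pct_emax <- NA_real_
  for (i in seq_len(nrow(out))) {
    wt <- out$construct == wtLabel & out$ligand == out$ligand[i] &
      out$session == out$session[i]
    if (any(wt) && out$construct[i] != wtLabel) {
      out$dpec50[i] <- out$pec50[i] - out$pec50[which(wt)[1]]
      out$pct_emax[i] <- out$emax[i] / out$emax[which(wt)[1]] * 100
    }
  }
  rownames(out) <- NULL
  out
}
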
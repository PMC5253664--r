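#' @include AllClasses.R
NULL

#' Unmodified fraction from chromatographic peak areas
#'
#' The dose-response observable of radiolytic footprinting: the peak area of
#' the unoxidized species divided by the total peak area of unoxidized plus
#' all oxidized species.
#'
#' @param areaUnmod peak area of the unoxidized species (>= 0).
#' @param areasMod numeric vector of peak areas of oxidized species (may be
#'   empty).
#' @return fraction in \[0, 1\].
#' @examples
#' unmodifiedFraction(80, 20)        # 0.8
#' unmodifiedFraction(50, c(30, 20)) # 0.5
#' @export
unmodifiedFraction <- function(areaUnmod, areasMod = numeric()) {
  stopifnot(length(areaUnmod) == 1)
  if (areaUnmod < 0 || any(areasMod < 0)) stop("peak areas must be >= 0")
  total <- areaUnmod + sum(areasMod)
  if (total <= 0) stop("undefined fraction: total peak area is zero")
  areaUnmod / total
}

#' Fit a pseudo-first-order oxidation rate constant
#'
#' Least-squares fit of the exponential dose-response Y = Y0 * exp(-k t)
#' to the unmodified fraction versus exposure time. The fit is initialised by
#' log-linear regression on the positive fractions and refined by bounded
#' nonlinear least squares with Y0 free in (0, 1.05] and k >= 0. When
#' multiple replicates are supplied they are pooled into one fit and the
#' uncertainty of k is taken from the fit covariance.
#'
#' @param time exposure times, all replicates concatenated.
#' @param y unmodified fractions matching `time`.
#' @param replicate optional replicate labels (same length as `time`); used
#'   only for book-keeping under pooled fitting, or to fit each replicate
#'   separately when `perReplicate = TRUE`.
#' @param timeUnit `"ms"` (default, the instrument's exposure scale) or
#'   `"s"`. Rates are always reported in 1/s.
#' @param perReplicate fit each replicate separately and return a list of
#'   [RateConstant-class] (diagnostic mode); default pools.
#' @return a [RateConstant-class] (or a list of them).
#' @examples
#' t <- c(0, 5, 10, 15)
#' fitFirstOrder(t, exp(-2 * t / 1000))  # recovers k = 2 /s
#' @export
fitFirstOrder <- function(time, y, replicate = NULL,
                          timeUnit = c("ms", "s"), perReplicate = FALSE) {
  timeUnit <- match.arg(timeUnit)
  stopifnot(length(time) == length(y))
  if (is.null(replicate)) replicate <- rep("1", length(time))
  if (perReplicate) {
    reps <- split(seq_along(time), replicate)
    return(lapply(reps, function(idx)
      fitFirstOrder(time[idx], y[idx], timeUnit = timeUnit)))
  }
  if (any(time < 0)) stop("exposure times must be non-negative")
  for (idx in split(seq_along(time), replicate)) {
    tt <- time[idx]
    if (is.unsorted(tt, strictly = TRUE))
      stop("times must be strictly increasing within a replicate")
  }
  if (length(unique(time)) < 3)
    stop("insufficient data: need at least 3 distinct time points")
  if (!any(time == 0)) stop("a t = 0 point is required")
  ts <- if (timeUnit == "ms") time / 1000 else time

  # stage 1: log-linear initial estimate, excluding non-positive fractions
  pos <- y > 0
  if (sum(pos) >= 2 && length(unique(ts[pos])) >= 2) {
    lf <- stats::lm(log(y[pos]) ~ ts[pos])
    k0 <- max(0, -unname(coef(lf)[2]))
    y00 <- min(1.05, max(1e-3, exp(unname(coef(lf)[1]))))
  } else {
    k0 <- 1
    y00 <- max(1e-3, min(1.05, mean(y[time == 0])))
  }

  # stage 2: bounded nonlinear least squares on the exponential form
  dat <- data.frame(ts = ts, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 * exp(-k * ts), data = dat,
                      start = list(y0 = y00, k = k0),
                      lower = c(y0 = 1e-6, k = 0),
                      upper = c(y0 = 1.05, k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit failure: ", conditionMessage(e),
                             " [k0=", signif(k0, 3), ", n=", length(y), "]"))
  cf <- coef(fit)
  sdk <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                  error = function(e) NA_real_)
  if (cf[["k"]] == 0 && any(diff(tapply(y, ts, mean)) > 0))
    warning("monotonicity: k pinned at 0 with increasing fractions")
  new("RateConstant",
      k = unname(cf[["k"]]), y0 = unname(cf[["y0"]]),
      sdK = as.numeric(sdk), nPoints = length(y),
      nReplicates = length(unique(replicate)),
      rss = sum(stats::resid(fit)^2))
}

#' Fit rate constants for every species in a rates table
#'
#' Groups a dose-response table (schema [ratesTableSchema()]) by
#' (site, species) where a species is a (peptide, modification mass) pair,
#' computes the unmodified fraction per row, pools replicates, and fits the
#' pseudo-first-order model for each group.
#'
#' @param rates data.frame in the rates-table schema (from [readTable()] or
#'   [simulateFootprinting()]).
#' @param perReplicate see [fitFirstOrder()].
#' @return rate table: one row per (site, species) with columns `site`,
#'   `residues`, `peptide_id`, `mod_mass`, `k_per_s`, `sd_k`, `y0`,
#'   `n_points`, `n_replicates`, `rss`.
#' @export
fitRates <- function(rates, perReplicate = FALSE) {
  need <- c("peptide_id", "site", "mod_mass", "time_ms", "area_unmod",
            "area_mod", "replicate")
  missing <- setdiff(need, names(rates))
  if (length(missing)) stop("rates table missing column(s): ",
                            paste(missing, collapse = ", "))
  if (!"residues" %in% names(rates)) rates$residues <- NA_character_
  grp <- interaction(rates$site, rates$peptide_id, rates$mod_mass, drop = TRUE)
  pieces <- lapply(split(rates, grp), function(d) {
    d <- d[order(d$replicate, d$time_ms), , drop = FALSE]
    y <- mapply(unmodifiedFraction, d$area_unmod, d$area_mod)
    rc <- fitFirstOrder(d$time_ms, y, replicate = d$replicate,
                        timeUnit = "ms", perReplicate = perReplicate)
    if (perReplicate) {
      ks <- vapply(rc, rateK, 1)
      rc <- new("RateConstant", k = mean(ks), y0 = mean(vapply(rc, rateY0, 1)),
                sdK = if (length(ks) > 1) stats::sd(ks) else NA_real_,
                nPoints = nrow(d), nReplicates = length(ks),
                rss = sum(vapply(rc, function(f) f@rss, 1)))
    }
    data.frame(site = d$site[1], residues = d$residues[1],
               peptide_id = d$peptide_id[1], mod_mass = d$mod_mass[1],
               k_per_s = rateK(rc), sd_k = rateSd(rc), y0 = rateY0(rc),
               n_points = rc@nPoints, n_replicates = rc@nReplicates,
               rss = rc@rss, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  consolidateRates(out)
}

#' Consolidate per-species rate fits into a unique-keyed rate table
#'
#' Validates that each (site, species) pair appears once and orders the
#' table for downstream protection/comparison modules.
#'
#' @param fits data.frame with at least `site`, `mod_mass`, `peptide_id`,
#'   `k_per_s` columns (as produced per group by [fitRates()]).
#' @return the same table, sorted, with unique (site, peptide, mod_mass) keys.
#' @export
consolidateRates <- function(fits) {
  key <- paste(fits$site, fits$peptide_id, fits$mod_mass)
  if (any(duplicated(key)))
    stop("key collision: duplicate (site, species) entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  fits <- fits[order(fits$site, fits$peptide_id, fits$mod_mass), , drop = FALSE]
  rownames(fits) <- NULL
  fits
}
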
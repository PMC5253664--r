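#' @include AllClasses.R
NULL

#' Rate ratios between two liganded states
#'
#' Joins two fitted rate tables on their (site, peptide, modification-mass)
#' species keys and reports log10(k_A / k_B) for every shared species.
#' Species detected in only one state are never silently dropped: they are
#' returned in the `"orphans"` attribute as presence/absence rows. Species
#' with non-positive rates are excluded with a recorded reason. The ratio
#' standard deviation is propagated from the fit uncertainties by the delta
#' method.
#'
#' @param ratesA,ratesB rate tables from [fitRates()] for states A and B.
#' @param stateNames length-2 character, names of the two states used in the
#'   output columns (avoids silent orientation errors).
#' @return data.frame `site`, `residues`, `peptide_id`, `mod_mass`,
#'   `k_<A>`, `k_<B>`, `log10_ratio`, `sd_log10_ratio`; attributes
#'   `"orphans"` (unmatched rows with a `state` column) and `"excluded"`.
#' @export
rateRatios <- function(ratesA, ratesB, stateNames = c("A", "B")) {
  stopifnot(length(stateNames) == 2)
  keyA <- paste(ratesA$site, ratesA$peptide_id, ratesA$mod_mass)
  keyB <- paste(ratesB$site, ratesB$peptide_id, ratesB$mod_mass)
  shared <- intersect(keyA, keyB)
  orphanRows <- function(d, nm) {
    d <- d[, c("site", "peptide_id", "mod_mass", "k_per_s"), drop = FALSE]
    d$state <- rep(nm, nrow(d))
    d
  }
  orphans <- rbind(orphanRows(ratesA[!keyA %in% shared, , drop = FALSE],
                              stateNames[1]),
                   orphanRows(ratesB[!keyB %in% shared, , drop = FALSE],
                              stateNames[2]))
  a <- ratesA[match(shared, keyA), , drop = FALSE]
  b <- ratesB[match(shared, keyB), , drop = FALSE]
  ok <- a$k_per_s > 0 & b$k_per_s > 0
  excluded <- a$site[!ok]
  if (length(excluded))
    message("rateRatios excluded ", sum(!ok),
            " species with non-positive rates: ",
            paste(excluded, collapse = ", "))
  a <- a[ok, , drop = FALSE]; b <- b[ok, , drop = FALSE]
  out <- data.frame(site = a$site, residues = a$residues,
                    peptide_id = a$peptide_id, mod_mass = a$mod_mass,
                    kA = a$k_per_s, kB = b$k_per_s,
                    log10_ratio = log10(a$k_per_s / b$k_per_s),
                    sd_log10_ratio = sqrt((a$sd_k / a$k_per_s)^2 +
                                          (b$sd_k / b$k_per_s)^2) / log(10),
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "kA"] <- paste0("k_", stateNames[1])
  names(out)[names(out) == "kB"] <- paste0("k_", stateNames[2])
  rownames(out) <- NULL
  attr(out, "orphans") <- orphans
  attr(out, "excluded") <- excluded
  attr(out, "stateNames") <- stateNames
  out
}

#' Aggregate species-level rate ratios to residues
#'
#' Residues covered by multiple oxidation events (different peptides or
#' modification masses) receive the arithmetic mean of the log10 ratios.
#' Ambiguous two-residue sites contribute their ratio to both residues and
#' are marked ambiguous.
#'
#' @param ratios data.frame from [rateRatios()].
#' @return data.frame `chain`, `resno`, `residue`, `mean_log10_ratio`,
#'   `n_species`, `ambiguous`.
#' @export
aggregatePerResidue <- function(ratios) {
  if (!nrow(ratios))
    return(data.frame(chain = character(), resno = integer(),
                      residue = character(), mean_log10_ratio = numeric(),
                      n_species = integer(), ambiguous = logical()))
  ps <- parseSite(ratios$site)
  rows <- lapply(seq_len(nrow(ratios)), function(i) {
    resnos <- ps$resno[[i]]
    codes <- if (!is.na(ratios$residues[i]) && nzchar(ratios$residues[i]))
      strsplit(ratios$residues[i], "")[[1]] else rep(NA_character_, length(resnos))
    if (length(codes) != length(resnos)) codes <- rep(codes[1], length(resnos))
    data.frame(chain = ps$chain[i], resno = resnos, residue = codes,
               log10_ratio = ratios$log10_ratio[i],
               ambiguous = ps$ambiguous[i], stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  key <- paste(long$chain, long$resno)
  agg <- lapply(split(long, key), function(d) {
    data.frame(chain = d$chain[1], resno = d$resno[1],
               residue = d$residue[1],
               mean_log10_ratio = mean(d$log10_ratio),
               n_species = nrow(d), ambiguous = any(d$ambiguous),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify residues by fold change in oxidation rate
#'
#' Labels each residue `"increased_in_B"` when its rate in state B exceeds
#' the rate in state A by more than the fold threshold (strict inequality;
#' under the A/B ratio convention this is mean log10 ratio <
#' -log10(threshold)), `"decreased_in_B"` symmetrically, and `"unchanged"`
#' otherwise. The default threshold 1.4 corresponds to a > 40% rate change.
#'
#' @param perResidue data.frame from [aggregatePerResidue()].
#' @param thresholdFold fold-change threshold (> 1; default 1.4).
#' @return the input with a `label` column added.
#' @export
classifyActivationSites <- function(perResidue, thresholdFold = 1.4) {
  stopifnot(thresholdFold > 1)
  cut <- log10(thresholdFold)
  lr <- perResidue$mean_log10_ratio
  perResidue$label <- ifelse(lr < -cut, "increased_in_B",
                             ifelse(lr > cut, "decreased_in_B", "unchanged"))
  perResidue
}
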
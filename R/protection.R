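#' @include AllClasses.R
NULL

#' Protection factor from an oxidation rate
#'
#' The protection factor of a site is the intrinsic reactivity of its residue
#' (or the sum of intrinsic reactivities over all residues of a multi-residue
#' site) divided by the measured oxidation rate constant:
#' PF = sum(R_i) / k. High PF means the side chain is shielded from solvent.
#'
#' @param k measured oxidation rate constant in 1/s (> 0).
#' @param residues character vector of one-letter residue codes contributing
#'   to the site (1 or 2 for ambiguous assignments, more for peptide-level
#'   rates).
#' @param reactivities named reactivity vector from [loadReactivityTable()].
#' @return list with `pf`, `ln_pf`, `k`, `reactivity_sum`.
#' @examples
#' r <- c(W = 10, F = 20)
#' protectionFactor(2, "W", r)$pf        # 5
#' protectionFactor(3, c("W", "F"), r)$pf # 10
#' @export
protectionFactor <- function(k, residues, reactivities) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0)
    stop("k must be a single positive rate")
  unknown <- setdiff(residues, names(reactivities))
  if (length(unknown))
    stop("no intrinsic reactivity for residue(s): ",
         paste(unknown, collapse = ", "))
  rs <- sum(reactivities[residues])
  pf <- rs / k
  list(pf = pf, ln_pf = log(pf), k = k, reactivity_sum = rs)
}

#' Convert a rate table into a protection-factor table
#'
#' Applies [protectionFactor()] to every retained species of a fitted rate
#' table. By default only the +16 Da (single oxygen addition) species enter,
#' matching the standard protection-factor analysis; sites whose residues
#' lack intrinsic reactivities, or with non-positive fitted rates, are
#' skipped with a recorded reason.
#'
#' @param rates rate table from [fitRates()].
#' @param reactivities named reactivity vector.
#' @param modMass modification-mass filter in Da (default 16); `NULL` keeps
#'   all species.
#' @return data.frame with columns `site`, `residues`, `peptide_id`,
#'   `mod_mass`, `k_per_s`, `reactivity_sum`, `pf`, `ln_pf`; skipped rows are
#'   reported in the `"skipped"` attribute (site + reason).
#' @export
protectionTable <- function(rates, reactivities, modMass = 16) {
  stopifnot(is.data.frame(rates))
  if (!is.null(modMass)) rates <- rates[rates$mod_mass %in% modMass, , drop = FALSE]
  skipped <- data.frame(site = character(), reason = character(),
                        stringsAsFactors = FALSE)
  rows <- vector("list", nrow(rates))
  for (i in seq_len(nrow(rates))) {
    res <- siteResidueCodes(rates$residues[i], rates$site[i])
    if (anyNA(res)) {
      skipped <- rbind(skipped, data.frame(site = rates$site[i],
                                           reason = "no residue assignment"))
      next
    }
    if (length(setdiff(res, names(reactivities)))) {
      skipped <- rbind(skipped, data.frame(
        site = rates$site[i],
        reason = paste0("non-oxidizable residue(s): ",
                        paste(setdiff(res, names(reactivities)), collapse = ","))))
      next
    }
    if (rates$k_per_s[i] <= 0) {
      skipped <- rbind(skipped, data.frame(site = rates$site[i],
                                           reason = "non-positive rate"))
      next
    }
    p <- protectionFactor(rates$k_per_s[i], res, reactivities)
    rows[[i]] <- data.frame(site = rates$site[i],
                            residues = paste(res, collapse = ""),
                            peptide_id = rates$peptide_id[i],
                            mod_mass = rates$mod_mass[i],
                            k_per_s = p$k, reactivity_sum = p$reactivity_sum,
                            pf = p$pf, ln_pf = p$ln_pf,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    warning("empty result: no species retained after filtering")
    out <- data.frame(site = character(), residues = character(),
                      peptide_id = character(), mod_mass = numeric(),
                      k_per_s = numeric(), reactivity_sum = numeric(),
                      pf = numeric(), ln_pf = numeric())
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  if (nrow(skipped)) {
    msg <- paste0(skipped$site, " (", skipped$reason, ")")
    message("protectionTable skipped ", nrow(skipped), " site(s): ",
            paste(msg, collapse = "; "))
  }
  attr(out, "skipped") <- skipped
  out
}

# residue codes of a site: from the residues column when present, else NA
siteResidueCodes <- function(residues, site) {
  if (!is.na(residues) && nzchar(residues))
    return(strsplit(residues, "")[[1]])
  NA_character_
}
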
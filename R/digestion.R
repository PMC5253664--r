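#' @include AllClasses.R
NULL

#' Protease cleavage rules
#'
#' A specific rule cuts the backbone between residues i and i+1 when residue
#' i is in the `after` set (e.g. trypsin: after Lys/Arg) or residue i+1 is in
#' the `before` set (e.g. AspN: before Asp). A nonspecific rule (pepsin under
#' permissive conditions) enumerates all substrings within length bounds.
#' There is no proline exception.
#'
#' @param name rule name.
#' @param after,before character vectors of one-letter codes.
#' @param nonspecific logical; if TRUE, `minLen`/`maxLen` bound the peptides.
#' @param minLen,maxLen peptide length bounds for nonspecific cleavage.
#' @return an object of class `"enzymeRule"`.
#' @export
enzymeRule <- function(name, after = character(), before = character(),
                       nonspecific = FALSE, minLen = 5, maxLen = 30) {
  if (!nonspecific && !length(after) && !length(before))
    stop("a specific rule needs a non-empty after/before set")
  if (nonspecific && !(minLen >= 1 && minLen <= maxLen))
    stop("nonspecific rule needs 1 <= minLen <= maxLen")
  structure(list(name = name, after = after, before = before,
                 nonspecific = nonspecific, minLen = minLen, maxLen = maxLen),
            class = "enzymeRule")
}

#' @rdname enzymeRule
#' @export
trypsinRule <- function() enzymeRule("trypsin", after = c("K", "R"))

#' @rdname enzymeRule
#' @export
aspNRule <- function() enzymeRule("AspN", before = "D")

#' @rdname enzymeRule
#' @export
lysCRule <- function() enzymeRule("LysC", after = "K")

#' @rdname enzymeRule
#' @param minLen,maxLen length bounds of the nonspecific digest.
#' @export
pepsinRule <- function(minLen = 5, maxLen = 30)
  enzymeRule("pepsin", nonspecific = TRUE, minLen = minLen, maxLen = maxLen)

#' Read protein sequences from a FASTA file
#'
#' Convenience wrapper for feeding FASTA sequences into [digest()].
#'
#' @param path path to an (uncompressed) amino-acid FASTA file.
#' @return named character vector of sequences.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  setNames(as.character(aas), names(aas))
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water (18.010565 Da).
#'
#' @param sequence peptide sequence (standard one-letter codes).
#' @return mass in Da.
#' @examples
#' monoisotopicMass("GG") # 132.05349
#' @export
monoisotopicMass <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  aa <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(aa, names(MONO_MASS))
  if (length(unknown)) stop("unknown residue(s): ",
                            paste(unknown, collapse = ", "))
  sum(MONO_MASS[aa]) + WATER_MASS
}

#' In-silico protease digestion
#'
#' For specific rules, cut sites are the union over all supplied rules and
#' peptides are enumerated up to `missed` skipped cut sites. For a
#' nonspecific rule, every substring within the rule's length bounds is a
#' peptide. Output is sorted by (start, end).
#'
#' @param sequence protein sequence (one-letter codes).
#' @param rules a single `enzymeRule` or list of them. A nonspecific rule
#'   cannot be combined with specific rules.
#' @param missed maximum missed cleavages (specific rules only).
#' @return data.frame `start`, `end` (1-based, inclusive), `sequence`,
#'   `mass`, `missed`.
#' @examples
#' digest("AKRDG", list(trypsinRule(), aspNRule()))      # AK, R, DG
#' digest("AKRDG", trypsinRule(), missed = 1)
#' @export
digest <- function(sequence, rules, missed = 0) {
  if (!nzchar(sequence)) stop("empty sequence")
  if (inherits(rules, "enzymeRule")) rules <- list(rules)
  stopifnot(all(vapply(rules, inherits, TRUE, "enzymeRule")))
  n <- nchar(sequence)
  aa <- strsplit(sequence, "")[[1]]
  nonspec <- vapply(rules, function(r) r$nonspecific, TRUE)
  if (any(nonspec)) {
    if (length(rules) > 1)
      stop("a nonspecific rule cannot be combined with other rules")
    r <- rules[[1]]
    rows <- list()
    for (len in seq(r$minLen, min(r$maxLen, n))) {
      starts <- seq_len(n - len + 1)
      rows[[length(rows) + 1]] <- data.frame(start = starts,
                                             end = starts + len - 1)
    }
    pep <- do.call(rbind, rows)
    pep$missed <- NA_integer_
  } else {
    # cut after position i when aa[i] in 'after' or aa[i+1] in 'before'
    cuts <- sort(unique(unlist(lapply(rules, function(r) {
      c(which(aa[-n] %in% r$after),
        which(aa[-1] %in% r$before))
    }))))
    bounds <- c(0, cuts, n)
    starts <- bounds[-length(bounds)] + 1
    ends <- bounds[-1]
    nFrag <- length(starts)
    rows <- list()
    for (i in seq_len(nFrag)) {
      for (m in 0:min(missed, nFrag - i)) {
        rows[[length(rows) + 1]] <- data.frame(start = starts[i],
                                               end = ends[i + m], missed = m)
      }
    }
    pep <- do.call(rbind, rows)
  }
  pep$sequence <- substring(sequence, pep$start, pep$end)
  pep$mass <- vapply(pep$sequence, monoisotopicMass, 1, USE.NAMES = FALSE)
  pep <- pep[order(pep$start, pep$end), c("start", "end", "sequence", "mass",
                                          "missed")]
  rownames(pep) <- NULL
  pep
}

#' Match an observed precursor mass against theoretical peptides
#'
#' Returns every peptide whose monoisotopic mass is within `tolPpm` parts
#' per million of the observed mass (relative to the theoretical mass),
#' sorted by ppm error. Isobaric peptides are all returned; no arbitrary
#' tie-break.
#'
#' @param observed observed mass in Da.
#' @param peptides data.frame from [digest()] (needs a `mass` column).
#' @param tolPpm tolerance in ppm (default 10, the usual precursor setting).
#' @return the matching rows with a `ppm_error` column, sorted by |ppm|.
#' @export
matchMass <- function(observed, peptides, tolPpm = 10) {
  stopifnot(tolPpm > 0)
  ppm <- (observed - peptides$mass) / peptides$mass * 1e6
  hit <- abs(ppm) <= tolPpm
  out <- peptides[hit, , drop = FALSE]
  out$ppm_error <- ppm[hit]
  out <- out[order(abs(out$ppm_error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residue coverage of a peptide set
#'
#' Fraction of the sequence covered by the union of peptide intervals.
#'
#' @param peptides data.frame with `start`, `end` columns (may be empty).
#' @param sequenceLength protein length.
#' @return list with `fraction` and `intervals` (data.frame of merged
#'   covered intervals).
#' @export
coverage <- function(peptides, sequenceLength) {
  if (!nrow(peptides))
    return(list(fraction = 0,
                intervals = data.frame(start = integer(), end = integer())))
  if (any(peptides$start < 1 | peptides$end > sequenceLength |
          peptides$start > peptides$end))
    stop("peptide interval out of range [1, ", sequenceLength, "]")
  ir <- IRanges::reduce(IRanges::IRanges(peptides$start, peptides$end))
  covered <- sum(IRanges::width(ir))
  list(fraction = covered / sequenceLength,
       intervals = data.frame(start = IRanges::start(ir),
                              end = IRanges::end(ir)))
}
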
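#' @include AllClasses.R
NULL

#' Declare a table schema
#'
#' Column specification for [readTable()]: required columns with their types,
#' plus optional columns with defaults used when the column is absent.
#'
#' @param required named character vector, `c(colname = "numeric"|"character")`.
#' @param optional named list of default values; the default's type declares
#'   the column type.
#' @return an object of class `"tableSchema"`.
#' @export
tableSchema <- function(required, optional = list()) {
  stopifnot(is.character(required), length(names(required)) == length(required))
  structure(list(required = required, optional = optional),
            class = "tableSchema")
}

#' Schema of the oxidation-rates dose-response table
#'
#' One row per (peptide species, exposure time, replicate): `peptide_id`,
#' `site` (e.g. `"A:17"` or `"A:17-18"` for a two-residue ambiguous
#' assignment), `mod_mass` (modification mass shift in Da, e.g. 16),
#' `time_ms` (exposure time, milliseconds), `area_unmod` and `area_mod`
#' (chromatographic peak areas of the unoxidized species and the summed
#' oxidized species), `replicate`. Optional `residues` gives the one-letter
#' code(s) of the assigned residue(s) (e.g. `"W"` or `"WF"`).
#'
#' @return a `tableSchema`
#' @export
ratesTableSchema <- function() {
  tableSchema(
    required = c(peptide_id = "character", site = "character",
                 mod_mass = "numeric", time_ms = "numeric",
                 area_unmod = "numeric", area_mod = "numeric",
                 replicate = "character"),
    optional = list(residues = NA_character_))
}

#' Schema of the BRET dose-response table
#'
#' One row per well: `ligand`, `construct`, `session` (same-day pairing key),
#' `conc_M` (molar ligand concentration; 0 allowed for baseline wells),
#' `response` (BRET ratio), `replicate`.
#'
#' @return a `tableSchema`
#' @export
bretTableSchema <- function() {
  tableSchema(
    required = c(ligand = "character", construct = "character",
                 session = "character", conc_M = "numeric",
                 response = "numeric", replicate = "character"))
}

detectSep <- function(headerLine) {
  if (grepl("\t", headerLine, fixed = TRUE)) "\t" else ","
}

#' Read a delimited table against a schema
#'
#' Comma or tab delimiter is auto-detected from the header line; columns are
#' matched by name, not order; LF and CRLF line endings are both accepted.
#' Missing optional columns are filled with their declared defaults. Unknown
#' extra columns are kept but flagged with a warning. Non-numeric cells in a
#' numeric column raise an error naming the offending rows.
#'
#' @param path file path to delimited text with a header line.
#' @param schema a [tableSchema()].
#' @return data.frame of typed records; input row numbers (1 = first data
#'   row) are preserved in the `row` attribute column order of the file.
#' @export
readTable <- function(path, schema) {
  stopifnot(inherits(schema, "tableSchema"))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) stop("empty table file: ", path)
  sep <- detectSep(lines[1])
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                          header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  req <- schema$required
  missing <- setdiff(names(req), names(df))
  if (length(missing))
    stop("table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  extras <- setdiff(names(df), c(names(req), names(schema$optional)))
  if (length(extras))
    warning("ignoring unknown column(s): ", paste(extras, collapse = ", "))
  for (col in names(req)) {
    if (req[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
      if (length(bad))
        stop("non-numeric value in column '", col, "' at data row(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
      df[[col]] <- v
    }
  }
  for (col in names(schema$optional)) {
    if (!col %in% names(df)) {
      df[[col]] <- schema$optional[[col]]
    } else if (is.numeric(schema$optional[[col]])) {
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    }
  }
  df$.row <- seq_len(nrow(df))
  df
}

# ---- site identifiers ------------------------------------------------------

#' Site identifier helpers
#'
#' A site assignment names one residue (`"A:17"`) or two sequence-adjacent
#' residues when the oxidation event could not be resolved between
#' neighbours (`"A:17-18"`, flagged ambiguous).
#'
#' @param site character vector of site strings.
#' @return `parseSite`: data.frame with `chain`, `resno` (list column of
#'   integer vectors), `ambiguous`. `siteResnos`: list of integer vectors.
#' @export
parseSite <- function(site) {
  m <- regmatches(site, regexec("^([^:]+):([0-9]+)(-([0-9]+))?$", site))
  bad <- vapply(m, length, 1L) == 0
  if (any(bad)) stop("malformed site id(s): ", paste(site[bad], collapse = ", "))
  chain <- vapply(m, `[`, "", 2)
  r1 <- as.integer(vapply(m, `[`, "", 3))
  r2 <- suppressWarnings(as.integer(vapply(m, `[`, "", 5)))
  amb <- !is.na(r2)
  if (any(amb & abs(r2 - r1) != 1))
    stop("two-residue sites must name sequence-adjacent residues: ",
         paste(site[amb & abs(r2 - r1) != 1], collapse = ", "))
  data.frame(chain = chain,
             resno = I(Map(function(a, b) if (is.na(b)) a else c(a, b), r1, r2)),
             ambiguous = amb, stringsAsFactors = FALSE)
}

#' @rdname parseSite
#' @export
siteResnos <- function(site) parseSite(site)$resno

# ---- PDB reading -----------------------------------------------------------

#' Read a protein structure from a PDB file
#'
#' Returns the non-hydrogen, non-water, non-hetero atoms of one model of a
#' PDB file as a [ProteinStructure-class]. Alternate locations are resolved
#' to the highest-occupancy conformer (ties keep the first).
#'
#' @param path path to a PDB file.
#' @param modelIndex which MODEL of a multi-model file to use (default 1).
#' @param includeHydrogens keep hydrogen atoms (default FALSE; heavy-atom
#'   SASA is the crystallographic convention).
#' @return a [ProteinStructure-class]
#' @export
readStructure <- function(path, modelIndex = 1, includeHydrogens = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e)))
  nModels <- nrow(pdb$xyz)
  if (modelIndex < 1 || modelIndex > nModels)
    stop("modelIndex ", modelIndex, " out of range: file has ", nModels,
         " model(s)")
  xyz <- pdb$xyz[modelIndex, ]
  at <- pdb$atom
  at$x <- xyz[seq(1, length(xyz), 3)]
  at$y <- xyz[seq(2, length(xyz), 3)]
  at$z <- xyz[seq(3, length(xyz), 3)]

  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  at$element <- elem
  if (!includeHydrogens) at <- at[at$element != "H", , drop = FALSE]
  if (nrow(at) == 0) stop("empty model: no protein atoms after filtering")

  # altloc resolution: keep highest occupancy per (chain, resno, atom name)
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]

  code <- unname(AA1[at$resid])
  code[is.na(code)] <- "X"
  chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain)
  df <- data.frame(chain = chain, resno = at$resno, code = code,
                   name = trimws(at$elety), element = at$element,
                   x = at$x, y = at$y, z = at$z, occ = at$o,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chain, df$resno), , drop = FALSE]
  rownames(df) <- NULL
  new("ProteinStructure", atoms = df)
}

# ---- PDB writing -----------------------------------------------------------

formatAtomName <- function(name, element) {
  # PDB alignment: element symbol in columns 13-14 for 1-letter elements
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) == 1) sprintf(" %-3s", name) else sprintf("%-4s", name)
}

#' Write a structure with per-residue values in the B-factor column
#'
#' Writes ATOM/TER/END records where each atom's B-factor carries the value
#' mapped to its residue, enabling residue-level colouring in external
#' viewers (e.g. protection changes on a structure). Residues without a value
#' receive the sentinel (default 0.00). Values outside the fixed-width
#' B-factor field range \[-99.99, 999.99\] are clamped with a warning.
#'
#' @param structure a [ProteinStructure-class].
#' @param values named numeric vector keyed by site string `"chain:resno"`
#'   (e.g. `c("A:17" = 1.5)`); two-residue keys `"A:17-18"` assign both.
#' @param path output file path.
#' @param sentinel B-factor for residues without a value.
#' @return invisibly, the path.
#' @export
writeAnnotatedStructure <- function(structure, values, path, sentinel = 0) {
  a <- atoms(structure)
  bmap <- rep(sentinel, nrow(a))
  if (length(values)) {
    ps <- parseSite(names(values))
    for (i in seq_along(values)) {
      hit <- a$chain == ps$chain[i] & a$resno %in% ps$resno[[i]]
      if (!any(hit))
        stop("annotated residue not present in structure: ", names(values)[i])
      bmap[hit] <- values[[i]]
    }
  }
  if (any(bmap < -99.99 | bmap > 999.99)) {
    warning("B-factor value(s) outside [-99.99, 999.99] clamped")
    bmap <- pmin(pmax(bmap, -99.99), 999.99)
  }
  res3 <- AA3[a$code]
  res3[is.na(res3)] <- "UNK"
  lines <- character(nrow(a) + 2)
  for (i in seq_len(nrow(a))) {
    lines[i] <- sprintf(
      "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, formatAtomName(a$name[i], a$element[i]), "", res3[i], a$chain[i],
      a$resno[i], "", a$x[i], a$y[i], a$z[i], a$occ[i], bmap[i], a$element[i])
  }
  lines[nrow(a) + 1] <- "TER"
  lines[nrow(a) + 2] <- "END"
  writeLines(lines, path)
  invisible(path)
}
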
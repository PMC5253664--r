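#' @include AllClasses.R
NULL

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
}

runManifest <- function(command, inputs, params, seed = NULL) {
  hash <- function(p) if (is.character(p) && length(p) == 1 &&
                          file.exists(p)) {
    unname(tools::md5sum(p))
  } else NA_character_
  list(command = command,
       inputs = lapply(inputs, function(p)
         list(path = if (is.character(p)) p else "<in-memory>",
              md5 = hash(p))),
       params = params, seed = seed,
       package_version = as.character(utils::packageVersion("hrfp")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

writeOutputs <- function(outputs, manifest, outDir) {
  if (is.null(outDir)) return(invisible(NULL))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(outputs)) {
    if (is.data.frame(outputs[[nm]]))
      utils::write.csv(outputs[[nm]], file.path(outDir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

resolveRates <- function(ratesTable, stageName) {
  stage(stageName, {
    if (is.character(ratesTable))
      ratesTable <- readTable(ratesTable, ratesTableSchema())
    stopifnot(is.data.frame(ratesTable))
    ratesTable
  })
}

resolveStructure <- function(structure) {
  stage("structure input", {
    if (is.character(structure)) structure <- readStructure(structure)
    stopifnot(is(structure, "ProteinStructure"))
    structure
  })
}

#' Free-state analysis: rates to protection factors to calibration
#'
#' Chains the full reference-state pipeline: fit pseudo-first-order rates
#' from the dose-response table, convert the +16 Da species to protection
#' factors, compute site-level fractional side-chain SASA from the
#' structure, and calibrate the ln PF versus fSASA line.
#'
#' @param ratesTable dose-response table ([ratesTableSchema()] layout) or a
#'   path to one.
#' @param structure a [ProteinStructure-class] or a PDB path.
#' @param reactivities,sasaRef tables (defaults: bundled).
#' @param modMass species filter for protection factors (default 16 Da).
#' @param probe,nPoints SASA parameters, see [shrakeRupley()].
#' @param outDir optional output directory; when set, the rate, protection,
#'   accessibility and calibration tables plus a reproducibility manifest
#'   are written there as CSV/JSON.
#' @param seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return list with `rates`, `protection`, `accessibility`, `joined`
#'   (per-site fSASA + lnPF pairs) and `model` (a
#'   [CalibrationModel-class]).
#' @export
runFreeState <- function(ratesTable, structure,
                         reactivities = loadReactivityTable(),
                         sasaRef = loadSasaRefTable(), modMass = 16,
                         probe = 1.4, nPoints = 960, outDir = NULL,
                         seed = NULL) {
  rt <- resolveRates(ratesTable, "rates input")
  st <- resolveStructure(structure)
  rates <- stage("kinetics", fitRates(rt))
  prot <- stage("protection", protectionTable(rates, reactivities, modMass))
  acc <- stage("sasa", siteAccessibility(prot, st, sasaRef, reactivities,
                                         probe = probe, nPoints = nPoints))
  joined <- stage("calibration", {
    m <- merge(prot[, c("site", "residues", "k_per_s", "pf", "ln_pf")],
               acc[, c("site", "fsasa", "sasa_w", "sasa_ref_w")],
               by = "site")
    m[order(m$site), , drop = FALSE]
  })
  model <- stage("calibration", calibrate(joined$fsasa, joined$ln_pf))
  calDf <- data.frame(intercept = calIntercept(model),
                      slope = calSlope(model), pearson_r = pearsonR(model),
                      n = calN(model), sigma = model@sigma)
  manifest <- runManifest(
    "free_state",
    list(rates = ratesTable, structure = structure),
    list(modMass = modMass, probe = probe, nPoints = nPoints), seed)
  writeOutputs(list(rates = rates, protection = prot, accessibility = acc,
                    calibration = calDf), manifest, outDir)
  list(rates = rates, protection = prot, accessibility = acc,
       joined = joined, model = model, manifest = manifest)
}

#' Bound-state analysis: predict accessibility from a calibration
#'
#' Fits bound-state rates, converts them to protection factors, inverts the
#' free-state calibration to predict bound-state fractional SASA, and (when
#' the free-state accessibility is supplied) reports the per-site burial
#' change.
#'
#' @param ratesTableBound bound-state dose-response table or path.
#' @param model a [CalibrationModel-class] from [runFreeState()].
#' @param freeAccessibility optional accessibility table from the free-state
#'   run (columns `site`, `fsasa`, `sasa_ref_w`); enables the delta ranking
#'   and absolute SASA prediction.
#' @inheritParams runFreeState
#' @return list with `rates`, `protection`, `predicted` (site, ln_pf,
#'   fsasa_raw, fsasa, clipped), and `delta` (when free accessibility was
#'   given).
#' @export
runBoundState <- function(ratesTableBound, model,
                          reactivities = loadReactivityTable(),
                          freeAccessibility = NULL, modMass = 16,
                          outDir = NULL, seed = NULL) {
  stopifnot(is(model, "CalibrationModel"))
  rt <- resolveRates(ratesTableBound, "rates input")
  rates <- stage("kinetics", fitRates(rt))
  prot <- stage("protection", protectionTable(rates, reactivities, modMass))
  pred <- stage("prediction", {
    p <- predictBoundFsasa(prot$ln_pf, model)
    cbind(site = prot$site, residues = prot$residues, p,
          stringsAsFactors = FALSE)
  })
  delta <- NULL
  if (!is.null(freeAccessibility)) {
    delta <- stage("prediction", deltaAccessibility(
      freeAccessibility[, c("site", "fsasa")],
      pred[, c("site", "fsasa")]))
    if ("sasa_ref_w" %in% names(freeAccessibility)) {
      idx <- match(pred$site, freeAccessibility$site)
      pred$sasa_pred <- pred$fsasa * freeAccessibility$sasa_ref_w[idx]
    }
  }
  manifest <- runManifest("bound_state", list(rates = ratesTableBound),
                          list(modMass = modMass,
                               slope = calSlope(model),
                               intercept = calIntercept(model)), seed)
  outs <- list(rates = rates, protection = prot, predicted = pred)
  if (!is.null(delta)) outs$delta <- delta
  writeOutputs(outs, manifest, outDir)
  c(outs, list(model = model, manifest = manifest))
}

#' Two-state comparison: rate ratios, residue aggregation, classification
#'
#' Fits rates for both states (or accepts already-fitted rate tables),
#' computes per-species log10 rate ratios, aggregates to residues, labels
#' residues by the fold-change threshold, and optionally writes a PDB whose
#' B-factor column carries the mean log10 ratio for visual mapping.
#'
#' @param ratesA,ratesB dose-response tables (or paths), or already-fitted
#'   rate tables (recognised by a `k_per_s` column).
#' @param structure optional [ProteinStructure-class] (or PDB path) for the
#'   annotated-structure output.
#' @param thresholdFold classification threshold (default 1.4, i.e. > 40%
#'   rate change).
#' @param stateNames names of the two states for output columns.
#' @param outDir optional output directory (comparison CSV, annotated PDB,
#'   manifest).
#' @param seed recorded in the manifest.
#' @return list with `ratios`, `perResidue` (classified), `orphans`, and
#'   `annotatedPdb` path when a structure and `outDir` were given.
#' @export
runStateCompare <- function(ratesA, ratesB, structure = NULL,
                            thresholdFold = 1.4, stateNames = c("A", "B"),
                            outDir = NULL, seed = NULL) {
  fitIfNeeded <- function(x, nm) {
    x <- resolveRates(x, paste0("rates input ", nm))
    if ("k_per_s" %in% names(x)) x else stage("kinetics", fitRates(x))
  }
  ra <- fitIfNeeded(ratesA, stateNames[1])
  rb <- fitIfNeeded(ratesB, stateNames[2])
  ratios <- stage("statecomp", rateRatios(ra, rb, stateNames))
  perRes <- stage("statecomp",
                  classifyActivationSites(aggregatePerResidue(ratios),
                                          thresholdFold))
  annotated <- NULL
  if (!is.null(structure) && !is.null(outDir)) {
    st <- resolveStructure(structure)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    annotated <- file.path(outDir, "state_compare_annotated.pdb")
    vals <- setNames(perRes$mean_log10_ratio,
                     paste0(perRes$chain, ":", perRes$resno))
    keep <- names(vals) %in% paste0(atoms(st)$chain, ":", atoms(st)$resno)
    stage("annotation",
          writeAnnotatedStructure(st, vals[keep], annotated))
  }
  manifest <- runManifest("state_compare",
                          list(ratesA = ratesA, ratesB = ratesB),
                          list(thresholdFold = thresholdFold,
                               stateNames = stateNames), seed)
  writeOutputs(list(ratios = ratios, per_residue = perRes), manifest, outDir)
  list(ratios = ratios, perResidue = perRes,
       orphans = attr(ratios, "orphans"), annotatedPdb = annotated,
       manifest = manifest)
}
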
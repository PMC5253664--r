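#' @include AllClasses.R
NULL

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# cylindrical placement helper for ideal-helix atoms
helixAtom <- function(i, r, dphiDeg, dz, name, element, code, chain, resno) {
  phi <- (100 * i + dphiDeg) * pi / 180
  data.frame(chain = chain, resno = resno, code = code, name = name,
             element = element, x = r * cos(phi), y = r * sin(phi),
             z = 1.5 * i + dz, occ = 1, stringsAsFactors = FALSE)
}

buildHelixChain <- function(codes, chain, offset = c(0, 0, 0), startRes = 1) {
  rows <- list()
  for (j in seq_along(codes)) {
    i <- j - 1
    resno <- startRes + j - 1
    code <- codes[j]
    rows[[length(rows) + 1]] <- rbind(
      helixAtom(i, 1.55, -28, -0.70, "N", "N", code, chain, resno),
      helixAtom(i, 2.28, 0, 0, "CA", "C", code, chain, resno),
      helixAtom(i, 1.67, 26, 0.55, "C", "C", code, chain, resno),
      helixAtom(i, 2.60, 38, 0.95, "O", "O", code, chain, resno),
      if (code != "G")
        helixAtom(i, 3.35, -8, -0.25, "CB", if (code == "M") "S" else "C",
                  code, chain, resno))
  }
  df <- do.call(rbind, rows)
  df$x <- df$x + offset[1]; df$y <- df$y + offset[2]; df$z <- df$z + offset[3]
  df
}

buildStrandChain <- function(codes, chain, y0, flip = FALSE, startRes = 1) {
  rows <- list()
  n <- length(codes)
  for (j in seq_along(codes)) {
    i <- if (flip) n - j else j - 1
    resno <- startRes + j - 1
    code <- codes[j]
    up <- if (j %% 2 == 0) 1 else -1
    base <- data.frame(
      chain = chain, resno = resno, code = code,
      name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      x = 3.3 * i + c(-1.2, 0, 1.2, 1.4),
      y = y0 + c(0, 0, 0, 1.1),
      z = c(0.1, 0.3, 0.1, 0.2) * up, occ = 1, stringsAsFactors = FALSE)
    if (code != "G")
      base <- rbind(base, data.frame(
        chain = chain, resno = resno, code = code, name = "CB",
        element = if (code == "M") "S" else "C",
        x = 3.3 * i, y = y0, z = 1.6 * up, occ = 1))
    rows[[length(rows) + 1]] <- base
  }
  do.call(rbind, rows)
}

#' Generate a synthetic fixture structure
#'
#' Builds small ideal-geometry protein structures with stub side chains
#' (a single pseudo-atom at the C-beta position) for testing the SASA and
#' calibration machinery without external coordinate files:
#' \describe{
#'   \item{helix}{one ideal alpha-helical chain (rise 1.5 A/residue, 100
#'     deg/residue).}
#'   \item{bundle}{a compact three-helix bundle in one chain: core-facing
#'     side chains are buried and surface side chains exposed, giving the
#'     globular-protein accessibility contrast needed for calibration
#'     studies (a bare helix exposes every side chain almost equally).}
#'   \item{sheet_pair}{two antiparallel extended strands in one chain pair.}
#'   \item{two_domain_complex}{two helical chains packed against each other;
#'     the contact residues form a known "interface" truth set whose SASA
#'     drops in the complex relative to the separated chains (see
#'     [complexInterface()]).}
#' }
#' Sequences are drawn from the 20 standard residues under the given seed,
#' so repeated calls with the same arguments are identical.
#'
#' @param kind `"helix"`, `"sheet_pair"` or `"two_domain_complex"`.
#' @param nResidues total residue count (>= 5; split across chains for the
#'   complex).
#' @param seed integer seed.
#' @return a [ProteinStructure-class].
#' @export
makeFixtureStructure <- function(kind = c("helix", "bundle", "sheet_pair",
                                          "two_domain_complex"),
                                 nResidues = 30, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(nResidues >= 5)
  alphabet <- setdiff(names(AA3), character(0))
  withSeed(seed, {
    codes <- sample(alphabet, nResidues, replace = TRUE)
    df <- switch(kind,
      helix = buildHelixChain(codes, "A"),
      bundle = {
        n1 <- ceiling(nResidues / 3)
        n2 <- ceiling((nResidues - n1) / 2)
        segs <- list(seq_len(n1), n1 + seq_len(n2),
                     seq(n1 + n2 + 1, nResidues))
        # packing tight enough that core-facing side chains are truly
        # buried (fSASA near 0), as in a globular protein core
        offs <- list(c(0, 0, 0), c(9.0, 0, 0.75), c(4.5, 7.8, 1.5))
        do.call(rbind, lapply(1:3, function(j)
          buildHelixChain(codes[segs[[j]]], "A", offset = offs[[j]],
                          startRes = segs[[j]][1])))
      },
      sheet_pair = {
        n1 <- ceiling(nResidues / 2)
        rbind(buildStrandChain(codes[1:n1], "A", 0),
              buildStrandChain(codes[(n1 + 1):nResidues], "B", 4.8,
                               flip = TRUE))
      },
      two_domain_complex = {
        n1 <- ceiling(nResidues / 2)
        rbind(buildHelixChain(codes[1:n1], "A"),
              buildHelixChain(codes[(n1 + 1):nResidues], "B",
                              offset = c(9.2, 0, 0.75)))
      })
    new("ProteinStructure", atoms = df)
  })
}

#' Interface residues of a multi-chain structure
#'
#' Residues having any atom within `cutoff` of an atom in a different chain.
#'
#' @param structure a [ProteinStructure-class] with >= 2 chains.
#' @param cutoff contact distance in angstrom (default 6).
#' @return data.frame `chain`, `resno`, `code` of interface residues.
#' @export
complexInterface <- function(structure, cutoff = 6) {
  a <- atoms(structure)
  if (length(unique(a$chain)) < 2) stop("structure has a single chain")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  contact <- rep(FALSE, nrow(a))
  other <- outer(a$chain, a$chain, "!=")
  d2 <- as.matrix(stats::dist(xyz))^2
  contact <- apply(d2 <= cutoff^2 & other, 1, any)
  sq <- residueSequence(structure)
  key <- paste(a$chain, a$resno)
  hit <- unique(key[contact])
  sq[paste(sq$chain, sq$resno) %in% hit, , drop = FALSE]
}

#' Simulate a radiolytic footprinting experiment with known truth
#'
#' The generative model inverts the analysis chain: per-residue fractional
#' side-chain SASA is computed from the structure, true rates follow
#' k = R_residue / exp(a + b * fSASA) (so ln PF is exactly linear in fSASA
#' with intercept `a` and slope `b`), observed per-site rates are drawn
#' lognormally around the truth (`rateNoise` = sdlog), and dose-response
#' points Y = exp(-k t) receive multiplicative lognormal noise
#' (`fractionNoise`), truncated at 1 when converting to peak areas. With all
#' noise at zero the full pipeline returns (a, b) exactly and Pearson
#' R = -1.
#'
#' Default conditions mirror a paper-scale chemokine experiment: 25 mapped
#' +16 Da sites, duplicate exposures over a 0-15 ms dose range, and rate
#' noise sdlog 0.45 (which, propagated through the pipeline, yields an
#' illustrative ln PF versus fSASA correlation in the -0.7 to -0.9 range
#' rather than the noiseless -1).
#'
#' @param structure a [ProteinStructure-class].
#' @param a,b calibration intercept and slope (b < 0).
#' @param reactivities,sasaRef tables, see [loadReactivityTable()] and
#'   [loadSasaRefTable()].
#' @param timesMs exposure times in ms; must include 0 and >= 3 points.
#' @param nSites number of oxidation sites to sample among eligible
#'   (oxidizable, reference-covered) residues; `NULL` keeps all.
#' @param replicates number of replicates.
#' @param rateNoise lognormal sdlog on per-site rates.
#' @param fractionNoise lognormal sdlog on unmodified fractions.
#' @param totalArea total chromatographic peak area per measurement.
#' @param quantifiableOnly restrict the sampled sites to species whose decay
#'   is measurable within the exposure window (at least `minDecay` natural
#'   log units of decay at the last time point and at most `maxFirstDecay`
#'   at the first nonzero point). Real experiments report rates only for
#'   species with quantifiable dose-response; without this guard, sites far
#'   outside the dose window contribute pure fit noise.
#' @param minDecay,maxFirstDecay the window bounds above (natural log
#'   units).
#' @param seed integer seed.
#' @param dir optional directory; when given, writes `rates.csv` and the
#'   machine-readable truth sidecar `truth.json` there.
#' @return list with `rates` (data.frame in the [ratesTableSchema()] layout)
#'   and `truth` (per-site truth table plus the generator parameters).
#' @export
simulateFootprinting <- function(structure, a = 4, b = -3.5,
                                 reactivities = loadReactivityTable(),
                                 sasaRef = loadSasaRefTable(),
                                 timesMs = c(0, 0.5, 1, 2, 5, 10, 15),
                                 nSites = 25, replicates = 2,
                                 rateNoise = 0.45, fractionNoise = 0.05,
                                 totalArea = 1e6, quantifiableOnly = TRUE,
                                 minDecay = 0.2, maxFirstDecay = 3,
                                 seed = 1, dir = NULL) {
  stopifnot(b < 0, length(timesMs) >= 3, any(timesMs == 0))
  prs <- perResidueSasa(structure)
  prs$ref <- unname(sasaRef[prs$code])
  eligible <- prs[prs$code %in% names(reactivities) & !is.na(prs$ref), ,
                  drop = FALSE]
  if (!nrow(eligible)) stop("no oxidizable residues with reference areas")
  eligible$fsasa <- eligible$sasa / eligible$ref
  eligible$ln_pf_true <- a + b * eligible$fsasa
  eligible$k_true <- unname(reactivities[eligible$code]) /
    exp(eligible$ln_pf_true)
  if (quantifiableOnly) {
    tMax <- max(timesMs) / 1000
    tFirst <- min(timesMs[timesMs > 0]) / 1000
    ok <- eligible$k_true * tMax >= minDecay &
      eligible$k_true * tFirst <= maxFirstDecay
    if (!any(ok)) stop("no site has quantifiable decay in the dose window")
    eligible <- eligible[ok, , drop = FALSE]
  }
  withSeed(seed, {
    if (!is.null(nSites) && nSites < nrow(eligible)) {
      eligible <- eligible[sort(sample(nrow(eligible), nSites)), ,
                           drop = FALSE]
    }
    eligible$k_obs <- eligible$k_true *
      exp(stats::rnorm(nrow(eligible), 0, rateNoise))
    eligible$site <- paste0(eligible$chain, ":", eligible$resno)

    grid <- expand.grid(i = seq_len(nrow(eligible)),
                        rep = seq_len(replicates), t = timesMs)
    y <- exp(-eligible$k_obs[grid$i] * grid$t / 1000)
    if (fractionNoise > 0)
      y <- y * exp(stats::rnorm(length(y), 0, fractionNoise))
    y <- pmin(y, 1)
    rates <- data.frame(
      peptide_id = paste0("pep", sprintf("%03d", grid$i)),
      site = eligible$site[grid$i],
      residues = eligible$code[grid$i],
      mod_mass = 16,
      time_ms = grid$t,
      area_unmod = totalArea * y,
      area_mod = totalArea * (1 - y),
      replicate = paste0("r", grid$rep),
      stringsAsFactors = FALSE)
    rates <- rates[order(rates$site, rates$replicate, rates$time_ms), ,
                   drop = FALSE]
    rownames(rates) <- NULL
    truth <- list(
      sites = eligible[, c("site", "chain", "resno", "code", "sasa", "ref",
                           "fsasa", "ln_pf_true", "k_true", "k_obs")],
      a = a, b = b, rateNoise = rateNoise, fractionNoise = fractionNoise,
      timesMs = timesMs, replicates = replicates, seed = seed)
    rownames(truth$sites) <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(rates, file.path(dir, "rates.csv"), row.names = FALSE)
      jsonlite::write_json(truth, file.path(dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    list(rates = rates, truth = truth)
  })
}

#' Simulate a two-state footprinting comparison with a protected truth set
#'
#' Generates rate tables for two liganded states A and B that share baseline
#' rates derived from the structure's accessibility; residues in the
#' protected set have their state-B rate divided by `foldProtection`
#' (protection by the state-B ligand). Lognormal noise is applied
#' independently per state.
#'
#' @param structure a [ProteinStructure-class].
#' @param protectedSites character vector of site ids (`"chain:resno"`) to
#'   protect in state B; defaults to the complex interface when the
#'   structure has two chains.
#' @param foldProtection fold reduction of state-B rates at protected sites.
#' @param rateNoise lognormal sdlog applied to each state's rates.
#' @param seed integer seed.
#' @inheritParams simulateFootprinting
#' @return list with `ratesA`, `ratesB` (fitted-rate-table layout, i.e. the
#'   output layout of [fitRates()]) and `truth`.
#' @export
simulateStateComparison <- function(structure, protectedSites = NULL,
                                    foldProtection = 3, rateNoise = 0.1,
                                    a = 4, b = -3.5,
                                    reactivities = loadReactivityTable(),
                                    sasaRef = loadSasaRefTable(), seed = 1) {
  prs <- perResidueSasa(structure)
  prs$ref <- unname(sasaRef[prs$code])
  eligible <- prs[prs$code %in% names(reactivities) & !is.na(prs$ref), ,
                  drop = FALSE]
  eligible$site <- paste0(eligible$chain, ":", eligible$resno)
  if (is.null(protectedSites)) {
    iface <- complexInterface(structure)
    protectedSites <- paste0(iface$chain, ":", iface$resno)
  }
  withSeed(seed, {
    fsasa <- eligible$sasa / eligible$ref
    kBase <- unname(reactivities[eligible$code]) / exp(a + b * fsasa)
    kA <- kBase * exp(stats::rnorm(length(kBase), 0, rateNoise))
    prot <- eligible$site %in% protectedSites
    kB <- kBase / ifelse(prot, foldProtection, 1) *
      exp(stats::rnorm(length(kBase), 0, rateNoise))
    mk <- function(k) data.frame(
      site = eligible$site, residues = eligible$code,
      peptide_id = paste0("pep", sprintf("%03d", seq_along(k))),
      mod_mass = 16, k_per_s = k, sd_k = k * rateNoise, y0 = 1,
      n_points = 14L, n_replicates = 2L, rss = 0,
      stringsAsFactors = FALSE)
    list(ratesA = mk(kA), ratesB = mk(kB),
         truth = list(protected = eligible$site[prot],
                      foldProtection = foldProtection,
                      rateNoise = rateNoise, seed = seed))
  })
}

#' Simulate a BRET dose-response table
#'
#' Four-parameter-logistic responses with additive Gaussian noise, in the
#' [bretTableSchema()] layout. With `sigma = 0` a fit recovers the inputs
#' exactly.
#'
#' @param ec50 EC50 in M.
#' @param emax response amplitude (top - bottom).
#' @param hill Hill slope.
#' @param doses molar concentrations (an 8-point half-log dilution by
#'   default); a zero-dose baseline well is added automatically.
#' @param sigma additive Gaussian noise SD (response units).
#' @param replicates replicates per dose.
#' @param bottom baseline response.
#' @param ligand,construct,session labels for the output table.
#' @param seed integer seed.
#' @return data.frame in the BRET table schema.
#' @export
simulateBret <- function(ec50, emax = 1, hill = 1,
                         doses = 10^seq(-10, -6.5, by = 0.5), sigma = 0,
                         replicates = 3, bottom = 0, ligand = "ligand",
                         construct = "WT", session = "s1", seed = 1) {
  stopifnot(ec50 > 0)
  withSeed(seed, {
    conc <- c(0, doses)
    grid <- expand.grid(conc = conc, rep = seq_len(replicates))
    mu <- ifelse(grid$conc == 0, bottom,
                 bottom + emax / (1 + 10^((log10(ec50) - log10(grid$conc)) * hill)))
    y <- mu + if (sigma > 0) stats::rnorm(nrow(grid), 0, sigma) else 0
    data.frame(ligand = ligand, construct = construct, session = session,
               conc_M = grid$conc, response = y,
               replicate = paste0("r", grid$rep), stringsAsFactors = FALSE)
  })
}
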
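Package: hrfp
Title: Analysis of Hydroxyl Radical Protein Footprinting Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of radiolytic (hydroxyl radical)
    protein footprinting mass-spectrometry experiments. Fits pseudo-first-order
    oxidation rate constants from dose-response tables of unmodified peptide
    fractions, converts rates to protection factors using residue-specific
    intrinsic reactivities, computes solvent-accessible surface areas from PDB
    coordinates with a deterministic Shrake-Rupley lattice, calibrates the
    log-protection-factor versus fractional-SASA relation on a reference state
    and inverts it to predict residue burial in a ligand-bound state, maps
    ligand-induced protection and exposure by between-state rate ratios, and
    supports in-silico protease digestion, peptide mass matching, and
    four-parameter-logistic dose-response (BRET) pharmacology. A synthetic
    experiment generator with known ground truth makes every pipeline stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    minpack.lm,
    IRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'hrfp-package.R'
    'AllClasses.R'
    'calibration.R'
    'digestion.R'
    'kinetics.R'
    'pharm.R'
    'pipeline.R'
    'protection.R'
    'sasa.R'
    'statecomp.R'
    'structio.R'
    'synthetic.R'
    'tables.R'
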
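---
title: "Quantitative analysis of hydroxyl radical protein footprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analysis of hydroxyl radical protein footprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrfp)
```

## The measurement and its model

Radiolytic (hydroxyl radical) footprinting irradiates a protein solution
with synchrotron X-rays; radiolysis of water generates hydroxyl radicals
that covalently oxidize solvent-exposed side chains, most commonly adding
+16 Da. Quantitative mass spectrometry after protease digestion yields, for
each oxidized species at each exposure time, chromatographic peak areas of
the unoxidized and oxidized forms. The fraction of unmodified peptide

$$Y(t) = \frac{A_{\mathrm{unmod}}}{A_{\mathrm{unmod}} + \sum_j A_{\mathrm{mod},j}}$$

decays pseudo-first-order with the exposure time,
$Y = Y_0\, e^{-k t}$, and the rate constant $k$ (in s$^{-1}$) reports how
exposed the oxidized side chain is to bulk solvent.

`fitFirstOrder()` implements this fit in two stages: a log-linear
regression on the positive fractions supplies starting values, and a
bounded Levenberg-Marquardt fit of the exponential form refines them.
$Y_0$ is a free parameter in $(0, 1.05]$ rather than fixed at 1, because
partial oxidation before the first exposure or area-integration offsets
shift the amplitude without affecting the rate. Replicates are pooled into
one fit by default, with the uncertainty of $k$ taken from the fit
covariance; a `perReplicate` flag fits each replicate separately and
averages, for diagnostics. Exposure times in input tables are milliseconds
(the dose range of a synchrotron beamline shutter, typically 0-15 ms);
rates are always reported in s$^{-1}$.

## Protection factors

Different side chains have very different intrinsic propensities for
hydroxyl-radical attack, so raw rates are not comparable across residues.
The protection factor of a site normalises the measured rate by the
intrinsic reactivity:

$$\mathrm{PF} = \frac{\sum_i R_i}{k_{\mathrm{FP}}}$$

where the sum runs over the residue(s) the oxidation event is mapped to —
a single residue for a resolved site, both candidates for a two-residue
ambiguous assignment, or all oxidizable residues of a peptide-level rate.
High PF means protection (burial); the natural log of PF is the quantity
used downstream.

The intrinsic reactivities are *configuration, not constants*: the
bundled default table is derived from published radiolysis rate constants
of free side chains, rescaled to a relative per-second scale, and any
user table can be swapped in (`loadReactivityTable()`). Because PF is
homogeneous of degree 1 in the reactivity scale, rescaling the whole
table by a constant shifts only the calibration intercept (by $\ln c$)
and leaves the slope and the Pearson correlation untouched — this
invariance is asserted in the test suite, and it is what makes the
calibration robust to the exact provenance of the table.

## Solvent accessibility

Per-residue solvent-accessible surface area (SASA) is computed with a
Shrake-Rupley estimator written for this package: each atom's van der
Waals sphere is expanded by the probe radius (default 1.4 Å, a water
molecule) and sampled with a deterministic golden-spiral lattice
(default 960 points/atom); the accessible area is the expanded-sphere
area times the fraction of lattice points not buried in any neighbouring
expanded sphere. The defaults follow crystallographic convention: heavy
atoms only, per-element radii (C 1.70, N 1.55, O 1.52, S 1.80 Å,
configurable), and side-chain atoms only when summing per residue —
backbone atoms are not oxidation targets, and the calibration uses
fractional *side-chain* accessibility.

Two numerical choices deserve a note:

* **Frame canonicalisation.** A fixed global point lattice is strictly
  monotone under atom addition (occluders can only remove accessible
  points) but is only approximately invariant under rotation of the
  input. `shrakeRupley()` therefore moves coordinates to a deterministic
  principal-axes pose before sampling (`frame = "canonical"`, the
  default), which makes total SASA invariant under rigid motion to
  near machine precision on generic structures; `frame = "input"` keeps
  the lattice fixed in the input frame and preserves exact monotonicity.
  Each property is verified on its own path.
* **Lattice density.** At 960 points/atom the total SASA of a test
  structure differs from a 4x denser lattice by about 0.01%; the
  two-sphere analytic spherical-cap area is matched to about 0.1% at
  10,000 points.

Fractional SASA normalises the observed area by a residue-specific
standard maximum area (`loadSasaRefTable()`; theoretical-maximum total
and side-chain columns are bundled). For peptide-level or two-residue
sites, both the observed SASA and the reference are combined with the
*same* weights before the ratio is taken, with weights proportional to
intrinsic reactivity,

$$w_i = \frac{R_i}{\sum_j R_j}, \qquad
f\mathrm{SASA} = \frac{\sum_i w_i\,\mathrm{SASA}_i}
                      {\sum_i w_i\,\mathrm{SASA}_{\mathrm{REF},i}},$$

on the rationale that the measured rate of a multi-residue species is
dominated by its most reactive side chains. This weighting is a design
choice of the package (a uniform-weight alternative sits behind the
`uniform` switch); values above 1 are flagged rather than rejected.

## Calibration and bound-state prediction

On a reference state with a known structure, $\ln \mathrm{PF}$ is
regressed on fSASA by ordinary least squares (`calibrate()`), and the
Pearson correlation of the pairs is reported. Protection rises as
exposure falls, so the slope and $R$ are negative. The regression
direction is $\ln \mathrm{PF}$ on fSASA, inverted algebraically for
prediction; an inverse-regression alternative is available behind a
flag, since with noise in both variables neither direction is uniquely
"correct".

For a ligand-bound state with no usable structure, measured
$\ln \mathrm{PF}$ values are pushed through the inverted line,
$f\mathrm{SASA} = (\ln \mathrm{PF} - a)/b$ (`predictBoundFsasa()`).
Predictions are clamped to $[0, 1]$ by default — fractional
accessibility is physically bounded — with the raw value kept alongside
and a flag marking clamped sites. `deltaAccessibility()` ranks sites by
the drop in accessibility between states; no significance test is
attached to the ranking, because the comparison is descriptive.

Only +16 Da species enter protection-factor analysis by default
(`modMass = 16`), the modification for which intrinsic reactivities are
tabulated; the filter is configurable.

## Two-state comparison

When neither state supports absolute interpretation (e.g. a membrane
receptor bound to two different ligands), the package compares states by
the log rate ratio per species, $\log_{10}(k_A/k_B)$, with states named
explicitly in the output to avoid orientation mistakes. Residues covered
by several oxidation events get the arithmetic mean of their log ratios;
two-residue ambiguous sites contribute to both residues and stay
flagged. Classification uses a strict fold threshold (default 1.4, i.e.
a > 40% rate change, applied after residue aggregation): rates more than
1.4-fold higher in state B label the residue `increased_in_B`, exactly
1.4-fold is `unchanged`. Species observed in a single state are reported
as presence/absence rows, never imputed. Ratio uncertainties are
propagated from the fit standard deviations by the delta method and
emitted for the user; no hypothesis-testing machinery is layered on top.

## Digestion and mass matching

In-silico proteolysis supports the rules used in footprinting practice:
trypsin (cut after Lys/Arg), AspN (cut before Asp), LysC (after Lys),
with the cut-site union taken when enzymes are combined, missed
cleavages enumerated up to a bound, and no proline exception.
Nonspecific (peptic) digestion enumerates all substrings within length
bounds, defaulting to 5-30 residues — permissive pepsin conditions
produce essentially nonspecific cleavage and the bounds are
configuration. Peptide monoisotopic masses use the standard residue
table plus one water; precursor matching uses a strict ppm window
(default 10 ppm) relative to the theoretical mass, returning all
isobaric candidates. Coverage is the union of peptide intervals over the
sequence length.

## Pharmacology

BRET β-arrestin-recruitment dose-response curves are fit with the
four-parameter logistic

$$y = \mathrm{bottom} +
\frac{\mathrm{top} - \mathrm{bottom}}
     {1 + 10^{(\log_{10}\mathrm{EC}_{50} - \log_{10} x)\,h}},$$

with the Hill slope free within $[0.3, 5]$. $E_{\max}$ is reported as
top − bottom (the response difference between zero and saturating
ligand) and potency as $\mathrm{pEC}_{50} = -\log_{10}\mathrm{EC}_{50}$.
Zero-dose wells anchor the bottom asymptote as pseudo-concentration
points three log-units below the lowest dose (a fit-stability device).
Mutant estimates are normalised to wild-type measurements from the same
session (ΔpEC50 and %Emax), mirroring same-day experimental pairing;
`foldPotency()` reports EC50 ratios with a rounded-fold convenience
value.

## The synthetic-experiment generator

Every stage is testable without external data because the generator
inverts the analysis model. `makeFixtureStructure()` builds
ideal-geometry backbones with single pseudo-atom side chains at the
C-beta position: a bare helix, a compact three-helix bundle (the
workhorse for calibration studies — a bare helix exposes every side
chain almost equally, while the bundle has a buried core and hence the
accessibility contrast of a globular protein), an antiparallel strand
pair, and a two-chain complex whose contact residues form a known
protected truth set.

`simulateFootprinting()` computes true fractional side-chain SASA from
the structure, sets $k = R_{\mathrm{res}} / e^{a + b\,f\mathrm{SASA}}$
so that $\ln \mathrm{PF}$ is exactly linear in fSASA, draws observed
rates lognormally around the truth, and emits dose-response tables in
the same schema the pipeline reads, plus a machine-readable truth
sidecar. Default conditions are paper-scale: 25 mapped +16 Da sites,
duplicate exposures at 0-15 ms, rate noise sdlog 0.45 and fraction noise
sdlog 0.05. Sites are sampled among species whose decay is *measurable*
in the dose window (at least 0.2 natural-log units of decay by the last
time point, at most 3 by the first nonzero point) — real experiments
likewise report rates only for species with quantifiable dose-response,
and sites far outside the window would contribute pure fit noise rather
than information.

What the generator does *not* emulate: chromatographic peak shapes and
integration error, sequence-context modulation of intrinsic reactivity,
secondary oxidation chemistry, correlated replicate structure, and real
side-chain rotamers (side chains are C-beta stubs, which compresses the
fSASA dynamic range relative to a real protein). Passing recovery tests
therefore demonstrate correctness of the estimators under the stated
noise model, not instrument-level realism.

## Simulation scales and reproducibility

The recovery benchmarks run at these problem sizes, chosen to mirror the
scale of a single-protein footprinting study while keeping the full
suite fast: rate-constant recovery uses 200 simulations at each of
$k \in \{1, 10, 100\}$ s$^{-1}$ with fraction noise 0.05, sampling each
decay on its own time scale ($t_{\max} = 3/k$, the standard design for
measuring a first-order rate — a fixed 15 ms window cannot resolve a
1 s$^{-1}$ rate, whose total decay over the window is 1.5%);
calibration-slope recovery uses 100 simulated experiments of 25 sites at
rate noise 0.1; protected-set recovery uses 200 two-state simulations at
3-fold protection and the 1.4-fold threshold; logistic-potency recovery
uses 200 noisy triplicate curves. All generators are seed-deterministic,
pipeline outputs are pure functions of their inputs (the SASA lattice is
deterministic), and each orchestration function records a manifest
(input hashes, parameters, package version, seed) sufficient to
reproduce a run.

## Known limitations

* Intrinsic-reactivity and reference-area tables are representative
  defaults, not measured constants; absolute PF values depend on them,
  though calibration slopes and correlations do not.
* The Shrake-Rupley estimator is numerical; exact analytic SASA
  (power-diagram methods) is out of scope.
* Dose normalisation from fluorophore decay controls is an experimental
  QC step and is not modelled; rates from samples with very different
  radical doses are not directly comparable.
* Peptide-level rates attribute oxidation by reactivity weighting; when
  a peptide's oxidation is actually dominated by a weakly reactive but
  highly exposed residue, the weighted fSASA misassigns the signal.
* The two-state classification is descriptive; with two replicates the
  rate uncertainties are too coarse for formal error control, which is
  why propagated SDs are emitted but not thresholded.
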
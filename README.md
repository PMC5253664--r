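# hrfp — hydroxyl radical protein footprinting analysis

`hrfp` is an R package for quantitative analysis of radiolytic
(hydroxyl radical) protein footprinting mass-spectrometry experiments,
a structural technique in which synchrotron X-ray radiolysis of water
generates •OH radicals that oxidize solvent-exposed side chains.
Because the oxidation rate of a side chain tracks its solvent
exposure, dose–response measurements map residue burial, ligand
interfaces and conformational changes — including for membrane
proteins such as GPCR:ligand complexes that resist crystallography.
The package is aimed at structural mass-spectrometry practitioners who
have per-peptide peak-area tables and want calibrated, residue-level
structural readouts.

## What it computes

1. **Oxidation kinetics.** The unmodified fraction
   Y = A_unmod / (A_unmod + Σ A_mod) is fit to the pseudo-first-order
   model Y = Y₀·e^(−kt) (pooled replicates, bounded nonlinear least
   squares, rates in s⁻¹).
2. **Protection factors.** PF = ΣRᵢ / k_FP, the summed intrinsic
   side-chain reactivity over the measured rate; ln PF is the
   burial-tracking statistic.
3. **Solvent accessibility.** Per-residue side-chain SASA from PDB
   coordinates via a deterministic Shrake–Rupley lattice (probe 1.4 Å),
   normalised to fractional SASA by residue-specific reference areas,
   with reactivity-weighted combination for peptide-level sites.
4. **Calibration and prediction.** OLS of ln PF on fSASA for a free
   state with known structure (ln PF = a + b·fSASA, Pearson R), inverted
   to predict residue burial in a ligand-bound state and rank
   ligand-induced burial changes.
5. **Two-state comparison.** Per-species log₁₀(k_A/k_B) rate ratios,
   residue-level averaging, and >40% fold-change classification
   (threshold 1.4), written onto the structure through the B-factor
   column for visualisation.
6. **Support modules.** In-silico digestion (trypsin/AspN/LysC,
   nonspecific pepsin), monoisotopic masses and 10-ppm precursor
   matching, sequence coverage; four-parameter-logistic BRET
   dose–response fits (pEC50, Emax, ΔpEC50, %Emax, fold potency); and a
   seed-deterministic synthetic-experiment generator with ground truth.

## Worked example

A synthetic free-state experiment at paper scale (25 mapped +16 Da
sites, duplicate 0–15 ms exposures, lognormal rate noise 0.45):

```r
library(hrfp)

protein <- makeFixtureStructure("bundle", 90, seed = 7)
protein
#> ProteinStructure: 438 atoms, 90 residues, 1 chain(s) [A]

exp1 <- simulateFootprinting(protein, seed = 1)
head(exp1$rates, 3)
#>   peptide_id site residues mod_mass time_ms area_unmod  area_mod replicate
#> 1     pep003 A:12        Y       16     0.0   929101.2 70898.807        r1
#> 2     pep003 A:12        Y       16     0.5   991798.9  8201.053        r1
#> 3     pep003 A:12        Y       16     1.0   981707.4 18292.599        r1

res <- runFreeState(exp1$rates, protein)
head(res$protection[, c("site", "residues", "k_per_s", "pf", "ln_pf")], 3)
#>   site residues  k_per_s        pf    ln_pf
#> 1 A:12        Y 12.78499 101.68175 4.621848
#> 2 A:15        W 81.74475  15.90316 2.766518
#> 3  A:2        Y 34.65709  37.51036 3.624617

res$model
#> CalibrationModel: lnPF = 3.8238 -2.8045 * fSASA  (Pearson R = -0.569, n = 25, sigma = 0.471)
```

The fitted rate of the tyrosine at residue 12 (12.8 s⁻¹) is slow for a
tyrosine, so its protection factor is high (PF ≈ 102, ln PF ≈ 4.6): the
side chain is buried. The calibration line recovers the generating
intercept/slope (a = 4, b = −3.5) within noise, and the negative Pearson
R is the burial–protection anticorrelation the method relies on; with
the noise set to zero the recovery is exact and R = −1. The model then
predicts bound-state burial from bound-state rates via
`runBoundState()`, and `runStateCompare()` maps two-ligand rate ratios
onto residues:

```r
fp <- foldPotency(33e-9, 8.5e-9)   # EC50s of two agonists
#> fold: 3.88  rounded: 4
```

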
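---
title: "Positional 13C isotopomer analysis of HRMAS spectra: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional 13C isotopomer analysis of HRMAS spectra: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmasflux)
```

## The problem

Infusing a pregnant animal with a positionally labeled substrate
(1-^13^C-glucose or 2-^13^C-acetate) and acquiring HRMAS NMR spectra of
intact fetal tissue gives a positional read-out of central carbon
metabolism: which carbons of alanine, lactate, glutamate and glutamine carry
^13^C, and how much, reflects the relative activity of glycolysis, pyruvate
dehydrogenase (PDH), pyruvate carboxylase (PC), malic enzyme (ME) and
glutamine synthetase (GS). In the growth-restriction model this package
emulates, litter-matched FGR and AGA fetuses from the same mothers are
compared, so the statistics are simple two-arm t-tests at small n.

The raw spectra behind such studies are typically not public. The package
therefore pairs every analysis step with a synthetic generator that renders
cohorts and multinuclear spectra with the reported statistical structure, so
the full chain — label propagation, spectral quantification, isotopomer
statistics, group comparison — is testable end to end.

## Label propagation model

`propagate()` tracks the *per-position labeling probability* of each tracked
carbon (Pyr C2/C3, AcCoA C1/C2, OAA C2/C3, Mal C2/C3, aKG C2/C3/C4, and the
observable Lac, Ala, Glu, Gln positions). Isotopomer correlations are
ignored: 2D ^1^H-^13^C HSQC measures positional enrichment only, so
per-position probabilities carry all the information the analysis uses.

One TCA-cycle "turn" applies the atom maps in `atom_map_registry()`:

* glycolysis: Glc C1 labels **half** of pyruvate C3 (C1/C6 symmetry of the
  fructose-1,6-bisphosphate cleavage) — the origin of the 50% correction
  below;
* PDH: Pyr C3 → AcCoA C2 (methyl); acetate enters at the same position;
* citrate synthase → aKG: OAA C2 → aKG C3, OAA C3 → aKG C2, AcCoA C2 → aKG
  C4, AcCoA C1 → aKG C5; aKG C1 is lost as CO~2~;
* succinate: a chemically symmetric molecule, so the C2/C3 pair is always
  fully symmetrized (this is what distributes second-turn label equally to
  Glu C2 and C3);
* PC: Pyr C2/C3 → OAA C2/C3 without passing succinate;
* ME: Mal C2/C3 → Pyr C2/C3 1:1, feeding the "Lac C2C3" pool.

Fluxes are relative; `dilution_unlabeled` admits unlabeled carbon at the
acetyl-CoA and OAA nodes. Each pool update is a flux-weighted mixture of its
sources; `n_turns` iterates turn by turn (the per-turn output distinguishes
first- from second-turn products) or to a fixed point (`"steady_state"`,
tolerance 10^-9^, capped at 1000 turns with an explicit error carrying the
residual).

**Scrambling.** The `scrambling` parameter is the fraction of the mixed OAA
pool that back-exchanges through symmetric fumarate before citrate
synthase. Cycle carbon is already symmetric when it arrives (succinate), so
`scrambling` only affects PC-derived carbon: at 1 (the conservative default)
the Glu C2/C3 asymmetry is erased; below 1 the asymmetry survives, which is
what the PC/PDH estimator reads. With full back-exchange disabled the
estimator `(GluC2 − GluC3)/GluC4` returns `pc/(pc + pdh)` exactly — a
slightly compressed but monotone read-out of the anaplerotic ratio
(`analysis/05_flux_ratios.R` prints the recovery curve).

**Glutamate vs glutamine pools.** Observed Glu labeling is the aKG label
scaled by `glu_turnover`, the fraction of the Glu pool exchanged during the
infusion (default 0.7); Gln labeling is the aKG label scaled by
`gs/(gs + gln_exchange)`. With complete Glu turnover Gln can never exceed
Glu; at the defaults Gln C4 exceeds Glu C4 once `gs > 0.7` (the documented
threshold), reproducing the preferential glial routing of acetate into
glutamine without a full two-compartment model — a deliberate
simplification, not a biological claim.

The propagation is cross-checked in the test suite against an independent
molecule-by-molecule Monte-Carlo simulator (10^5^ molecules, each with a
fully independent carbon ancestry) at up to three turns.

## Spectral rendering and quantification

All three renderers draw from a `true_metabolic_state` (pools in a.u./mg,
labeled fractions, ^31^P pools, tissue pH, drift rates) and are exact models
of what the quantifiers assume, so round-trip tests at zero noise measure
the numerical error of the quantifiers alone.

| quantity | default | note |
|---|---|---|
| 1D line shape | Lorentzian, FWHM 1.5 Hz | CPMG and ^31^P |
| lactate CH~3~ doublet | 1.32 ppm, ^3^J~HH~ = 6.9 Hz | reference anchor |
| ^13^C satellite offset | ±½·^1^J~CH~, ^1^J~CH~ = 127 Hz | literature methyl value; configurable |
| macromolecule background | 2 Gaussians, FWHM ~40 Hz, 1.54–1.14 ppm | CPMG attenuates but does not remove it |
| HSQC peaks | 2D Gaussian, FWHM 0.01 ppm (^1^H) × 0.5 ppm (^13^C) | grid 0.004 × 0.2 ppm |
| HSQC template | 60 metabolite + 4 noise ROIs, ±0.04 × ±1.0 ppm | synthetic assignment list; user-replaceable CSV |
| drift | +10% over 5.2 h for Gln C4, Lac C2, Lac C3 | linear; slopes are placeholders (no published values) |
| pH → Pi shift | pKa 6.75, δ~acid~ 3.27, δ~base~ 5.69 ppm | literature constants; the true calibration is unpublished |

Quantification choices worth knowing:

* **ROI integration** subtracts a robust local baseline (median of the ROI
  border pixels) and normalizes to net tissue weight; SNR is computed
  against the pooled SD of the four noise regions, and peaks below SNR 3 are
  kept but flagged. ppm axes run high→low and windows are half-open.
* **Lactate deconvolution** (1.54–1.14 ppm) fits the parent doublet, the
  right ^13^C satellite doublet, the alanine doublet and two broad
  Gaussians by bounded Levenberg–Marquardt (positions constrained to ±0.01
  ppm, one shared narrow linewidth), then re-solves the areas exactly by
  linear least squares at the fitted positions (variable projection),
  clipping negative areas at zero with a flag. The left satellite is tied to
  the right one (satellites are symmetric) rather than fitted independently,
  because it overlaps alanine. The labeled pool is reported as 2 × the right
  satellite; total lactate as parent + labeled.
* **Glutamine integration** uses exactly 2.48–2.42 ppm with a linear
  baseline through flanks at 2.53–2.49 and 2.388–2.368 ppm — below
  succinate (2.41 ppm, excluded by design) and above the glutamate C4
  multiplet, so neither contaminates the baseline. Lorentzian tails put ~4%
  of the true area outside any 24 Hz window; the round-trip tests therefore
  compare against the *in-window* analytic area.
* **^31^P deconvolution** fits Lorentzians for PE, PC, GPE (the 1.00 ppm
  reference, which must be detectable), GPC and Pi (position free within the
  titration-plausible window); in heart tissue two 2,3-DPG components
  overlap PC, which is fitted but reported as missing.

## The synthetic cohort: what it emulates

`make_cohort()` reproduces the perinatal design: Bernoulli stillbirth per
fetus (defaults 55% FGR, 14% AGA), truncated-normal birth and placental
weights (47.2 ± 7.1 vs 34.9 ± 7.2 g; 5.6 ± 1.3 vs 4.5 ± 1.5 g), CTR mothers
with an AGA horn only, and per-fetus RNG substreams so cohorts extend
without reshuffling. `select_hrmas_subcohort()` draws the 27-fetus HRMAS
design (3 CTR + 6/6 GLC + 6/6 ACE), two tissues per fetus, with 3 samples
dropped at random in the study-default scenario. Net tissue weight is
49.7 ± 3.0 mg with the constant 2.22 mg D~2~O load carried in the manifest.

**Effect sizes and variability.** FGR effects are multiplicative factors on
the labeled excess (ACE group: brain Lac C2 ×0.77, Lac C3 ×0.80, heart Gln
C4 ×0.77) and on heart phosphodiester pools (infused AGA hearts at 1/1.5 of
the FGR/CTR baseline; 1/1.3 for glucose, where only a tendency was
reported). Between-sample CVs of the labeled levels are not published;
they are *implied* by the reported t-tests at n = 6/6 (p = 0.0456 for a
−23% contrast gives CV ≈ 0.177; p = 0.0272 for −20% gives ≈ 0.140;
p = 0.0029 for −23% gives ≈ 0.106). The generator treats these as targets
for the CV of the CTR-referenced excess: because the natural-abundance
background (1.1%) shares the pool variability, pool noise enters the excess
amplified by (na + excess)/excess, and `assign_true_state()` solves for the
per-position enrichment noise that realizes the target on top of a 5% pool
CV. The effective precursor enrichment (0.17) is calibrated so positional
enrichments fall in the reported <10% range (e.g. glucose-brain Lac C3
around 8–9%).

A second generator, `state_from_incorporation()`, bypasses the flux model
and draws labeled excess volumes directly from the bundled reference
composition table, respecting the printed SDs of both the component rows and
the derived rows (the non-Ala/Lac/Glx remainder and the glycolytic partition
are drawn directly; Lac C3 is reconstructed as Lac C2 + partition; Glx
components are rescaled compositionally). This is the generator used for
the parameter-recovery tests, because the printed derived-row SDs encode
compositional correlations that independent per-row draws would violate.

**What passing tests do not show about real data.** The renderers share
their line-shape families with the fitters, so round-trip accuracy is a
statement about the numerics, not about model mismatch on real spectra
(phasing errors, shimming, relaxation weighting, spinning sidebands and
water suppression are all out of scope). The ROI template is a synthetic
assignment list with deliberately disjoint windows; real HSQC templates
overlap. Litter structure is ignored by the t-tests, as in the source
design; a mixed-model extension is noted but not implemented.

## Derived quantities

* **Positional enrichment**: `(I_inf − I_ctr)/I_ctr`, scaled by the 1.1%
  natural abundance to percent units; for 1-^13^C-glucose the de-novo pool
  is only 50% labeled, so total de-novo synthesis applies a ×2 correction
  (2.4% positional ⇒ 4.8% total; 8% ⇒ 16%).
* **Incorporation fractions**: per-sample excesses (floored at 0) as
  percent of the quantified set, so each sample sums to 100; the derived
  rows SUM(Ala+Lac+Glx), Glycolysis (Lac C3′ = LacC3 − LacC2) and TCAc
  (Glx + 2·LacC2) are computed per sample from the exact identities —
  unfloored, so the identities hold row-wise even when a sample's partition
  is negative — and then averaged. The standalone `lac_partition()` floors
  at zero with a flag for reporting.
* **Flux ratios**: `pc_over_pdh = (GluC2 − GluC3)/GluC4` and
  `pc_over_me = (GluC2 − GluC3)/(2·LacC2)`; both formulas are returned as
  metadata. The exact published estimators live in an unavailable
  supplement; these canonical forms are validated against the propagation
  model instead, and the glucose-brain default calibration (pc = 0.3,
  scrambling = 0.2) places the estimator at ≈0.15, inside the 0.1–0.3 band
  reported for control fetal brains. Note the printed glucose-brain
  composition itself implies ≈0.11 by this formula.
* **GS relative activity**: primary form GlnC4/GluC4 (0.86 at the reference
  acetate-brain means); the compositional alternative GlnC4/(GlnC4+GluC4)
  is reported alongside, since which form the original supplement used is
  unknown.

## Statistics

Arms are gated by Shapiro–Wilk (reported, never auto-switched); group
contrasts use the classic pooled-variance Student's t-test, two-tailed
unpaired for different subjects and one-tailed paired (accumulation
direction, final ≥ initial) for the same subjects at two time points. No
multiple-testing correction is applied, matching the source analysis; the
comparison table carries the number of tests for post-correction. Fetuses
from the same mother are treated as independent, as the source design
implies.

## Problem sizes used by the test suite

The suite validates: renderer↔quantifier round trips at zero noise and
unbiasedness over noisy replicates; the Monte-Carlo cross-check at 10^5^
molecules (3 binomial SE); type-I error of the test machinery over 10^4^
null simulations (±1%); recovery of the reference derived rows from 4
rendered cohorts of 12 samples per tissue/group cell (within 2 SE at
n = 12); majority detection of the four headline effects over 500 seeds at
the measured-variable level, where per-seed power is deliberately marginal
(≈0.55–0.95, as the reported p-values imply); and ≥80% sign recovery over
10 fully rendered pipeline runs. These sizes keep the default suite around
three minutes on one core while leaving each check statistically sharp.

## Known limitations

* Single-compartment propagation: neuron/glia separation is represented
  only through the GS/PC parameters, not as explicit compartments.
* Per-position probabilities cannot predict ^13^C-^13^C multiplets
  (isotopomer correlations); Gln C2C3 and GABA are not modeled, as they
  were not detectable in the emulated experiment.
* Drift slopes, the pH calibration constants and the ROI boundaries are
  placeholders or literature defaults where the study reports none; all are
  configurable and flagged in output metadata.
* Absolute concentrations (mM) are out of scope; all pools are in arbitrary
  units per mg tissue.
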
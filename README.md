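# hrmasflux

Simulation and analysis of positional ¹³C-tracer HRMAS NMR metabolomics in a
litter-matched fetal growth restriction (FGR) vs appropriate-for-gestational-age
(AGA) design.

Infusing 1-¹³C-glucose or 2-¹³C-acetate and acquiring ¹H-CPMG, 2D ¹H-¹³C HSQC
and ³¹P HRMAS spectra of intact fetal brain and heart tissue gives a positional
read-out of central carbon metabolism. The raw spectra behind such studies are
rarely public, so this package pairs every analysis step with a synthetic
generator: cohorts, ground-truth metabolic states and rendered multinuclear
spectra with the reported statistical structure, making the whole chain
testable end to end. It is aimed at NMR metabolomics practitioners who want a
reusable, validated implementation of this class of analysis, and at
methodologists who want a realistic simulation bench for it.

## What it computes

* **Label propagation** (`propagate()`): per-position ¹³C labeling
  probabilities through glycolysis and the TCA cycle from explicit carbon atom
  maps, with relative fluxes for PDH, PC, ME, GS, acetate uptake and unlabeled
  dilution. Glucose C1 labels half the glycolytic pyruvate C3 pool (C1/C6
  symmetry); acetate C2 enters at the acetyl-CoA methyl (aKG C4 → Glu C4 on
  the first turn, equal Glu C2/C3 on the second via symmetric succinate).
* **Spectral quantification** (`integrate_roi()`, `deconvolve_lactate()`,
  `integrate_glutamine()`, `quantify_p31()`, `estimate_ph()`): 60-ROI HSQC
  template integration with local baselines and weight normalization,
  constrained deconvolution of the lactate methyl region (parent doublet at
  1.32 ppm, J = 6.9 Hz, ¹³C satellites at ±½·¹J₍CH₎), baseline-corrected
  glutamine integration over 2.48–2.42 ppm excluding succinate, ³¹P
  phosphomonoester/diester deconvolution referenced to GPE (1.00 ppm), and pH
  from the Pi shift via pH = pKa + log₁₀((δ − δ_acid)/(δ_base − δ)).
* **Isotopomer statistics** (`positional_enrichment()`,
  `incorporation_fractions()`, `lac_partition()`, `tcac_fraction()`,
  `flux_ratios()`, `gs_relative_activity()`): enrichment as
  (I_infused − I_control)/I_control with the ×2 de-novo correction for
  1-¹³C-glucose, per-sample incorporation percentages with the derived rows
  SUM(Ala+Lac+Glx), Glycolysis (LacC3 − LacC2) and TCAc (Glx + 2·LacC2), the
  anaplerotic estimator (GluC2 − GluC3)/GluC4, and GS activity GlnC4/GluC4.
* **Cohort statistics** (`compare_groups()`, `normality_check()`,
  `fit_drift()`, `initial_vs_final()`): Shapiro–Wilk gating, pooled-variance
  Student's t-tests (two-tailed unpaired across subjects, one-tailed paired
  across time points), and linear HRMAS time-drift handling.
* **Orchestration** (`run_pipeline()`): the full simulate → render →
  quantify → analyze → compare chain for the bundled study-default scenario
  (9 mothers: 2 CTR, 4 GLC, 3 ACE; brain + heart per fetus; 3 samples
  dropped), deterministic per seed.

The methods vignette (`vignettes/isotopomer-workflow.Rmd`) documents the
models, every tunable parameter with its default and rationale, and the
limitations of the synthetic data.

## Worked example

```r
library(hrmasflux)
res <- run_pipeline(run_config(seed = 7))
writeLines(res$report)
```

```
hrmasflux pipeline report (scenario study_default, seed 7)
samples: 51 (0 flagged)

Significant FGR-vs-AGA contrasts (p < 0.05):
  ACE brain_cortex Lac C3: -19.7% (p = 0.0075)
  ACE brain_cortex Lac C2: -30.7% (p = 0.0035)
  ACE brain_cortex lac_13c: -10.1% (p = 0.0078)
  ACE heart_apex gpc_gpe: +45.1% (p = 0.0000)
  ACE heart_apex ph: -1.7% (p = 0.0349)
  GLC heart_apex lac_total: +5.5% (p = 0.0313)
  GLC heart_apex gpc_gpe: +34.9% (p = 0.0003)

Initial vs final acquisition (paired, one-tailed):
  gln_area: +6.6% (p = 0.0000)
```

Reading this: 51 rendered tissue samples were quantified. In the acetate
group, FGR brains show the slower lactate turnover built into the generator
(Lac C2/C3 labeled levels down ~20–30% vs AGA littermates, read from the
CTR-referenced HSQC excess), FGR hearts accumulate ~45% more
glycerophosphodiesters (GPC+GPE, from the ³¹P fit), and the paired
initial-vs-final comparison detects the ~10%-per-session glutamine
accumulation drift. Contrasts like the heart pH dip or the glucose-group
lactate total are type-I events at α = 0.05 across ~50 uncorrected tests —
the same trade-off the emulated design makes. Per-sample tables
(`res$quant`, `res$enrichment`, `res$incorporation`, `res$flux_ratios`) hold
the underlying numbers; positional enrichments for glucose-infused AGA brains
average ~8% for Lac C3 and ~4% for Glu C4, inside the expected <10% range.

The numbered drivers under `analysis/` run the same workflow as a narrative:
`01_simulate_cohort.R` (perinatal cohort and manifest), `02_render_quantify.R`
(full pipeline run + example spectra), `03_isotopomer_analysis.R`
(incorporation and enrichment tables), `04_group_comparisons.R` (contrasts,
drift, multi-seed stability), `05_flux_ratios.R` (PC/PDH recovery curve, GS
activity). Each writes its tables under `results/`.

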
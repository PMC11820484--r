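# midflux

Carbon-flux analysis of stable-isotope (U-¹³C-glucose) tracing experiments
in cultured hepatocyte steatosis models, from GC/MS mass isotopomer
distributions (MIDs) to pathway readouts and group statistics.

Steatotic hepatocytes reroute glucose carbon: de novo lipogenesis rises,
pyruvate entry into the TCA cycle shifts between carboxylase and
dehydrogenase routes, and pentose-phosphate activity changes. midflux is
for researchers quantifying those shifts from ¹³C-labeling patterns of
fatty acids, glutamate, glycogen-derived glucose, and RNA ribose measured
by GC/MS selected-ion monitoring, together with the accompanying plate
assays (medium glucose, CCK-8 proliferation, Oil Red O staining).

## What it computes

* **MID handling** — normalization of SIM intensities, natural-isotope
  abundance correction by nonnegative least squares against a per-fragment
  convolution matrix, excess-isotopomer vectors over a baseline.
* **De novo lipogenesis (MIDA)** — a newly synthesized fatty acid is a
  polymer of N acetyl units (palmitate 8; stearate and oleate 9), each
  ¹³C₂-labeled with probability *p*, so the new pool is binomial over even
  mass shifts. The doublet ratio r = E₄/E₂ = ((N−1)/2)·p/(1−p) gives the
  lipogenic acetyl-CoA enrichment in closed form, and
  FNS = E₂ / [C(N,1) p (1−p)^(N−1)] gives the fraction of new synthesis.
  Desaturation (oleate/stearate) and elongation (stearate/palmitate)
  indices are ratios of FNS values.
* **PC/PDH ratio** — from the corrected m2 fractions of the glutamate TAB
  fragments: PC/PDH = m₂(152) / (m₂(198) − m₂(152)).
* **SIGmn** — summed ¹³C molar enrichment Σ n·Mₙ of glycogen-derived
  glucose (6 carbons) and RNA ribose (carbons 1–5).
* **Plate arithmetic** — glucose (mM), per-interval and cumulative
  depletion, proliferation %, ORO fold change.
* **Statistics** — Shapiro–Wilk, one-way ANOVA, Tukey HSD, and a
  direction-of-change summary matrix across the outcome panel.
* **Synthetic studies** — `simulateStudy()` generates complete
  group-structured MID and plate tables from configured truth parameters,
  so every estimator is validated by parameter recovery.

## Worked example

```r
library(midflux)

cfg <- simulationConfig(seed = 42, replicatesPerGroup = 3,
                        midMultiplicativeCv = 0, absorbanceCv = 0)
study <- simulateStudy(cfg)
res <- runPipeline(study)

subset(res$midaGroups, fatty_acid == "palmitate")
#>           group n mean sd fatty_acid p_mean
#> 7       control 3 0.25  0  palmitate   0.19
#> 8         morin 3 0.30  0  palmitate   0.19
#> 9    naringenin 3 0.22  0  palmitate   0.19
#> 10 oa_steatosis 3 0.25  0  palmitate   0.19
#> 11    silibinin 3 0.22  0  palmitate   0.20
#> 12   topiramate 3 0.22  0  palmitate   0.19

res$pcPdhGroups[, c("group", "n", "mean")]
#>          group n      mean
#> 1      control 3 1.3499079
#> 2 oa_steatosis 3 0.9398178
#> 3   naringenin 3 0.8700427
#> 4        morin 3 1.5497310
#> 5   topiramate 3 1.2898551
#> 6    silibinin 3 1.1801937

res$plate$oroFoldChange
#>          group fold_vs_control
#> 1      control             1.0
#> 2        morin             1.6
#> 3   naringenin             1.6
#> 4 oa_steatosis             1.6
#> 5    silibinin             1.3
#> 6   topiramate             1.3
```

Reading: in this noiseless simulated study the pipeline recovers the
configured group truths exactly — acetyl-CoA enrichment 0.19 across arms
(0.20 for silibinin), palmitate FNS elevated in the morin arm, the PC/PDH
ratio depressed in steatosis (0.94 vs control 1.35), and 1.6-/1.3-fold
ORO staining. `res$report$direction` condenses the Tukey tests into an
outcome × group matrix of "increased" / "decreased" / "no change" calls
against the untreated control.

Measured data enter the same way via `readMidTable()` /
`readPlateTable()` (CSV dialects documented on those functions), with
`runPipeline(..., correctNA = FALSE)` for instrument-corrected MIDs.

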
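# labelkin

Kinetic modeling and normalization of stable-isotope cell-labeling
experiments in R.

Stable-isotope labeling with deuterated water (D₂O) or deuterated glucose
(6,6-D₂-glucose) is the standard technique for measuring lymphocyte and
myeloid-cell turnover *in vivo*: label is administered for a period τ,
deuterium is incorporated into the DNA of dividing cells, and the labeled
fraction of DNA in a sorted population is followed through labeling and
washout. Glucose- and water-based studies have historically produced
proliferation estimates differing several-fold. `labelkin` implements the
modeling toolkit needed to analyze both kinds of experiment under a common
framework and to diagnose the main culprit for the discrepancy: unreliable
normalization of DNA enrichment to the precursor availability, especially
for plasma glucose, whose enrichment fluctuates diurnally and is easily
mis-sampled.

The package is aimed at quantitative immunologists and modelers working
with deuterium enrichment time series (plasma, urine, or DNA of named cell
populations, exchanged as CSV).

## What is implemented

**Precursor schedules** — the body-water enrichment curve
U(t) = f(1−e^(−δt)) + βe^(−δt) during labeling with exponential washout
after; the square glucose pulse of height ū (the mean plasma enrichment,
trapezoid rule); a diurnally modulated pulse with its minimum at
mid-scotophase; empirical interpolants. Plus `fit_water_curve()` and
`diurnal_profile()`.

**Kinetic models** (closed-form, verified against a raw-pool numerical
oracle): the kinetic heterogeneity model dF/dt = p·b·U(t) − d\*·F, in which
the disappearance rate of labeled cells d\* need not equal the population
proliferation rate p; the N-component multi-exponential model (2N−1
parameters, AICc order selection); a growing-culture model for in vitro
labeling; a bone-marrow model with fixed maturation delay Δ and blood
turnover d, whose plateau parameter ψ equals 1 exactly when normalization
is correct; a delayed-observation model; and a water-forced granulocyte
model for estimating the water scaling factor b_w.

**Normalization** — conventional glucose (divide by b_g·ū, b_g = 0.65 by
default), reference-population plateau (thymocytes, granulocytes,
monocytes), and fitted b_w. Over-unity values after normalization — the
tell-tale of an underestimated precursor — are flagged, never clipped.

**Fitting** — seeded multi-start bounded least squares
(Levenberg–Marquardt refinement), pooled population/individual fits,
AICc and Akaike-weight model averaging, curvature and bootstrap
confidence intervals, exact two-tailed Mann–Whitney / Wilcoxon
signed-rank comparisons. `fit_kinetics()` returns a classed object with
`print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
`simulate` and `vcov` methods.

**Synthetic studies** — seeded generators mirroring the in vitro dual-label
culture, the cross-sectional two-arm mouse study (including diurnal plasma
glucose fluctuation and a plasma mean that under-reports availability),
and the human 1-day/7-day monocyte and 9-week granulocyte designs, each
storing its ground truth for round-trip testing.

**Pipeline** — `combine_subsets()` (e.g. total CD4 from naïve + memory),
`run_reconciliation()` (the end-to-end normalization-scheme comparison),
and a thin command-line wrapper in `inst/cli/labelkin` with subcommands
`simulate | normalize | fit | select-order | monocyte-plateau | reconcile`.

## Worked example

Simulate a seven-day D₂-glucose mouse study (cross-sectional sacrifice,
3 mice per day, noise SD 0.002), anchor the maximal attainable DNA
enrichment on thymocytes, normalize PBMC and fit the kinetic
heterogeneity model:

```r
library(labelkin)

study <- gen_mouse("glucose", seed = 42)        # truth: p_pbmc = 0.05/day
thy   <- study$series[study$series$population == "thymocytes", ]
plat  <- estimate_reference_plateau(thy, glucose_pulse(1, 7))
round(plat$plateau, 4)
#> [1] 0.0484

pbmc <- study$series[study$series$population == "PBMC", ]
fit  <- fit_kinetics(kinetic_het_model(),
                     normalize_to_plateau(pbmc, plat$plateau),
                     glucose_pulse(1, 7))
fit
#> Labeling-kinetics fit (kinetic_het)
#>   estimates: p = 0.04924, d_star = 0.03853, b = 1
#>   n = 30, free parameters = 2, RSS = 0.04128, AICc = -193.2

bootstrap_ci(fit, n_boot = 200)
#>             lo      hi
#> p      0.04392 0.05488
#> d_star 0.02433 0.05632
#> bootstrap replicates: 200  converged: 100%
```

The fitted plateau (4.84%) recovers the generating label ceiling (4.9%);
the PBMC proliferation estimate 0.049/day recovers the generating truth
0.05/day, with a 95% bootstrap interval of roughly 0.044–0.055. Had we
normalized to b_g × mean plasma enrichment instead (`u_bar` ≈ 0.033 here,
below the ceiling/b_g), the estimate would inflate to ≈ 0.11/day — the
mis-normalization mechanism that `run_reconciliation()` quantifies
side-by-side for both arms and both schemes.

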
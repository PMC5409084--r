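# phiflux

Quantitative analysis of ammonium-prepulse intracellular-pH (pH~i~)
experiments, together with a mechanistic simulator of transporter-driven
pH~i~ regulation that provides ground truth for validating the analysis.

## Who this is for

Labs that measure acid-base transport in cultured cells with
dual-excitation ratiometric dyes (BCECF): the package converts
F495/F440 ratio recordings to pH~i~ through a nigericin high-K+
calibration, quantifies buffering capacity and net base uptake from an
NH4Cl prepulse, extracts resting and plateau pH~i~, and runs the group
statistics used for genotype comparisons. Because such studies depend on
a chain of derived quantities, the package ships a forward model of the
whole experiment so that every analysis stage can be checked against a
known truth.

## The model and the derived quantities

A simulated cell integrates a flux balance

    dpH_i/dt = (J_NBC + J_NHE - J_load) / beta_tot(pH_i)

with linear below-set-point transporter kinetics

    J_NBC = g * a_nbc * max(0, pH_set_nbc - pH_i)   (needs Na+, CO2/HCO3-)
    J_NHE = a_nhe * max(0, pH_set_nhe - pH_i)       (needs Na+, blocked by DMA)

and open-system buffering
`beta_tot = beta_i + ln(10) * c_CO2 * 10^(pH - pK)`. The genotype
multiplier `g` scales Na+/HCO3- co-transport capacity; risk-allele
carriers have `g > 1`. NH4Cl application and washout are instantaneous
NH3-equilibration jumps solved from `beta * dpH = ±[NH4+]_i`, with
`[NH4+]_i` from Henderson-Hasselbalch at pKa 9.2.

The analysis computes, per recording:

* calibration line `ratio = intercept + slope * pH` and its inverse;
* buffering capacity `beta = Delta[NH4+]_i / Delta pH_i` from the washout;
* net base uptake (mmol/L/min) = 15-s regression slope of pH~i~ (per
  minute) x buffering capacity, profiled against pH~i~ in 0.05-pH bins;
* baseline and final plateau pH~i~ as 1-min means;
* the recovery resampled on the common 280-point grid (60-900 s after
  Na+ reintroduction, 3-s spacing);

and, per cohort: repeated-measures two-way ANOVA (genotype x time),
Mann-Whitney U plateau contrasts (exact for combined n <= 16),
least-squares slope comparison of uptake profiles, paired t tests with
Bonferroni correction. A separate module quantifies allelic expression
imbalance from chromatogram peak heights normalized to genomic DNA.

## Worked example

Simulate the default vascular-smooth-muscle cohort (5 risk-allele
carriers, 7 protective homozygotes) under the CO2/HCO3- + DMA protocol
and run the full pipeline:

```r
library(phiflux)
res <- run_pipeline(run_config("vsmc", "co2_dma",
                               n_risk = 5, n_protective = 7, seed = 1))
subset(res$contrast, quantity == "plateau_ph")
#>  condition   quantity mean_risk sem_risk n_risk mean_protective sem_protective
#>    co2_dma plateau_ph     7.189 0.005963      5           7.102       0.004851
#>  n_protective  delta delta_sem
#>             7 0.0874  0.007687
```

The genotype difference in mean plateau pH~i~ is 0.0874 ± 0.0077: the
pipeline recovers the generator's built-in effect (the closed-form
contrast is `0.35 * (1 - 1/1.33) = 0.0868`) through calibration,
conversion, and plateau averaging on noisy traces. The statistics table
reports the corresponding tests:

```r
res$stats
#>              test              effect statistic   df         p     p_adj
#>      mann_whitney    plateau genotype   35.0000   NA 2.525e-03 1.263e-02
#>  rm_two_way_anova      recovery group  124.7301    1 5.723e-07 2.862e-06
#>  rm_two_way_anova       recovery time  169.8128  279 0.000e+00 0.000e+00
#>  rm_two_way_anova recovery group:time    1.7303  279 1.209e-11 6.043e-11
#>  slope_comparison        uptake slope    0.6325 1676 5.271e-01 1.000e+00
```

The exact Mann-Whitney test (U = 35, p = 0.0025) and the ANOVA group
effect both detect the contrast. Allelic imbalance works the same way on
peak-height tables:

```r
q <- simulate_peak_quartets(8, fold = 1.3, noise_cv = 0.1, seed = 2)
imb <- cohort_imbalance(q)
#> geometric mean ratio 1.173, t = 2.10, df = 7, p = 0.0739
```

A thin command-line wrapper over the same functions lives at
`inst/cli/phiflux.R` (verbs `simulate`, `calibrate`, `analyze`,
`compare`, `aei`, `run`).

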
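# adcpk

Pharmacokinetics, biodistribution and efficacy analysis for preclinical
antibody-drug conjugate (ADC) **predose** studies.

ADCs against antigens that are also expressed in normal tissue suffer
target-mediated uptake outside the tumor. A classic mitigation is to
predose unconjugated parental antibody (typically 24 h before the ADC) to
saturate the normal-tissue antigen sink while sparing tumor uptake.
`adcpk` provides the quantitative toolchain such a mouse study needs, for
pharmacologists and pharmacokineticists working with ADC or
radioimmunoconjugate models:

* **Disposition model** — a two-compartment antibody PK model with
  parallel linear and saturable (Michaelis–Menten, i.e. target-mediated)
  clearance, for one or several co-circulating analytes (mAb + ADC),
  solved with a stiff integrator and hard restarts at bolus events:

  $$\frac{dA_1}{dt} = -\frac{CL}{V_1}A_1 - \frac{Q}{V_1}A_1
    + \frac{Q}{V_2}A_2 - \frac{V_m\,C_1}{K_m + C},
  \qquad C_1 = A_1/V_1$$

  with $V_1, V_2$ (mL/kg), $CL, Q$ (mL/kg/day), $V_m$ (µg/day/kg),
  $K_m$ (µg/mL); amounts in µg/kg, time in days.
* **Estimation** — naive-pooled weighted least squares under a
  proportional error model, log-scale multi-start Levenberg–Marquardt,
  asymptotic standard errors, broom-style `tidy()`/`glance()`/`augment()`.
* **Regimens and assays** — predose × ADC study grids (predose at −1 d),
  total-antibody vs conjugated-ADC ELISA semantics, %ID/mL conversions.
* **Biodistribution** — gamma counts → decay-corrected,
  background-subtracted %ID/g, tissue ratios with error propagation, and
  the residualizing (In-111) vs non-residualizing (I-125) internalization
  contrast.
* **Efficacy** — caliper volumes ($V = lw^2/2$), group mean ± SEM with
  censoring at the maximum allowable volume, %TGI.
* **Synthetic data** — seeded generators emulating each study design, so
  every stage has a ground-truth round trip.

All user-facing functions take data frames and return tibbles, so stages
chain naturally with the pipe; `autoplot()`/`plot_*()` give ggplot2
figures for each result type.

## Worked example

Generate a study-shaped multi-dose PK dataset (7 dose levels spanning
0.342–10.5 mg/kg, 10% proportional noise), refit the model, and chase the
downstream analyses:

```r
library(adcpk)

cfg <- synthetic_study_config()          # study-design defaults + seed
pk_data <- generate_pk(cfg, seed = 101)
fit <- pk_fit(pk_data, attr(pk_data, "regimens"),
              init = adc_reference_params(), seed = 101)
fit
#> <pk_fit> proportional-error weighted least squares
#>   126 observations, objective 1.12395, converged
#> # A tibble: 6 × 5
#>   term  estimate std.error rel.std.error unit
#>   <chr>    <dbl>     <dbl>         <dbl> <chr>
#> 1 V1      55.9      1.32          0.0236 mL/kg
#> 2 V2      58.5      2.49          0.0426 mL/kg
#> 3 CL       8.58     0.485         0.0566 mL/kg/day
#> 4 Cld     98.2      9.17          0.0933 mL/kg/day
#> 5 Vm      39.6      2.90          0.0732 ug/day/kg
#> 6 Km       0.158    0.0565        0.358  ug/mL
```

The generating values were (55.5, 58.6, 8.97, 105, 38.1, 0.142); every
estimate lands within a couple of standard errors, and the wide relative
error on `Km` reflects its intrinsically weak identifiability once doses
saturate the target-mediated pathway.

Simulate a 1 mg/kg predose (−24 h) + 1 mg/kg ADC regimen with the fitted
parameters and read it the way the two ELISAs would:

```r
reg <- regimen(dose_event("mAb", -1, 1000), dose_event("ADC", 0, 1000))
sim <- pk_simulate(fit$estimates, reg, times = seq(-1, 7, 0.25))
predict_assay(sim) |> dplyr::filter(time %in% c(0, 3, 7))
#>    time assay          concentration
#> 1     0 conjugated_adc         17.9
#> 2     3 conjugated_adc          6.16
#> 3     7 conjugated_adc          3.99
#> 4     0 total_antibody         25.5
#> 5     3 total_antibody         11.7
#> 6     7 total_antibody          7.56
```

The total-antibody curve exceeds the conjugated-ADC curve by the
circulating residual mAb (7.6 µg/mL at the moment of the ADC dose).
Biodistribution and efficacy follow the same pattern:

```r
bio <- generate_biodist(cfg, seed = 101)
summ <- summarize_biodist(percent_id_per_gram(bio$records, bio$standards))
tissue_ratio(dplyr::filter(summ, isotope == "In-111", timepoint == 3),
             "tumor", "blood")
#>   isotope group timepoint ratio ratio_sd
#> 1 In-111  3d            3  2.00   0.0139

eff <- summarize_groups(generate_efficacy(cfg, seed = 101))
percent_tgi(eff, "ADC 3 mg/kg", "vehicle", day = 28)
#> [1] 92.14331
percent_tgi(eff, "ADC 1 mg/kg", "vehicle", day = 28)
#> [1] 54.62869
```

The 72 h tumor-to-blood ratio of 2 for the residualizing label and the
dose-ordered growth inhibition (92% at the 3 mg/kg-like arm vs 55% at
1 mg/kg) recover the ground truth wired into the generators.

`run_pipeline(study_manifest(...))` chains fit → regimen simulation →
biodistribution → efficacy over CSV/YAML inputs and writes tidy CSV/JSON
outputs; see `?run_pipeline`.

## Further reading

The methods vignette (`vignettes/adc-predose-modelling.Rmd`) documents
the model and its assumptions, the estimation choices, the %ID/g
arithmetic, the synthetic-data generators and their limits, and the
package's numerical decisions.
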
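---
title: "Modelling ADC predose studies: disposition, biodistribution and efficacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ADC predose studies: disposition, biodistribution and efficacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(adcpk)
library(dplyr)
```

## The problem

Antibody-drug conjugates (ADCs) against targets that are also expressed in
normal tissue face an antigen "sink": target-mediated uptake outside the
tumor both drains drug and exposes healthy tissue to the payload. One
mitigation is *predosing* — giving unconjugated parental antibody
(typically 24 h before the ADC) to saturate the normal-tissue sink while
leaving enough accessible antigen in the tumor. Evaluating this strategy
in mice requires four quantitative pieces, all covered by this package:

1. a disposition model for the antibody that captures the saturable,
   target-mediated clearance pathway (`tmdd_rhs()`, `pk_simulate()`);
2. estimation of that model's parameters from multi-dose
   concentration–time data (`pk_fit()`);
3. dose-normalised tissue uptake from gamma counting, `%ID/g`
   (`percent_id_per_gram()` and friends); and
4. tumor-growth-inhibition summaries from caliper data
   (`tumor_volume()`, `summarize_groups()`, `percent_tgi()`).

A seeded synthetic-data generator (`generate_pk()`, `generate_biodist()`,
`generate_efficacy()`) emulates the study designs so the entire pipeline
is testable without animal data.

## The disposition model

Drug amount (µg/kg body weight) is tracked in a central compartment
(volume $V_1$, mL/kg) exchanging with a peripheral compartment ($V_2$)
at distributional clearance $Q$ (`Cld`). Elimination from the central
compartment is the sum of a linear pathway (clearance $CL$) and a
saturable Michaelis–Menten pathway representing target-mediated
disposition (TMDD): maximal rate $V_m$ (µg/day/kg) and half-saturation
concentration $K_m$ (µg/mL). For analyte $i$ with central concentration
$C_i = A_{1,i}/V_1$:

$$
\frac{dA_{1,i}}{dt} = -\frac{CL}{V_1}A_{1,i} - \frac{Q}{V_1}A_{1,i}
  + \frac{Q}{V_2}A_{2,i} - \frac{V_m\,C_i}{K_m + C_{\mathrm{drv}}},
\qquad
\frac{dA_{2,i}}{dt} = \frac{Q}{V_1}A_{1,i} - \frac{Q}{V_2}A_{2,i}.
$$

This is the standard two-compartment disposition model with parallel
linear and Michaelis–Menten elimination; it is the unique structure
consistent with a parameter set expressed as
(V1, V2, CL, Cld, Vm, Km) in the units above. Doses are IV boluses that
add `dose` µg/kg to $A_1$ instantaneously; times are in days, and event
times may be negative (a predose at $-24$ h is `time = -1`).

**Multi-analyte coupling.** When unconjugated mAb and ADC co-circulate,
both bind the same target. Under the default `coupling = "shared"`, the
saturable pathway is driven by the *total* central concentration
($C_{\mathrm{drv}} = \sum_j C_j$) and each analyte is eliminated in
proportion to its own concentration — the two species compete for one
capacity-limited pathway, which is the mechanistically sensible choice
for a predose study and the reason predosing spares tracer from the sink.
`coupling = "independent"` ($C_{\mathrm{drv}} = C_i$) is available both
as a comparison and because it makes each analyte's curve exactly the
single-analyte solution (useful for decomposition identities). With one
analyte the two modes coincide. Since the contribution of predosed mAb to
total-antibody curves can be simulated either way and the study data do
not discriminate between them, we default to the shared pathway and
expose the switch.

**Numerics.** The system is stiff when concentrations transition through
$K_m$, so it is integrated with `lsoda` (adaptive stiff/non-stiff
switching, the counterpart of MATLAB's `ode15s`) with a *hard restart at
every bolus event*: the state is discontinuous there, and restarting the
integrator is more robust than letting the step-size controller discover
the jump. Defaults `rtol = 1e-8`, `atol = 1e-10`; the value reported *at*
an event time is the post-dose state. Trace negative amounts from solver
round-off are clipped to zero on output only — never in the state fed
back to the solver, which would break mass balance. Each analyte also
carries a cumulative-elimination state so `mass_balance()` can audit
`dose = A1 + A2 + eliminated` at every output time; the test suite holds
this to 0.1% across randomised parameter draws.

The right-hand side is implemented once in C (`src/tmdd.c`) for speed —
fitting evaluates it tens of thousands of times — and once in plain R;
a test pins the two against each other.

## Parameter estimation

`pk_fit()` performs naive-pooled weighted least squares under a
proportional (constant-CV) error model:

$$
\hat\theta = \arg\min_\theta \sum_k
  \left(\frac{y_k - f_k(\theta)}{f_k(\theta)}\right)^2 .
$$

Choices that matter, and why:

* **Prediction-weighted residuals.** The denominator is the model
  prediction, not the observation — the standard PK choice, which keeps
  near-zero observations from exploding the objective.
* **Log-scale optimisation, multi-start.** All six parameters are
  positive and $K_m$ can span orders of magnitude, so optimisation runs
  on $\log\theta$ (box $[-25, 25]$) by Levenberg–Marquardt
  (`minpack.lm::nls.lm`). Five starts by default: the supplied `init`
  plus four jittered by independent factors uniform on $[0.5, 1.5]$,
  seeded explicitly (`seed` is an argument of every stochastic routine in
  the package; default 1234).
* **One solver call per objective evaluation.** Dose groups are
  independent animal sets, so they are stacked as independent analytes of
  a single ODE system and solved together.
* **Standard errors** come from the asymptotic covariance
  $\hat\sigma^2 (J^\top J)^{-1}$ of the log-parameters at the optimum
  (forward-difference Jacobian), mapped to natural scale by the delta
  method. A parameter is flagged `poorly_identified` when its SE exceeds
  the estimate, when its Jacobian column is numerically null, or when the
  optimiser pinned it to the box — the latter two catch the
  single-dose-saturated design where $K_m$ collapses to a boundary with a
  deceptively small SE.
* **Design sensitivity.** With data from a single dose level deep in the
  saturated regime, $V_m$ and $K_m$ trade off against $CL$;
  the fit warns when fewer than two distinct dose levels are supplied.

The estimation-error bars of the reference parameter set
(`adc_reference_params()`) already tell the identifiability story: the
printed relative error is about 2% for $V_1$ but ~68% for $K_m$, whose
half-saturation concentration (0.142 µg/mL) sits below most observed
concentrations at therapeutic doses.

## Assay semantics

Serum exposure in predose studies is read by two ELISAs:
*total antibody* (detects mAb and ADC alike) and *conjugated ADC*
(detects only antibody still carrying drug). `predict_assay()` maps a
simulation onto these: the total curve is the sum of central
concentrations, the conjugated curve is the ADC analyte alone. Under
independent coupling, total minus conjugated is exactly the mAb-only
simulation; under shared coupling the difference reflects competition
(the acceptance suite checks the combined totals are bracketed by the
nonlinear superposition from below and the $V_m = 0$ linear
superposition from above). Deconjugation (DAR loss) is out of scope, so
the ADC analyte means "total-antibody-equivalent concentration of dosed
conjugate".

Blood concentrations convert to dose-normalised form with
`percent_id_per_ml()`; absolute injected amounts use the regimen's body
weight, defaulting to 0.0275 kg (midpoint of the 25–30 g mice used in
these studies) when none is recorded.

## Biodistribution

`percent_id_per_gram()` implements the classical cut-and-count pipeline:
background subtraction, decay correction, normalisation to a
dosing-solution standard representing the full injected dose, division
by wet tissue mass:

$$
\%ID/g = \frac{(\text{counts} - \text{bg})\,2^{\Delta t / T_{1/2}}}
  {(\text{std} - \text{std}_{bg})\,2^{\Delta t_{std} / T_{1/2}}}
  \cdot \frac{100}{\text{mass}} .
$$

Both sample and standard are corrected to the injection instant, so the
reference time drops out of the ratio when they are counted together.
Half-lives default to the physical constants (In-111: 2.805 d, I-125:
59.4 d) and are overridable. Negative net counts after background
subtraction are clipped to zero with a warning (they are counting noise);
a non-positive *standard* is an error because nothing can be normalised.
Dual-isotope spillover between counting windows is assumed resolved by
the counter.

The two labels carry complementary information: In-111-DOTA catabolites
residualize inside cells after the antibody is degraded, while I-125
(tyrosine-iodinated) does not, so the In-111 − I-125 contrast
(`residualization_contrast()`) indexes internalization and catabolism.
`tissue_ratio()` reports tumor/blood-type ratios with first-order error
propagation, validated against a Monte-Carlo oracle in the tests.

## Efficacy

Caliper measurements convert to volume by the ellipsoid rule
$V = l w^2/2$; records with width exceeding length are auto-swapped with
a warning. Group curves are mean ± SEM. Animals reaching the maximum
allowable volume (default 3000 mm³) are excluded from subsequent
summaries with the censoring day recorded — no carry-forward imputation,
matching the usual presentation of xenograft growth curves (the
alternative, carrying the last value forward, would bias late control
means downward in the opposite way; exclusion at least is explicit).
`percent_tgi()` is provided as a convenience metric, defined as the
baseline-anchored delta ratio
$100\,(1 - \Delta V_t / \Delta V_c)$; when the control arm regresses the
metric is undefined and returns `NA` with a warning rather than a
misleading number.

## The synthetic-data generators

The generators emulate the *shape* of the study, not its biology:

* **PK** (`generate_pk()`): model predictions at seven dose levels
  spanning 0.342–10.5 mg/kg, sample times {0.02, 0.25, 1, 2, 4, 7} days,
  multiplied by $(1+\varepsilon)$, $\varepsilon \sim N(0, cv)$ with
  $cv = 0.10$ and redrawn where $1+\varepsilon \le 0$; $n = 3$ replicates
  per point. Optional dense early sampling (0.05, 0.1 d) at the lowest
  dose levels sharpens the saturable-pathway information.
* **Biodistribution** (`generate_biodist()`): Poisson counts around
  truth × mass × standard × decay, plus Poisson background; the default
  truth table echoes the blood/tumor/spleen/muscle pattern of a
  dual-isotope study, including a 72 h In-111 tumor/blood ratio of 2.
* **Efficacy** (`generate_efficacy()`): lognormal baselines around
  250 ± 30 mm³, exponential growth at 0.09/day (a doubling time of about
  a week, which carries a control arm from 250 mm³ to the 3000 mm³ limit
  over the 28-day window), and a one-off multiplicative kill per arm
  (defaults 0.55 / 0.85 for the 1 / 3 mg/kg-like arms). This is
  explicitly a *fixture* model — a labelled stand-in, not a
  pharmacodynamic model: no exposure–response link is claimed, and
  passing ordering tests says nothing about real dose–response beyond
  monotonicity of the pipeline.

All generators are pure functions of (config, seed). What the synthetic
data do *not* emulate: between-animal PK variability (the noise is
residual-only, matching the naive-pooled estimator), assay
quantification limits, isotope crosstalk, tumor heterogeneity and the
binding-site-barrier spatial effects discussed for high-expressing
models. Parameter-recovery results on these fixtures therefore
demonstrate correctness of the estimator under its own assumptions, not
robustness to model misspecification.

## Problem sizes and test design

The recovery experiments used in the tests and in
`scripts/acceptance.R` run 20 seeded replicates of the 7-dose design
(126–144 observations each) and refit each with the default 5-start
optimiser; a replicate takes well under a second thanks to the compiled
right-hand side, and medians over replicates are compared against the
generating values. Property suites use 20–100 randomised parameter draws.
These sizes were chosen to make the stochastic checks reproducible and
sharp at interactive time scales.

## Known limitations

* Naive-pooled estimation only; no mixed-effects, no Bayesian posterior.
* Single dosed species per group during fitting (assay curves may still
  contain multiple simulated analytes).
* IV bolus only; no infusion or oral absorption.
* The Michaelis–Menten approximation of TMDD: no explicit receptor pool,
  binding kinetics or internalization compartments, hence no way to
  represent receptor occupancy directly.
* `%ID/g` treats blood as a tissue with measured mass; the per-mL view
  assumes unit density.
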
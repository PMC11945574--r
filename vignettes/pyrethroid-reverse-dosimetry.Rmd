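---
title: "Reverse dosimetry and risk assessment for pyrethroids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse dosimetry and risk assessment for pyrethroids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyredose)
```

This vignette is the package's account of its science: the models, the
priors, the numerical choices, and — just as importantly — what the
synthetic validation does and does not demonstrate about real survey
data.

## The problem

Urinary biomonitoring surveys report pyrethroid metabolites
(3PBA, FPBA, DBCA, cis-/trans-DCCA) in spot samples, left-censored at
limits of detection that differ by metabolite and survey cycle. The
quantities of regulatory interest are upstream: daily intakes of the
parent compounds, and margins between those intakes (or the internal
doses they produce) and toxicological points of departure. The package
treats this as four linked problems: reverse dosimetry, benchmark-dose
estimation, systemic point-of-departure simulation, and margin
computation.

## Chemical registry

Parent compounds are isomer-resolved (cis/trans), grouped by parent
(permethrin = 40% cis + 60% trans, the commercial split, applied also
to cypermethrin and cyfluthrin as a documented default). The molar
transformation fraction `phi(p→m)` is the fraction of an absorbed
parent dose ultimately excreted in urine as metabolite `m`; row sums
never exceed 1, the remainder being other elimination. FPBA maps only
to cyfluthrin and DBCA only to deltamethrin, so these are
compound-specific biomarkers; 3PBA and the DCCAs are shared. Two
unmeasured downstream metabolite slots are carried in the registry (and
excluded from all likelihoods) so that further-metabolism sensitivity
analyses remain expressible — continued metabolism of a "terminal"
biomarker would otherwise silently bias intakes downward.

The shipped `phi` values, molar masses, and the cypermethrin:permethrin
intake ratio of 0.1 are package defaults representative of the human
excretion-fraction literature; all are overridable through the CSV
registry interface, and no claim is made that they reproduce any
specific published parameter table.

## The kinetic model and its steady-state reduction

The compartmental model has a gut lumen with competing first-order
absorption (`ka`) and fecal elimination (`kf`), flow-limited liver,
fat, richly and slowly perfused tissues, a permeability-limited brain,
and plasma. Hepatic clearance acts on the unbound liver venous
concentration; each metabolite formed enters a one-compartment pool
cleared into urine with a ~12 h half-life. Brain uptake is driven by
the *unbound* plasma concentration (equilibrium
`C_brain = fup · P_brain · C_plasma`), which is the standard
permeability-limited form and the only one in which the unbound
fraction is a first-order sensitivity for brain dose — consistent with
published sensitivity rankings for this model family.

At steady state under constant intake, every absorbed parent molecule
is metabolized, a fraction `phi` appears in urine as each metabolite,
and all kinetic detail cancels:

$$C_m = \sum_p D_p \, BW \, \frac{k_a}{k_a + k_f}
        \, \phi_{pm} \, \frac{MW_m}{MW_p} \, / \, V_{urine}.$$

The package uses this analytical map for all inference (it is linear
in the intakes and costs nothing per MCMC step) and keeps the ODE for
forward simulation, dose metrics, and validation. The central internal
oracle — verified in the test suite over 50 random parameter draws —
is that the ODE's terminal urinary excretion rate under constant
dosing matches the analytical map to within 1% (observed agreement is
better than 0.01%). Solver: `deSolve::lsoda` at `rtol = 1e-8`,
`atol = 1e-10`; parent mass balance is checked on every simulated
course. Steady-state concentrations can be normalized by daily urine
volume (ng/mL) or daily creatinine (µg/g); both are implemented and
config-selected, since survey practice varies.

## Bayesian population model

Per stratum (compound group × age group × cycle, estimated
independently because that is how results are reported and compared):

* individual log intake $z_i \sim N(\mu, \sigma_{pop}^2)$;
* detected record: $\log C_{im} \sim N(\log \hat C_{im}(z_i),
  \sigma_{res}^2)$;
* non-detect: $N(\text{policy value} \mid \hat C_{im}(z_i),
  \text{LOD}/4)$ with the policy value 0 or LOD/2 — two selectable
  policies run as a sensitivity pair, not a hybrid, because they give
  deliberately different inferences for non-detects. `half_lod` is the
  default; the ±2 SD window of that density spans (0, LOD), so it acts
  as a soft censoring window;
* priors: $\mu$ uniform on log10 intake over [−12, 0] mg/kg/day
  (placed on the log scale — a natural-scale uniform over 12 decades
  would concentrate essentially all prior mass at the top decade and
  be anything but non-informative); $\sigma_{pop}^2 \sim$
  inverse-gamma(shape 5.0, scale 2.25), prior-mean variance 0.5625,
  i.e. a GSD near 2; $\sigma_{res}^2 \sim$ half-normal(SD 0.3),
  corresponding to a residual GSD of $\exp\sqrt{0.3} \approx 1.7$.

Body weight enters per individual where the table provides it, the
age-group mean otherwise. Cypermethrin, which lacks a specific
biomarker, is tied to permethrin by the configurable 0.1 intake ratio
rather than estimated.

### Sampler design

With one record per subject, $\sigma_{pop}$ and $\sigma_{res}$ are
identified only jointly (the data constrain their sum) and a naive
latent-variable Gibbs sampler stalls on that ridge. Two samplers are
used:

* **Single compound group** (the common case for specific biomarkers):
  subjects whose records are all detected have an exactly Gaussian
  marginal likelihood after integrating the latent intake out
  analytically; only subjects with a censored record keep an explicit
  latent. The population median is conjugate (truncated normal), the
  two variances move by a joint log-scale random walk, and an
  exchange move trades residual against population variance at
  constant total — along which the single-record marginal is exactly
  invariant — so the ridge is traversed freely. Split-R̂ is routinely
  below 1.05 within 3,000 iterations.
* **Several coupled groups** (shared metabolites such as 3PBA):
  adaptive Metropolis-within-Gibbs over the latent intake matrix with
  conjugate population updates, plus group translation, dispersion
  rescale, and variance-exchange moves. This sampler needs longer
  chains (the analysis drivers use 8,000 iterations).

Three chains by default; convergence is assessed by split-R̂ below 1.1
on every parameter, with effective sample sizes reported. All seeds
are explicit; identical seeds give bit-identical draws.

### The high-throughput comparator

The simplified estimator fits a censored lognormal to the urine
concentrations by maximum likelihood (via `fitdistrplus::fitdistcens`),
verifies the fit against the empirical CDF (reported as the maximum
gap on the full-population scale), and inverts the steady-state map at
complete absorption, apportioning shared metabolites across parents by
supplied attribution fractions. On uncensored, noise-free synthetic
data it agrees with the full Bayesian estimator within a factor of two
(test-verified); on realistic data it sits lower, mainly through the
complete-absorption assumption.

## Benchmark-dose analysis

Continuous dose-response summaries (dose, n, mean, SD) are fit with
the standard eight-family continuous menu: linear, 2nd-order
polynomial, power, Hill, and exponential models 2–5. The likelihood
uses the group sufficient statistics under a common residual SD;
priors are wide normals on the sampling scale ("non-informative" in
the operational sense that the data dominate), with power/shape
exponents restricted to [1, 18] — the conventional guard against
supralinear low-dose extrapolation. The benchmark response is a shift
of the mean equal to one control SD (implemented as a shift using the
modeled residual SD, the common default), in the adverse direction
inferred from the overall trend (decreasing locomotor activity is
adverse). The BMD is solved per posterior draw by root finding; draws
beyond the tested dose range flag the fit as effectively unbounded
(flat response).

Posterior model weights come from a Laplace–Metropolis approximation
of each model's marginal likelihood (posterior mode plus the
determinant of the draw covariance). This was chosen over a
stabilized harmonic mean after the latter proved too noisy for 8-way
averaging at practical iteration counts; Laplace–Metropolis is smooth,
cheap, and adequate for weighting nested/non-nested families of 3–5
parameters. Non-converged fits (split-R̂ ≥ 1.1) are excluded from the
average with a warning. The averaged posterior is the weight-mixture
of per-model BMD posteriors; BMD is its median and BMDL its 5th
percentile (one-sided 95% lower bound, the regulatory convention).
On noise-free linear data the averaged BMD recovers the closed form
SD/|slope| within 5% (test-verified).

## Margins of exposure

External MOE divides the BMDL by the intake estimate; internal MOIE
divides a rat-model dose metric at the BMDL dose (Cmax or AUC in
plasma or brain) by the Monte Carlo distribution of the same metric in
the human model at the estimated exposure. Which exposure summary
feeds the margin is a config switch (GM, P95, or the conservative P99
"top-1%" convention, the default in the pipeline); both median and 5th
percentile of the margin are reported, and the acceptability flag
compares the 5th percentile to the target margin (default 100 from the
usual 10×10 factors; regulatory comparisons for these compounds
typically use 10⁴, so the threshold is configurable and logged).

A caveat the package states plainly: when one chemical parameter set
is scaled allometrically between rat and human — as here, where no
species-specific calibration is bundled — the rat produces *lower*
internal doses per mg/kg than the human (smaller animals clear faster
per kilogram), so MOIE sits below MOE. Reversing that ordering
requires independently calibrated rat and human parameterizations.
Users supplying their own calibrated parameter sets get whichever
ordering those parameters imply; the package does not tune kinetic
constants to force either outcome.

## The synthetic-data generator

The generator is the population model run forward, and its defaults
define the validation conditions:

* 7 biennial cycles, 5 age groups, 5 measured metabolites; cis-DCCA
  leaves the panel after the third cycle and DBCA after the fourth,
  mimicking survey panel shrinkage;
* per-cycle LODs placed so first-cycle adult detection approximates
  the reported survey pattern (3PBA ≈ 70%, trans-DCCA ≈ 16%,
  cis-DCCA ≈ 25%, FPBA ≈ 6%, DBCA ≈ 1.5%), with LODs falling and
  intakes rising (~12% per cycle, about two-fold across the design)
  so detection improves over time;
* intakes lognormal with GSD 2 and children at roughly twice the
  adult level; body weights lognormal around age-group references;
  multiplicative residual GSD 1.7 on concentrations.

Recovery studies in the test suite use a single stratum of n = 500
with the LOD at the 30th percentile of the concentration distribution
and a generating intake of 10⁻⁵ mg/kg/day; across 20 replicates the
posterior median stays within ±0.3 log10 units (typically ±0.05), all
split-R̂ below 1.1, and the 90% credible interval covers the truth in
at least 80% of replicates. These sizes keep the default validation
run inside a few minutes on one CPU; they are stated here because any
reader scaling them up should expect the same behaviour, only slower.

What the generator does *not* emulate — and therefore what passing
tests do not demonstrate about real data: within-day spot-sample
timing variability (concentrations of short-half-life compounds peak
two- to three-fold above the daily average; an optional multiplicative
peak-factor term exists but is off by default), hydration and
creatinine variation beyond the fixed per-group values, survey
weights and complex sampling design (a weight column is accepted but
defaults to 1; no design-based estimation is attempted), assay
changes across cycles beyond the LOD, and real exposure episodicity —
the steady-state assumption itself. Observed P95/P50 ratios in real
surveys (up to ~20) exceed what the generator's GSD-2 intakes plus
GSD-1.7 residual produce (~3–5), and that gap is precisely the
spot-sampling variability the model does not claim to capture.

## Numerical choices and degenerate inputs

* Quantiles use linear interpolation between order statistics
  (type 7) throughout; P95/P50 on small strata is sensitive to this
  choice, so it is fixed and stated. A floor of 20 observations
  applies.
* Censored descriptive statistics substitute LOD/√2 by default
  (LOD/2 and 0 as options); inference never substitutes — it uses the
  censored likelihood.
* Split-R̂ on constant chains is defined as 1 (zero-variance guard).
* An all-censored stratum yields a flagged bound-only result from the
  censored-lognormal fit (geometric-mean LOD as the upper bound), and
  an all-censored cycle in the trend report carries its LOD bound
  with a flag rather than a fabricated GM.
* The BMD search interval is capped at 100× the top dose; draws at
  the cap are reported in `unbounded_frac` rather than silently
  truncated into a finite-looking posterior.
* Age-group similarity clustering uses Euclidean distance on log10
  medians with average linkage — a deterministic, column-permutation-
  invariant choice made explicit because the clustering method is
  otherwise an easy source of irreproducibility.

## Known limitations

Dermal and inhalation routes are simulatable forward but not used in
reconstruction. No in-vitro-to-in-vivo extrapolation of clearances, no
cumulative multi-compound risk index, no survey-weighted estimation.
The shipped kinetic parameters are literature-representative defaults,
not a calibrated reproduction of any specific published
parameterization, and conclusions that hinge on species-specific
kinetics (notably the MOE/MOIE ordering) follow the supplied
parameters.
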
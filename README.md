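# pyredose

Biomonitoring-based reverse dosimetry and acute-neurotoxicity risk
assessment for pyrethroid insecticides, in R.

Population surveys measure pyrethroid exposure indirectly, as urinary
metabolite concentrations (3PBA, FPBA, DBCA, cis-/trans-DCCA) that are
heavily left-censored at assay- and cycle-specific limits of detection
(LOD). Regulators need the quantity those surveys do not report: the
daily intake of the parent compounds (deltamethrin, permethrin,
cypermethrin, cyfluthrin), and ultimately the margin between that
intake and a toxicological point of departure. `pyredose` implements
the full chain for exposure scientists and risk assessors:

1. **Steady-state PBK reverse dosimetry.** Under constant daily intake
   the kinetic model reduces to a linear map from intake to urinary
   metabolite concentration,

   `C_m = sum_p D_p · BW · f_abs,p · phi(p→m) · (MW_m / MW_p) / V_urine`,

   where `D_p` is the intake of parent `p` (mg/kg/day), `f_abs` its
   absorbed oral fraction, `phi(p→m)` the molar fraction excreted in
   urine as metabolite `m`, and `V_urine` the daily urine output
   (creatinine normalization is the config-selected alternative).
2. **Bayesian population inference** on that map: individual log
   intakes are lognormal with population median and variance;
   detected observations get a lognormal likelihood, non-detects a
   Normal(policy value | prediction, LOD/4) likelihood with the policy
   value set to 0 or LOD/2; priors are uniform on log10 intake over
   [−12, 0] mg/kg/day, inverse-gamma(5.0, 2.25) on the population
   log-variance, and half-normal(0.3) on the residual log-variance
   (a residual GSD of about 1.7). Three chains, split-R̂ convergence.
   A simplified high-throughput comparator (censored-lognormal MLE of
   the urine distribution, inverted through the same map at complete
   absorption) is included.
3. **Bayesian benchmark-dose analysis** of continuous locomotor-
   activity data: eight standard families fit by MCMC, a benchmark
   response of one control SD, and model averaging by posterior model
   weights; BMDL is the 5th percentile of the averaged posterior.
4. **Margins of exposure.** External MOE = BMDL / intake; internal
   MOIE = rat-model dose metric at the BMDL dose (Cmax or AUC, plasma
   or brain) divided by the Monte Carlo distribution of the same
   metric in the life-stage human model.

A full compartmental PBK model (gut, liver, fat, brain
(permeability-limited), richly/slowly perfused tissues, plasma,
metabolite pools) backs the steady-state map; the two agree to well
under 1% at steady state, which the test suite verifies over random
parameter draws. A synthetic-survey generator with known ground truth
(per-cycle LODs, shrinking metabolite panels, lognormal intakes and
body weights) drives all validation.

## Worked example

Forward map — what urine concentrations does a child's intake imply?

```r
library(pyredose)
reg  <- default_registry()
conc <- steady_state_urine(
  c(`cis-permethrin` = 2e-5, `trans-permethrin` = 3e-5,
    deltamethrin = 1e-6),                      # mg/kg/day
  reg, physiology = default_physiology("6-11"))
round(conc, 4)
#>       3PBA       FPBA       DBCA   cis-DCCA trans-DCCA
#>     0.2486     0.0000     0.0052     0.0933     0.2427   # ng/mL
```

Inverse problem — recover a population intake from a censored survey
and compute the margin of exposure:

```r
truth <- generator_truth(
  intakes = data.frame(compound = "deltamethrin", age_group = "20-65",
                       cycle = "2015-2016", gm = 1e-5, gsd = 2),
  lods = data.frame(metabolite = "DBCA", cycle = "2015-2016", lod = 0.1),
  n_per_stratum = 400, residual_gsd = 1.7, seed = 7)
tab  <- generate_survey(truth, reg)            # 70.5% below the LOD
post <- sample_posterior(tab, reg, chains = 3, iterations = 3000,
                         seed = 21)
post$summary[, c("compound", "log10_intake_med", "gsd_pop", "rhat_max")]
#>      compound log10_intake_med  gsd_pop rhat_max
#>  deltamethrin        -5.104941 1.306627 1.027307
compute_moe(1.79, 10^post$summary$log10_intake_med, target = 1e4)
#> <MOE> median 2.279e+05, P05 2.279e+05, target 1e+04 (acceptable)
```

Despite 70% censoring, the posterior median lands within 0.11 log10
units of the generating intake (10⁻⁵ mg/kg/day), and the margin
against the deltamethrin BMDL of 1.79 mg/kg clears the 10⁴
acceptability threshold by more than an order of magnitude.

## Analysis workflow

The `analysis/` scripts run the four stages over the default synthetic
scenario and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_survey.R` | generate the 7-cycle survey; detection rates, 3PBA trend, P95/P50, age-group clustering |
| `02_reverse_dosimetry.R` | Bayesian intake reconstruction per stratum; high-throughput comparator |
| `03_bmd.R` | eight-model Bayesian BMD averaging on synthetic locomotor-activity data with known BMD |
| `04_risk.R` | MOE and MOIE distributions per compound; risk table |

Each script is a thin driver over the package functions; run them in
order from the repository root with `Rscript`.

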
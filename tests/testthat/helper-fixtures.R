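# Shared fixtures: a minimal one-compound/one-metabolite registry with
# round numbers, a 70 kg reference adult, and a single-stratum survey
# generator with the LOD placed at a chosen quantile of the true
# concentration distribution.

mini_registry <- function(phi = 0.4) {
  pyre_registry(
    data.frame(id = "deltamethrin", molar_mass = 505.2,
               parent_group = "deltamethrin", isomer_fraction = 1),
    data.frame(id = c("3PBA", "FPBA", "DBCA", "cis-DCCA", "trans-DCCA"),
               molar_mass = c(214.2, 232.2, 298.0, 209.1, 209.1),
               measured = TRUE),
    if (phi > 0)
      data.frame(compound = "deltamethrin", metabolite = "DBCA",
                 phi = phi)
    else
      data.frame(compound = character(), metabolite = character(),
                 phi = numeric())
  )
}

adult70 <- function() {
  p <- default_physiology("20-65", body_weight = 70)
  p$daily_urine_volume <- 1.5
  p
}

# Single-stratum deltamethrin/DBCA survey; LOD at the cens_q quantile of
# the marginal concentration distribution so the expected censoring
# fraction equals cens_q.
recovery_survey <- function(n = 500, log10_gm = -5, gsd = 2,
                            residual_gsd = 1.7, cens_q = 0.3, seed = 1) {
  reg <- default_registry()
  phys <- default_physiology("20-65")
  co <- steady_state_coefficients(reg, NULL, phys)["deltamethrin", "DBCA"]
  ref <- physiology_table()
  bw_gsd <- ref$bw_gsd[ref$age_group == "20-65"]
  ## marginal log-scale spread of the concentration: intake, body
  ## weight and residual act multiplicatively
  sig <- sqrt(log(gsd)^2 + log(bw_gsd)^2 + log(residual_gsd)^2)
  lod <- co * 10^log10_gm * exp(stats::qnorm(cens_q) * sig)
  truth <- generator_truth(
    intakes = data.frame(compound = "deltamethrin", age_group = "20-65",
                         cycle = "1999-2000", gm = 10^log10_gm,
                         gsd = gsd),
    lods = data.frame(metabolite = "DBCA", cycle = "1999-2000",
                      lod = lod),
    n_per_stratum = n, residual_gsd = residual_gsd, seed = seed)
  generate_survey(truth, reg)
}
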
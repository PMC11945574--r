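# A well-stirred reduction of the compartmental model: all partition
# coefficients 1 and very large tissue flows make the whole body one
# compartment of volume V_tot, with first-order elimination
# k = CL_met * fup / V_tot. Bolus and first-order-absorption closed
# forms then provide independent oracles.
wellstirred_setup <- function(cl_k, fup = 1) {
  phys <- default_physiology("20-65", body_weight = 70)
  phys$flows <- phys$flows * 0 + 1e6
  vtot <- sum(phys$volumes)
  prm <- pbk_params("deltamethrin", ka = 1, kf = 0, fup = fup,
                    cl_met = cl_k * vtot / fup, pa_brain = 1e6,
                    partition = c(liver = 1, brain = 1, fat = 1,
                                  rich = 1, slow = 1))
  list(phys = phys, prm = prm, vtot = vtot)
}

test_that("zero dose gives identically zero concentrations", {
  tc <- simulate_timecourse(default_pbk_params(), default_physiology(),
                            dosing_schedule("oral"), default_registry(),
                            duration = 12)
  expect_true(all(abs(as.matrix(tc$series[-1])) < 1e-12))
})

test_that("well-stirred bolus matches the one-compartment closed form", {
  k <- 0.2
  ws <- wellstirred_setup(k)
  D <- 1  # mg/kg
  tc <- simulate_timecourse(
    ws$prm, ws$phys,
    dosing_schedule("inhalation", events = data.frame(time = 0, dose = D)),
    default_registry(), duration = 24, dt = 0.05)
  s <- tc$series[tc$series$time > 0.2, ]  # past flow equilibration
  expected <- D * 70 / ws$vtot * exp(-k * s$time) * 1000
  expect_lt(max(abs(s$plasma / expected - 1)), 1e-3)
})

test_that("oral absorption follows the Bateman solution at the peak", {
  ka <- 1; ke <- 0.1
  ws <- wellstirred_setup(ke)
  D <- 1
  tc <- simulate_timecourse(
    ws$prm, ws$phys,
    dosing_schedule("oral", events = data.frame(time = 0, dose = D)),
    default_registry(), duration = 48, dt = 0.02)
  dm <- dose_metrics(tc)
  tmax <- log(ka / ke) / (ka - ke)
  cmax_exp <- D * 70 * ka / (ws$vtot * (ka - ke)) *
    (exp(-ke * tmax) - exp(-ka * tmax)) * 1000
  expect_lt(abs(dm$cmax_plasma / cmax_exp - 1), 0.005)
})

test_that("constant dosing converges to the analytical steady state", {
  reg <- default_registry()
  phys <- default_physiology("20-65", body_weight = 70)
  prm <- default_pbk_params("deltamethrin")
  tc <- simulate_timecourse(prm, phys, dosing_schedule("oral", rate = 1e-3),
                            reg, duration = 24 * 40, dt = 1)
  s <- tc$series
  ss <- steady_state_urine(c(deltamethrin = 1e-3), reg,
                           list(deltamethrin = prm), phys,
                           metabolites = tc$metabolites)
  nlast <- nrow(s)
  for (m in tc$metabolites) {
    u <- s[[paste0("urine_", m)]]
    rate24 <- u[nlast] - u[nlast - 24]   # mg/day over the final day
    conc <- rate24 / phys$daily_urine_volume * 1000
    expect_lt(abs(conc / ss[m] - 1), 0.01)
  }
})

test_that("mass balance holds to within solver tolerance", {
  tc <- simulate_timecourse(
    default_pbk_params(), default_physiology(),
    dosing_schedule("oral", events = data.frame(time = 0, dose = 2)),
    default_registry(), duration = 72, rtol = 1e-8, atol = 1e-10)
  expect_lt(tc$balance_gap / tc$dosed_mg, 1e-7)
})

test_that("steady-state map reproduces the worked arithmetic chain", {
  reg <- mini_registry(phi = 0.4)
  ## use the 3PBA molar-mass pair of the worked example
  reg$matrix$metabolite <- "3PBA"
  reg <- validate_registry(reg)
  prm <- list(deltamethrin = pbk_params("deltamethrin", ka = 1, kf = 0))
  conc <- steady_state_urine(c(deltamethrin = 1e-3), reg, prm, adult70())
  expect_equal(round(conc[["3PBA"]], 2), 7.91)
  ## zero intake
  expect_true(all(steady_state_urine(c(deltamethrin = 0), reg, prm,
                                     adult70()) == 0))
  ## linearity: doubling every intake doubles every concentration
  c2 <- steady_state_urine(c(deltamethrin = 2e-3), reg, prm, adult70())
  expect_equal(c2[["3PBA"]], 2 * conc[["3PBA"]])
})

test_that("creatinine normalization divides by daily creatinine", {
  reg <- mini_registry(0.4)
  prm <- list(deltamethrin = pbk_params("deltamethrin", ka = 1, kf = 0))
  phys <- adult70()
  cv <- steady_state_urine(c(deltamethrin = 1e-3), reg, prm, phys,
                           normalization = "volume")
  cc <- steady_state_urine(c(deltamethrin = 1e-3), reg, prm, phys,
                           normalization = "creatinine")
  expect_equal(cc[["DBCA"]] / cv[["DBCA"]],
               phys$daily_urine_volume / phys$daily_creatinine)
  phys$daily_urine_volume <- 0
  expect_error(steady_state_urine(c(deltamethrin = 1e-3), reg, prm, phys),
               "positive")
})

test_that("ODE steady state matches the analytical map over random draws", {
  ## a reduced version of the full oracle sweep (the acceptance suite
  ## runs 50 draws); random kinetics, long constant-rate simulation
  reg <- mini_registry(0.4)
  phys <- default_physiology("20-65", body_weight = 70)
  set.seed(99)
  for (i in 1:5) {
    prm <- pbk_params("deltamethrin",
                      ka = runif(1, 0.2, 1), kf = runif(1, 0.05, 0.5),
                      fup = runif(1, 0.05, 0.3),
                      cl_met = runif(1, 50, 300),
                      pa_brain = runif(1, 1, 10),
                      partition = c(liver = runif(1, 2, 8),
                                    brain = runif(1, 1, 5),
                                    fat = runif(1, 20, 80),
                                    rich = runif(1, 2, 8),
                                    slow = runif(1, 1, 4)),
                      ku_met = runif(1, 0.03, 0.2))
    tc <- simulate_timecourse(prm, phys, dosing_schedule("oral", rate = 1e-3),
                              reg, duration = 1500, dt = 2)
    s <- tc$series
    u <- s$urine_DBCA
    nl <- nrow(s)
    rate24 <- (u[nl] - u[nl - 12]) / (s$time[nl] - s$time[nl - 12]) * 24
    conc <- rate24 / phys$daily_urine_volume * 1000
    ss <- steady_state_urine(c(deltamethrin = 1e-3), reg,
                             list(deltamethrin = prm), phys)
    expect_lt(abs(conc / ss[["DBCA"]] - 1), 0.01)
  }
})

test_that("dose metrics: constant curve and monotonicity in dose", {
  fake <- structure(list(series = data.frame(
    time = 0:10, plasma = rep(3, 11), brain = rep(1.5, 11))),
    class = "pyre_timecourse")
  dm <- dose_metrics(fake)
  expect_equal(dm$cmax_plasma, 3)
  expect_equal(dm$auc_plasma, 30)
  expect_equal(dm$auc_brain, 15)
  ## monotone non-decreasing in dose
  prm <- default_pbk_params(); phys <- default_physiology()
  cm <- vapply(c(0.5, 1, 2), function(D) {
    tc <- simulate_timecourse(
      prm, phys, dosing_schedule("oral", events = data.frame(time = 0,
                                                             dose = D)),
      default_registry(), duration = 24, dt = 0.25)
    dose_metrics(tc)$cmax_plasma
  }, numeric(1))
  expect_true(all(diff(cm) > 0))
})

test_that("Monte Carlo dose metrics are reproducible and linear in dose", {
  a <- monte_carlo_human_metrics(1e-4, 1.5, n = 5, seed = 42, duration = 12)
  b <- monte_carlo_human_metrics(1e-4, 1.5, n = 5, seed = 42, duration = 12)
  expect_identical(a, b)
  ## degenerate uncertainty -> every draw equals the deterministic run
  d0 <- monte_carlo_human_metrics(
    1e-4, 1, n = 3, seed = 1, duration = 12,
    uncertainty_gsd = c(partition_brain = 1, fup = 1, cl_met = 1,
                        pa_brain = 1))
  expect_equal(length(unique(round(d0$cmax_plasma, 12))), 1L)
  ## scaling the intake GM by 10 scales the median Cmax by 10
  m1 <- monte_carlo_human_metrics(
    1e-5, 1, n = 3, seed = 3, duration = 12,
    uncertainty_gsd = c(partition_brain = 1, fup = 1, cl_met = 1,
                        pa_brain = 1))
  m2 <- monte_carlo_human_metrics(
    1e-4, 1, n = 3, seed = 3, duration = 12,
    uncertainty_gsd = c(partition_brain = 1, fup = 1, cl_met = 1,
                        pa_brain = 1))
  expect_equal(median(m2$cmax_plasma) / median(m1$cmax_plasma), 10,
               tolerance = 1e-4)   # exact up to solver tolerance
})
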
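test_that("noise-free generation equals the deterministic map", {
  reg <- default_registry()
  phys <- default_physiology("20-65")
  co <- steady_state_coefficients(reg, NULL, phys)
  truth <- generator_truth(
    intakes = data.frame(compound = "deltamethrin", age_group = "20-65",
                         cycle = "1999-2000", gm = 1e-5, gsd = 2),
    lods = data.frame(metabolite = c("DBCA", "3PBA"),
                      cycle = "1999-2000", lod = 1e-12),
    n_per_stratum = 50, residual_gsd = 1, seed = 19)
  tab <- generate_survey(truth, reg)
  expect_equal(sum(tab$below_lod), 0)
  ## with no residual noise, both metabolites of a subject come from
  ## the same intake through the linear map, so their ratio is exactly
  ## the coefficient ratio for every subject
  dbca <- tab[tab$metabolite == "DBCA", ]
  pba <- tab[tab$metabolite == "3PBA", ]
  pba <- pba[match(dbca$subject_id, pba$subject_id), ]
  expect_equal(dbca$value / pba$value,
               rep(co["deltamethrin", "DBCA"] / co["deltamethrin", "3PBA"],
                   nrow(dbca)))
  ## determinism: the same seed regenerates the identical table
  tab2 <- generate_survey(truth, reg)
  expect_identical(tab$value, tab2$value)
})

test_that("LOD at a chosen concentration quantile censors that fraction", {
  ## binomial 3-sigma bands at n = 2000
  tab <- recovery_survey(n = 2000, cens_q = 0.5, seed = 23)
  expect_lt(abs(mean(tab$below_lod) - 0.5), 3 * sqrt(0.25 / 2000))
  tab30 <- recovery_survey(n = 2000, cens_q = 0.3, seed = 24)
  expect_lt(abs(mean(tab30$below_lod) - 0.3), 3 * sqrt(0.21 / 2000))
})

test_that("generated concentrations match the composed truth at scale", {
  ## GM of concentration = GM_intake * E_geo[bw * coef]; GSD combines
  ## intake, body-weight and residual spreads in quadrature
  reg <- default_registry()
  phys <- default_physiology("20-65")
  co1 <- steady_state_coefficients(reg, NULL, phys,
                                   body_weight = 1)["deltamethrin",
                                                    "DBCA"]
  ref <- physiology_table()
  ref <- ref[ref$age_group == "20-65", ]
  truth <- generator_truth(
    intakes = data.frame(compound = "deltamethrin", age_group = "20-65",
                         cycle = "1999-2000", gm = 1e-5, gsd = 2),
    lods = data.frame(metabolite = "DBCA", cycle = "1999-2000",
                      lod = 1e-12),
    n_per_stratum = 1e5, residual_gsd = 1.7, seed = 25)
  tab <- generate_survey(truth, reg)
  lg <- log(tab$value)
  gm_expected <- 1e-5 * ref$body_weight * co1
  sd_expected <- sqrt(log(2)^2 + log(ref$bw_gsd)^2 + log(1.7)^2)
  expect_equal(exp(mean(lg)), gm_expected, tolerance = 0.02)
  expect_equal(sd(lg), sd_expected, tolerance = 0.02)
})

test_that("dose-response truth records the analytic benchmark dose", {
  d <- generate_doseresponse("linear", c(100, -5), 10, c(0, 1, 3, 10),
                             10, noise = FALSE, seed = 1)
  expect_equal(attr(d, "truth_bmd"), 2.0)
  ## zero slope, zero noise: flat data, unbounded truth
  d0 <- generate_doseresponse("linear", c(100, 0), 10, c(0, 1, 3),
                              10, noise = FALSE, seed = 1)
  expect_true(all(d0$mean == 100))
  expect_equal(attr(d0, "truth_bmd"), Inf)
  ## curved family: the recorded root matches independent inversion
  th <- c(100, 0.08, 1.8)  # a * exp(b * d^g), increasing
  d3 <- generate_doseresponse("exponential3", th, control_sd = 10,
                              doses = c(0, 1, 3, 10), n_per_group = 10,
                              noise = FALSE, seed = 2)
  f <- function(d) th[1] * exp(th[2] * d^th[3])
  root <- uniroot(function(d) (f(d) - f(0)) - 10, c(0, 50),
                  tol = 1e-12)$root
  expect_equal(attr(d3, "truth_bmd"), root, tolerance = 1e-6)
})

test_that("the default scenario carries the survey design structure", {
  sc <- default_scenario(n_per_stratum = 5, seed = 1)
  expect_equal(length(unique(sc$intakes$cycle)), 7)
  expect_equal(sort(unique(sc$intakes$age_group)), sort(age_groups()))
  ## panel shrinkage: cis-DCCA and DBCA absent from late cycles
  late <- sc$lods[sc$lods$cycle == "2015-2016", ]
  expect_false("cis-DCCA" %in% late$metabolite)
  expect_false("DBCA" %in% late$metabolite)
  early <- sc$lods[sc$lods$cycle == "1999-2000", ]
  expect_equal(sort(early$metabolite),
               sort(c("3PBA", "FPBA", "DBCA", "cis-DCCA", "trans-DCCA")))
  ## LODs vary across cycles
  expect_gt(length(unique(sc$lods$lod[sc$lods$metabolite == "3PBA"])), 1)
})
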
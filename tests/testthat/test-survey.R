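make_records <- function(values, lod = 0.1, metabolite = "3PBA",
                         cycle = "1999-2000", age_group = "20-65") {
  below <- values < lod
  data.frame(subject_id = seq_along(values), cycle = cycle,
             age_group = age_group, body_weight = 70,
             metabolite = metabolite,
             value = ifelse(below, NA_real_, values),
             lod = lod, below_lod = below)
}

test_that("survey validation rejects inconsistent censoring", {
  d <- make_records(c(0.5, 0.2, 0.05))
  expect_s3_class(survey_table(d), "pyre_survey")
  d2 <- d; d2$value[3] <- 0.05          # below-LOD row with a value
  expect_error(survey_table(d2), "missing value")
  d3 <- d; d3$lod <- 0
  expect_error(survey_table(d3), "LOD must be positive")
  d4 <- d; d4$value[1] <- NA            # detected row without a value
  expect_error(survey_table(d4), "value >= LOD")
})

test_that("detection rate counts records at or above the LOD", {
  tab <- survey_table(make_records(c(1, 2, 3)))
  expect_equal(detection_rate(tab, "3PBA"), 1.0)
  tab2 <- survey_table(make_records(c(0.01, 0.02, 0.03, 0.04, 0.5)))
  expect_equal(detection_rate(tab2, "3PBA"), 0.2)
  expect_error(detection_rate(tab, "FPBA"), "no records")
  ## invariance under record order
  tab3 <- survey_table(make_records(c(0.5, 0.01, 0.3, 0.02)))
  tab4 <- survey_table(make_records(c(0.02, 0.3, 0.01, 0.5)))
  expect_equal(detection_rate(tab3, "3PBA"), detection_rate(tab4, "3PBA"))
})

test_that("percentile ratio: constant sample, scale invariance, floor", {
  expect_equal(percentile_ratio(rep(2, 50)), 1.0)
  set.seed(4)
  x <- rlnorm(500, 0, 0.5)
  expect_equal(percentile_ratio(x), percentile_ratio(7 * x))
  expect_error(percentile_ratio(x[1:10]), "at least 20")
  expect_error(percentile_ratio(rep(0, 50)), "not positive")
})

test_that("P95/P50 of lognormal samples approaches GSD^1.6449", {
  set.seed(11)
  x <- rlnorm(1e5, meanlog = 3, sdlog = log(2))
  expect_equal(percentile_ratio(x), 2^qnorm(0.95), tolerance = 0.02)
})

test_that("geometric mean trend recovers flat and doubling patterns", {
  flat <- do.call(rbind, lapply(c("1999-2000", "2001-2002", "2003-2004"),
                                function(cy)
                                  make_records(c(1, 2, 4, 8), cycle = cy)))
  tr <- geometric_mean_trend(survey_table(flat), "3PBA")
  expect_equal(tr$gm[3] / tr$gm[1], 1.0)

  set.seed(21)
  grow <- do.call(rbind, lapply(1:3, function(i)
    make_records(rlnorm(400, log(0.5) + (i - 1) * log(2), 0.4),
                 lod = 1e-6, cycle = paste0("c", i))))
  tr2 <- geometric_mean_trend(survey_table(grow), "3PBA")
  expect_equal(tr2$gm[3] / tr2$gm[1], 4, tolerance = 0.15)

  expect_error(geometric_mean_trend(
    survey_table(make_records(c(1, 2))), "3PBA"), "fewer than 2")
})

test_that("all-censored cycles are flagged with an LOD bound", {
  d1 <- make_records(c(1, 2, 4), cycle = "a")
  d2 <- make_records(c(0.01, 0.02, 0.03), cycle = "b")
  tr <- geometric_mean_trend(survey_table(rbind(d1, d2)), "3PBA")
  expect_true(tr$all_censored[tr$cycle == "b"])
  expect_equal(tr$gm[tr$cycle == "b"], 0.1)  # the LOD bound
})

test_that("age-group similarity clusters constructed separations", {
  m <- rbind(A = rep(1e-3, 4), B = rep(1.1e-3, 4),
             C = rep(0.1, 4), D = rep(0.11, 4), E = rep(0.12, 4))
  hc <- age_group_similarity(m)
  ## the first split separates {A,B} from {C,D,E}
  k2 <- cutree(hc, 2)
  expect_equal(k2[["A"]], k2[["B"]])
  expect_equal(k2[["C"]], k2[["D"]])
  expect_false(k2[["A"]] == k2[["C"]])
  ## identical rows merge at distance 0
  m2 <- rbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(9, 9, 9))
  expect_equal(min(age_group_similarity(m2)$height), 0)
  ## column permutation leaves the topology unchanged
  hc1 <- age_group_similarity(m)
  hc2 <- age_group_similarity(m[, c(3, 1, 4, 2)])
  expect_equal(cutree(hc1, 2), cutree(hc2, 2))
  expect_error(age_group_similarity(m[1, , drop = FALSE]), "at least 2")
})

test_that("survey tables round-trip through the canonical CSV", {
  tab <- recovery_survey(n = 30, seed = 5)
  td <- withr::local_tempdir()
  f <- file.path(td, "survey.csv")
  write_survey(tab, f)
  tab2 <- read_survey(f)
  expect_identical(tab$value, tab2$value)
  expect_identical(tab$body_weight, tab2$body_weight)
  expect_identical(tab$below_lod, tab2$below_lod)
  expect_identical(tab$lod, tab2$lod)
})
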
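#' Life-stage physiology
#'
#' Reference physiology by age group. Body weight, daily urine volume and
#' daily creatinine excretion are the quantities that matter for the
#' steady-state urine map; cardiac output and compartment volumes/flows
#' feed the full compartmental model. The age bins follow the five groups
#' used in U.S. population exposure work (<6, 6-11, 12-19, 20-65, >65).
#'
#' @param age_group one of `age_groups()`.
#' @param body_weight kg; default is the age-group reference weight.
#' @return object of class `pyre_physiology`: body_weight (kg),
#'   daily_urine_volume (L/day), daily_creatinine (g/day),
#'   urine_creatinine (g/L), cardiac_output (L/h), and per-compartment
#'   volumes (L) and plasma flows (L/h).
#' @export
default_physiology <- function(age_group = "20-65", body_weight = NULL) {
  ref <- physiology_table()
  if (!age_group %in% ref$age_group)
    stop("unknown age group: ", age_group, call. = FALSE)
  row <- ref[ref$age_group == age_group, ]
  bw <- if (is.null(body_weight)) row$body_weight else body_weight
  stopifnot(bw > 0)
  co <- 15 * bw^0.74  # L/h, allometric cardiac output (plasma flow basis)
  phys <- list(
    age_group = age_group,
    body_weight = bw,
    daily_urine_volume = row$daily_urine_volume,
    daily_creatinine = row$daily_creatinine,
    urine_creatinine = row$urine_creatinine,
    cardiac_output = co,
    # volumes as body-weight fractions (density 1); sum < 1
    volumes = c(plasma = 0.044, liver = 0.026, brain = 0.020,
                fat = 0.210, rich = 0.050, slow = 0.500) * bw,
    # plasma flows as cardiac-output fractions
    flows = c(liver = 0.25, brain = 0.12, fat = 0.05,
              rich = 0.30, slow = 0.28) * co
  )
  class(phys) <- "pyre_physiology"
  phys
}

#' Age groups used throughout the package
#' @return character vector of the five age bins.
#' @export
age_groups <- function() AGE_GROUPS

#' Reference physiology table
#'
#' Per-age-group body weight (kg, with a lognormal GSD used by the
#' synthetic-survey generator), daily urine volume (L/day), daily
#' creatinine excretion (g/day) and urine creatinine (g/L). Shipped as a
#' CSV under `extdata` so alternative parameterizations can be swapped in.
#'
#' @return data.frame.
#' @export
physiology_table <- function() {
  f <- system.file("extdata", "physiology_age_groups.csv",
                   package = "pyredose")
  utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
}
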
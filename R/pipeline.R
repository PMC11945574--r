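#' End-to-end pipeline: reverse dosimetry -> BMD -> systemic POD -> margins
#'
#' Orchestrates the four stages over a survey table and a set of
#' dose-response datasets: (1) Bayesian reverse dosimetry of population
#' intakes, (2) model-averaged benchmark doses, (3) systemic points of
#' departure simulated in the rat model at the BMDL dose, (4) MOE and
#' MOIE distributions. A run manifest records seeds, settings, per-stage
#' convergence flags, and MD5 hashes of the written outputs.
#'
#' @name pipeline
NULL

#' Rat physiology for systemic POD simulation
#'
#' A 0.25 kg reference rat with the same compartment structure as the
#' human model (volumes as body-weight fractions, allometric cardiac
#' output).
#'
#' @param body_weight kg.
#' @return `pyre_physiology`.
#' @export
rat_physiology <- function(body_weight = 0.25) {
  co <- 15 * body_weight^0.74
  structure(list(
    age_group = "rat", body_weight = body_weight,
    daily_urine_volume = 0.015, daily_creatinine = 0.005,
    urine_creatinine = 0.4, cardiac_output = co,
    volumes = c(plasma = 0.044, liver = 0.037, brain = 0.006,
                fat = 0.070, rich = 0.050, slow = 0.600) * body_weight,
    flows = c(liver = 0.25, brain = 0.02, fat = 0.07,
              rich = 0.33, slow = 0.33) * co),
    class = "pyre_physiology")
}

#' Systemic point of departure at the BMDL dose
#'
#' Simulates a single oral BMDL dose in the rat model and extracts the
#' four dose metrics.
#'
#' @param compound registry compound id.
#' @param bmdl mg/kg.
#' @param registry,params rat kinetic parameters default to the
#'   compound's human set (kinetics scale allometrically inside the
#'   simulator).
#' @param duration h.
#' @return `pyre_pod`.
#' @export
systemic_pod <- function(compound, bmdl, registry = default_registry(),
                         params = NULL, duration = 48) {
  if (is.null(params)) params <- default_pbk_params(compound)
  params$compound <- compound
  tc <- simulate_timecourse(
    params, rat_physiology(),
    dosing_schedule("oral", events = data.frame(time = 0, dose = bmdl)),
    registry, duration = duration, dt = 0.05)
  pod_set(compound, bmdl, dose_metrics(tc))
}

#' Pipeline configuration
#'
#' @param survey `pyre_survey` or path to the canonical CSV.
#' @param doseresponse named list of `pyre_doseresponse` (or CSV paths
#'   with columns dose, n, mean, sd), one per compound group.
#' @param registry `pyre_registry` (default registry when NULL).
#' @param seed integer, mandatory.
#' @param chains,iterations reverse-dosimetry MCMC settings.
#' @param bmd_iterations per-chain iterations for the BMD stage.
#' @param lod_policy below-LOD policy.
#' @param exposure_quantile which posterior exposure summary feeds the
#'   margins: "gm", "p95" or "p99" (top-1% convention).
#' @param target_moe acceptability threshold.
#' @param mc_draws Monte Carlo draws for human dose metrics.
#' @param allow_unconverged continue past non-converged stages.
#' @param out_dir when non-NULL, stage outputs are written there as
#'   CSV/JSON and hashed into the manifest.
#' @return list of class `pyre_config`.
#' @export
pipeline_config <- function(survey, doseresponse, registry = NULL,
                            seed, chains = 3, iterations = 4000,
                            bmd_iterations = 4000,
                            lod_policy = "half_lod",
                            exposure_quantile = c("p99", "p95", "gm"),
                            target_moe = 100, mc_draws = 50,
                            allow_unconverged = FALSE, out_dir = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  exposure_quantile <- match.arg(exposure_quantile)
  if (is.character(survey)) {
    if (!file.exists(survey)) stop("survey file not found: ", survey,
                                   call. = FALSE)
    survey <- read_survey(survey)
  }
  doseresponse <- lapply(doseresponse, function(d) {
    if (is.character(d)) {
      if (!file.exists(d)) stop("dose-response file not found: ", d,
                                call. = FALSE)
      dd <- utils::read.csv(d)
      d <- dose_response_data(dd$dose, dd$n, dd$mean, dd$sd)
    }
    d
  })
  structure(list(survey = survey, doseresponse = doseresponse,
                 registry = if (is.null(registry)) default_registry()
                 else registry,
                 seed = seed, chains = chains, iterations = iterations,
                 bmd_iterations = bmd_iterations, lod_policy = lod_policy,
                 exposure_quantile = exposure_quantile,
                 target_moe = target_moe, mc_draws = mc_draws,
                 allow_unconverged = allow_unconverged,
                 out_dir = out_dir),
            class = "pyre_config")
}

#' Run the four-stage pipeline
#'
#' @param config `pyre_config`.
#' @return list of class `pyre_run`: `posterior`, `bmd` (per compound),
#'   `pods`, `margins`, `risk` table, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pyre_config"))
  manifest <- list(seed = config$seed,
                   settings = config[c("chains", "iterations",
                                       "bmd_iterations", "lod_policy",
                                       "exposure_quantile", "target_moe")],
                   stages = list(), hashes = list(),
                   package_version = as.character(
                     utils::packageVersion("pyredose")))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tt <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      status = "completed",
      wall_s = as.numeric(difftime(Sys.time(), tt, units = "secs")))
    val
  }
  ## stage 1: reverse dosimetry
  post <- stage("reverse_dosimetry",
                sample_posterior(config$survey, config$registry,
                                 chains = config$chains,
                                 iterations = config$iterations,
                                 lod_policy = config$lod_policy,
                                 seed = config$seed))
  conv_ok <- all(vapply(post$convergence, `[[`, logical(1), "pass"))
  manifest$stages$reverse_dosimetry$converged <- conv_ok
  if (!conv_ok && !config$allow_unconverged)
    stop("pipeline stopped: reverse-dosimetry stage did not converge ",
         "(use allow_unconverged to override)", call. = FALSE)
  ## stage 2: BMD per compound group
  bmds <- stage("bmd", {
    out <- list()
    for (g in names(config$doseresponse)) {
      out[[g]] <- bmd_analysis(config$doseresponse[[g]],
                               chains = config$chains,
                               iterations = config$bmd_iterations,
                               seed = config$seed + 17L)
    }
    out
  })
  ## stage 3: systemic PODs in the rat model
  pods <- stage("systemic_pod", {
    out <- list()
    for (g in names(bmds)) {
      cmpd_ids <- config$registry$compounds$id[
        config$registry$compounds$parent_group == g]
      out[[g]] <- systemic_pod(cmpd_ids[1], bmds[[g]]$bmdl,
                               config$registry)
    }
    out
  })
  ## stage 4: margins
  margins <- stage("margins", {
    out <- list()
    summ <- post$summary
    for (g in names(bmds)) {
      rows <- summ[summ$compound == g, , drop = FALSE]
      if (!nrow(rows)) next
      expo <- switch(config$exposure_quantile,
                     gm = max(rows$intake_gm),
                     p95 = max(10^(rows$log10_intake_med) *
                                 rows$gsd_pop^stats::qnorm(0.95)),
                     p99 = max(10^(rows$log10_intake_med) *
                                 rows$gsd_pop^stats::qnorm(0.99)))
      out[[paste0(g, "_MOE")]] <-
        compute_moe(bmds[[g]]$bmdl, expo, config$target_moe)
      hm <- monte_carlo_human_metrics(
        intake_gm = expo, intake_gsd = 1.1,
        params = default_pbk_params(
          config$registry$compounds$id[
            config$registry$compounds$parent_group == g][1]),
        registry = config$registry, n = config$mc_draws,
        seed = config$seed + 29L)
      for (met in c("cmax_plasma", "auc_plasma", "cmax_brain",
                    "auc_brain")) {
        out[[paste0(g, "_MOIE_", met)]] <-
          compute_moie(pods[[g]], hm, met, config$target_moe)
      }
    }
    out
  })
  risk <- risk_table(margins)
  manifest$wall_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fs <- file.path(config$out_dir, "posterior_summary.csv")
    fr <- file.path(config$out_dir, "risk_table.csv")
    utils::write.csv(post$summary, fs, row.names = FALSE)
    utils::write.csv(risk, fr, row.names = FALSE)
    manifest$hashes <- as.list(tools::md5sum(c(fs, fr)))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(posterior = post, bmd = bmds, pods = pods,
                 margins = margins, risk = risk, manifest = manifest),
            class = "pyre_run")
}
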
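#' Compartmental kinetic model for pyrethroids and their metabolites
#'
#' A generic multi-route PBK model: gut lumen with competing first-order
#' oral absorption and fecal elimination, flow-limited liver, fat, richly
#' and slowly perfused tissues, a permeability-limited brain, and a
#' central plasma compartment. Hepatic metabolism converts the parent
#' into its urinary metabolites with fixed molar fractions; each
#' metabolite occupies a one-compartment pool cleared into urine by a
#' first-order rate. Dermal and inhalation dosing are supported forward
#' (skin depot with first-order uptake; direct input to plasma).
#'
#' @name pbk
NULL

#' Kinetic parameters for one compound
#'
#' @param compound id used for labelling.
#' @param ka oral absorption rate constant, 1/h.
#' @param kf fecal elimination rate constant, 1/h. The absorbed fraction
#'   is `ka / (ka + kf)`.
#' @param fup unbound fraction in plasma, dimensionless.
#' @param cl_met hepatic metabolic clearance referenced to unbound liver
#'   venous concentration, L/h (scaled internally by BW^0.75 / 70^0.75).
#' @param pa_brain brain plasma permeability, L/h (same scaling).
#' @param partition named tissue:plasma partition coefficients
#'   (liver, brain, fat, rich, slow).
#' @param ku_met urinary elimination rate constant applied to every
#'   metabolite pool, 1/h (~12 h half-life by default).
#' @param ka_dermal first-order uptake from the skin depot, 1/h.
#' @return object of class `pyre_pbk_params`.
#' @export
pbk_params <- function(compound = "deltamethrin",
                       ka = 0.35, kf = 0.35, fup = 0.10,
                       cl_met = 150, pa_brain = 5,
                       partition = c(liver = 4, brain = 3, fat = 50,
                                     rich = 4, slow = 2),
                       ku_met = 0.058, ka_dermal = 0.05) {
  stopifnot(ka >= 0, kf >= 0, ka + kf > 0, fup >= 0, fup <= 1,
            cl_met >= 0, pa_brain >= 0, all(partition > 0), ku_met > 0)
  structure(list(compound = compound, ka = ka, kf = kf, fup = fup,
                 cl_met = cl_met, pa_brain = pa_brain,
                 partition = partition, ku_met = ku_met,
                 ka_dermal = ka_dermal),
            class = "pyre_pbk_params")
}

#' Absorbed oral fraction implied by the absorption/fecal competition
#' @param params `pyre_pbk_params`.
#' @return ka / (ka + kf).
#' @export
absorbed_fraction <- function(params) params$ka / (params$ka + params$kf)

#' Default per-compound kinetic parameter sets
#'
#' Deltamethrin parameters are the reference set; cypermethrin and
#' cyfluthrin reuse them (no compound-specific human kinetic data), and
#' permethrin gets faster, more complete absorption. Values are package
#' defaults representative of the pyrethroid kinetic literature.
#'
#' @param compound a registry compound id.
#' @return `pyre_pbk_params`.
#' @export
default_pbk_params <- function(compound = "deltamethrin") {
  if (grepl("permethrin$", compound) && !grepl("cypermethrin$", compound)) {
    pbk_params(compound, ka = 0.50, kf = 0.21)   # f_abs ~ 0.70
  } else {
    pbk_params(compound)                         # f_abs = 0.50
  }
}

#' Dosing schedule
#'
#' @param route "oral", "dermal" or "inhalation".
#' @param events data.frame with columns `time` (h) and `dose` (mg/kg)
#'   for bolus events, or NULL.
#' @param rate constant dose rate, mg/kg/day, applied over
#'   `rate_interval` (h, default the whole simulation).
#' @param rate_interval length-2 numeric, h.
#' @return object of class `pyre_dosing`.
#' @export
dosing_schedule <- function(route = c("oral", "dermal", "inhalation"),
                            events = NULL, rate = 0,
                            rate_interval = c(0, Inf)) {
  route <- match.arg(route)
  if (!is.null(events)) {
    stopifnot(all(events$time >= 0), all(diff(events$time) >= 0),
              all(events$dose >= 0))
  }
  stopifnot(rate >= 0, length(rate_interval) == 2,
            rate_interval[1] <= rate_interval[2])
  structure(list(route = route, events = events, rate = rate,
                 rate_interval = rate_interval), class = "pyre_dosing")
}

pbk_state_names <- function(metabolites) {
  c("A_gut", "A_skin", "A_pl", "A_li", "A_fa", "A_rp", "A_sp", "A_br",
    "A_fec", "A_met_cum",
    paste0("Am_", metabolites), paste0("Au_", metabolites))
}

pbk_rhs <- function(t, y, p) {
  with(p, {
    Cpl <- y["A_pl"] / V["plasma"]
    Cli <- y["A_li"] / V["liver"]; Cfa <- y["A_fa"] / V["fat"]
    Crp <- y["A_rp"] / V["rich"];  Csp <- y["A_sp"] / V["slow"]
    Cbr <- y["A_br"] / V["brain"]
    vli <- Cli / P["liver"]; vfa <- Cfa / P["fat"]
    vrp <- Crp / P["rich"];  vsp <- Csp / P["slow"]
    in_rate <- if (t >= rate_interval[1] && t <= rate_interval[2]) rate_mg_h else 0
    gut_in  <- if (route == "oral") in_rate else 0
    pl_in   <- if (route == "inhalation") in_rate else 0
    met_rate <- cl_met * fup * vli          # mg parent / h
    dgut <- gut_in - (ka + kf) * y["A_gut"]
    dskin <- -ka_dermal * y["A_skin"]
    dli <- Q["liver"] * (Cpl - vli) + ka * y["A_gut"] - met_rate
    dfa <- Q["fat"]   * (Cpl - vfa)
    drp <- Q["rich"]  * (Cpl - vrp)
    dsp <- Q["slow"]  * (Cpl - vsp)
    ## permeability-limited brain: influx driven by unbound plasma
    ## drug, efflux by brain concentration over the partition
    ## coefficient, so at equilibrium C_brain = fup * P_brain * C_plasma
    dbr <- pa_brain * (fup * Cpl - Cbr / P["brain"])
    dpl <- Q["liver"] * vli + Q["fat"] * vfa + Q["rich"] * vrp +
      Q["slow"] * vsp -
      (Q["liver"] + Q["fat"] + Q["rich"] + Q["slow"]) * Cpl -
      pa_brain * (fup * Cpl - Cbr / P["brain"]) +
      ka_dermal * y["A_skin"] + pl_in
    dfec <- kf * y["A_gut"]
    dmet <- met_rate
    nm <- length(met_ids)
    Am <- y[10 + seq_len(nm)]
    dAm <- met_rate * phi_mass - ku_met * Am
    dAu <- ku_met * Am
    list(c(dgut, dskin, dpl, dli, dfa, drp, dsp, dbr, dfec, dmet, dAm, dAu))
  })
}

#' Simulate the compartmental model
#'
#' @param params `pyre_pbk_params`.
#' @param physiology `pyre_physiology`.
#' @param dosing `pyre_dosing`.
#' @param registry `pyre_registry`; metabolite pools are created for every
#'   metabolite with a pathway from `params$compound`.
#' @param duration simulated time, h.
#' @param dt output grid spacing, h.
#' @param rtol,atol solver tolerances (lsoda).
#' @return object of class `pyre_timecourse`: a data.frame `series` with
#'   the time grid (h), per-compartment concentrations (ng/mL plasma and
#'   tissues; amounts for sinks, mg), plus attributes recording dose
#'   bookkeeping for the mass-balance check.
#' @export
simulate_timecourse <- function(params, physiology, dosing,
                                registry = default_registry(),
                                duration = 24, dt = 0.1,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(duration > 0)
  bw <- physiology$body_weight
  rows <- registry$matrix[registry$matrix$compound == params$compound &
                            registry$matrix$phi > 0, , drop = FALSE]
  met_ids <- rows$metabolite
  mw_p <- registry$compounds$molar_mass[
    registry$compounds$id == params$compound]
  if (!length(mw_p)) stop("compound not in registry: ", params$compound,
                          call. = FALSE)
  mw_m <- registry$metabolites$molar_mass[
    match(met_ids, registry$metabolites$id)]
  phi_mass <- rows$phi * mw_m / mw_p          # mg metabolite per mg parent
  scale <- (bw / 70)^0.75
  p <- list(
    V = physiology$volumes, Q = physiology$flows, P = params$partition,
    ka = params$ka, kf = params$kf, fup = params$fup,
    cl_met = params$cl_met * scale, pa_brain = params$pa_brain * scale,
    ku_met = params$ku_met, ka_dermal = params$ka_dermal,
    route = dosing$route,
    rate_mg_h = dosing$rate * bw / 24,
    rate_interval = dosing$rate_interval,
    met_ids = met_ids, phi_mass = phi_mass
  )
  nm <- length(met_ids)
  y0 <- stats::setNames(numeric(10 + 2 * nm), pbk_state_names(met_ids))
  evt <- NULL
  if (!is.null(dosing$events) && nrow(dosing$events)) {
    target <- switch(dosing$route, oral = "A_gut", dermal = "A_skin",
                     inhalation = "A_pl")
    evt <- data.frame(var = target, time = dosing$events$time,
                      value = dosing$events$dose * bw, method = "add")
  }
  times <- sort(unique(c(seq(0, duration, by = dt), duration,
                         if (!is.null(evt)) evt$time)))
  out <- deSolve::lsoda(y0, times, pbk_rhs, p, rtol = rtol, atol = atol,
                        events = if (!is.null(evt)) list(data = evt))
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite state in compartment '%s' at t = %.3g h",
                 colnames(out)[bad[2]], out[bad[1], 1]), call. = FALSE)
  }
  out <- as.data.frame(out)
  ## concentrations, ng/mL (mg/L * 1000)
  ser <- data.frame(
    time = out$time,
    plasma = out$A_pl / physiology$volumes["plasma"] * 1000,
    liver  = out$A_li / physiology$volumes["liver"] * 1000,
    fat    = out$A_fa / physiology$volumes["fat"] * 1000,
    rich   = out$A_rp / physiology$volumes["rich"] * 1000,
    slow   = out$A_sp / physiology$volumes["slow"] * 1000,
    brain  = out$A_br / physiology$volumes["brain"] * 1000,
    gut = out$A_gut, skin = out$A_skin,
    feces_cum = out$A_fec, metabolized_cum = out$A_met_cum,
    row.names = NULL
  )
  for (m in met_ids) {
    ser[[paste0("urine_", m)]] <- out[[paste0("Au_", m)]]
    ser[[paste0("body_", m)]] <- out[[paste0("Am_", m)]]
  }
  ## cumulative input at each output time (bolus events count once the
  ## solver has passed them; rows at an event time are pre-event)
  ev_t <- if (!is.null(dosing$events)) dosing$events$time else numeric(0)
  ev_d <- if (!is.null(dosing$events)) dosing$events$dose * bw else numeric(0)
  input_cum <- vapply(out$time, function(t)
    sum(ev_d[ev_t < t]) +
      p$rate_mg_h * max(0, min(t, p$rate_interval[2]) -
                          max(0, p$rate_interval[1])), numeric(1))
  dosed <- sum(ev_d) +
    p$rate_mg_h * max(0, min(duration, p$rate_interval[2]) -
                        max(0, p$rate_interval[1]))
  ## parent mass balance: input = in-body + fecal + metabolized (all mg
  ## parent); the metabolite pools have their own balance via phi_mass
  in_body <- out$A_gut + out$A_skin + out$A_pl + out$A_li + out$A_fa +
    out$A_rp + out$A_sp + out$A_br
  keep_rows <- !out$time %in% ev_t
  structure(list(series = ser, metabolites = met_ids,
                 compound = params$compound,
                 dosed_mg = dosed,
                 balance_gap = max(abs((input_cum - in_body - out$A_fec -
                                          out$A_met_cum)[keep_rows]), 0),
                 physiology = physiology, params = params),
            class = "pyre_timecourse")
}

#' Steady-state urinary metabolite concentrations from daily intakes
#'
#' The analytical reduction of the compartmental model under constant
#' daily intake: at steady state every absorbed parent molecule is
#' metabolized, a molar fraction phi of it appears in urine as each
#' metabolite, and the urinary mass flux divided by daily urine output
#' (or daily creatinine) gives the concentration. The map is linear in
#' each intake:
#' \deqn{C_m = \sum_p D_p \, BW \, f_{abs,p} \, \phi_{pm} \,
#'       \frac{MW_m}{MW_p} / V_{urine}}
#'
#' @param intakes named numeric, mg/kg/day per registry compound id
#'   (missing compounds are zero).
#' @param registry `pyre_registry`.
#' @param params_list named list of `pyre_pbk_params` per compound;
#'   defaults from `default_pbk_params()`.
#' @param physiology `pyre_physiology`.
#' @param normalization "volume" (ng/mL) or "creatinine"
#'   (micrograms per g creatinine).
#' @param metabolites metabolite ids to report; defaults to measured ones.
#' @return named numeric vector of concentrations.
#' @export
steady_state_urine <- function(intakes, registry,
                               params_list = NULL,
                               physiology = default_physiology(),
                               normalization = c("volume", "creatinine"),
                               metabolites = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(all(intakes >= 0))
  if (is.null(metabolites))
    metabolites <- registry$metabolites$id[registry$metabolites$measured]
  denom <- switch(normalization,
                  volume = physiology$daily_urine_volume,
                  creatinine = physiology$daily_creatinine)
  if (!is.finite(denom) || denom <= 0)
    stop("urine output / creatinine must be positive", call. = FALSE)
  bw <- physiology$body_weight
  out <- stats::setNames(numeric(length(metabolites)), metabolites)
  for (cmpd in names(intakes)) {
    if (intakes[[cmpd]] == 0) next
    prm <- if (!is.null(params_list) && cmpd %in% names(params_list))
      params_list[[cmpd]] else default_pbk_params(cmpd)
    fabs <- absorbed_fraction(prm)
    for (m in metabolites) {
      y <- metabolite_mass_yield(registry, cmpd, m)
      if (y == 0) next
      flux <- intakes[[cmpd]] * bw * fabs * y      # mg/day
      out[m] <- out[m] + flux / denom * 1000       # ng/mL or ug/g
    }
  }
  out
}

#' Per-individual steady-state coefficients
#'
#' Linear coefficients c[compound, metabolite] such that the predicted
#' concentration is `sum_p intake_p * c[p, m]` for one individual. Used
#' by the Bayesian sampler and the synthetic-data generator.
#'
#' @inheritParams steady_state_urine
#' @param body_weight kg; overrides the physiology body weight.
#' @return matrix compounds x metabolites, ng/mL per (mg/kg/day).
#' @export
steady_state_coefficients <- function(registry,
                                      params_list = NULL,
                                      physiology = default_physiology(),
                                      body_weight = NULL,
                                      normalization = "volume",
                                      metabolites = NULL) {
  if (is.null(metabolites))
    metabolites <- registry$metabolites$id[registry$metabolites$measured]
  cmpds <- registry$compounds$id
  out <- matrix(0, length(cmpds), length(metabolites),
                dimnames = list(cmpds, metabolites))
  phys <- physiology
  if (!is.null(body_weight)) phys$body_weight <- body_weight
  for (cmpd in cmpds) {
    iv <- stats::setNames(1, cmpd)
    out[cmpd, ] <- steady_state_urine(iv, registry, params_list, phys,
                                      normalization, metabolites)
  }
  out
}

#' Internal dose metrics of a simulated time course
#'
#' @param tc `pyre_timecourse`.
#' @return object of class `pyre_dose_metrics`: cmax_plasma, auc_plasma
#'   (ng/mL, ng.h/mL), cmax_brain, auc_brain (ng/g, ng.h/g; unit tissue
#'   density). AUC by the trapezoidal rule over the simulated window.
#' @export
dose_metrics <- function(tc) {
  s <- tc$series
  stopifnot(nrow(s) > 0)
  trap <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
  structure(list(
    cmax_plasma = max(s$plasma), auc_plasma = trap(s$time, s$plasma),
    cmax_brain = max(s$brain), auc_brain = trap(s$time, s$brain)),
    class = "pyre_dose_metrics")
}

#' Monte Carlo distribution of human internal dose metrics
#'
#' Samples a daily intake from a lognormal population distribution and
#' multiplicative lognormal uncertainty factors on the most sensitive
#' kinetic parameters (brain partition, unbound fraction, metabolic
#' clearance, brain permeability), simulates a single daily oral dose,
#' and collects the four dose metrics.
#'
#' @param intake_gm,intake_gsd lognormal intake distribution, mg/kg/day.
#' @param params baseline `pyre_pbk_params`.
#' @param physiology `pyre_physiology`.
#' @param registry `pyre_registry`.
#' @param uncertainty_gsd named numeric GSDs for parameter uncertainty;
#'   set to 1 for a degenerate (deterministic-parameter) run.
#' @param n number of draws.
#' @param duration simulated window per draw, h.
#' @param seed integer seed (mandatory for reproducibility).
#' @return data.frame with n rows: intake, cmax_plasma, auc_plasma,
#'   cmax_brain, auc_brain.
#' @export
monte_carlo_human_metrics <- function(intake_gm, intake_gsd,
                                      params = default_pbk_params(),
                                      physiology = default_physiology(),
                                      registry = default_registry(),
                                      uncertainty_gsd = c(
                                        partition_brain = 1.2, fup = 1.2,
                                        cl_met = 1.3, pa_brain = 1.3),
                                      n = 100, duration = 24, seed) {
  stopifnot(n >= 1, intake_gm > 0, intake_gsd >= 1)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  draw_f <- function(gsd, k) if (gsd <= 1) rep(1, k) else
    exp(stats::rnorm(k, 0, log(gsd)))
  intake <- intake_gm * draw_f(intake_gsd, n)
  f_pbr <- draw_f(uncertainty_gsd[["partition_brain"]], n)
  f_fup <- draw_f(uncertainty_gsd[["fup"]], n)
  f_cl  <- draw_f(uncertainty_gsd[["cl_met"]], n)
  f_pa  <- draw_f(uncertainty_gsd[["pa_brain"]], n)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    prm <- params
    prm$partition[["brain"]] <- prm$partition[["brain"]] * f_pbr[i]
    prm$fup <- min(1, prm$fup * f_fup[i])
    prm$cl_met <- prm$cl_met * f_cl[i]
    prm$pa_brain <- prm$pa_brain * f_pa[i]
    dos <- dosing_schedule("oral",
                           events = data.frame(time = 0, dose = intake[i]))
    tc <- simulate_timecourse(prm, physiology, dos, registry,
                              duration = duration, dt = 0.25)
    dm <- dose_metrics(tc)
    res[[i]] <- data.frame(intake = intake[i],
                           cmax_plasma = dm$cmax_plasma,
                           auc_plasma = dm$auc_plasma,
                           cmax_brain = dm$cmax_brain,
                           auc_brain = dm$auc_brain)
  }
  do.call(rbind, res)
}
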
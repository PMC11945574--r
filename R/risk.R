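#' Margins of exposure: external (MOE) and internal (MOIE)
#'
#' MOE divides an external point of departure (the BMDL, mg/kg) by the
#' estimated human daily intake. MOIE divides a systemic point of
#' departure (a dose metric simulated in the rat model at the BMDL dose)
#' by the corresponding predicted human dose metric. Both are computed
#' element-wise over draws so the result is a distribution; the
#' acceptability flag compares the 5th percentile against the target
#' margin.
#'
#' @name risk
NULL

margin_result <- function(draws, target, kind, metric = NA_character_) {
  stopifnot(all(draws > 0))
  qs <- stats::quantile(draws, c(0.05, 0.5), names = FALSE)
  structure(list(kind = kind, metric = metric, draws = draws,
                 median = qs[2], p05 = qs[1], target = target,
                 acceptable = qs[1] >= target),
            class = "pyre_margin")
}

#' @export
print.pyre_margin <- function(x, ...) {
  cat(sprintf("<%s%s> median %.4g, P05 %.4g, target %.4g (%s)\n",
              x$kind, if (is.na(x$metric)) "" else paste0(":", x$metric),
              x$median, x$p05, x$target,
              if (x$acceptable) "acceptable" else "below target"))
  invisible(x)
}

#' External margin of exposure
#'
#' @param bmdl benchmark dose lower bound, mg/kg.
#' @param exposure intake estimate(s), mg/kg/day: a scalar summary or a
#'   vector of draws.
#' @param target acceptability threshold (default 100; regulatory
#'   comparisons for these compounds typically use 1e4).
#' @return `pyre_margin`.
#' @export
compute_moe <- function(bmdl, exposure, target = 100) {
  stopifnot(bmdl > 0)
  if (any(!is.finite(exposure)) || any(exposure <= 0))
    stop("exposure must be positive", call. = FALSE)
  margin_result(bmdl / exposure, target, "MOE")
}

#' Systemic point-of-departure set
#'
#' @param compound id.
#' @param bmdl external BMDL, mg/kg.
#' @param metrics `pyre_dose_metrics` simulated at the BMDL dose in the
#'   rat model.
#' @return object of class `pyre_pod`.
#' @export
pod_set <- function(compound, bmdl, metrics) {
  stopifnot(bmdl > 0, inherits(metrics, "pyre_dose_metrics"))
  if (any(unlist(metrics) <= 0))
    stop("systemic POD metrics must be positive", call. = FALSE)
  structure(list(compound = compound, bmdl = bmdl, metrics = metrics),
            class = "pyre_pod")
}

#' Internal margin of exposure
#'
#' @param pod `pyre_pod`.
#' @param human_metrics data.frame of human dose-metric draws from
#'   [monte_carlo_human_metrics()].
#' @param metric one of cmax_plasma, auc_plasma, cmax_brain, auc_brain.
#' @param target acceptability threshold.
#' @return `pyre_margin` over draws.
#' @export
compute_moie <- function(pod, human_metrics,
                         metric = c("cmax_plasma", "auc_plasma",
                                    "cmax_brain", "auc_brain"),
                         target = 100) {
  metric <- match.arg(metric)
  if (!metric %in% names(human_metrics))
    stop("metric ", metric, " missing from human draws", call. = FALSE)
  num <- pod$metrics[[metric]]
  if (is.null(num)) stop("metric ", metric, " missing from POD",
                         call. = FALSE)
  den <- human_metrics[[metric]]
  if (any(den <= 0)) stop("human dose-metric draws must be positive",
                          call. = FALSE)
  margin_result(num / den, target, "MOIE", metric)
}

#' Risk table over compounds and metrics
#'
#' @param margins named list of `pyre_margin`.
#' @return data.frame: name, kind, metric, median, p05, target, flag.
#' @export
risk_table <- function(margins) {
  do.call(rbind, lapply(names(margins), function(nm) {
    m <- margins[[nm]]
    data.frame(name = nm, kind = m$kind, metric = m$metric,
               median = m$median, p05 = m$p05, target = m$target,
               acceptable = m$acceptable, stringsAsFactors = FALSE)
  }))
}
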
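#' Censored urinary biomarker survey tables
#'
#' A survey table is a long-format data.frame of individual spot-urine
#' measurements: one row per (subject, metabolite), with the
#' metabolite-and-cycle-specific limit of detection (LOD), a censoring
#' flag, and the covariates the dosimetry needs (age group, body weight,
#' optional urinary creatinine, optional survey weight). Non-detects
#' carry a missing concentration.
#'
#' @name survey
NULL

SURVEY_COLS <- c("subject_id", "cycle", "age_group", "body_weight",
                 "metabolite", "value", "lod", "below_lod")

#' Construct / validate a survey table
#'
#' @param records data.frame with columns subject_id, cycle, age_group,
#'   body_weight, metabolite, value (ng/mL; NA when below the LOD), lod
#'   (ng/mL), below_lod (logical); optional creatinine (g/L) and weight.
#' @return the validated data.frame with class `pyre_survey`.
#' @export
survey_table <- function(records) {
  records <- as.data.frame(records)
  missing_cols <- setdiff(SURVEY_COLS, names(records))
  if (length(missing_cols))
    stop("survey table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"weight" %in% names(records)) records$weight <- 1
  if (any(records$lod <= 0, na.rm = TRUE))
    stop("LOD must be positive", call. = FALSE)
  bad <- records$below_lod & !is.na(records$value)
  if (any(bad))
    stop("below-LOD records must have missing value", call. = FALSE)
  bad2 <- !records$below_lod &
    (is.na(records$value) | records$value < records$lod)
  if (any(bad2))
    stop("detected records must carry value >= LOD", call. = FALSE)
  class(records) <- c("pyre_survey", "data.frame")
  records
}

#' Read / write the canonical survey CSV
#' @param path file path.
#' @return `pyre_survey`.
#' @export
read_survey <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  d$below_lod <- as.logical(d$below_lod)
  survey_table(d)
}

#' @rdname read_survey
#' @param table `pyre_survey`.
#' @export
write_survey <- function(table, path) {
  d <- as.data.frame(table)
  for (j in seq_along(d)) if (is.double(d[[j]]))
    d[[j]] <- sprintf("%.17g", d[[j]])
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(table)
}

select_records <- function(table, metabolite = NULL, cycle = NULL,
                           age_group = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(metabolite)) keep <- keep & table$metabolite %in% metabolite
  if (!is.null(cycle)) keep <- keep & table$cycle %in% cycle
  if (!is.null(age_group)) keep <- keep & table$age_group %in% age_group
  out <- table[keep, , drop = FALSE]
  if (!nrow(out)) stop("selection matches no records", call. = FALSE)
  out
}

#' Detection rate of a metabolite
#'
#' Fraction of records at or above the LOD in the selected stratum.
#'
#' @param table `pyre_survey`.
#' @param metabolite metabolite id.
#' @param cycle,age_group optional filters.
#' @return fraction in [0, 1].
#' @export
detection_rate <- function(table, metabolite, cycle = NULL,
                           age_group = NULL) {
  d <- select_records(table, metabolite, cycle, age_group)
  mean(!d$below_lod)
}

#' Substitute censored values for descriptive statistics
#'
#' Non-detects are replaced by LOD/sqrt(2) (default), LOD/2, or 0.
#' Inference never uses substitution; this is only for descriptive
#' summaries (detection tables, percentile ratios, trends).
#'
#' @param d survey rows.
#' @param policy "lod_sqrt2", "lod_half" or "zero".
#' @return numeric vector of concentrations.
#' @export
impute_censored <- function(d, policy = c("lod_sqrt2", "lod_half", "zero")) {
  policy <- match.arg(policy)
  v <- d$value
  sub <- switch(policy, lod_sqrt2 = d$lod / sqrt(2),
                lod_half = d$lod / 2, zero = 0)
  v[d$below_lod] <- sub[d$below_lod]
  v
}

#' Upper-to-median percentile ratio
#'
#' P95/P50 (by default) of a positive sample, a unitless index of
#' population variability. For lognormal data with geometric standard
#' deviation GSD the large-sample value is GSD^1.6449 (z_{0.95}).
#' Quantiles use linear interpolation between order statistics (type 7).
#'
#' @param values positive numeric sample.
#' @param upper,lower percentiles in (0, 100).
#' @param min_n minimum sample size (default 20).
#' @return ratio >= 0.
#' @export
percentile_ratio <- function(values, upper = 95, lower = 50, min_n = 20) {
  values <- values[is.finite(values)]
  if (length(values) < min_n)
    stop("need at least ", min_n, " values", call. = FALSE)
  q <- stats::quantile(values, c(upper, lower) / 100, type = 7, names = FALSE)
  if (q[2] <= 0) stop("lower percentile is not positive", call. = FALSE)
  q[1] / q[2]
}

#' Per-cycle geometric mean trend of a metabolite
#'
#' Geometric means with log-scale normal-approximation confidence
#' intervals, one per cycle. Censored values are substituted per
#' `policy`; a cycle with no detected record is flagged and its GM is
#' reported as the LOD-based upper bound.
#'
#' @param table `pyre_survey`.
#' @param metabolite metabolite id.
#' @param policy censoring substitution policy (see [impute_censored()]).
#' @param conf confidence level.
#' @return data.frame: cycle, n, detected, gm, lo, hi, all_censored.
#' @export
geometric_mean_trend <- function(table, metabolite, policy = "lod_sqrt2",
                                 conf = 0.95) {
  d <- select_records(table, metabolite)
  cycles <- sort(unique(d$cycle))
  if (length(cycles) < 2)
    stop("metabolite measured in fewer than 2 cycles", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- lapply(cycles, function(cy) {
    dd <- d[d$cycle == cy, , drop = FALSE]
    allc <- all(dd$below_lod)
    v <- impute_censored(dd, policy)
    if (allc) {
      gm <- exp(mean(log(dd$lod)))      # below-LOD bound
      return(data.frame(cycle = cy, n = nrow(dd), detected = 0,
                        gm = gm, lo = NA_real_, hi = NA_real_,
                        all_censored = TRUE))
    }
    lg <- log(v[v > 0])
    se <- stats::sd(lg) / sqrt(length(lg))
    data.frame(cycle = cy, n = nrow(dd), detected = sum(!dd$below_lod),
               gm = exp(mean(lg)), lo = exp(mean(lg) - z * se),
               hi = exp(mean(lg) + z * se), all_censored = FALSE)
  })
  do.call(rbind, out)
}

#' Exposure-pattern similarity across age groups
#'
#' Hierarchical clustering (Euclidean distance on log10 medians, average
#' linkage) of the age-group-by-cycle matrix of median exposures. The
#' result is deterministic in the input matrix and invariant to the
#' ordering of cycle columns.
#'
#' @param median_matrix numeric matrix, rows = age groups, columns =
#'   cycles, of median exposures or concentrations (positive).
#' @return an `hclust` object over the age groups.
#' @export
age_group_similarity <- function(median_matrix) {
  stopifnot(is.matrix(median_matrix))
  if (nrow(median_matrix) < 2)
    stop("need at least 2 age groups", call. = FALSE)
  if (any(!is.finite(median_matrix)) || any(median_matrix <= 0))
    stop("median matrix must be complete and positive", call. = FALSE)
  stats::hclust(stats::dist(log10(median_matrix)), method = "average")
}
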
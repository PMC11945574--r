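#' Bayesian benchmark-dose estimation for continuous endpoints
#'
#' Group-summary dose-response data (dose, n, mean, SD) are fit with
#' eight standard continuous families under vague priors by adaptive
#' random-walk MCMC; the benchmark response is a shift of the mean equal
#' to one control standard deviation (the modeled residual SD), in the
#' adverse direction inferred from the data. The benchmark dose (BMD) is
#' solved per posterior draw; model-averaged results mix per-model BMD
#' posteriors by posterior model weights from a Laplace-Metropolis
#' marginal-likelihood approximation. The BMDL is the 5th percentile of
#' the averaged posterior (one-sided 95% lower bound).
#'
#' @name bmd
NULL

BMD_FAMILIES <- c("linear", "polynomial2", "power", "hill",
                  "exponential2", "exponential3", "exponential4",
                  "exponential5")

#' Dose-response data container
#'
#' @param dose,n,mean,sd group-level summaries; a dose-0 control group
#'   is required, doses distinct and non-negative, n >= 1, sd >= 0.
#' @param endpoint label (e.g. "locomotor activity").
#' @return data.frame of class `pyre_doseresponse`.
#' @export
dose_response_data <- function(dose, n, mean, sd,
                               endpoint = "locomotor activity") {
  stopifnot(length(dose) == length(n), length(mean) == length(dose),
            length(sd) == length(dose))
  if (any(duplicated(dose)) || any(dose < 0))
    stop("doses must be distinct and non-negative", call. = FALSE)
  if (!any(dose == 0)) stop("a dose-0 control group is required",
                            call. = FALSE)
  stopifnot(all(n >= 1), all(sd >= 0))
  d <- data.frame(dose = dose, n = n, mean = mean, sd = sd)
  d <- d[order(d$dose), ]
  attr(d, "endpoint") <- endpoint
  class(d) <- c("pyre_doseresponse", "data.frame")
  d
}

## mean functions; theta is the natural parameter vector per family
bmd_mean_fun <- function(family) {
  switch(family,
    linear       = function(d, th) th[1] + th[2] * d,
    polynomial2  = function(d, th) th[1] + th[2] * d + th[3] * d^2,
    power        = function(d, th) th[1] + th[2] * d^th[3],
    hill         = function(d, th)
      th[1] + th[2] * d^th[4] / (th[3]^th[4] + d^th[4]),
    exponential2 = function(d, th) th[1] * exp(th[2] * d),
    exponential3 = function(d, th) th[1] * exp(th[2] * sign(d) * abs(d)^th[3]),
    exponential4 = function(d, th) th[1] * (th[3] + (1 - th[3]) *
                                              exp(-th[2] * d)),
    exponential5 = function(d, th) th[1] * (th[3] + (1 - th[3]) *
                                              exp(-(th[2] * d)^th[4])),
    stop("unknown family: ", family, call. = FALSE))
}

## parameterization on the sampling scale (unconstrained); returns the
## natural parameters. Shape/power exponents are kept in [1, 18]
## (standard restriction against supralinear low-dose behaviour); the
## exponential-4/5 asymptote ratio th[3] is positive.
bmd_transform <- function(family, data) {
  m0 <- data$mean[data$dose == 0]
  dmax <- max(data$dose)
  rng <- max(abs(diff(range(data$mean))), stats::median(data$sd), 1e-6)
  pw <- function(x) 1 + 17 * stats::plogis(x)   # exponent in (1, 18)
  switch(family,
    linear = list(
      k = 3, init = c(m0, -rng / max(dmax, 1), log(stats::median(
        pmax(data$sd, rng / 10)))),
      to_theta = function(x) c(x[1], x[2]),
      sigma = function(x) exp(x[3])),
    polynomial2 = list(
      k = 4, init = c(m0, -rng / max(dmax, 1), 0,
                      log(stats::median(pmax(data$sd, rng / 10)))),
      to_theta = function(x) c(x[1], x[2], x[3] / max(dmax, 1)),
      sigma = function(x) exp(x[4])),
    power = list(
      k = 4, init = c(m0, -rng / max(dmax, 1), 0,
                      log(stats::median(pmax(data$sd, rng / 10)))),
      to_theta = function(x) c(x[1], x[2], pw(x[3])),
      sigma = function(x) exp(x[4])),
    hill = list(
      k = 5, init = c(m0, -rng, log(max(dmax / 2, 1e-3)), 0,
                      log(stats::median(pmax(data$sd, rng / 10)))),
      to_theta = function(x) c(x[1], x[2], exp(x[3]), pw(x[4])),
      sigma = function(x) exp(x[5])),
    exponential2 = list(
      k = 3, init = c(max(m0, 1e-6), -0.1 / max(dmax, 1) * 10,
                      log(stats::median(pmax(data$sd, rng / 10)))),
      to_theta = function(x) c(abs(x[1]) + 1e-12, x[2]),
      sigma = function(x) exp(x[3])),
    exponential3 = list(
      k = 4, init = c(max(m0, 1e-6), -0.1, 0,
                      log(stats::median(pmax(data$sd, rng / 10)))),
      to_theta = function(x) c(abs(x[1]) + 1e-12, x[2], pw(x[3])),
      sigma = function(x) exp(x[4])),
    exponential4 = list(
      k = 4, init = c(max(m0, 1e-6), log(1 / max(dmax, 1)), 0,
                      log(stats::median(pmax(data$sd, rng / 10)))),
      to_theta = function(x) c(abs(x[1]) + 1e-12, exp(x[2]),
                               exp(x[3]) / (1 + exp(x[3])) * 2),
      sigma = function(x) exp(x[4])),
    exponential5 = list(
      k = 5, init = c(max(m0, 1e-6), log(1 / max(dmax, 1)), 0, 0,
                      log(stats::median(pmax(data$sd, rng / 10)))),
      to_theta = function(x) c(abs(x[1]) + 1e-12, exp(x[2]),
                               exp(x[3]) / (1 + exp(x[3])) * 2, pw(x[4])),
      sigma = function(x) exp(x[5])),
    stop("unknown family: ", family, call. = FALSE))
}

## normal likelihood from group sufficient statistics
bmd_loglik <- function(x, tr, f, data) {
  th <- tr$to_theta(x); sg <- tr$sigma(x)
  mu <- f(data$dose, th)
  if (any(!is.finite(mu)) || !is.finite(sg) || sg <= 0) return(-Inf)
  sum(-data$n * log(sg) -
        (data$n * (data$mean - mu)^2 + (data$n - 1) * data$sd^2) /
        (2 * sg^2))
}

## vague priors on the sampling scale: wide normals keep the posterior
## proper without informing the fit
bmd_logprior <- function(x, scale = 50) {
  sum(stats::dnorm(x, 0, scale, log = TRUE))
}

## BMD at BMR = 1 residual SD, adverse direction `dir` (-1 decreasing)
bmd_from_theta <- function(theta, sigma, family, f, dmax, dir) {
  target <- function(d) {
    v <- dir * (f(d, theta) - f(0, theta)) - sigma
    ifelse(is.finite(v), v, .Machine$double.xmax)   # overflowing curves
  }
  upper <- dmax * 100
  tu <- target(upper)
  if (tu <= 0) return(Inf)   # never reaches the BMR
  out <- try(stats::uniroot(target, c(0, upper), tol = 1e-10)$root,
             silent = TRUE)
  if (inherits(out, "try-error")) Inf else out
}

#' Fit one benchmark-dose model
#'
#' @param data `pyre_doseresponse`.
#' @param family one of `bmd_families()`.
#' @param chains,iterations MCMC settings; the second half of each chain
#'   is kept.
#' @param seed integer, mandatory.
#' @param bmr_sd benchmark response in control-SD units (default 1).
#' @return object of class `pyre_bmd_fit`: `bmd` draws (capped at 100x
#'   the top dose; `unbounded_frac` is the fraction of draws beyond the
#'   tested dose range, flagging flat responses), kept parameter draws,
#'   log marginal-likelihood estimate, convergence report, and the
#'   adverse direction used.
#' @export
fit_bmd_model <- function(data, family = "linear", chains = 3,
                          iterations = 30000, seed, bmr_sd = 1) {
  stopifnot(inherits(data, "pyre_doseresponse"),
            family %in% BMD_FAMILIES, chains >= 1, iterations >= 200)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  f <- bmd_mean_fun(family)
  tr <- bmd_transform(family, data)
  dmax <- max(data$dose)
  ## adverse direction: sign of the overall trend (decreasing activity
  ## is adverse for locomotor endpoints)
  dir <- if (stats::cov(data$dose, data$mean) <= 0) -1 else 1
  keep_from <- floor(iterations / 2) + 1L
  kept <- iterations - keep_from + 1L
  chain_draws <- vector("list", chains)
  chain_lp <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed((seed + 977L * ch) %% .Machine$integer.max)
    x <- tr$init + stats::rnorm(tr$k, 0, 0.05 * (abs(tr$init) + 0.1))
    lp <- bmd_loglik(x, tr, f, data) + bmd_logprior(x)
    step <- rep(0.1, tr$k)
    acc <- rep(0, tr$k); cnt <- 0
    dm <- matrix(NA_real_, kept, tr$k)
    lpv <- numeric(kept)
    for (it in seq_len(iterations)) {
      for (j in seq_len(tr$k)) {     # component-wise RW Metropolis
        x2 <- x; x2[j] <- x[j] + stats::rnorm(1, 0, step[j])
        lp2 <- bmd_loglik(x2, tr, f, data) + bmd_logprior(x2)
        if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
          x <- x2; lp <- lp2; acc[j] <- acc[j] + 1
        }
      }
      cnt <- cnt + 1
      if (it < keep_from && it %% 100 == 0) {
        step <- step * exp(acc / cnt - 0.35)
        acc[] <- 0; cnt <- 0
      }
      if (it >= keep_from) {
        dm[it - keep_from + 1L, ] <- x
        lpv[it - keep_from + 1L] <- lp
      }
    }
    chain_draws[[ch]] <- dm
    chain_lp[[ch]] <- lpv
  }
  conv <- if (chains >= 2) gelman_rubin(chain_draws) else NULL
  all_draws <- do.call(rbind, chain_draws)
  all_lp <- unlist(chain_lp)
  ## BMD per draw (thinned for speed)
  thin <- max(1L, floor(nrow(all_draws) / 2000))
  idx <- seq(1, nrow(all_draws), by = thin)
  cap <- dmax * 100
  bmd_draws <- vapply(idx, function(i) {
    x <- all_draws[i, ]
    b <- bmd_from_theta(tr$to_theta(x), bmr_sd * tr$sigma(x), family, f,
                        dmax, dir)
    min(b, cap)
  }, numeric(1))
  ## a BMD beyond the tested dose range is extrapolation; report the
  ## fraction so flat or near-flat responses are flagged
  unbounded_frac <- mean(bmd_draws >= dmax)
  ## Laplace-Metropolis marginal likelihood
  imax <- which.max(all_lp)
  S <- stats::cov(all_draws)
  ld <- determinant(S, logarithm = TRUE)
  logdet <- if (ld$sign > 0) as.numeric(ld$modulus) else -Inf
  logml <- all_lp[imax] + 0.5 * tr$k * log(2 * pi) + 0.5 * logdet
  structure(list(family = family, bmd = bmd_draws,
                 unbounded_frac = unbounded_frac,
                 draws = all_draws, logml = logml, convergence = conv,
                 direction = dir, bmr_sd = bmr_sd, cap = cap),
            class = "pyre_bmd_fit")
}

#' The eight-model continuous menu
#' @return character vector of family names.
#' @export
bmd_families <- function() BMD_FAMILIES

#' Posterior model weights
#'
#' Normalized weights from the per-model Laplace-Metropolis log marginal
#' likelihoods. Non-converged fits (split-Rhat at or above the
#' threshold) are excluded with a warning.
#'
#' @param fits list of `pyre_bmd_fit`.
#' @param rhat_threshold exclusion threshold (default 1.1).
#' @return named numeric weights summing to 1 over the retained fits
#'   (zero for excluded ones).
#' @export
posterior_model_weights <- function(fits, rhat_threshold = 1.1) {
  stopifnot(length(fits) >= 1)
  nm <- vapply(fits, `[[`, "", "family")
  ok <- vapply(fits, function(f)
    is.null(f$convergence) || max(f$convergence$rhat) < rhat_threshold,
    logical(1))
  if (!any(ok)) stop("no converged model fits", call. = FALSE)
  if (any(!ok))
    warning("excluding non-converged fit(s): ",
            paste(nm[!ok], collapse = ", "), call. = FALSE)
  lml <- vapply(fits, `[[`, numeric(1), "logml")
  w <- rep(0, length(fits))
  lz <- lml[ok] - max(lml[ok])
  w[ok] <- exp(lz) / sum(exp(lz))
  stats::setNames(w, nm)
}

#' Model-averaged benchmark dose
#'
#' Mixes the per-model BMD posteriors according to the posterior model
#' weights and summarizes the mixture: BMD = median, BMDL = 5th
#' percentile, BMDU = 95th percentile.
#'
#' @param fits list of `pyre_bmd_fit`.
#' @param weights from [posterior_model_weights()]; recomputed when NULL.
#' @param lower_percentile BMDL percentile (default 5).
#' @param mix_draws size of the mixture sample.
#' @param seed used for the mixture resampling.
#' @return object of class `pyre_avg_bmd`: bmd, bmdl, bmdu, weights,
#'   mixture draws, unbounded flag.
#' @export
model_average_bmd <- function(fits, weights = NULL, lower_percentile = 5,
                              mix_draws = 20000, seed = 1) {
  if (is.null(weights)) weights <- posterior_model_weights(fits)
  stopifnot(abs(sum(weights) - 1) < 1e-8, all(weights >= 0))
  set.seed(seed)
  counts <- stats::rmultinom(1, mix_draws, weights)[, 1]
  mix <- unlist(lapply(seq_along(fits), function(i) {
    if (counts[i] == 0) return(numeric(0))
    sample(fits[[i]]$bmd, counts[i], replace = TRUE)
  }))
  qs <- stats::quantile(mix, c(lower_percentile / 100, 0.5, 0.95),
                        names = FALSE)
  unb <- mean(!is.finite(mix) | mix >= fits[[1]]$cap)
  structure(list(bmd = qs[2], bmdl = qs[1], bmdu = qs[3],
                 weights = weights, draws = mix,
                 unbounded_frac = unb),
            class = "pyre_avg_bmd")
}

#' Fit the full menu and average
#'
#' Convenience wrapper: fits all (or a subset of) families, computes
#' weights, and averages.
#'
#' @inheritParams fit_bmd_model
#' @param families subset of [bmd_families()].
#' @return `pyre_avg_bmd` with the per-model fits attached as `fits`.
#' @export
bmd_analysis <- function(data, families = bmd_families(), chains = 3,
                         iterations = 30000, seed, bmr_sd = 1) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  fits <- lapply(families, function(fam)
    fit_bmd_model(data, fam, chains = chains, iterations = iterations,
                  seed = seed + match(fam, BMD_FAMILIES) * 7919L,
                  bmr_sd = bmr_sd))
  w <- posterior_model_weights(fits)
  avg <- model_average_bmd(fits, w, seed = seed)
  avg$fits <- fits
  avg
}
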
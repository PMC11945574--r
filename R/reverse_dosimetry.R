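#' Bayesian reverse dosimetry from censored urinary biomarkers
#'
#' Population daily intakes of parent pyrethroids are inferred from
#' left-censored urinary metabolite concentrations through the linear
#' steady-state map. The hierarchical model per stratum (compound group
#' x age group x cycle):
#' \itemize{
#'   \item individual log intake z_i ~ Normal(mu, sigma_pop) (natural log),
#'   \item predicted concentration = steady-state map of exp(z_i),
#'   \item detected observation: lognormal around the prediction with
#'     residual SD sigma_res (log scale),
#'   \item non-detect: Normal density with SD = LOD/4 evaluated at a
#'     policy value (0 or LOD/2) against the prediction,
#'   \item priors: mu uniform on log10 intake over [-12, 0] (mg/kg/day),
#'     sigma_pop^2 ~ inverse-gamma(shape 5.0, scale 2.25),
#'     sigma_res^2 ~ half-normal(sd 0.3) (GSD exp(sqrt(0.3)) ~ 1.7).
#' }
#' Sampling is adaptive Metropolis-within-Gibbs: vectorized random-walk
#' updates of the latent intakes, conjugate draws for mu (truncated
#' normal) and sigma_pop^2 (inverse-gamma), and a random-walk step for
#' the residual variance.
#'
#' @name reverse_dosimetry
NULL

#' Prior specification
#'
#' @param log10_intake_range support of the uniform prior on log10
#'   intake, mg/kg/day.
#' @param popvar_shape,popvar_scale inverse-gamma prior on the
#'   population log-scale variance (prior mean variance
#'   scale/(shape-1) = 0.5625, i.e. GSD ~ 2).
#' @param resvar_halfnormal_sd half-normal prior SD on the residual
#'   log-scale variance.
#' @return object of class `pyre_priors`.
#' @export
prior_spec <- function(log10_intake_range = c(-12, 0),
                       popvar_shape = 5.0, popvar_scale = 2.25,
                       resvar_halfnormal_sd = 0.3) {
  stopifnot(log10_intake_range[1] < log10_intake_range[2],
            popvar_shape > 2, popvar_scale > 0,
            resvar_halfnormal_sd > 0)
  structure(list(log10_intake_range = log10_intake_range,
                 popvar_shape = popvar_shape, popvar_scale = popvar_scale,
                 resvar_halfnormal_sd = resvar_halfnormal_sd),
            class = "pyre_priors")
}

#' Geometric standard deviation implied by a log-scale variance
#' @param v variance on the natural-log scale.
#' @return exp(sqrt(v)).
#' @export
gsd_from_logvar <- function(v) exp(sqrt(v))

#' Observation log-likelihood for one record
#'
#' Detected records contribute a lognormal density of the observed
#' concentration given the prediction; non-detects contribute a normal
#' density with SD = LOD/4 of the policy value (0 or LOD/2) given the
#' prediction.
#'
#' @param value observed concentration, ng/mL (NA when below LOD).
#' @param below_lod logical.
#' @param lod limit of detection, ng/mL.
#' @param predicted predicted concentration, ng/mL (> 0).
#' @param residual_sd log-scale residual SD.
#' @param lod_policy "half_lod" or "zero".
#' @return log density.
#' @export
log_likelihood <- function(value, below_lod, lod, predicted, residual_sd,
                           lod_policy = c("half_lod", "zero")) {
  lod_policy <- match.arg(lod_policy)
  if (!is.finite(predicted) || predicted <= 0)
    stop("predicted concentration must be positive", call. = FALSE)
  if (below_lod) {
    pol <- if (lod_policy == "half_lod") lod / 2 else 0
    stats::dnorm(pol, mean = predicted, sd = lod / 4, log = TRUE)
  } else {
    stats::dlnorm(value, meanlog = log(predicted), sdlog = residual_sd,
                  log = TRUE)
  }
}

## ---- internal: one-stratum sampler ---------------------------------------

# obs_log: n x M matrix of log observed (NA if censored/absent)
# cens:    n x M logical (TRUE = below LOD); NA-absent cells FALSE w/ mask
# present: n x M logical, record exists
# lod:     n x M
# B0:      G x M steady-state coefficients at BW = 1 (free groups only,
#          tied groups folded in)
# bw:      length-n body weights
stratum_loglik <- function(Z, sres, obs_log, cens, present, lod, polval,
                           B0, bw) {
  pred <- (exp(Z) * bw) %*% B0            # n x M
  ll <- matrix(0, nrow(pred), ncol(pred))
  det <- present & !cens
  if (any(det))
    ll[det] <- stats::dnorm(obs_log[det], log(pred[det]), sres, log = TRUE)
  cc <- present & cens
  if (any(cc))
    ll[cc] <- stats::dnorm(polval[cc], pred[cc], lod[cc] / 4, log = TRUE)
  rowSums(ll)
}

## Marginalized sampler for a single compound group.
## Subjects whose records are all detected have an exactly Gaussian
## marginal (the latent intake integrates out analytically); subjects
## with a censored record keep an explicit latent. Population location
## is conjugate; the two variances move by a joint 2-D random walk on
## the marginal posterior, which has no funnel geometry.
run_marginal_chain <- function(dat, priors, iterations, burn_frac,
                               lod_policy, chain_seed, thin_latents = 0) {
  set.seed(chain_seed)
  n <- length(dat$bw)
  lo <- priors$log10_intake_range[1] * log(10)
  hi <- priors$log10_intake_range[2] * log(10)
  off <- sweep(matrix(log(dat$B0[1, ]), n, ncol(dat$obs_log),
                      byrow = TRUE), 1, log(dat$bw), `+`)
  det_cells <- dat$present & !dat$cens
  has_cens <- rowSums(dat$present & dat$cens) > 0
  D <- which(!has_cens & rowSums(det_cells) > 0)
  C <- which(has_cens)
  ## sufficient statistics for the marginalized (all-detected) subjects
  resid <- dat$obs_log - off
  resid[!det_cells] <- 0
  kD <- rowSums(det_cells)[D]
  tD <- rowSums(resid)[D]
  SD <- rowSums((resid * det_cells)^2)[D]
  ## censored-subject record data
  nC <- length(C)
  polC <- if (nC) {
    pv <- if (lod_policy == "half_lod") dat$lod[C, , drop = FALSE] / 2 else
      matrix(0, nC, ncol(dat$lod))
    pv
  } else NULL
  loglik_D <- function(mu, s2g, s2r) {
    if (!length(D)) return(0)
    v <- s2r + kD * s2g
    r <- tD - kD * mu
    q <- SD - 2 * mu * tD + kD * mu^2
    sum(-0.5 * ((kD - 1) * log(s2r) + log(v)) -
          0.5 * (q / s2r - s2g * r^2 / (s2r * v)))
  }
  loglik_C <- function(z, s2r) {
    if (!nC) return(numeric(0))
    pred <- exp(off[C, , drop = FALSE] + z)   # n_C x M
    ll <- matrix(0, nC, ncol(pred))
    dd <- det_cells[C, , drop = FALSE]
    cc <- dat$present[C, , drop = FALSE] & dat$cens[C, , drop = FALSE]
    if (any(dd))
      ll[dd] <- stats::dnorm(dat$obs_log[C, , drop = FALSE][dd],
                             log(pred[dd]), sqrt(s2r), log = TRUE)
    if (any(cc))
      ll[cc] <- stats::dnorm(polC[cc], pred[cc],
                             dat$lod[C, , drop = FALSE][cc] / 4,
                             log = TRUE)
    rowSums(ll)
  }
  lprior_var <- function(s2g, s2r) {
    (-priors$popvar_shape - 1) * log(s2g) - priors$popvar_scale / s2g +
      stats::dnorm(s2r, 0, priors$resvar_halfnormal_sd, log = TRUE)
  }
  mu <- stats::runif(1, lo + 0.25 * (hi - lo), hi - 0.25 * (hi - lo))
  s2g <- priors$popvar_scale / (priors$popvar_shape - 1)
  s2r <- 0.09
  zC <- stats::rnorm(nC, mu, sqrt(s2g))
  llC <- loglik_C(zC, s2r)
  step_z <- 0.5; step_v <- 0.4
  acc_z <- 0; acc_v <- 0; cnt <- 0
  keep_from <- floor(iterations * burn_frac) + 1L
  kept <- iterations - keep_from + 1L
  draws <- matrix(NA_real_, kept, 3)
  colnames(draws) <- c(paste0("mu_", dat$groups),
                       paste0("sigma_", dat$groups), "sigma_res")
  lat <- if (thin_latents > 0 && nC)
    matrix(NA_real_, ceiling(kept / thin_latents), nC) else NULL
  for (it in seq_len(iterations)) {
    ## latents of censored subjects: vectorized random walk
    if (nC) {
      z2 <- zC + stats::rnorm(nC, 0, step_z)
      ll2 <- loglik_C(z2, s2r)
      lpr <- stats::dnorm(z2, mu, sqrt(s2g), log = TRUE) -
        stats::dnorm(zC, mu, sqrt(s2g), log = TRUE)
      acc <- log(stats::runif(nC)) < ll2 - llC + lpr
      zC[acc] <- z2[acc]; llC[acc] <- ll2[acc]
      acc_z <- acc_z + mean(acc)
    }
    ## mu: conjugate Gaussian (marginal subjects + latents), truncated
    P <- sum(kD / (s2r + kD * s2g)) + nC / s2g
    mn <- (sum(tD / (s2r + kD * s2g)) + sum(zC) / s2g) / P
    s <- 1 / sqrt(P)
    u <- stats::runif(1, stats::pnorm(lo, mn, s), stats::pnorm(hi, mn, s))
    mu <- stats::qnorm(u, mn, s)
    ## (sigma_pop^2, sigma_res^2): joint 2-D log-scale random walk
    e <- stats::rnorm(2, 0, step_v)
    s2g_p <- s2g * exp(e[1]); s2r_p <- s2r * exp(e[2])
    ## latents move non-centrally with the population scale so the
    ## proposal stays on the typical set
    zC_p <- mu + (zC - mu) * sqrt(s2g_p / s2g)
    llC_p <- loglik_C(zC_p, s2r_p)
    lr <- loglik_D(mu, s2g_p, s2r_p) - loglik_D(mu, s2g, s2r) +
      sum(llC_p) - sum(llC) +
      lprior_var(s2g_p, s2r_p) - lprior_var(s2g, s2r) +
      e[1] + e[2]   # Jacobians; the z-rescale cancels against its prior
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      s2g <- s2g_p; s2r <- s2r_p; zC <- zC_p; llC <- llC_p
      acc_v <- acc_v + 1
    }
    ## variance exchange at constant total: the single-record marginal
    ## depends on the variances only through their sum, so this move
    ## traverses the weakly-identified ridge essentially freely
    e2 <- stats::rnorm(1, 0, 0.6)
    s2r_p <- s2r * exp(e2)
    s2g_p <- s2g + s2r - s2r_p
    if (s2g_p > 0) {
      zC_p <- mu + (zC - mu) * sqrt(s2g_p / s2g)
      llC_p <- loglik_C(zC_p, s2r_p)
      lr <- loglik_D(mu, s2g_p, s2r_p) - loglik_D(mu, s2g, s2r) +
        sum(llC_p) - sum(llC) +
        lprior_var(s2g_p, s2r_p) - lprior_var(s2g, s2r) + e2
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        s2g <- s2g_p; s2r <- s2r_p; zC <- zC_p; llC <- llC_p
      }
    }
    cnt <- cnt + 1
    if (it < keep_from && it %% 50 == 0) {
      step_z <- step_z * exp(acc_z / cnt - 0.35)
      step_v <- step_v * exp(acc_v / cnt - 0.25)
      acc_z <- 0; acc_v <- 0; cnt <- 0
    }
    if (it >= keep_from) {
      k <- it - keep_from + 1L
      draws[k, ] <- c(mu, sqrt(s2g), sqrt(s2r))
      if (!is.null(lat) && k %% thin_latents == 0)
        lat[k / thin_latents, ] <- zC
    }
  }
  list(draws = draws, latents = lat)
}

## Latent-variable sampler for several jointly-estimated compound
## groups (shared metabolites couple the groups, so nothing
## marginalizes); adaptive Metropolis-within-Gibbs with group
## translation and rescale moves.
run_stratum_chain <- function(dat, priors, iterations, burn_frac,
                              lod_policy, chain_seed, thin_latents = 0) {
  if (nrow(dat$B0) == 1)
    return(run_marginal_chain(dat, priors, iterations, burn_frac,
                              lod_policy, chain_seed, thin_latents))
  set.seed(chain_seed)
  n <- length(dat$bw); G <- nrow(dat$B0)
  lo <- priors$log10_intake_range[1] * log(10)
  hi <- priors$log10_intake_range[2] * log(10)
  polval <- if (lod_policy == "half_lod") dat$lod / 2 else
    matrix(0, n, ncol(dat$lod))
  mu <- stats::runif(G, lo + 0.25 * (hi - lo), hi - 0.25 * (hi - lo))
  sig2 <- rep(priors$popvar_scale / (priors$popvar_shape - 1), G)
  sres2 <- 0.09
  Z <- matrix(stats::rnorm(n * G, rep(mu, each = n),
                           rep(sqrt(sig2), each = n)), n, G)
  step_z <- rep(0.5, G); step_r <- 0.5
  keep_from <- floor(iterations * burn_frac) + 1L
  kept <- iterations - keep_from + 1L
  draws <- matrix(NA_real_, kept, 2 * G + 1)
  colnames(draws) <- c(paste0("mu_", dat$groups),
                       paste0("sigma_", dat$groups), "sigma_res")
  lat <- if (thin_latents > 0)
    array(NA_real_, c(ceiling(kept / thin_latents), n, G)) else NULL
  ll_cur <- stratum_loglik(Z, sqrt(sres2), dat$obs_log, dat$cens,
                           dat$present, dat$lod, polval, dat$B0, dat$bw)
  acc_z <- rep(0, G); acc_r <- 0; adapt_n <- 0
  for (it in seq_len(iterations)) {
    ## latent intakes, vectorized per group
    for (g in seq_len(G)) {
      Z2 <- Z
      Z2[, g] <- Z[, g] + stats::rnorm(n, 0, step_z[g])
      ll_new <- stratum_loglik(Z2, sqrt(sres2), dat$obs_log, dat$cens,
                               dat$present, dat$lod, polval, dat$B0, dat$bw)
      lpr <- stats::dnorm(Z2[, g], mu[g], sqrt(sig2[g]), log = TRUE) -
        stats::dnorm(Z[, g], mu[g], sqrt(sig2[g]), log = TRUE)
      acc <- log(stats::runif(n)) < ll_new - ll_cur + lpr
      Z[acc, g] <- Z2[acc, g]
      ll_cur[acc] <- ll_new[acc]
      acc_z[g] <- acc_z[g] + mean(acc)
    }
    ## mu and sigma_pop^2: conjugate given Z
    for (g in seq_len(G)) {
      m <- mean(Z[, g]); s <- sqrt(sig2[g] / n)
      u <- stats::runif(1, stats::pnorm(lo, m, s), stats::pnorm(hi, m, s))
      mu[g] <- stats::qnorm(u, m, s)
      ss <- sum((Z[, g] - mu[g])^2)
      sig2[g] <- 1 / stats::rgamma(1, priors$popvar_shape + n / 2,
                                   priors$popvar_scale + ss / 2)
    }
    ## group moves: translate (Z, mu) jointly and rescale the latent
    ## dispersion with sigma_pop; both traverse posterior ridges that
    ## single-site updates cross slowly
    for (g in seq_len(G)) {
      dlt <- stats::rnorm(1, 0, 0.1)
      if (mu[g] + dlt > lo && mu[g] + dlt < hi) {
        Z2 <- Z; Z2[, g] <- Z[, g] + dlt
        ll_new <- stratum_loglik(Z2, sqrt(sres2), dat$obs_log, dat$cens,
                                 dat$present, dat$lod, polval, dat$B0,
                                 dat$bw)
        if (log(stats::runif(1)) < sum(ll_new - ll_cur)) {
          Z <- Z2; mu[g] <- mu[g] + dlt; ll_cur <- ll_new
        }
      }
      eps <- stats::rnorm(1, 0, 0.1); cf <- exp(eps)
      Z2 <- Z; Z2[, g] <- mu[g] + (Z[, g] - mu[g]) * cf
      s2p_g <- sig2[g] * cf^2
      ll_new <- stratum_loglik(Z2, sqrt(sres2), dat$obs_log, dat$cens,
                               dat$present, dat$lod, polval, dat$B0,
                               dat$bw)
      ## prior(Z|mu,sigma*cf) and the Z-Jacobian cancel; remaining:
      ## inverse-gamma ratio at sig2*cf^2 plus the log-scale Jacobian
      lr <- sum(ll_new - ll_cur) +
        (-priors$popvar_shape - 1) * log(cf^2) -
        priors$popvar_scale * (1 / s2p_g - 1 / sig2[g]) + 2 * eps
      if (log(stats::runif(1)) < lr) {
        Z <- Z2; sig2[g] <- s2p_g; ll_cur <- ll_new
      }
    }
    ## residual variance: log-scale random walk with a coupled rescale
    ## of every latent column against its population variance
    e <- stats::rnorm(1, 0, step_r)
    s2p <- sres2 * exp(e)
    tot <- sig2 + sres2
    sig2_p <- tot - s2p
    if (all(sig2_p > 0)) {
      Z2 <- Z
      for (g in seq_len(G))
        Z2[, g] <- mu[g] + (Z[, g] - mu[g]) * sqrt(sig2_p[g] / sig2[g])
      ll_prop <- stratum_loglik(Z2, sqrt(s2p), dat$obs_log, dat$cens,
                                dat$present, dat$lod, polval, dat$B0,
                                dat$bw)
      lr <- sum(ll_prop - ll_cur) +
        sum((-priors$popvar_shape - 1) * log(sig2_p / sig2) -
              priors$popvar_scale * (1 / sig2_p - 1 / sig2)) +
        (sres2^2 - s2p^2) / (2 * priors$resvar_halfnormal_sd^2) +
        e
      if (log(stats::runif(1)) < lr) {
        sres2 <- s2p; sig2 <- sig2_p; Z <- Z2; ll_cur <- ll_prop
        acc_r <- acc_r + 1
      }
    }
    adapt_n <- adapt_n + 1
    if (it < keep_from && it %% 50 == 0) {
      step_z <- step_z * exp(acc_z / adapt_n - 0.35)
      step_r <- step_r * exp(acc_r / adapt_n - 0.25)
      acc_z[] <- 0; acc_r <- 0; adapt_n <- 0
    }
    if (it >= keep_from) {
      k <- it - keep_from + 1L
      draws[k, ] <- c(mu, sqrt(sig2), sqrt(sres2))
      if (!is.null(lat) && k %% thin_latents == 0)
        lat[k / thin_latents, , ] <- Z
    }
  }
  list(draws = draws, latents = lat)
}

#' Sample the posterior of population intakes
#'
#' Fits the hierarchical censored model independently in every
#' (age group, cycle) stratum of the table, for the parent compound
#' groups identifiable from the measured metabolites.
#'
#' @param table `pyre_survey`.
#' @param registry `pyre_registry`.
#' @param params_list named per-compound `pyre_pbk_params` (defaults used
#'   when missing).
#' @param physiology_by_group named list of `pyre_physiology` per age
#'   group (defaults from [default_physiology()]).
#' @param priors `pyre_priors`.
#' @param compounds parent-group names to estimate; default: every group
#'   whose metabolites appear in the table.
#' @param tie named numeric: groups whose intake is a fixed ratio of
#'   another group's, e.g. `c(cypermethrin = 0.1)` ties cypermethrin to
#'   0.1 x permethrin (the default when cypermethrin has no specific
#'   biomarker in the table).
#' @param tie_to named character giving the anchor group for each tied
#'   group (default permethrin).
#' @param chains,iterations,burn_frac MCMC settings.
#' @param lod_policy "half_lod" or "zero" (below-LOD observation policy).
#' @param seed integer, mandatory.
#' @param store_latents keep thinned draws of latent individual intakes.
#' @return object of class `pyre_posterior`: per-stratum draw matrices
#'   (log10-intake medians, population GSD, residual GSD), a summary
#'   table, and a convergence report.
#' @export
sample_posterior <- function(table, registry = default_registry(),
                             params_list = NULL,
                             physiology_by_group = NULL,
                             priors = prior_spec(),
                             compounds = NULL,
                             tie = c(cypermethrin = 0.1),
                             tie_to = c(cypermethrin = "permethrin"),
                             chains = 3, iterations = 10000,
                             burn_frac = 0.5,
                             lod_policy = c("half_lod", "zero"),
                             seed, store_latents = FALSE) {
  lod_policy <- match.arg(lod_policy)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(chains >= 1, iterations >= 10)
  mets <- sort(unique(table$metabolite))
  unknown <- setdiff(mets, registry$metabolites$id)
  if (length(unknown))
    stop("metabolite(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  grp_of <- stats::setNames(registry$compounds$parent_group,
                            registry$compounds$id)
  ## groups producing any observed metabolite
  producers <- unique(grp_of[registry$matrix$compound[
    registry$matrix$metabolite %in% mets & registry$matrix$phi > 0]])
  if (!length(producers))
    stop("no parent compound produces the observed metabolites",
         call. = FALSE)
  if (is.null(compounds))
    compounds <- setdiff(producers, names(tie))
  free <- setdiff(compounds, names(tie))
  if (!length(free)) stop("no free compound groups to estimate",
                          call. = FALSE)
  strata <- unique(table[, c("age_group", "cycle")])
  fits <- list(); summaries <- list(); conv <- list()
  for (si in seq_len(nrow(strata))) {
    ag <- strata$age_group[si]; cy <- strata$cycle[si]
    sub <- table[table$age_group == ag & table$cycle == cy, , drop = FALSE]
    phys <- if (!is.null(physiology_by_group) &&
                ag %in% names(physiology_by_group))
      physiology_by_group[[ag]] else default_physiology(ag)
    dat <- build_stratum_data(sub, registry, params_list, phys,
                              free, tie, tie_to, mets)
    ch <- lapply(seq_len(chains), function(k)
      run_stratum_chain(dat, priors, iterations, burn_frac, lod_policy,
                        chain_seed = (seed + si * 131L + k) %% .Machine$integer.max,
                        thin_latents = if (store_latents) 50 else 0))
    key <- paste(ag, cy, sep = "|")
    fits[[key]] <- ch
    dr <- lapply(ch, `[[`, "draws")
    conv[[key]] <- gelman_rubin(dr)
    all_dr <- do.call(rbind, dr)
    for (g in dat$groups) {
      mu_d <- all_dr[, paste0("mu_", g)] / log(10)   # log10 mg/kg/day
      sg_d <- exp(all_dr[, paste0("sigma_", g)])     # population GSD
      qs <- stats::quantile(mu_d, c(0.05, 0.5, 0.95), names = FALSE)
      summaries[[length(summaries) + 1L]] <- data.frame(
        age_group = ag, cycle = cy, compound = g,
        log10_intake_med = qs[2], log10_intake_p05 = qs[1],
        log10_intake_p95 = qs[3],
        intake_gm = 10^qs[2], gsd_pop = stats::median(sg_d),
        gsd_res = stats::median(exp(all_dr[, "sigma_res"])),
        rhat_max = max(conv[[key]]$rhat), stringsAsFactors = FALSE)
    }
  }
  structure(list(fits = fits, summary = do.call(rbind, summaries),
                 convergence = conv, groups = free, seed = seed,
                 lod_policy = lod_policy, chains = chains,
                 iterations = iterations),
            class = "pyre_posterior")
}

build_stratum_data <- function(sub, registry, params_list, phys,
                               free, tie, tie_to, mets) {
  subj <- unique(sub$subject_id)
  n <- length(subj); M <- length(mets)
  idx_s <- match(sub$subject_id, subj)
  idx_m <- match(sub$metabolite, mets)
  obs_log <- matrix(NA_real_, n, M)
  cens <- matrix(FALSE, n, M); present <- matrix(FALSE, n, M)
  lod <- matrix(NA_real_, n, M)
  present[cbind(idx_s, idx_m)] <- TRUE
  cens[cbind(idx_s, idx_m)] <- sub$below_lod
  lod[cbind(idx_s, idx_m)] <- sub$lod
  det <- !sub$below_lod
  obs_log[cbind(idx_s[det], idx_m[det])] <- log(sub$value[det])
  bw <- sub$body_weight[match(subj, sub$subject_id)]
  ## group x metabolite coefficients at BW = 1
  coef1 <- steady_state_coefficients(registry, params_list, phys,
                                     body_weight = 1, metabolites = mets)
  grp_of <- stats::setNames(registry$compounds$parent_group,
                            registry$compounds$id)
  isof <- stats::setNames(registry$compounds$isomer_fraction,
                          registry$compounds$id)
  group_coef <- function(g) {
    ids <- names(grp_of)[grp_of == g]
    colSums(coef1[ids, , drop = FALSE] * isof[ids])
  }
  B0 <- matrix(0, length(free), M, dimnames = list(free, mets))
  for (g in free) B0[g, ] <- group_coef(g)
  for (tg in names(tie)) {
    anchor <- tie_to[[tg]]
    if (anchor %in% free)
      B0[anchor, ] <- B0[anchor, ] + tie[[tg]] * group_coef(tg)
  }
  keep <- rowSums(B0) > 0
  if (!all(keep)) B0 <- B0[keep, , drop = FALSE]
  if (!nrow(B0))
    stop("unidentifiable configuration: no metabolite links to the ",
         "requested compound groups", call. = FALSE)
  list(obs_log = obs_log, cens = cens, present = present, lod = lod,
       bw = bw, B0 = B0, groups = rownames(B0), metabolites = mets)
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain
#' in half. Parameters with zero total variance (constant chains) are
#' reported as 1 by convention.
#'
#' @param chains list of draw matrices (iterations x parameters), equal
#'   dimensions, one per chain.
#' @param threshold pass threshold (default 1.1).
#' @return object of class `pyre_convergence`: per-parameter `rhat`,
#'   effective sample size `ess`, and `pass`.
#' @export
gelman_rubin <- function(chains, threshold = 1.1) {
  if (!is.list(chains) || length(chains) < 2)
    stop("need at least 2 chains", call. = FALSE)
  len <- unique(vapply(chains, nrow, integer(1)))
  if (length(len) != 1 || len < 10)
    stop("chains must have equal length >= 10", call. = FALSE)
  half <- floor(len / 2)
  segs <- list()
  for (ch in chains) {
    segs[[length(segs) + 1L]] <- ch[seq_len(half), , drop = FALSE]
    segs[[length(segs) + 1L]] <- ch[(len - half + 1):len, , drop = FALSE]
  }
  P <- ncol(chains[[1]]); m <- length(segs); nn <- half
  rhat <- ess <- stats::setNames(numeric(P), colnames(chains[[1]]))
  for (p in seq_len(P)) {
    x <- vapply(segs, function(s) s[, p], numeric(nn))
    means <- colMeans(x); vars <- apply(x, 2, stats::var)
    W <- mean(vars); B <- nn * stats::var(means)
    if (!is.finite(W) || W <= .Machine$double.eps * max(1, mean(x)^2)) {
      rhat[p] <- 1; ess[p] <- nn * m
    } else {
      vhat <- (nn - 1) / nn * W + B / nn
      rhat[p] <- sqrt(vhat / W)
      ess[p] <- min(nn * m, nn * m * vhat / B)
    }
  }
  structure(list(rhat = rhat, ess = ess, threshold = threshold,
                 pass = all(rhat < threshold)),
            class = "pyre_convergence")
}

#' Censored-lognormal maximum-likelihood fit
#'
#' The simplified high-throughput treatment of non-detects: the
#' population urine concentration is assumed lognormal and GM/GSD are
#' estimated by maximum likelihood under left-censoring at the
#' record-specific LOD. The fitted CDF is compared to the empirical CDF
#' of the detected values as a goodness-of-fit report.
#'
#' @param values concentrations, ng/mL (NA for non-detects).
#' @param below_lod logical.
#' @param lod per-record LOD.
#' @return object of class `pyre_cens_fit`: gm, gsd, meanlog, sdlog,
#'   n, n_censored, cdf_max_gap (sup gap between fitted and empirical
#'   CDF over detected values), all_censored flag (with `gm_upper`
#'   LOD-based bound when TRUE).
#' @export
censored_lognormal_fit <- function(values, below_lod, lod) {
  stopifnot(length(values) == length(below_lod),
            length(lod) == length(values))
  if (all(below_lod)) {
    return(structure(list(gm = NA_real_, gsd = NA_real_,
                          meanlog = NA_real_, sdlog = NA_real_,
                          n = length(values), n_censored = length(values),
                          cdf_max_gap = NA_real_, all_censored = TRUE,
                          gm_upper = exp(mean(log(lod)))),
                     class = "pyre_cens_fit"))
  }
  cd <- data.frame(left = ifelse(below_lod, NA_real_, values),
                   right = ifelse(below_lod, lod, values))
  fit <- fitdistrplus::fitdistcens(cd, "lnorm")
  ml <- unname(fit$estimate["meanlog"]); sl <- unname(fit$estimate["sdlog"])
  ## fitted vs empirical CDF on the full-population scale: a censored
  ## record sits below its LOD, so it counts as below x once its LOD
  ## does
  det <- sort(values[!below_lod])
  n <- length(values)
  emp <- vapply(det, function(x)
    (sum(below_lod & lod <= x) + sum(!below_lod & values <= x)) / n,
    numeric(1))
  gap <- max(abs(stats::plnorm(det, ml, sl) - emp))
  structure(list(gm = exp(ml), gsd = exp(sl), meanlog = ml, sdlog = sl,
                 n = length(values), n_censored = sum(below_lod),
                 cdf_max_gap = gap, all_censored = FALSE),
            class = "pyre_cens_fit")
}

#' High-throughput steady-state intake estimate
#'
#' Inverts the steady-state map for one metabolite assuming complete
#' absorption (the simplified comparator): intake (mg/kg/day) =
#' GM_urine (ng/mL) x V_urine (L/day) / (BW (kg) x mass yield x 1000),
#' apportioned across parent compounds by attribution fractions.
#'
#' @param gm_urine metabolite geometric mean, ng/mL.
#' @param metabolite metabolite id.
#' @param registry `pyre_registry`.
#' @param physiology `pyre_physiology`.
#' @param attribution named fractions over compound ids summing to 1;
#'   default attributes everything to the single producing compound and
#'   errors when several exist.
#' @return named numeric of parent intakes, mg/kg/day.
#' @export
ht_intake_estimate <- function(gm_urine, metabolite,
                               registry = default_registry(),
                               physiology = default_physiology(),
                               attribution = NULL) {
  stopifnot(gm_urine >= 0)
  producers <- registry$matrix$compound[
    registry$matrix$metabolite == metabolite & registry$matrix$phi > 0]
  if (!length(producers))
    stop("no parent produces ", metabolite, call. = FALSE)
  if (is.null(attribution)) {
    if (length(producers) > 1)
      stop("metabolite ", metabolite, " has several parents; supply ",
           "attribution fractions", call. = FALSE)
    attribution <- stats::setNames(1, producers)
  }
  if (abs(sum(attribution) - 1) > 1e-8)
    stop("attribution fractions must sum to 1", call. = FALSE)
  out <- stats::setNames(numeric(length(attribution)), names(attribution))
  for (cmpd in names(attribution)) {
    y <- metabolite_mass_yield(registry, cmpd, metabolite)
    if (y == 0) stop("zero mass yield for ", cmpd, " -> ", metabolite,
                     call. = FALSE)
    flux <- gm_urine * physiology$daily_urine_volume / 1000  # mg/day
    out[cmpd] <- attribution[[cmpd]] * flux /
      (physiology$body_weight * y)
  }
  out
}
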
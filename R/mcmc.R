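#' MCMC settings
#'
#' Defaults follow the analysis protocol: 3 chains of 3500 iterations each,
#' the first 200 discarded as burn-in, every 6th retained thereafter
#' (550 retained draws per chain). Proposal scales adapt only during burn-in,
#' so the retained draws form a valid Markov chain.
#'
#' @param n_chains Number of chains.
#' @param n_iter Iterations per chain.
#' @param burn_in Iterations discarded from the start of each chain.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param adapt Adapt proposal scales during burn-in.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3, n_iter = 3500, burn_in = 200,
                          thin = 6, adapt = TRUE) {
  stopifnot(n_chains >= 1, n_iter > burn_in, burn_in >= 0, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin), adapt = isTRUE(adapt)),
            class = "mcmc_settings")
}

#' Sample the posterior of the seasonal CJS model
#'
#' Adaptive Metropolis-within-Gibbs over parameter blocks: the four seasonal
#' baseline survivals (random walk on the probability scale, where their Beta
#' prior lives), the survival coefficients, the detection baselines (random
#' walk inside their uniform supports), the detection snow effect, the vector
#' of individual detection random effects (element-wise proposals, accepted
#' per individual since likelihood contributions are independent across
#' individuals), and the random-effect SD. The likelihood is the marginalized
#' forward-algorithm CJS likelihood ([cjs_loglik_total()]), exact conditional
#' on the random effects.
#'
#' Initialization draws each baseline survival from its Beta prior and each
#' detection baseline from its uniform prior, sets all coefficients and
#' random effects to 0 and `sigma_det` to 0.5, guaranteeing a finite
#' starting density; a bounded number of redraws is attempted if the
#' likelihood is degenerate at the start.
#'
#' With an empty dataset (0 individuals) the likelihood is identically zero
#' and the sampler draws from the prior, which is how the prior sensibility
#' check is run.
#'
#' @param data A [cjs_data()] (may have zero individuals).
#' @param masks A [season_mask()].
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_settings()].
#' @param seed Integer seed; identical inputs and seed give identical draws.
#' @param store_eps Keep the per-individual random-effect draws (needed by
#'   the posterior predictive check).
#' @return An object of class `cjs_posterior`: list with `draws` (data frame
#'   with columns `chain`, `iteration`, the four seasonal biweekly survivals
#'   `phi_summer`..`phi_spring`, `beta_snow_surv`, `beta_mass`, `beta_sex`,
#'   `beta_fed`, `p_full`, `p_reduced`, `beta_snow_det`, `sigma_det`), `eps`
#'   (matrix of random-effect draws aligned with `draws` rows, or `NULL`),
#'   and `meta` (settings, priors, masks, seed, snow scaling, sampler
#'   description).
#' @export
sample_posterior <- function(data, masks = season_mask(),
                             priors = prior_spec(),
                             mcmc = mcmc_settings(), seed = 1,
                             store_eps = TRUE) {
  stopifnot(inherits(data, "cjs_data"), inherits(mcmc, "mcmc_settings"))
  withr::local_seed(seed)

  n <- nrow(data$y)
  T <- nrow(data$calendar)
  pre <- .mcmc_precompute(data, masks)

  n_keep <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  par_names <- c(paste0("phi_", SEASONS), "beta_snow_surv", "beta_mass",
                 "beta_sex", "beta_fed", "p_full", "p_reduced",
                 "beta_snow_det", "sigma_det")
  all_draws <- vector("list", mcmc$n_chains)
  all_eps <- vector("list", mcmc$n_chains)

  for (ch in seq_len(mcmc$n_chains)) {
    res <- .run_chain(pre, priors, mcmc, n_keep, par_names, n)
    res$draws <- cbind(chain = ch,
                       iteration = mcmc$burn_in + mcmc$thin *
                         seq_len(n_keep),
                       res$draws)
    all_draws[[ch]] <- res$draws
    all_eps[[ch]] <- res$eps
  }

  draws <- do.call(rbind, all_draws)
  eps <- if (store_eps && n > 0) do.call(rbind, all_eps) else NULL
  structure(list(draws = as.data.frame(draws),
                 eps = eps,
                 meta = list(settings = mcmc, priors = priors, masks = masks,
                             seed = seed, n_individuals = n,
                             n_occasions = T,
                             snow_scaling = data$snow_scaling,
                             sampler = paste("adaptive Metropolis-within-",
                                             "Gibbs; blocks: seasonal ",
                                             "survivals, survival ",
                                             "coefficients, detection ",
                                             "baselines, detection snow ",
                                             "effect, individual random ",
                                             "effects (element-wise), ",
                                             "sigma; adaptation during ",
                                             "burn-in only", sep = ""))),
            class = "cjs_posterior")
}

# static pieces reused by every likelihood evaluation of a chain
.mcmc_precompute <- function(data, masks) {
  cal <- data$calendar
  n <- nrow(data$y)
  T <- nrow(cal)
  s_int <- cal$season[-1L]
  s_idx <- match(s_int, SEASONS)
  z_int <- data$z[-1L]
  cov <- data$covariates
  mk <- function(v, active) if (n > 0)
    tcrossprod(as.numeric(v), as.numeric(s_int %in% active)) else
      matrix(0, 0, T - 1L)
  list(y = data$y, f = data$f, n = n, T = T,
       s_idx = s_idx, z_int = z_int, z_occ = data$z,
       M_mass = mk(cov$mass_z, masks$mass),
       M_sex = mk(cov$sex, masks$sex),
       M_fed = mk(cov$fed, masks$fed),
       effort = cal$effort,
       is_full = cal$effort == "full",
       is_none = cal$effort == "none")
}

# linear-predictor pieces: survival logit(i, t) = lp_static(i, t) + v[t],
# detection logit(i, t) = base_p[t] + eps[i] (-Inf encodes effort "none")
.v_phi <- function(pre, s, b_snow) qlogis(s)[pre$s_idx] + b_snow * pre$z_int

.lp_static <- function(pre, b_mass, b_sex, b_fed) {
  b_mass * pre$M_mass + b_sex * pre$M_sex + b_fed * pre$M_fed
}

.base_p <- function(pre, p_full, p_reduced, b_snow_det) {
  ifelse(pre$is_none, -Inf,
         qlogis(ifelse(pre$is_full, p_full, p_reduced)) +
           b_snow_det * pre$z_occ)
}

.run_chain <- function(pre, priors, mcmc, n_keep, par_names, n) {
  eval_ll <- function(lp_static, v, base_p, eps) {
    if (n == 0L) return(numeric(0))
    cpp_cjs_loglik_pred(pre$y, pre$f, lp_static, v, base_p, eps)
  }

  # initial values: survival/detection baselines from their priors,
  # coefficients and random effects at 0
  for (try in 1:20) {
    s <- rbeta(4, priors$surv_shape1, priors$surv_shape2)
    p_full <- runif(1, priors$p_full_range[1], priors$p_full_range[2])
    p_reduced <- runif(1, priors$p_reduced_range[1],
                       priors$p_reduced_range[2])
    b <- c(snow_surv = 0, mass = 0, sex = 0, fed = 0)
    b_snow_det <- 0
    sigma <- 0.5
    eps <- rep(0, n)
    lp_static <- .lp_static(pre, b["mass"], b["sex"], b["fed"])
    v <- .v_phi(pre, s, b["snow_surv"])
    base_p <- .base_p(pre, p_full, p_reduced, b_snow_det)
    ll <- eval_ll(lp_static, v, base_p, eps)
    if (all(is.finite(ll))) break
    if (try == 20)
      stop("could not find a finite starting likelihood", call. = FALSE)
  }

  scales <- list(s = rep(0.03, 4), b = rep(0.25, 4), p_full = 0.05,
                 p_reduced = 0.1, b_snow_det = 0.25, eps = 0.8,
                 sigma = 0.25, rescale = 0.4)
  acc <- rapply(scales, function(x) x * 0, how = "replace")
  adapt_win <- 50L

  lp_coef <- function(x) dnorm(x, 0, priors$coef_sd, log = TRUE)
  lp_s1 <- function(x) dbeta(x, priors$surv_shape1, priors$surv_shape2,
                             log = TRUE)

  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  eps_draws <- if (n > 0) matrix(NA_real_, n_keep, n) else NULL
  keep_i <- 0L

  for (iter in seq_len(mcmc$n_iter)) {
    ll_sum <- sum(ll)

    # seasonal baseline survivals
    for (k in 1:4) {
      prop <- s[k] + rnorm(1, 0, scales$s[k])
      if (prop > 0 && prop < 1) {
        s2 <- s; s2[k] <- prop
        v2 <- .v_phi(pre, s2, b["snow_surv"])
        ll2 <- eval_ll(lp_static, v2, base_p, eps)
        logr <- sum(ll2) - ll_sum + lp_s1(prop) - lp_s1(s[k])
        if (is.finite(logr) && log(runif(1)) < logr) {
          s <- s2; v <- v2; ll <- ll2; ll_sum <- sum(ll)
          acc$s[k] <- acc$s[k] + 1
        }
      }
    }

    # survival coefficients
    for (k in 1:4) {
      prop <- b[k] + rnorm(1, 0, scales$b[k])
      b2 <- b; b2[k] <- prop
      if (k == 1L) {  # snow effect lives in the occasion-level part
        v2 <- .v_phi(pre, s, prop)
        lp2 <- lp_static
      } else {
        v2 <- v
        lp2 <- .lp_static(pre, b2["mass"], b2["sex"], b2["fed"])
      }
      ll2 <- eval_ll(lp2, v2, base_p, eps)
      logr <- sum(ll2) - ll_sum + lp_coef(prop) - lp_coef(b[k])
      if (is.finite(logr) && log(runif(1)) < logr) {
        b <- b2; v <- v2; lp_static <- lp2; ll <- ll2; ll_sum <- sum(ll)
        acc$b[k] <- acc$b[k] + 1
      }
    }

    # detection baselines and snow effect
    upd_det <- function(val, lo, hi, lpfun, scale, rebuild) {
      prop <- val + rnorm(1, 0, scale)
      if (prop <= lo || prop >= hi) return(list(val = val, hit = FALSE))
      bp2 <- rebuild(prop)
      ll2 <- eval_ll(lp_static, v, bp2, eps)
      logr <- sum(ll2) - ll_sum + lpfun(prop) - lpfun(val)
      if (is.finite(logr) && log(runif(1)) < logr)
        list(val = prop, hit = TRUE, base_p = bp2, ll = ll2)
      else list(val = val, hit = FALSE)
    }

    r <- upd_det(p_full, priors$p_full_range[1], priors$p_full_range[2],
                 function(x) 0, scales$p_full,
                 function(x) .base_p(pre, x, p_reduced, b_snow_det))
    if (r$hit) { p_full <- r$val; base_p <- r$base_p; ll <- r$ll
      ll_sum <- sum(ll); acc$p_full <- acc$p_full + 1 }

    r <- upd_det(p_reduced, priors$p_reduced_range[1],
                 priors$p_reduced_range[2], function(x) 0,
                 scales$p_reduced,
                 function(x) .base_p(pre, p_full, x, b_snow_det))
    if (r$hit) { p_reduced <- r$val; base_p <- r$base_p; ll <- r$ll
      ll_sum <- sum(ll); acc$p_reduced <- acc$p_reduced + 1 }

    r <- upd_det(b_snow_det, -Inf, Inf, lp_coef, scales$b_snow_det,
                 function(x) .base_p(pre, p_full, p_reduced, x))
    if (r$hit) { b_snow_det <- r$val; base_p <- r$base_p; ll <- r$ll
      ll_sum <- sum(ll); acc$b_snow_det <- acc$b_snow_det + 1 }

    # individual random effects: element-wise accept/reject is valid because
    # individual likelihood contributions are independent across individuals
    if (n > 0) {
      eps2 <- eps + rnorm(n, 0, scales$eps)
      ll2 <- eval_ll(lp_static, v, base_p, eps2)
      logr <- (ll2 - ll) + dnorm(eps2, 0, sigma, log = TRUE) -
        dnorm(eps, 0, sigma, log = TRUE)
      take <- is.finite(logr) & log(runif(n)) < logr
      if (any(take)) {
        eps[take] <- eps2[take]
        ll[take] <- ll2[take]
        ll_sum <- sum(ll)
      }
      acc$eps <- acc$eps + mean(take)

      # sigma: half-normal prior x N(0, sigma) likelihood of eps
      lp_sig <- function(x) {
        if (x <= 0) return(-Inf)
        dnorm(x, 0, priors$sigma_det_sd, log = TRUE) +
          sum(dnorm(eps, 0, x, log = TRUE))
      }
      prop <- sigma + rnorm(1, 0, scales$sigma)
      logr <- lp_sig(prop) - lp_sig(sigma)
      if (is.finite(logr) && log(runif(1)) < logr) {
        sigma <- prop
        acc$sigma <- acc$sigma + 1
      }

      # joint rescaling of (eps, sigma): the random effects are only weakly
      # identified when detection is near 1, which makes the hierarchy a
      # funnel; a multiplicative move along it mixes sigma where separate
      # updates stall. Acceptance ratio reduces to
      # loglik difference + half-normal prior difference + log(a).
      la <- rnorm(1, 0, scales$rescale)
      a <- exp(la)
      eps2 <- a * eps
      ll2 <- eval_ll(lp_static, v, base_p, eps2)
      logr <- sum(ll2) - ll_sum +
        dnorm(a * sigma, 0, priors$sigma_det_sd, log = TRUE) -
        dnorm(sigma, 0, priors$sigma_det_sd, log = TRUE) + la
      if (is.finite(logr) && log(runif(1)) < logr) {
        eps <- eps2
        sigma <- a * sigma
        ll <- ll2
        ll_sum <- sum(ll)
        acc$rescale <- acc$rescale + 1
      }
    } else {
      # prior-only draw for sigma (half-normal), random walk
      prop <- sigma + rnorm(1, 0, scales$sigma)
      if (prop > 0) {
        logr <- dnorm(prop, 0, priors$sigma_det_sd, log = TRUE) -
          dnorm(sigma, 0, priors$sigma_det_sd, log = TRUE)
        if (log(runif(1)) < logr) { sigma <- prop; acc$sigma <- acc$sigma + 1 }
      }
    }

    # proposal-scale adaptation, burn-in only
    if (mcmc$adapt && iter <= mcmc$burn_in && iter %% adapt_win == 0L) {
      tune <- function(sc, a) pmin(pmax(sc * exp(a / adapt_win - 0.44), 1e-4),
                                   10)
      scales$s <- tune(scales$s, acc$s)
      scales$b <- tune(scales$b, acc$b)
      scales$p_full <- tune(scales$p_full, acc$p_full)
      scales$p_reduced <- tune(scales$p_reduced, acc$p_reduced)
      scales$b_snow_det <- tune(scales$b_snow_det, acc$b_snow_det)
      scales$eps <- tune(scales$eps, acc$eps)
      scales$sigma <- tune(scales$sigma, acc$sigma)
      scales$rescale <- tune(scales$rescale, acc$rescale)
      acc <- rapply(acc, function(x) x * 0, how = "replace")
    }

    if (iter > mcmc$burn_in &&
        (iter - mcmc$burn_in) %% mcmc$thin == 0L) {
      keep_i <- keep_i + 1L
      draws[keep_i, ] <- c(s, b, p_full, p_reduced, b_snow_det, sigma)
      if (!is.null(eps_draws)) eps_draws[keep_i, ] <- eps
    }
  }

  list(draws = draws, eps = eps_draws)
}

#' Extract a cjs_params object from one posterior draw
#'
#' @param samples A `cjs_posterior`.
#' @param row Row index into `samples$draws`.
#' @return A [cjs_params()] with `eps` filled from the stored random-effect
#'   draws when available.
#' @export
params_from_draw <- function(samples, row) {
  d <- samples$draws[row, ]
  eps <- if (!is.null(samples$eps)) as.numeric(samples$eps[row, ]) else
    numeric(0)
  cjs_params(alpha = qlogis(as.numeric(d[paste0("phi_", SEASONS)])),
             beta_snow_surv = d$beta_snow_surv,
             beta_mass = d$beta_mass, beta_sex = d$beta_sex,
             beta_fed = d$beta_fed,
             p_full = d$p_full, p_reduced = d$p_reduced,
             beta_snow_det = d$beta_snow_det,
             sigma_det = d$sigma_det, eps = eps)
}

#' Write posterior draws and a run manifest
#'
#' Serializes a `cjs_posterior` as `draws.csv` (chain and iteration columns
#' plus one column per parameter) and `manifest.json` (seed, MCMC settings,
#' priors, masks, snow-covariate scaling, sampler description, and the R-hat
#' table).
#'
#' @param samples A `cjs_posterior`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_posterior <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(samples$draws, file.path(dir, "draws.csv"), row.names = FALSE)
  rh <- gelman_rubin(samples)
  manifest <- list(seed = samples$meta$seed,
                   settings = unclass(samples$meta$settings),
                   priors = unclass(samples$meta$priors),
                   masks = unclass(samples$meta$masks),
                   snow_scaling = samples$meta$snow_scaling,
                   sampler = samples$meta$sampler,
                   n_individuals = samples$meta$n_individuals,
                   rhat = as.list(rh))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_posterior
#' @details `read_posterior()` rebuilds a `cjs_posterior` from a directory
#'   written by `write_posterior()` (without the random-effect draws, which
#'   are not serialized).
#' @export
read_posterior <- function(dir) {
  draws <- read.csv(file.path(dir, "draws.csv"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  masks <- do.call(season_mask, man$masks)
  structure(list(draws = draws, eps = NULL,
                 meta = list(settings = do.call(mcmc_settings,
                                                man$settings),
                             masks = masks, seed = man$seed,
                             n_individuals = man$n_individuals,
                             snow_scaling = man$snow_scaling,
                             sampler = man$sampler)),
            class = "cjs_posterior")
}
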
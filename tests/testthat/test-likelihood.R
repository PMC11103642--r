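random_history <- function(L) {
  h <- c(1L, sample(0:1, L - 1L, replace = TRUE))
  list(h = h, phi = runif(L - 1L), p = runif(L))
}

test_that("single-step histories have their closed-form likelihoods", {
  phi <- 0.8
  p <- 0.6
  expect_equal(cjs_loglik_individual(c(1, 1), phi, c(0.5, p)),
               log(phi * p))
  expect_equal(cjs_loglik_individual(c(1, 0), phi, c(0.5, p)),
               log((1 - phi) + phi * (1 - p)))
  expect_equal(brute_force_loglik(c(1, 1), phi, c(0.5, p)), log(phi * p))
  expect_equal(brute_force_loglik(c(1, 0), phi, c(0.5, p)),
               log((1 - phi) + phi * (1 - p)))
  # certain survival and detection: an all-ones history is certain
  expect_equal(brute_force_loglik(rep(1, 5), rep(1, 4), rep(1, 5)), 0)
  expect_equal(cjs_loglik_individual(rep(1, 5), rep(1, 4), rep(1, 5)), 0)
})

test_that("forward recursion agrees with enumeration on random histories", {
  withr::local_seed(42)
  for (rep in 1:200) {
    L <- sample(3:8, 1)
    rh <- random_history(L)
    expect_equal(cjs_loglik_individual(rh$h, rh$phi, rh$p),
                 brute_force_loglik(rh$h, rh$phi, rh$p),
                 tolerance = 1e-12)
  }
})

test_that("impossible data are rejected, not silently scored", {
  expect_error(cjs_loglik_individual(c(1, 1), 0.9, c(1, 0)),
               "detection probability 0")
  expect_error(brute_force_loglik(c(1, 1), 0.9, c(1, 0)),
               "detection probability 0")
  expect_error(cjs_loglik_individual(c(0, 1), 0.9, c(0.5, 0.5)), "release")
})

test_that("survival predictor is the masked linear model", {
  p <- study_params()
  covs <- list(mass_z = 0, sex = 0, fed = 0)
  occ_w <- list(season = "winter", z = 0)
  expect_equal(survival_logit(p, covs, occ_w), p$alpha[["winter"]])
  # linearity in the snow covariate
  occ_w1 <- list(season = "winter", z = 1.5)
  expect_equal(survival_logit(p, covs, occ_w1) -
                 survival_logit(p, covs, occ_w),
               p$beta_snow_surv * 1.5)
  # mass acts in summer only under the default mask
  heavy <- list(mass_z = 2, sex = 0, fed = 0)
  expect_equal(survival_logit(p, heavy, occ_w),
               survival_logit(p, covs, occ_w))
  occ_s <- list(season = "summer", z = 0)
  expect_equal(survival_logit(p, heavy, occ_s) -
                 survival_logit(p, covs, occ_s), 2 * p$beta_mass)
  expect_error(survival_logit(p, covs, list(season = "monsoon", z = 0)),
               "unknown season")
  # a snow-driven logit shift of -1.49 pulls 0.971 down to about 0.883
  expect_equal(plogis(qlogis(0.971) - 1.49), 0.883, tolerance = 1e-3)
})

test_that("detection probability honours regimes, snow and random effects", {
  p <- study_params()
  p$eps <- c(0, 0.7)
  expect_equal(detection_prob(p, 1, list(effort = "none", z = 3)), 0)
  expect_equal(detection_prob(p, 1, list(effort = "full", z = 0)), p$p_full)
  expect_equal(detection_prob(p, 1, list(effort = "reduced", z = 0)),
               p$p_reduced)
  # raising z by 1 drops the detection logit by beta_snow_det
  d0 <- detection_prob(p, 1, list(effort = "full", z = 0))
  d1 <- detection_prob(p, 1, list(effort = "full", z = 1))
  expect_equal(qlogis(d1) - qlogis(d0), p$beta_snow_det)
  expect_equal(qlogis(detection_prob(p, 2, list(effort = "full", z = 0))) -
                 qlogis(d0), 0.7)
})

test_that("total likelihood sums individual contributions symmetrically", {
  d <- make_dataset(n = 30, seed = 14)
  pars <- d$truth$params
  lls <- cjs_loglik_by_individual(d$data, pars)
  expect_equal(cjs_loglik_total(d$data, pars), sum(lls))
  expect_true(all(lls <= 0))

  # permuting individuals leaves the total unchanged
  perm <- sample(30)
  d2 <- d$data
  d2$y <- d2$y[perm, ]
  d2$f <- d2$f[perm]
  d2$covariates <- d2$covariates[perm, ]
  pars2 <- pars
  pars2$eps <- pars$eps[perm]
  expect_equal(cjs_loglik_total(d2, pars2), cjs_loglik_total(d$data, pars))

  # empty data has log-likelihood 0
  expect_equal(cjs_loglik_total(make_empty_data(), study_params()), 0)

  # single individual reduces to the per-history function
  mats <- cjsnow:::build_phi_p(d$data, pars)
  i <- 7L
  f <- d$data$f[i]
  T <- ncol(d$data$y)
  expect_equal(lls[i],
               cjs_loglik_individual(d$data$y[i, f:T],
                                     mats$phi[i, f:(T - 1)],
                                     mats$p[i, f:T]))
})

test_that("C++ forward core matches the R recursion individual by individual", {
  d <- make_dataset(n = 40, seed = 31)
  pars <- d$truth$params
  mats <- cjsnow:::build_phi_p(d$data, pars)
  T <- ncol(d$data$y)
  lls <- cjs_loglik_by_individual(d$data, pars)
  for (i in seq_len(40)) {
    f <- d$data$f[i]
    expect_equal(lls[i],
                 cjs_loglik_individual(d$data$y[i, f:T],
                                       mats$phi[i, f:(T - 1)],
                                       mats$p[i, f:T]),
                 tolerance = 1e-12)
  }
})

test_that("the sampler's predictor-based likelihood equals the public one", {
  d <- make_dataset(n = 50, seed = 63, calendar = study_calendar())
  pars <- d$truth$params
  masks <- season_mask()
  pre <- cjsnow:::.mcmc_precompute(d$data, masks)
  lp <- cjsnow:::.lp_static(pre, pars$beta_mass, pars$beta_sex,
                            pars$beta_fed)
  v <- cjsnow:::.v_phi(pre, plogis(pars$alpha), pars$beta_snow_surv)
  bp <- cjsnow:::.base_p(pre, pars$p_full, pars$p_reduced,
                         pars$beta_snow_det)
  ll_pred <- cjsnow:::cpp_cjs_loglik_pred(d$data$y, d$data$f, lp, v, bp,
                                          pars$eps)
  expect_equal(ll_pred, cjs_loglik_by_individual(d$data, pars, masks),
               tolerance = 1e-12)
})

test_that("winter survival ignores mass and feeding under the summer mask", {
  d <- make_dataset(n = 20, seed = 17)
  pars <- d$truth$params
  d2 <- d$data
  d2$covariates$mass_z <- d2$covariates$mass_z + 5
  d2$covariates$fed <- 1L - d2$covariates$fed
  m1 <- cjsnow:::build_phi_p(d$data, pars, season_mask())
  m2 <- cjsnow:::build_phi_p(d2, pars, season_mask())
  wint <- which(d$data$calendar$season[-1] == "winter")
  expect_equal(m1$phi[, wint], m2$phi[, wint])
  summ <- which(d$data$calendar$season[-1] == "summer")
  expect_false(isTRUE(all.equal(m1$phi[, summ], m2$phi[, summ])))
})

test_that("increasing survival on an all-detected path raises its likelihood", {
  h <- rep(1L, 6)
  p <- rep(0.7, 6)
  ll <- sapply(c(0.5, 0.7, 0.9, 0.99), function(phi)
    cjs_loglik_individual(h, rep(phi, 5), p))
  expect_true(all(diff(ll) > 0))
})
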
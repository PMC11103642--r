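#' Prior specification
#'
#' Mildly informative priors for the seasonal CJS model: each season's
#' baseline biweekly survival probability (at covariate value 0) gets a
#' Beta(95, 10) prior (mean 0.905), the detection baselines get
#' Uniform(0.7, 1) for full effort and Uniform(0.3, 0.9) for reduced effort,
#' all regression coefficients get Normal(0, `coef_sd`) priors with
#' `coef_sd` in `[1, 2]` (default 1), and the detection random-effect SD a
#' positive-truncated Normal(0, 1).
#'
#' @param surv_shape1,surv_shape2 Beta shape parameters of the baseline
#'   survival prior.
#' @param p_full_range,p_reduced_range Supports of the uniform detection
#'   priors.
#' @param coef_sd SD of the normal coefficient priors (between 1 and 2).
#' @param sigma_det_sd Scale of the half-normal prior on `sigma_det`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(surv_shape1 = 95, surv_shape2 = 10,
                       p_full_range = c(0.7, 1),
                       p_reduced_range = c(0.3, 0.9),
                       coef_sd = 1, sigma_det_sd = 1) {
  stopifnot(surv_shape1 > 0, surv_shape2 > 0,
            length(p_full_range) == 2L, p_full_range[1] < p_full_range[2],
            length(p_reduced_range) == 2L,
            p_reduced_range[1] < p_reduced_range[2],
            sigma_det_sd > 0)
  if (coef_sd < 1 || coef_sd > 2)
    stop("coef_sd must lie in [1, 2]", call. = FALSE)
  structure(list(surv_shape1 = surv_shape1, surv_shape2 = surv_shape2,
                 p_full_range = p_full_range,
                 p_reduced_range = p_reduced_range,
                 coef_sd = coef_sd, sigma_det_sd = sigma_det_sd),
            class = "prior_spec")
}

#' Log prior density of a parameter vector
#'
#' Sum of the component log-densities under a [prior_spec()], evaluated on
#' the scales the priors are stated on: baseline survivals and detection
#' baselines on the probability scale, coefficients on the logit-effect
#' scale, `sigma_det` on its positive half-line, and the individual random
#' effects as `N(0, sigma_det)` given `sigma_det` (the hierarchical prior).
#' Returns `-Inf` whenever any component is outside its support.
#'
#' @param params A [cjs_params()].
#' @param priors A [prior_spec()].
#' @return Log prior density (scalar; `-Inf` encodes a support violation).
#' @export
log_prior <- function(params, priors = prior_spec()) {
  s <- plogis(params$alpha)
  lp <- sum(dbeta(s, priors$surv_shape1, priors$surv_shape2, log = TRUE))
  lp <- lp + stats::dunif(params$p_full, priors$p_full_range[1],
                          priors$p_full_range[2], log = TRUE)
  lp <- lp + stats::dunif(params$p_reduced, priors$p_reduced_range[1],
                          priors$p_reduced_range[2], log = TRUE)
  lp <- lp + sum(dnorm(c(params$beta_snow_surv, params$beta_mass,
                         params$beta_sex, params$beta_fed,
                         params$beta_snow_det),
                       0, priors$coef_sd, log = TRUE))
  if (params$sigma_det < 0) return(-Inf)
  lp <- lp + log(2) + dnorm(params$sigma_det, 0, priors$sigma_det_sd,
                            log = TRUE)
  if (length(params$eps)) {
    if (params$sigma_det <= 0) return(-Inf)
    lp <- lp + sum(dnorm(params$eps, 0, params$sigma_det, log = TRUE))
  }
  if (!is.finite(lp)) return(-Inf)
  lp
}
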
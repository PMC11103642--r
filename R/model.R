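#' Logit-scale survival predictor
#'
#' The linear predictor of biweekly survival for one individual over one
#' interval: the seasonal intercept plus the snow effect plus every
#' mask-active individual effect,
#' `alpha[season] + beta_snow_surv * z + beta_mass * mass_z +
#' beta_sex * sex + beta_fed * fed`, where each of the last three terms is
#' included only when the interval's season is in that covariate's mask.
#'
#' @param params A [cjs_params()].
#' @param covariates List or one-row data frame with `mass_z`, `sex`, `fed`.
#' @param occasion List or one-row data frame with the interval's `season` and
#'   standardized snow value `z`.
#' @param masks A [season_mask()].
#' @return Logit-scale survival (numeric scalar).
#' @export
survival_logit <- function(params, covariates, occasion,
                           masks = season_mask()) {
  s <- occasion$season
  if (!s %in% SEASONS) stop("unknown season label: ", s, call. = FALSE)
  lp <- params$alpha[[s]] + params$beta_snow_surv * occasion$z
  if (s %in% masks$mass) lp <- lp + params$beta_mass * covariates$mass_z
  if (s %in% masks$sex)  lp <- lp + params$beta_sex * covariates$sex
  if (s %in% masks$fed)  lp <- lp + params$beta_fed * covariates$fed
  unname(lp)
}

#' Detection probability for one individual and occasion
#'
#' Zero exactly when the occasion had no tracking effort; otherwise the
#' inverse logit of `logit(p_regime) + beta_snow_det * z + eps_i`, where
#' `p_regime` is the full- or reduced-effort baseline.
#'
#' @param params A [cjs_params()]; `params$eps` must cover the individual.
#' @param individual Individual index into `params$eps` (an `eps` of length 0
#'   is treated as all zeros).
#' @param occasion List or one-row data frame with `effort` and `z`.
#' @return Detection probability in `[0, 1]`.
#' @export
detection_prob <- function(params, individual, occasion) {
  if (occasion$effort == "none") return(0)
  base <- switch(occasion$effort,
                 full = params$p_full,
                 reduced = params$p_reduced,
                 stop("unknown effort regime: ", occasion$effort,
                      call. = FALSE))
  eps <- if (length(params$eps)) params$eps[[individual]] else 0
  plogis(qlogis(base) + params$beta_snow_det * occasion$z + eps)
}

# Build per-individual survival and detection probability matrices.
#
# phi is n x (T-1): column t is survival over interval (t, t+1], using the
# season and snow covariate of occasion t+1 (the fortnight being survived).
# p is n x T: column t is detection probability at occasion t (structurally 0
# where effort is "none"; column 1 is never used by the likelihood because
# the model conditions on first release).
build_phi_p <- function(data, params, masks = season_mask()) {
  cal <- data$calendar
  n <- nrow(data$y)
  T <- nrow(cal)
  z <- data$z
  cov <- data$covariates
  eps <- if (length(params$eps) == n) params$eps else rep(0, n)
  if (length(params$eps) && length(params$eps) != n)
    stop("params$eps has length ", length(params$eps), " but data has ", n,
         " individuals", call. = FALSE)

  # survival: interval t -> t+1 governed by occasion t+1
  s_int <- cal$season[-1L]
  z_int <- z[-1L]
  lp <- matrix(params$alpha[s_int] + params$beta_snow_surv * z_int,
               nrow = n, ncol = T - 1L, byrow = TRUE)
  if (n > 0) {
    if (params$beta_mass != 0) {
      I <- as.numeric(s_int %in% masks$mass)
      lp <- lp + params$beta_mass * tcrossprod(cov$mass_z, I)
    }
    if (params$beta_sex != 0) {
      I <- as.numeric(s_int %in% masks$sex)
      lp <- lp + params$beta_sex * tcrossprod(as.numeric(cov$sex), I)
    }
    if (params$beta_fed != 0) {
      I <- as.numeric(s_int %in% masks$fed)
      lp <- lp + params$beta_fed * tcrossprod(as.numeric(cov$fed), I)
    }
  }
  phi <- plogis(lp)

  # detection: occasion-level baseline + snow effect, -Inf logit at no effort
  base <- ifelse(cal$effort == "none", -Inf,
                 qlogis(ifelse(cal$effort == "full",
                               params$p_full, params$p_reduced)) +
                   params$beta_snow_det * z)
  p <- plogis(matrix(base, nrow = n, ncol = T, byrow = TRUE) + eps)

  list(phi = phi, p = p)
}

#' Marginal CJS log-likelihood of one encounter history
#'
#' Forward (hidden-Markov) recursion over the latent alive/dead state,
#' conditioning on first release: the exact marginal probability of the
#' history, summing over all possible death intervals at or after the last
#' detection. Probabilities are rescaled at every step so long histories do
#' not underflow.
#'
#' @param history Binary vector of detections from the release occasion to the
#'   last occasion; `history[1]` must be 1.
#' @param phi_vec Survival probabilities per interval,
#'   `length(history) - 1` values; `phi_vec[t]` is survival from relative
#'   occasion `t` to `t + 1`.
#' @param p_vec Detection probabilities per occasion, same length as
#'   `history`; `p_vec[1]` is unused (conditioned on).
#' @return Log-likelihood (scalar, `<= 0`).
#' @export
cjs_loglik_individual <- function(history, phi_vec, p_vec) {
  L <- length(history)
  stopifnot(length(phi_vec) == L - 1L, length(p_vec) == L)
  if (any(phi_vec < 0 | phi_vec > 1) || any(p_vec < 0 | p_vec > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (history[1] != 1)
    stop("history must start with the release detection", call. = FALSE)
  if (any(history == 1 & p_vec == 0))
    stop("detection recorded at an occasion with detection probability 0",
         call. = FALSE)
  if (L == 1L) return(0)
  a_alive <- 1
  a_dead <- 0
  ll <- 0
  for (t in seq_len(L - 1L)) {
    if (history[t + 1L] == 1L) {
      na <- a_alive * phi_vec[t] * p_vec[t + 1L]
      nd <- 0
    } else {
      na <- a_alive * phi_vec[t] * (1 - p_vec[t + 1L])
      nd <- a_alive * (1 - phi_vec[t]) + a_dead
    }
    s <- na + nd
    if (s <= 0) return(-Inf)
    ll <- ll + log(s)
    a_alive <- na / s
    a_dead <- nd / s
  }
  ll
}

#' Brute-force CJS log-likelihood by death-time enumeration
#'
#' Independent oracle for [cjs_loglik_individual()]: enumerates every possible
#' death interval explicitly (alive through occasion `d`, dead thereafter, for
#' each `d` from the release occasion to beyond the last occasion) and sums
#' the corresponding probabilities. Exact but O(T^2); restricted to short
#' histories.
#'
#' @inheritParams cjs_loglik_individual
#' @return Log-likelihood (scalar).
#' @export
brute_force_loglik <- function(history, phi_vec, p_vec) {
  L <- length(history)
  stopifnot(length(phi_vec) == L - 1L, length(p_vec) == L)
  if (L > 25L)
    stop("enumeration oracle is limited to histories of <= 25 occasions",
         call. = FALSE)
  if (history[1] != 1)
    stop("history must start with the release detection", call. = FALSE)
  if (any(history == 1 & p_vec == 0))
    stop("detection recorded at an occasion with detection probability 0",
         call. = FALSE)
  if (L == 1L) return(0)
  total <- 0
  # d = last relative occasion alive (1..L); d < L means death in (d, d+1]
  for (d in seq_len(L)) {
    pr <- prod(phi_vec[seq_len(d - 1L)])
    if (d < L) pr <- pr * (1 - phi_vec[d])
    for (t in 2:L) {
      pr <- pr * if (t <= d) {
        if (history[t] == 1L) p_vec[t] else 1 - p_vec[t]
      } else {
        if (history[t] == 1L) 0 else 1
      }
    }
    total <- total + pr
  }
  log(total)
}

#' Total CJS log-likelihood of a dataset
#'
#' Sum over individuals of the marginalized forward-algorithm likelihood,
#' with survival and detection probabilities built from the linear predictors
#' (conditional on the individual random effects carried in `params$eps`).
#'
#' @param data A [cjs_data()].
#' @param params A [cjs_params()].
#' @param masks A [season_mask()].
#' @return Total log-likelihood (scalar; 0 for an empty dataset).
#' @export
cjs_loglik_total <- function(data, params, masks = season_mask()) {
  sum(cjs_loglik_by_individual(data, params, masks))
}

#' Per-individual CJS log-likelihoods
#'
#' @inheritParams cjs_loglik_total
#' @return Numeric vector of log-likelihood contributions, one per individual.
#' @export
cjs_loglik_by_individual <- function(data, params, masks = season_mask()) {
  stopifnot(inherits(data, "cjs_data"))
  n <- nrow(data$y)
  if (n == 0L) return(numeric(0))
  mats <- build_phi_p(data, params, masks)
  if (any(data$y == 1L & mats$p == 0))
    stop("detection recorded at an occasion with detection probability 0",
         call. = FALSE)
  cpp_cjs_loglik(data$y, data$f, mats$phi, mats$p)
}
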
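#' Observed m-array of an encounter dataset
#'
#' Rows are release occasions (every detection before the final occasion is a
#' release), columns 1..T-1 count first recaptures at occasions 2..T, and the
#' final column counts releases never seen again.
#'
#' @param data A [cjs_data()].
#' @return Integer matrix `(T-1) x T`.
#' @export
marray <- function(data) {
  stopifnot(inherits(data, "cjs_data"))
  cpp_marray(data$y, data$f)
}

#' Freeman-Tukey discrepancy
#'
#' `sum((sqrt(observed) - sqrt(expected))^2)` over all cells; the variance-
#' stabilized discrepancy used for goodness-of-fit on m-arrays.
#'
#' @param observed,expected Matrices of equal dimension.
#' @return Scalar discrepancy, `>= 0`.
#' @export
freeman_tukey <- function(observed, expected) {
  stopifnot(all(dim(observed) == dim(expected)))
  sum((sqrt(observed) - sqrt(expected))^2)
}

# simulate replicate detections given phi/p matrices and release occasions
simulate_y_replicate <- function(f, phi, p) {
  n <- length(f)
  T <- ncol(p)
  y <- matrix(0L, n, T)
  alive <- matrix(FALSE, n, T)
  alive[cbind(seq_len(n), f)] <- TRUE
  y[cbind(seq_len(n), f)] <- 1L
  for (t in seq_len(T - 1L)) {
    at_risk <- alive[, t] & f <= t
    nxt <- logical(n)
    nxt[at_risk] <- runif(sum(at_risk)) < phi[at_risk, t]
    newly <- f == t + 1L
    alive[, t + 1L] <- nxt | (alive[, t + 1L] & newly)
    det <- alive[, t + 1L] & !newly
    if (any(det))
      y[det, t + 1L] <- as.integer(runif(sum(det)) < p[det, t + 1L])
  }
  y
}

#' Posterior predictive check on the m-array
#'
#' For each of a subset of posterior draws, builds the survival/detection
#' matrices implied by that draw (using the stored individual random effects
#' when available, otherwise redrawing them from `N(0, sigma_det)`), computes
#' the Freeman-Tukey discrepancy between the observed m-array and its
#' expectation under the draw, simulates a replicate dataset from the draw
#' and computes the same discrepancy for the replicate (conditioning on the
#' replicate's own releases). The Bayesian p-value is the fraction of draws
#' whose replicate discrepancy is at least the observed one, so exact ties
#' count towards the p-value.
#'
#' @param samples A `cjs_posterior` with at least 100 retained draws.
#' @param data The fitted [cjs_data()].
#' @param statistic Discrepancy statistic; only `"freeman_tukey_marray"`.
#' @param n_draws Number of posterior draws to use (spread evenly).
#' @param seed Integer seed for the replicate simulations.
#' @return A list of class `cjs_ppc` with elements `p_value`, `D_obs`,
#'   `D_rep`, `statistic`, `n_draws`.
#' @export
posterior_predictive_pvalue <- function(samples, data,
                                        statistic = "freeman_tukey_marray",
                                        n_draws = 200, seed = 1) {
  stopifnot(inherits(samples, "cjs_posterior"), inherits(data, "cjs_data"))
  statistic <- match.arg(statistic)
  total <- nrow(samples$draws)
  if (total < 100L)
    stop("posterior predictive check needs at least 100 retained draws",
         call. = FALSE)
  n_draws <- min(n_draws, total)
  rows <- unique(round(seq(1, total, length.out = n_draws)))
  masks <- samples$meta$masks
  withr::local_seed(seed)

  m_obs <- marray(data)
  n <- nrow(data$y)
  D_obs <- numeric(length(rows))
  D_rep <- numeric(length(rows))
  for (k in seq_along(rows)) {
    pars <- params_from_draw(samples, rows[k])
    if (!length(pars$eps)) pars$eps <- rnorm(n, 0, pars$sigma_det)
    mats <- build_phi_p(data, pars, masks)
    e_obs <- cpp_expected_marray(data$y, data$f, mats$phi, mats$p)
    D_obs[k] <- freeman_tukey(m_obs, e_obs)
    y_rep <- simulate_y_replicate(data$f, mats$phi, mats$p)
    m_rep <- cpp_marray(y_rep, data$f)
    e_rep <- cpp_expected_marray(y_rep, data$f, mats$phi, mats$p)
    D_rep[k] <- freeman_tukey(m_rep, e_rep)
  }
  structure(list(p_value = mean(D_rep >= D_obs),
                 D_obs = D_obs, D_rep = D_rep,
                 statistic = statistic, n_draws = length(rows)),
            class = "cjs_ppc")
}

#' @export
print.cjs_ppc <- function(x, ...) {
  cat("Posterior predictive check (", x$statistic, ", ", x$n_draws,
      " draws)\n  Bayesian p-value: ", format(x$p_value, digits = 3),
      "\n", sep = "")
  invisible(x)
}
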
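#' Biweekly periods per season
#'
#' The annual cycle (1 July to 30 June) decomposed into 26 biweekly periods:
#' 4 in summer, 6 in autumn, 10 in winter, 6 in spring. These are the powers
#' used to convert biweekly survival to season-level survival.
#'
#' @return Named integer vector summing to 26.
#' @export
season_lengths <- function() {
  c(summer = 4L, autumn = 6L, winter = 10L, spring = 6L)
}

#' Season-level survival from biweekly survival
#'
#' @param phi_biweekly Biweekly survival probability (vectorized).
#' @param n_periods Number of biweekly periods in the season (positive
#'   integer).
#' @return `phi_biweekly ^ n_periods`.
#' @examples
#' season_survival(0.945, 6)  # ~0.712
#' @export
season_survival <- function(phi_biweekly, n_periods) {
  if (length(n_periods) != 1L || n_periods < 1 ||
      n_periods != round(n_periods))
    stop("n_periods must be a positive integer", call. = FALSE)
  if (any(phi_biweekly < 0 | phi_biweekly > 1))
    stop("phi_biweekly must lie in [0, 1]", call. = FALSE)
  phi_biweekly^n_periods
}

#' Winter scenario composition
#'
#' Per-period snow-day counts across the 10 winter periods. The mild scenario
#' has no snow at all; the harsh scenario follows the maximum observed length
#' of intense snow periods: 2 periods of extreme snow cover, 3 of high, 3 of
#' intermediate, and 2 without, totalling 60 of 140 winter days (43%) under
#' snow. The per-class day counts (12, 8, 4 days per period) are a
#' configuration default chosen to meet that structure and total.
#'
#' @param scenario `"mild"` or `"harsh"`, or a custom numeric vector of 10
#'   per-period snow-day counts (each in 0..14).
#' @return Numeric vector of length 10 with attribute `scenario`.
#' @export
winter_composition <- function(scenario = c("mild", "harsh")) {
  if (is.numeric(scenario)) {
    if (length(scenario) != 10L || any(scenario < 0 | scenario > 14))
      stop("a custom winter composition needs 10 per-period snow-day ",
           "counts in [0, 14]", call. = FALSE)
    return(structure(as.numeric(scenario), scenario = "custom"))
  }
  scenario <- match.arg(scenario)
  x <- switch(scenario,
              mild = rep(0, 10),
              harsh = c(12, 12, 8, 8, 8, 4, 4, 4, 0, 0))
  structure(x, scenario = scenario)
}

#' Overwinter survival under a snow scenario
#'
#' Product over the 10 winter periods of the biweekly winter survival implied
#' by the snow-day count of each period:
#' `prod(plogis(alpha_winter + beta_snow_surv * z(snow_days)))`, where `z` is
#' the standardization used at fitting time.
#'
#' @param alpha_winter Logit-scale winter survival intercept (survival at
#'   `z = 0`).
#' @param beta_snow_surv Logit-scale snow effect on survival.
#' @param composition A [winter_composition()].
#' @param snow_scaling List with `center` and `scale` of the snow covariate.
#' @return Overwinter survival probability.
#' @export
winter_survival <- function(alpha_winter, beta_snow_surv,
                            composition = winter_composition("mild"),
                            snow_scaling = list(center = 0, scale = 1)) {
  if (length(composition) != 10L || any(composition < 0 | composition > 14))
    stop("invalid winter composition", call. = FALSE)
  z <- (composition - snow_scaling$center) / snow_scaling$scale
  prod(plogis(alpha_winter + beta_snow_surv * z))
}

#' Annual survival from four seasonal survivals
#'
#' The product of the summer, autumn, winter and spring season-level
#' survivals: first-year survival from 1 July to 30 June.
#'
#' @param seasonals Numeric vector of the 4 seasonal survival probabilities.
#' @return Annual survival probability.
#' @examples
#' annual_survival(c(0.508, 0.673, 0.481, 0.712))  # ~0.117
#' @export
annual_survival <- function(seasonals) {
  if (length(seasonals) != 4L || any(seasonals < 0 | seasonals > 1))
    stop("seasonals must be 4 probabilities", call. = FALSE)
  prod(seasonals)
}

#' Seasonal partition of first-year mortality
#'
#' The share of all first-year deaths that occurs in each season:
#' `share_k = S_1 ... S_{k-1} * (1 - S_k) / (1 - S_annual) * 100`, where
#' `S_k` are the season-level survivals in within-year order. The four shares
#' sum to 100.
#'
#' @param seasonals Numeric vector of the 4 seasonal survival probabilities
#'   (summer, autumn, winter, spring).
#' @return Named numeric vector of 4 percentages.
#' @examples
#' mortality_partition(c(0.508, 0.673, 0.734, 0.712))
#' @export
mortality_partition <- function(seasonals) {
  if (length(seasonals) != 4L || any(seasonals < 0 | seasonals > 1))
    stop("seasonals must be 4 probabilities", call. = FALSE)
  ann <- prod(seasonals)
  if (ann >= 1)
    stop("no mortality: all seasonal survivals are 1", call. = FALSE)
  through <- cumprod(c(1, seasonals[1:3]))
  setNames(100 * through * (1 - seasonals) / (1 - ann), SEASONS)
}

#' Relative change between two survival probabilities
#'
#' `100 * (reference - alternative) / reference`: the percentage by which the
#' alternative scenario reduces survival relative to the reference.
#'
#' @param reference Reference survival (must be positive).
#' @param alternative Alternative survival.
#' @return Percentage change.
#' @examples
#' relative_change(0.178, 0.117)  # ~34.3
#' @export
relative_change <- function(reference, alternative) {
  if (any(reference <= 0)) stop("reference must be positive", call. = FALSE)
  100 * (reference - alternative) / reference
}

# per-draw biweekly survival for one season at given covariates under a mask
.draw_phi_season <- function(draws, season, fed, mass_z, masks) {
  lp <- qlogis(draws[[paste0("phi_", season)]])
  if (season %in% masks$fed) lp <- lp + draws$beta_fed * fed
  if (season %in% masks$mass) lp <- lp + draws$beta_mass * mass_z
  plogis(lp)
}

#' Per-draw derived demography
#'
#' Transforms posterior draws into the derived quantities of interest,
#' computed per draw and only then summarized: season-level survivals (for a
#' bird of average body mass, optionally fed), overwinter survival under the
#' mild and harsh scenarios, annual survival per scenario, and the seasonal
#' mortality partition per scenario. Sex enters no derived quantity (the
#' estimates are presented for an average bird, consistent with reporting
#' seasonal survival for birds of average mass without supplementary food).
#'
#' @param samples A `cjs_posterior`.
#' @param fed 0 (natural) or 1 (supplementary fed); affects the seasons in
#'   the fitted mask only.
#' @param mass_z Body mass covariate value (0 = average).
#' @param harsh A [winter_composition()] for the harsh scenario.
#' @param masks,snow_scaling Defaults taken from the fit's metadata.
#' @return A data frame with one row per draw and columns `S_summer`,
#'   `S_autumn`, `S_winter_mild`, `S_winter_harsh`, `S_spring`,
#'   `annual_mild`, `annual_harsh`, and the eight partition shares
#'   `part_<season>_<scenario>`.
#' @export
derive_demography <- function(samples, fed = 0, mass_z = 0,
                              harsh = winter_composition("harsh"),
                              masks = samples$meta$masks,
                              snow_scaling = samples$meta$snow_scaling) {
  stopifnot(inherits(samples, "cjs_posterior"))
  d <- samples$draws
  len <- season_lengths()
  S_sum <- .draw_phi_season(d, "summer", fed, mass_z, masks)^len["summer"]
  S_aut <- .draw_phi_season(d, "autumn", fed, mass_z, masks)^len["autumn"]
  S_spr <- .draw_phi_season(d, "spring", fed, mass_z, masks)^len["spring"]
  phi_win <- .draw_phi_season(d, "winter", fed, mass_z, masks)
  z_mild <- -snow_scaling$center / snow_scaling$scale
  z_harsh <- (as.numeric(harsh) - snow_scaling$center) / snow_scaling$scale
  S_win_mild <- plogis(qlogis(phi_win) + d$beta_snow_surv * z_mild)^
    len["winter"]
  S_win_harsh <- vapply(seq_len(nrow(d)), function(i)
    prod(plogis(qlogis(phi_win[i]) + d$beta_snow_surv[i] * z_harsh)),
    numeric(1))
  out <- data.frame(S_summer = S_sum, S_autumn = S_aut,
                    S_winter_mild = S_win_mild,
                    S_winter_harsh = S_win_harsh, S_spring = S_spr)
  out$annual_mild <- S_sum * S_aut * S_win_mild * S_spr
  out$annual_harsh <- S_sum * S_aut * S_win_harsh * S_spr
  for (sc in c("mild", "harsh")) {
    wcol <- paste0("S_winter_", sc)
    parts <- t(vapply(seq_len(nrow(out)), function(i)
      mortality_partition(c(out$S_summer[i], out$S_autumn[i],
                            out[[wcol]][i], out$S_spring[i])),
      numeric(4)))
    colnames(parts) <- paste0("part_", SEASONS, "_", sc)
    out <- cbind(out, parts)
  }
  out
}

#' Expected cohort survival trajectory
#'
#' For each posterior draw, multiplies `n0` birds of average body mass
#' through the 26 biweekly periods of the first year (4 summer, 6 autumn,
#' 10 winter, 6 spring), using the draw's scenario-specific biweekly
#' survivals; the trajectory is deterministic within a draw, uncertainty
#' comes from the posterior. Summaries are the median and central 95%
#' interval across draws.
#'
#' @param samples A `cjs_posterior`.
#' @param winter `"mild"` or `"harsh"` (or a custom [winter_composition()]).
#' @param fed 0 or 1, feeding treatment of the simulated cohort.
#' @param n0 Cohort size at release.
#' @param masks,snow_scaling Defaults taken from the fit's metadata.
#' @return Data frame with columns `period` (0..26), `median`, `lower`,
#'   `upper` (numbers of birds alive).
#' @export
cohort_trajectory <- function(samples, winter = "mild", fed = 0, n0 = 100,
                              masks = samples$meta$masks,
                              snow_scaling = samples$meta$snow_scaling) {
  stopifnot(inherits(samples, "cjs_posterior"))
  comp <- if (is.numeric(winter) || inherits(winter, "numeric"))
    winter_composition(winter) else winter_composition(winter)
  d <- samples$draws
  len <- season_lengths()
  z_win <- (as.numeric(comp) - snow_scaling$center) / snow_scaling$scale
  n_draw <- nrow(d)
  traj <- matrix(NA_real_, n_draw, 27L)
  phi_s <- .draw_phi_season(d, "summer", fed, 0, masks)
  phi_a <- .draw_phi_season(d, "autumn", fed, 0, masks)
  phi_w0 <- .draw_phi_season(d, "winter", fed, 0, masks)
  phi_p <- .draw_phi_season(d, "spring", fed, 0, masks)
  for (i in seq_len(n_draw)) {
    phi_seq <- c(rep(phi_s[i], len["summer"]),
                 rep(phi_a[i], len["autumn"]),
                 plogis(qlogis(phi_w0[i]) + d$beta_snow_surv[i] * z_win),
                 rep(phi_p[i], len["spring"]))
    traj[i, ] <- n0 * cumprod(c(1, phi_seq))
  }
  data.frame(period = 0:26,
             median = apply(traj, 2L, median),
             lower = apply(traj, 2L, quantile, probs = 0.025),
             upper = apply(traj, 2L, quantile, probs = 0.975))
}

#' Posterior summary tables
#'
#' `summarize_posterior()` reduces draws to the reported summaries: the
#' median and the central 95% credible interval (2.5th and 97.5th
#' percentiles, linear-interpolation quantiles). Derived quantities must be
#' computed per draw first and summarized last; this function only does the
#' summarizing.
#'
#' @param x A numeric vector of draws, or a data frame of draw columns.
#' @return For a vector: named numeric `(median, lower, upper)`. For a data
#'   frame: a data frame with one row per column.
#' @export
summarize_posterior <- function(x) {
  if (is.data.frame(x)) {
    out <- t(vapply(x, summarize_posterior, numeric(3)))
    return(data.frame(quantity = rownames(out), out, row.names = NULL))
  }
  c(median = median(x),
    lower = unname(quantile(x, 0.025)),
    upper = unname(quantile(x, 0.975)))
}

#' Report tables of seasonal and annual survival and mortality partition
#'
#' Builds the two standard report tables: seasonal survival (plus annual
#' survival for mild and harsh winters) with 95% credible intervals, and the
#' seasonal mortality partition for every scenario-by-feeding-group
#' combination. Probabilities are reported to 3 decimals and percentages to
#' 1 decimal.
#'
#' @param samples A `cjs_posterior`.
#' @param ... Passed to [derive_demography()] (e.g. a custom harsh
#'   composition).
#' @return List with data frames `survival` and `partition`.
#' @export
demography_tables <- function(samples, ...) {
  natural <- derive_demography(samples, fed = 0, ...)
  fed <- derive_demography(samples, fed = 1, ...)
  surv_rows <- c(S_summer = "Summer (post-fledging)", S_autumn = "Autumn",
                 S_winter_mild = "Winter (mild)",
                 S_winter_harsh = "Winter (harsh)", S_spring = "Spring",
                 annual_mild = "Annual survival (with mild winter)",
                 annual_harsh = "Annual survival (with harsh winter)")
  sm <- summarize_posterior(natural[names(surv_rows)])
  survival <- data.frame(quantity = unname(surv_rows),
                         round(sm[, c("median", "lower", "upper")], 3))
  part <- expand.grid(season = SEASONS, winter = c("mild", "harsh"),
                      group = c("natural", "fed"),
                      stringsAsFactors = FALSE)
  part$share <- mapply(function(se, wi, gr) {
    src <- if (gr == "natural") natural else fed
    round(median(src[[paste0("part_", se, "_", wi)]]), 1)
  }, part$season, part$winter, part$group)
  list(survival = survival, partition = part)
}
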
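# shared fixtures, all generated in code

# single-cohort calendar: release summer + one winter, 26 survival intervals
make_calendar <- function(n = 27, origin = "2009-05-15", effort = NULL,
                          overlap = "first_summer") {
  build_occasion_calendar(origin, n, effort_spec = effort,
                          overlap_rule = overlap)
}

# snow covariate for a calendar, standardized under the default policy;
# severity 1 = a deterministic average winter, so single-winter unit
# fixtures never draw an (otherwise realistic) snow-free winter that would
# leave the covariate unscalable
make_snow_z <- function(calendar, seed = 11, severity = 1) {
  series <- simulate_snow_series(calendar, seed = seed,
                                 severity = severity)
  sdy <- snow_days_by_occasion(series, calendar)
  sc <- snow_standardization(sdy, calendar)
  list(z = standardize_snow(sdy, sc$center, sc$scale),
       snow_days = sdy, scaling = sc, series = series)
}

# a full synthetic dataset at the study's generating values
make_dataset <- function(n = 300, seed = 1, params = study_params(),
                         calendar = make_calendar(), cohorts = 1,
                         snow_seed = 11, severity = 1,
                         masks = season_mask()) {
  sz <- make_snow_z(calendar, seed = snow_seed, severity = severity)
  ind <- simulate_individuals(n, cohorts, 0.5, seed = seed,
                              calendar = calendar)
  sim <- simulate_encounters(ind, params, calendar, sz$z,
                             seed = seed + 5000L, masks = masks)
  c(sim, list(individuals = ind, z = sz$z, scaling = sz$scaling,
              snow_days = sz$snow_days))
}

# the study design: 3 cohorts x 100 fledglings on the 79-occasion calendar,
# with the documented winter pattern (harsh, harsh, mild)
make_study_dataset <- function(seed = 1, params = study_params(),
                               snow_seed = 11) {
  make_dataset(n = 100, seed = seed, params = params,
               calendar = study_calendar(), cohorts = 3,
               snow_seed = snow_seed, severity = study_winter_severity())
}

# hand-built individual table bypassing the staggered-release generator
make_individual_table <- function(n, release, calendar,
                                  mass_z = rep(0, n), sex = rep(0L, n),
                                  fed = rep(0L, n)) {
  structure(data.frame(individual = seq_len(n), brood = seq_len(n),
                       cohort = 1L, sex = sex, mass_z = mass_z, fed = fed,
                       tagging_date = calendar$start_date[release],
                       release = rep(release, length.out = n)),
            class = c("individual_table", "data.frame"))
}

# empty dataset for prior-only sampling
make_empty_data <- function(calendar = make_calendar()) {
  cjs_data(matrix(0L, 0, nrow(calendar)), integer(0),
           data.frame(mass_z = numeric(0), sex = integer(0),
                      fed = integer(0)),
           calendar, rep(0, nrow(calendar)))
}

# constant-survival parameter vector (all seasons at the same phi)
flat_params <- function(phi, p = 0.9, sigma_det = 0) {
  cjs_params(alpha = rep(qlogis(phi), 4), p_full = p, p_reduced = p,
             sigma_det = sigma_det)
}

# Monte-Carlo standard error by batch means (handles autocorrelated chains)
batch_mcse <- function(x, n_batch = 30) {
  bm <- tapply(x, cut(seq_along(x), n_batch), mean)
  sd(bm) / sqrt(n_batch)
}
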
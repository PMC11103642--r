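test_that("season-level survival is biweekly survival powered up", {
  expect_equal(season_survival(0.945, 6), 0.712, tolerance = 5e-4)
  expect_equal(season_survival(0.844, 4), 0.508, tolerance = 2e-3)
  expect_equal(season_survival(1, 10), 1)
  expect_error(season_survival(0.9, 0), "positive integer")
  expect_error(season_survival(1.2, 4), "lie in")
})

test_that("winter scenarios behave like repeated biweekly survival", {
  aw <- qlogis(0.970)
  mild <- winter_composition("mild")
  expect_equal(winter_survival(aw, -0.4, mild), 0.970^10)
  harsh <- winter_composition("harsh")
  expect_equal(sum(harsh), 60)
  expect_equal(sort(as.numeric(table(harsh)), decreasing = TRUE),
               c(3, 3, 2, 2))  # 2 extreme + 3 high + 3 intermediate + 2 none
  # without a snow effect the composition is irrelevant
  expect_equal(winter_survival(aw, 0, harsh), winter_survival(aw, 0, mild))
  # any negative effect makes the harsh winter strictly worse
  for (b in c(-0.1, -0.4, -1)) {
    expect_lt(winter_survival(aw, b, harsh,
                              snow_scaling = list(center = 0, scale = 3)),
              winter_survival(aw, b, mild,
                              snow_scaling = list(center = 0, scale = 3)))
  }
  expect_error(winter_composition(rep(3, 9)), "10 per-period")
})

test_that("annual survival multiplies the four seasons", {
  expect_equal(round(annual_survival(c(0.508, 0.673, 0.481, 0.712)), 3),
               0.117)
  expect_equal(annual_survival(rep(1, 4)), 1)
  expect_equal(annual_survival(c(0, 0.9, 0.9, 0.9)), 0)
})

test_that("the mortality partition allocates deaths by season", {
  mild <- mortality_partition(c(0.508, 0.673, 0.734, 0.712))
  expect_equal(unname(round(mild, 1)), c(59.9, 20.2, 11.1, 8.8))
  harsh <- mortality_partition(c(0.508, 0.673, 0.481, 0.712))
  expect_equal(unname(round(harsh, 1)), c(55.7, 18.8, 20.1, 5.4))
  expect_equal(sum(mild), 100)
  expect_equal(sum(harsh), 100)
  expect_error(mortality_partition(rep(1, 4)), "no mortality")
})

test_that("relative change is measured against the reference scenario", {
  expect_equal(relative_change(0.178, 0.117), 34.3, tolerance = 0.05)
  expect_equal(relative_change(0.5, 0.5), 0)
  expect_equal(relative_change(1, 0.5), 50)
  expect_error(relative_change(0, 0.5), "positive")
})

test_that("posterior summaries use medians and 95% interpolated quantiles", {
  x <- rep(3.7, 50)
  expect_equal(summarize_posterior(x),
               c(median = 3.7, lower = 3.7, upper = 3.7))
  y <- as.numeric(1:1000)
  s <- summarize_posterior(y)
  expect_equal(unname(s), c(500.5, 25.975, 975.025))
})

# a deterministic "posterior" with two exact draws, for closed-form checks
fake_samples <- function(phi_winter = c(0.97, 0.95),
                         beta_snow = c(-0.4, -0.2)) {
  k <- length(phi_winter)
  draws <- data.frame(chain = 1L, iteration = seq_len(k),
                      phi_summer = rep(0.844, k), phi_autumn = rep(0.936, k),
                      phi_winter = phi_winter, phi_spring = rep(0.945, k),
                      beta_snow_surv = beta_snow, beta_mass = rep(0.48, k),
                      beta_sex = rep(0.153, k), beta_fed = rep(0.345, k),
                      p_full = rep(0.99, k), p_reduced = rep(0.8, k),
                      beta_snow_det = rep(-0.2, k), sigma_det = rep(0.3, k))
  structure(list(draws = draws, eps = NULL,
                 meta = list(masks = season_mask(),
                             snow_scaling = list(center = 0, scale = 4))),
            class = "cjs_posterior")
}

test_that("derived demography is computed per draw, then summarized", {
  s <- fake_samples()
  dd <- derive_demography(s)
  expect_equal(dd$S_summer, rep(0.844^4, 2))
  expect_equal(dd$S_winter_mild, c(0.97^10, 0.95^10))
  harsh_z <- winter_composition("harsh") / 4
  expect_equal(dd$S_winter_harsh[1],
               prod(plogis(qlogis(0.97) - 0.4 * harsh_z)))
  expect_equal(dd$annual_harsh,
               dd$S_summer * dd$S_autumn * dd$S_winter_harsh * dd$S_spring)
  # per-draw-then-summarize differs from transforming summaries: the median
  # of a product of jointly varying components is not the product of medians
  skew <- fake_samples(phi_winter = c(0.99, 0.93, 0.89),
                       beta_snow = c(-1.2, -0.1, -0.05))
  skew$draws$phi_summer <- c(0.80, 0.86, 0.90)  # anti-correlated with winter
  dd2 <- derive_demography(skew)
  expect_false(isTRUE(all.equal(
    median(dd2$annual_harsh),
    median(dd2$S_summer) * median(dd2$S_autumn) *
      median(dd2$S_winter_harsh) * median(dd2$S_spring))))
  # partition shares per draw sum to 100
  expect_equal(dd$part_summer_mild + dd$part_autumn_mild +
                 dd$part_winter_mild + dd$part_spring_mild, c(100, 100))
})

test_that("feeding lifts survival only through its masked seasons", {
  s <- fake_samples()
  nat <- derive_demography(s, fed = 0)
  fed <- derive_demography(s, fed = 1)
  expect_equal(fed$S_summer, rep(plogis(qlogis(0.844) + 0.345)^4, 2))
  expect_equal(fed$S_autumn, nat$S_autumn)  # mask: summer only
  expect_equal(fed$S_winter_mild, nat$S_winter_mild)
})

test_that("cohort trajectories decay multiplicatively through 26 periods", {
  s <- fake_samples(phi_winter = c(0.9, 0.9), beta_snow = c(0, 0))
  flat <- s
  for (col in paste0("phi_", c("summer", "autumn", "winter", "spring")))
    flat$draws[[col]] <- 0.9
  tr <- cohort_trajectory(flat, winter = "mild", fed = 0, n0 = 100)
  expect_equal(nrow(tr), 27)
  expect_equal(tr$median[1], 100)
  expect_equal(tr$median[27], 100 * 0.9^26, tolerance = 1e-10)

  certain <- flat
  for (col in paste0("phi_", c("summer", "autumn", "winter", "spring")))
    certain$draws[[col]] <- 1 - 1e-15
  tr2 <- cohort_trajectory(certain, winter = "mild")
  expect_equal(tr2$median, rep(100, 27), tolerance = 1e-10)

  # under the summer-only mask fed and unfed trajectories are parallel
  # (constant ratio) once the 4 summer periods are over
  s2 <- fake_samples()
  trf <- cohort_trajectory(s2, winter = "harsh", fed = 1)
  tru <- cohort_trajectory(s2, winter = "harsh", fed = 0)
  ratio <- trf$median[5:27] / tru$median[5:27]
  expect_equal(ratio, rep(ratio[1], 23), tolerance = 1e-10)
})

test_that("powering through seasons equals powering through 26 periods", {
  s <- fake_samples()
  dd <- derive_demography(s)
  tr <- cohort_trajectory(s, winter = "mild", fed = 0, n0 = 1)
  expect_equal(tr$median[27], median(dd$annual_mild), tolerance = 1e-12)
})

test_that("report tables carry the documented rounding", {
  s <- fake_samples()
  tabs <- demography_tables(s)
  expect_equal(nrow(tabs$survival), 7)
  expect_equal(nrow(tabs$partition), 16)
  expect_true(all(abs(tabs$survival$median * 1000 -
                        round(tabs$survival$median * 1000)) < 1e-9))
  shares <- tapply(tabs$partition$share,
                   list(tabs$partition$winter, tabs$partition$group), sum)
  expect_true(all(abs(shares - 100) < 0.11))
})
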
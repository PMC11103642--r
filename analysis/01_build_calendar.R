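#!/usr/bin/env Rscript

# Step 1: the time axis and the winter-harshness covariate.
#
# Builds the 79-occasion biweekly calendar (15 May 2009 onwards, three
# summers and three winters), marks the field effort regimes (4 occasions
# with no tracking, 6 with reduced effort), generates a synthetic daily
# snow-depth series over the span, and reduces it to the per-occasion
# snow-days covariate. Writes results/occasions.csv and the daily series.

library(cjsnow)

SEED <- 2009L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cal <- study_calendar()
cat("Calendar:", nrow(cal), "biweekly occasions from",
    format(cal$start_date[1]), "to", format(cal$start_date[nrow(cal)] + 13),
    "\n")
print(table(cal$season))
cat("Effort regimes:", sum(cal$effort == "full"), "full /",
    sum(cal$effort == "reduced"), "reduced /",
    sum(cal$effort == "none"), "none\n")

series <- simulate_snow_series(cal, seed = SEED,
                               severity = study_winter_severity())
write.csv(data.frame(date = format(series$date), snow_cm = series$snow_cm),
          file.path(out_dir, "daily_snow.csv"), row.names = FALSE)

snow_days <- snow_days_by_occasion(series, cal)
cal <- set_snow_days(cal, snow_days)
scaling <- snow_standardization(snow_days, cal)
cat("Snow days per winter occasion:\n")
print(snow_days[cal$season == "winter"])
cat(sprintf("Covariate scaling: center %.0f, scale %.3f (winter SD)\n",
            scaling$center, scaling$scale))

write_occasions(cal, file.path(out_dir, "occasions.csv"))
cat("Wrote", file.path(out_dir, "occasions.csv"), "\n")
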
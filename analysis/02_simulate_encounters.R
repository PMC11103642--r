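#!/usr/bin/env Rscript

# Step 2: synthetic cohorts and encounter histories.
#
# Simulates three annual cohorts of 100 radio-tagged fledglings (broods of
# 1-5, staggered May-July tagging, brood-level feeding treatment for half
# the broods) and runs the survival/detection model generatively at the
# study-scale parameter values to produce encounter histories with known
# truth. Writes the dataset and the generating truth under results/data/.

library(cjsnow)

SEED <- 2009L
out_dir <- "results"
data_dir <- file.path(out_dir, "data")

cal <- read_occasions(file.path(out_dir, "occasions.csv"))
snow_days <- cal$snow_days
scaling <- snow_standardization(snow_days, cal)
z <- standardize_snow(snow_days, scaling$center, scaling$scale)

individuals <- simulate_individuals(100, 3, 0.5, seed = SEED + 1,
                                    calendar = cal)
cat("Simulated", nrow(individuals), "individuals in",
    length(unique(individuals$brood)), "broods;",
    sum(individuals$fed), "received supplementary food\n")

truth <- study_params()
sim <- simulate_encounters(individuals, truth, cal, z, seed = SEED + 2)
cat("Detections per occasion (first 10):",
    head(colSums(sim$data$y), 10), "\n")
cat("Still alive at the final occasion:",
    sum(sim$truth$alive[, ncol(sim$data$y)]), "of", nrow(sim$data$y), "\n")

write_encounter_data(sim$data, data_dir)
jsonlite::write_json(
  list(seed = SEED + 2,
       params = truth[c("alpha", "beta_snow_surv", "beta_mass", "beta_sex",
                        "beta_fed", "p_full", "p_reduced", "beta_snow_det",
                        "sigma_det")],
       snow_scaling = scaling),
  file.path(data_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("Wrote", data_dir, "(encounters, individuals, occasions, truth)\n")
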
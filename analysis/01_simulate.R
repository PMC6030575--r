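#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohort.
#
# Generates a synthetic cohort with the reference structure (545 persons,
# the empirical distribution of 1-14 daily ratings per person, reference
# measurement parameters with latent correlation 0.80, baseline
# eligibility truncation at a sum score of 5) and writes the three tables
# plus a provenance record under results/.
#
# Usage: Rscript analysis/01_simulate.R [--seed <int>]

suppressPackageStartupMessages(library(dailyphq))

args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args)
  args[match("--seed", args) + 1L] else "20260929")

dir.create("results", showWarnings = FALSE)
cfg <- generator_config()
cohort <- generate_cohort(cfg, seed = seed)

write_long_daily(cohort$daily, "results/daily.csv")
write_panel(cohort$panel, "results/panel.csv")
utils::write.csv(cohort$truth, "results/truth.csv", row.names = FALSE)
jsonlite::write_json(
  list(seed = seed, n_persons = cfg$n_persons,
       cluster_sizes = unclass(cfg$cluster_sizes),
       latent_correlation = cfg$params$r,
       discretize = cfg$discretize,
       baseline = list(mean = cfg$baseline_mean, sd = cfg$baseline_sd,
                       floor = cfg$eligibility_floor),
       outcome_r2_targets = list(phq9 = cfg$r2_phq, sds = cfg$r2_sds),
       missing_week8 = cfg$missing_week8,
       package_version = as.character(utils::packageVersion("dailyphq"))),
  "results/provenance.json", auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("simulated %d persons, %d daily ratings (mean %.2f/person)\n",
            length(unique(cohort$daily$person_id)), nrow(cohort$daily),
            nrow(cohort$daily) / length(unique(cohort$daily$person_id))))
cat("wrote results/daily.csv, results/panel.csv, results/truth.csv\n")
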
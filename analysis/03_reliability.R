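#!/usr/bin/env Rscript

# Stage 3 — reliability of the daily measure and the questionnaire.
#
# Refits the measurement model (a few seconds) and reports the three
# reliabilities with delta-method 95% CIs: questionnaire omega,
# within-person (day-to-day) daily omega, and the person-mean reliability
# of the daily composite at the cohort's mean number of ratings. Also
# evaluates the same three quantities on the bundled reference parameter
# set for comparison.
#
# Usage: Rscript analysis/03_reliability.R

suppressPackageStartupMessages(library(dailyphq))

daily <- read_long_daily("results/daily.csv", continuous = TRUE)
panel <- read_panel("results/panel.csv", continuous = TRUE)
flt <- apply_sample_filters(daily, panel)

fit <- fit_mlcfa(flt$daily, flt$panel)
rel <- reliability_report(fit, n_bar = "auto")
rel$source <- "fitted"

ref <- default_measurement_params()
ref_rel <- reliability_report(ref, n_bar = rel$n_bar[1])
ref_rel$source <- "reference_params"

out <- rbind(rel, ref_rel)
utils::write.csv(out, "results/reliability.csv", row.names = FALSE)

for (i in seq_len(nrow(rel)))
  cat(sprintf("%-22s %.3f [%.3f, %.3f]\n", rel$quantity[i],
              rel$estimate[i], rel$lower[i], rel$upper[i]))
cat(sprintf("(n_bar = %.2f ratings/person)\n", rel$n_bar[1]))
cat("wrote results/reliability.csv\n")
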
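#!/usr/bin/env Rscript

# Stage 5 — predicting week-8 outcomes.
#
# Summarizes each person's in-window daily composite (mean, SD, min, max,
# linear slope), assembles the four predictor rosters, and fits each model
# for the two week-8 outcomes jointly by seemingly unrelated regression.
# Writes the long coefficient table mirroring the four-model layout.
#
# Usage: Rscript analysis/05_predict.R

suppressPackageStartupMessages(library(dailyphq))

daily <- read_long_daily("results/daily.csv", continuous = TRUE)
panel <- read_panel("results/panel.csv", continuous = TRUE)
flt <- apply_sample_filters(daily, panel)

summaries <- summarize_daily(flt$daily)
pred <- predict_report(flt$panel, summaries)

r2 <- unique(pred$table[, c("model", "outcome", "r2", "n")])
for (i in seq_len(nrow(r2)))
  cat(sprintf("model %d  %-9s R2 = %.3f (n = %d)\n", r2$model[i],
              r2$outcome[i], r2$r2[i], r2$n[i]))

utils::write.csv(pred$table, "results/prediction.csv", row.names = FALSE)
cat("wrote results/prediction.csv\n")
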
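#!/usr/bin/env Rscript
# Stage 2: fixations -> dwell-time proportions -> trial filter -> avoidance.
#
# Each fixation is assigned to the disgust image, the neutral image, or
# non-stimulus space (half-open 400x300 rectangles, centres 640 px apart);
# proportions are of total fixation time in the trial. Trials with > 50%
# missing data are dropped (strict rule), then the avoidance score
# (neutral - disgust dwell) is attached.

library(lookaway)

fixations <- read_table_csv("results/fixations.csv", "fixations")
grid <- read_table_csv("results/trial_grid.csv")

dwell <- compute_dwell(fixations, aoi_layout(), trial_duration_ms = 15000,
                       all_trials = grid)
filt <- filter_trials(dwell, max_missing = 0.5)
scored <- avoidance(filt$records)

write_table_csv(dwell, "results/dwell.csv", "dwell")
write_table_csv(scored, "results/avoidance.csv")

message(sprintf("%d trials, %d dropped for > 50%% missing data (%.1f%%)",
                nrow(dwell), filt$n_dropped, 100 * filt$n_dropped / nrow(dwell)))
by_phase <- aggregate(avoidance ~ phase, scored, mean)
message("mean avoidance by phase (positive = gaze away from disgust):")
for (i in seq_len(nrow(by_phase)))
  message(sprintf("  %-14s %+.3f", by_phase$phase[i], by_phase$avoidance[i]))
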
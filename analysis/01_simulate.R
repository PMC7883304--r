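#!/usr/bin/env Rscript
# Stage 1: generate the synthetic crossover study.
#
# 25 participants, two visits (domperidone / placebo, order counterbalanced),
# five preferential-looking phases per visit (24 + 24 trials around drug
# administration, then 10 / 10 / 10 around the incentivized-exposure block),
# four reversal-bandit sessions per participant, and self-report ratings.
# Ground truth: strong disgust avoidance (-1.5 logits), an
# exposure-facilitation effect of +0.5 logits in the domperidone
# post-incentive cell, and no drug effect on reward learning.

library(lookaway)

seed <- 20260918L
dir.create("results", showWarnings = FALSE)

design <- study_design(n_participants = 25, seed = seed)
study <- simulate_study(design,
                        gaze_sim_config(seed = seed),
                        rl_sim_config(seed = seed + 1L))

write_table_csv(study$fixations, "results/fixations.csv", "fixations")
write_table_csv(study$choices, "results/choices.csv", "choices")
write_table_csv(study$self_report, "results/self_report.csv", "self_report")
write_table_csv(study$true_params, "results/true_rl_params.csv")
write_table_csv(design$trial_grid, "results/trial_grid.csv")

message(sprintf("simulated %d participants: %d fixations, %d choices, %d ratings",
                design$n_participants, nrow(study$fixations),
                nrow(study$choices), nrow(study$self_report)))
message("ground truth: stimulus effect -1.5 logits, drug x phase interaction +0.5, RL drug effect 0")
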
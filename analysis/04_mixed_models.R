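#!/usr/bin/env Rscript
# Stage 4: the mixed-model inference structure.
#
# (a) Trial-level dwell LMM with factors stimulus, drug, phase, trial and a
#     participant random intercept (sum-to-zero coding, z-scored outcome:
#     coefficients are standardized betas, inference by Wald Z).
# (b) The calibrated interaction test on the avoidance difference: the
#     drug:phase term carries the drug x phase x stimulus effect.
# (c) Per-trial paired disgust-vs-neutral tests with Holm-Bonferroni flags.
# (d) Self-report LMM (no trial factor).

library(lookaway)

scored <- read_table_csv("results/avoidance.csv")
self_report <- read_table_csv("results/self_report.csv", "self_report")

show <- function(tag, eff) {
  message(sprintf("  %-28s beta = %+.3f  CI [%+.3f, %+.3f]  Z = %+.2f  p = %.4g",
                  tag, eff$beta, eff$ci_low, eff$ci_high, eff$z, eff$p))
}

# (a) exposure-phase dwell model (the study's primary structure)
long <- dwell_long(scored)
exposure <- long[long$phase %in% c("pre_incentive", "post_incentive"), ]
dwell_lmm <- fit_mixed_model(
  exposure, model_spec("dwell", c("stimulus", "drug", "phase", "trial")))
write_table_csv(dwell_lmm$effects, "results/dwell_effects.csv", "effects")
message(sprintf("dwell LMM (%d obs):", dwell_lmm$n_obs))
for (t in c("stimulus", "stimulus:drug:phase"))
  show(t, dwell_lmm$effects[dwell_lmm$effects$term == t, ])

# (b) calibrated difference-scale interaction test
avoid_lmm <- fit_avoidance_model(scored)
write_table_csv(avoid_lmm$effects, "results/avoidance_effects.csv", "effects")
message("avoidance model (negative drug:phase = avoidance falls more under domperidone):")
show("drug:phase", avoid_lmm$effects[avoid_lmm$effects$term == "drug:phase", ])

# (c) per-trial tests with Holm-Bonferroni
tests <- per_trial_tests(scored[scored$phase != "incentive", ])
tests$significant <- tests$p < 0.05
tests$holm_significant <- holm_bonferroni(tests$p, 0.05)
write_table_csv(tests, "results/per_trial_tests.csv")
message(sprintf("per-trial tests: %d/%d significant uncorrected, %d after Holm",
                sum(tests$significant, na.rm = TRUE), sum(!is.na(tests$p)),
                sum(tests$holm_significant, na.rm = TRUE)))

# (d) self-report: category effect, no trial factor
self_report$drug <- self_report$visit
sr_lmm <- fit_mixed_model(self_report,
                          model_spec("rating", c("category", "drug", "phase")))
write_table_csv(sr_lmm$effects, "results/self_report_effects.csv", "effects")
message("self-report LMM:")
show("category", sr_lmm$effects[sr_lmm$effects$term == "category", ])
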
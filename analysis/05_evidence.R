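#!/usr/bin/env Rscript
# Stage 5: evidence for the null drug effect on the control task.
#
# For each derived measure -- P(win), the fitted learning rates and inverse
# temperatures -- a mixed model of drug, phase and their interaction is
# compared against its intercept-only null (evidence ratio ER_0 from AIC,
# Bayes factor BF_01 from BIC; values over 1 favour the null, over 3 count
# as evidence under the strict 'over 3' convention), and a post hoc model of
# the post-minus-pre parameter difference tests the specific drug effect.

library(lookaway)

fits <- read_table_csv("results/rl_fits.csv")
ev <- rl_evidence_table(fits)
write_table_csv(ev, "results/rl_evidence.csv")

message("control-task null-evidence table (drug had no injected effect):")
message(sprintf("  %-13s %9s %8s | %9s %9s | %8s %8s",
                "measure", "beta_drug", "p", "ER0_null", "BF01_null",
                "ER0_drug", "BF01_drug"))
for (i in seq_len(nrow(ev))) {
  message(sprintf("  %-13s %+9.3f %8.3f | %9.2f %9.2f | %8.2f %8.2f",
                  ev$measure[i], ev$beta_drug[i], ev$p_drug[i],
                  ev$er0_null[i], ev$bf01_null[i],
                  ev$er0_drug[i], ev$bf01_drug[i]))
}
fav <- colMeans(ev[, c("er0_null", "bf01_null", "er0_drug", "bf01_drug")] > 1)
message(sprintf("fraction of measures favouring the null: %s",
                paste(sprintf("%s %.2f", names(fav), fav), collapse = ", ")))
message(sprintf("Jeffreys category of the drug-effect Bayes factors: %s",
                paste(interpret_evidence(ev$bf01_drug), collapse = ", ")))
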
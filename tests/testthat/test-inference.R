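# Mixed-model inference, post hoc drug models, per-trial tests and the
# Holm-Bonferroni step-down rule.

test_that("Holm-Bonferroni steps down exactly as the hand calculation", {
  expect_equal(holm_bonferroni(0.04), TRUE)                    # m = 1
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(TRUE, TRUE))  # 0.01<=0.025, 0.04<=0.05
  expect_equal(holm_bonferroni(c(0.03, 0.04)), c(FALSE, FALSE)) # 0.03 > 0.025 stops the ladder
  expect_equal(holm_bonferroni(c(0.02, 0.06)), c(TRUE, FALSE))  # rejects, then fails at 0.05
  expect_equal(holm_bonferroni(rep(1, 5)), rep(FALSE, 5))
  # flags come back in input order
  expect_equal(holm_bonferroni(c(0.04, 0.01)), c(TRUE, TRUE))
  # untestable entries are excluded from the family
  expect_equal(holm_bonferroni(c(0.01, NA, 0.04)), c(TRUE, NA, TRUE))
  expect_error(holm_bonferroni(c(0, 0.5)), "p-values")
})

test_that("Holm agrees with the independent step-down implementation", {
  set.seed(19)
  for (rep in 1:25) {
    p <- runif(sample(1:12, 1))^2
    mine <- holm_bonferroni(p)
    oracle <- stats::p.adjust(p, method = "holm") <= 0.05
    expect_equal(mine, oracle)
    # sandwiched between Bonferroni and uncorrected rejections
    bonf <- p <= 0.05 / length(p)
    expect_true(all(mine[bonf]))          # superset of Bonferroni
    expect_true(all(p[mine] <= 0.05))     # subset of uncorrected
  }
})

test_that("the trial-level mixed model recovers an injected stimulus effect", {
  d <- study_design(n_participants = 10, seed = 2)
  g <- simulate_gaze(d, gaze_sim_config(stimulus_effect = -1.5, seed = 2))
  rec <- filter_trials(compute_dwell(g$fixations,
                                     all_trials = d$trial_grid))$records
  long <- dwell_long(rec)
  m <- fit_mixed_model(long, model_spec("dwell",
                                        c("stimulus", "drug", "phase", "trial")))
  st <- m$effects[m$effects$term == "stimulus", ]
  expect_lt(st$beta, 0)
  expect_lt(st$p, 0.05)
  expect_true(st$ci_low <= st$beta && st$beta <= st$ci_high)
  # bookkeeping: two stimulus rows per retained dwell record
  expect_equal(m$n_obs, 2L * nrow(rec))
})

test_that("relabelled identical data shows no drug effect, injected sign returns", {
  # exchangeable by construction: every participant contributes the same
  # pair of values under both labels, so the drug effect is exactly zero
  set.seed(22)
  vals <- data.frame(participant = rep(1:12, 2), value = rnorm(24, 0.3, 0.2))
  base <- rbind(cbind(vals, drug = "placebo"),
                cbind(vals, drug = "domperidone"))
  ph <- suppressWarnings(posthoc_drug_difference(base))
  expect_equal(ph$effect$beta, 0, tolerance = 1e-6)

  set.seed(23)
  inj <- data.frame(participant = rep(1:30, 2),
                    drug = rep(c("placebo", "domperidone"), each = 30))
  # domperidone (+1 in the coding) carries the larger mean
  inj$value <- rnorm(60, 0, 0.3) + ifelse(inj$drug == "domperidone", 0.8, 0)
  ph2 <- suppressWarnings(posthoc_drug_difference(inj))
  expect_gt(ph2$effect$beta, 0)
  expect_lt(ph2$effect$p, 0.05)
  expect_lt(ph2$comparison$er_0, 1)   # evidence runs against the null here
  expect_error(posthoc_drug_difference(base[base$drug == "placebo", ]),
               "both drug conditions")
})

test_that("per-trial tests flag untestable cells and detect strong avoidance", {
  # zero variance of the paired differences: flagged, not given p = 1
  flat <- data.frame(participant = 1:6, visit = "placebo", phase = "baseline",
                     trial = 1L, p_disgust = 0.3, p_neutral = 0.3,
                     p_nonstim = 0.4)
  r <- per_trial_tests(flat)
  expect_false(r$testable)
  expect_true(is.na(r$p))

  set.seed(31)
  d <- study_design(n_participants = 12, seed = 31)
  g <- simulate_gaze(d, gaze_sim_config(stimulus_effect = -2, seed = 31))
  rec <- filter_trials(compute_dwell(g$fixations))$records
  base <- rec[rec$phase == "baseline", ]
  tests <- per_trial_tests(base)
  expect_gt(mean(tests$p < 0.05, na.rm = TRUE), 0.8)
  # invariant to participant ordering
  shuffled <- base[sample(nrow(base)), ]
  expect_equal(per_trial_tests(shuffled)$p, tests$p)
  # fewer than 3 pairs is untestable
  tiny <- base[base$participant <= 2, ]
  expect_true(all(!per_trial_tests(tiny)$testable))
})

test_that("self-report ratings show the stimulus-category effect without a trial factor", {
  d <- study_design(n_participants = 12, seed = 5)
  sr <- simulate_self_report(d, seed = 5)
  sr$drug <- sr$visit
  m <- fit_mixed_model(sr, model_spec("rating", c("category", "drug", "phase")))
  cat_row <- m$effects[m$effects$term == "category", ]
  expect_gt(cat_row$beta, 0)   # disgust (+1) rated far above neutral
  expect_lt(cat_row$p, 0.001)
})

test_that("the control-task evidence table has the full column structure", {
  st <- small_study(n = 6, seed = 41)
  fits <- fit_rl_sessions(st$choices, n_starts = 4)
  ev <- suppressWarnings(rl_evidence_table(fits))
  expect_equal(ev$measure, c("p_win", "eta", "beta", "eta_win", "eta_lose",
                             "beta_winlose"))
  expect_true(all(c("beta_drug", "p_drug", "beta_phase", "p_phase",
                    "beta_interaction", "p_interaction", "er0_null",
                    "bf01_null", "er0_drug", "bf01_drug") %in% names(ev)))
  expect_true(all(is.finite(unlist(ev[, -1]))))
  expect_true(all(ev$er0_null > 0 & ev$bf01_null > 0))
})

test_that("mixed-model preconditions are enforced", {
  df <- data.frame(participant = 1, value = rnorm(5), drug = "placebo")
  expect_error(fit_mixed_model(df, model_spec("value", "drug")),
               ">= 2 grouping units")
  expect_error(fit_mixed_model(data.frame(a = 1), model_spec("value", "drug")),
               "missing required column")
})
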
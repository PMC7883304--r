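# The synthetic-data generators: design, reversal schedule, agents, gaze and
# the whole-study bundle.

test_that("the crossover design balances drug order and image sides", {
  d <- study_design(n_participants = 10, seed = 3)
  # every participant has two visits with opposite drugs
  per_p <- split(d$visit_order$visit, d$visit_order$participant)
  expect_true(all(vapply(per_p, function(v)
    setequal(v, c("domperidone", "placebo")), logical(1))))
  # order counterbalanced up to rounding
  first <- d$visit_order$visit[d$visit_order$visit_index == 1]
  expect_equal(sum(first == "domperidone"), 5L)
  # sides balanced within each participant-visit-phase up to rounding
  grid <- d$trial_grid
  bal <- tapply(grid$disgust_side == "left",
                list(grid$participant, grid$visit, grid$phase), sum)
  counts <- tapply(grid$disgust_side == "left",
                   list(grid$participant, grid$visit, grid$phase), length)
  expect_true(all(abs(bal - counts / 2) <= 0.5, na.rm = TRUE))
  expect_equal(nrow(grid), 10L * 2L * (24 + 24 + 10 + 10 + 10))
})

test_that("the reversal schedule has the task's published shape", {
  set.seed(6)
  for (rep in 1:10) {
    sched <- make_reward_schedule(rl_sim_config())
    expect_equal(nrow(sched), 88L)                       # 88 trials
    swaps <- sum(diff(sched$p_a) != 0)
    expect_equal(swaps, 4L)                              # four reversals
    # at every trial the arm probabilities are {0.8, 0.2} as a set
    expect_true(all((sched$p_a == 0.8 & sched$p_b == 0.2) |
                      (sched$p_a == 0.2 & sched$p_b == 0.8)))
    # reversals roughly every 20 trials: jitter of +/-2 around 17.6k
    pts <- attr(sched, "reversals")
    expect_true(all(abs(pts - floor(88 / 5) * seq_len(4)) <= 2))
  }
  expect_error(make_reward_schedule(rl_sim_config(n_reversals = 90)),
               "n_reversals")
})

test_that("an indifferent agent chooses each arm half the time", {
  cfg <- rl_sim_config(n_trials = 4000, n_reversals = 4)
  sched <- make_reward_schedule(cfg)
  dat <- simulate_agent(agent_params("single", eta = 0.4, beta = 0), sched,
                        seed = 14)
  expect_lt(abs(mean(dat$choice == "A") - 0.5), 0.03)
})

test_that("a learning agent beats chance on the reversal schedule", {
  # pre-build Monte-Carlo oracle (2000 agents): mean win proportion 0.596
  set.seed(42)
  cfg <- rl_sim_config()
  p <- agent_params("single", eta = 0.3, beta = 5)
  wins <- replicate(300, {
    mean(simulate_agent(p, make_reward_schedule(cfg))$reward)
  })
  expect_gt(mean(wins), 0.55)
})

test_that("identical seeds and configs give byte-identical studies", {
  a <- small_study(n = 3, seed = 7)
  b <- small_study(n = 3, seed = 7)
  expect_identical(a$fixations, b$fixations)
  expect_identical(a$choices, b$choices)
  expect_identical(a$self_report, b$self_report)
  c_ <- small_study(n = 3, seed = 8)
  expect_false(identical(a$fixations, c_$fixations))
})

test_that("participant sub-streams make subsets reproducible", {
  d5 <- study_design(n_participants = 5, seed = 9)
  d_sub <- d5
  d_sub$n_participants <- 3L
  d_sub$visit_order <- d5$visit_order[d5$visit_order$participant <= 3, ]
  d_sub$trial_grid <- d5$trial_grid[d5$trial_grid$participant <= 3, ]
  g5 <- simulate_gaze(d5, gaze_sim_config(seed = 9))
  g3 <- simulate_gaze(d_sub, gaze_sim_config(seed = 9))
  # dropping later participants does not disturb earlier data streams
  f5 <- g5$fixations[g5$fixations$participant <= 3, ]
  rownames(f5) <- NULL
  rownames(g3$fixations) <- NULL
  expect_equal(g3$fixations, f5)
})

test_that("a null generator is symmetric and a strong stimulus effect is not", {
  d <- study_design(n_participants = 6, seed = 10)
  g0 <- simulate_gaze(d, gaze_sim_config(mean_dwell_logit_neutral = 0,
                                         stimulus_effect = 0,
                                         drug_phase_interaction = 0,
                                         incentive_boost = 0,
                                         missingness_rate = 0, seed = 10))
  av <- avoidance(compute_dwell(g0$fixations))
  expect_lt(abs(mean(av$avoidance)), 0.05)

  g1 <- simulate_gaze(d, gaze_sim_config(seed = 10))
  av1 <- avoidance(compute_dwell(g1$fixations))
  keep <- av1$phase != "incentive"
  expect_gt(mean(av1$avoidance[keep]), 0.2)
})

test_that("empirical dwell means converge to the configured predictors", {
  # marginal control: no noise, no missingness -> cell means match the
  # three-category logistic map within fixation-sampling error
  d <- study_design(n_participants = 8, seed = 12)
  cfg <- gaze_sim_config(participant_sd = 0, trial_noise_sd = 0,
                         missingness_rate = 0, incentive_boost = 0,
                         drug_phase_interaction = 0, seed = 12)
  g <- simulate_gaze(d, cfg)
  rec <- compute_dwell(g$fixations)
  wn <- exp(cfg$mean_dwell_logit_neutral)
  wd <- exp(cfg$mean_dwell_logit_neutral + cfg$stimulus_effect)
  expect_equal(mean(rec$p_neutral), wn / (wd + wn + 1), tolerance = 0.02)
  expect_equal(mean(rec$p_disgust), wd / (wd + wn + 1), tolerance = 0.02)
})

test_that("the injected drug x phase effect lands in the right cell", {
  d <- study_design(n_participants = 20, seed = 13)
  g <- simulate_gaze(d, gaze_sim_config(drug_phase_interaction = 1.5,
                                        trial_noise_sd = 0, seed = 13))
  av <- avoidance(compute_dwell(g$fixations))
  cell <- function(v, ph) mean(av$avoidance[av$visit == v & av$phase == ph])
  # avoidance reduced post-incentive under domperidone, matched elsewhere
  expect_lt(cell("domperidone", "post_incentive") + 0.1,
            cell("placebo", "post_incentive"))
  expect_lt(abs(cell("domperidone", "pre_incentive") -
                  cell("placebo", "pre_incentive")), 0.1)
})

test_that("configuration errors name the offending field", {
  expect_error(gaze_sim_config(missingness_rate = 1.2), "missingness_rate")
  expect_error(gaze_sim_config(participant_sd = -1), "participant_sd")
  expect_error(rl_sim_config(p_high = 2), "p_high")
  expect_error(rl_sim_config(n_trials = 0), "n_trials")
  expect_error(study_design(n_participants = 0), "n_participants")
})
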
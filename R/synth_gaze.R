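# Synthetic preferential-looking gaze data. Each trial's expected dwell split
# over {disgust image, neutral image, non-stimulus} comes from a
# multinomial-logit model on two linear predictors (one per image, relative
# to a non-stimulus baseline), with a Gaussian participant random intercept
# and Gaussian trial-level noise added on the logit scale; fixation streams
# are then rendered to match that split, and tracking loss masks a random
# fraction of each trial's fixations.

#' Configuration for the gaze simulator
#'
#' Effects are on the (multinomial) logit scale, relative to the
#' non-stimulus baseline, so they compose additively and the implied
#' proportions always lie in \[0, 1\] and sum to 1.
#'
#' @param mean_dwell_logit_neutral Linear predictor of the neutral image's
#'   dwell weight (default 0.8, putting roughly 55% of dwell on the neutral
#'   image when the disgust decrement is at its default).
#' @param stimulus_effect Disgust-image dwell decrement (default -1.5:
#'   strong avoidance, disgust dwell well below neutral dwell).
#' @param drug_phase_interaction Added to the disgust-image predictor in
#'   the post-incentive phase of the domperidone visit; positive values
#'   reduce avoidance there (default 0.5, an exposure-facilitation effect).
#' @param incentive_boost Added to the disgust-image predictor during the
#'   gaze-contingent incentive phase, in which participants are paid to
#'   fixate the disgusting image (default 2).
#' @param participant_sd SD of the participant random intercept applied to
#'   both image predictors (default 0.5 logits).
#' @param trial_noise_sd SD of independent per-trial noise on each image
#'   predictor (default 0.5 logits).
#' @param missingness_rate Expected fraction of each trial's fixations
#'   masked by tracking loss; the per-trial loss rate is Beta-distributed
#'   around this mean (concentration 5) so occasional trials lose most of
#'   their samples, as real tracker dropouts do (default 0.05, which makes
#'   roughly 1-2% of trials exceed the 50%-missing filter, the dropout
#'   rate the study reports).
#' @param trial_duration_ms Nominal trial duration (default 15000 ms).
#' @param seed Integer seed; participant sub-streams are derived from it so
#'   any participant subset is reproducible.
#' @return A list of class `gaze_sim_config`.
#' @export
gaze_sim_config <- function(mean_dwell_logit_neutral = 0.8,
                            stimulus_effect = -1.5,
                            drug_phase_interaction = 0.5,
                            incentive_boost = 2,
                            participant_sd = 0.5,
                            trial_noise_sd = 0.5,
                            missingness_rate = 0.05,
                            trial_duration_ms = 15000L,
                            seed = 1L) {
  structure(list(
    mean_dwell_logit_neutral = mean_dwell_logit_neutral,
    stimulus_effect = stimulus_effect,
    drug_phase_interaction = drug_phase_interaction,
    incentive_boost = incentive_boost,
    participant_sd = check_nonneg(participant_sd, "participant_sd"),
    trial_noise_sd = check_nonneg(trial_noise_sd, "trial_noise_sd"),
    missingness_rate = check_prob(missingness_rate, "missingness_rate"),
    trial_duration_ms = check_count(trial_duration_ms, "trial_duration_ms"),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "gaze_sim_config")
}

# Expected dwell proportions for one block of trials: multinomial logit over
# {disgust, neutral, non-stimulus} with the non-stimulus weight fixed at 1.
dwell_probs <- function(l_disgust, l_neutral) {
  wd <- exp(l_disgust)
  wn <- exp(l_neutral)
  denom <- wd + wn + 1
  cbind(p_disgust = wd / denom, p_neutral = wn / denom, p_nonstim = 1 / denom)
}

# Per-trial linear predictors for one participant's trial grid.
trial_predictors <- function(grid, cfg, b_p) {
  l_n <- cfg$mean_dwell_logit_neutral + b_p +
    rnorm(nrow(grid), 0, cfg$trial_noise_sd)
  l_d <- cfg$mean_dwell_logit_neutral + cfg$stimulus_effect + b_p +
    rnorm(nrow(grid), 0, cfg$trial_noise_sd) +
    cfg$incentive_boost * (grid$phase == "incentive") +
    cfg$drug_phase_interaction *
      (grid$visit == "domperidone" & grid$phase == "post_incentive")
  list(l_d = l_d, l_n = l_n)
}

# Render one participant's fixation stream. Fixations have log-normal
# durations (median ~280 ms) separated by 50 ms saccade gaps; each fixation
# lands in the disgust AOI, the neutral AOI, or the central gap between them
# with the trial's expected dwell probabilities.
render_fixations <- function(grid, probs, cfg, layout) {
  n_tr <- nrow(grid)
  n_fix <- max(1L, floor(cfg$trial_duration_ms / 350))
  total <- n_tr * n_fix
  dur <- pmax(60, round(rlnorm(total, log(280), 0.35)))
  trial_row <- rep(seq_len(n_tr), each = n_fix)
  # onsets: cumulative within trial with 50 ms gaps
  ends <- stats::ave(dur + 50, trial_row, FUN = cumsum)
  onset <- ends - dur - 50
  keep <- onset + dur <= cfg$trial_duration_ms
  # AOI membership per fixation
  u <- runif(total)
  p_d <- probs[trial_row, "p_disgust"]
  p_n <- probs[trial_row, "p_neutral"]
  aoi <- ifelse(u < p_d, "disgust", ifelse(u < p_d + p_n, "neutral", "nonstim"))

  rects <- aoi_rects(layout)
  side <- grid$disgust_side[trial_row]
  target <- ifelse(aoi == "nonstim", "gap",
                   ifelse((aoi == "disgust") == (side == "left"),
                          "left", "right"))
  x <- numeric(total)
  y <- numeric(total)
  for (tg in c("left", "right")) {
    i <- target == tg
    r <- rects[[tg]]
    x[i] <- runif(sum(i), r["x0"], r["x1"])
    y[i] <- runif(sum(i), r["y0"], r["y1"])
  }
  i <- target == "gap"
  x[i] <- runif(sum(i), rects$left["x1"], rects$right["x0"])
  y[i] <- runif(sum(i), 0, layout$screen_size[2])

  fx <- data.frame(
    participant = grid$participant[trial_row],
    visit = grid$visit[trial_row],
    phase = grid$phase[trial_row],
    trial = grid$trial[trial_row],
    onset_ms = onset, duration_ms = dur, x = x, y = y,
    disgust_side = side
  )[keep, ]

  # tracking loss: per-trial Beta-distributed loss rate, fixations masked
  # independently at that rate
  if (cfg$missingness_rate > 0) {
    kappa <- 5
    m_t <- rbeta(n_tr, cfg$missingness_rate * kappa,
                 (1 - cfg$missingness_rate) * kappa)
    row_of <- trial_row[keep]
    fx <- fx[runif(nrow(fx)) >= m_t[row_of], ]
  }
  rownames(fx) <- NULL
  fx
}

#' Simulate fixation streams for a whole study
#'
#' @param design A [study_design()].
#' @param cfg A [gaze_sim_config()].
#' @param layout An [aoi_layout()]; its `disgust_side` is overridden
#'   per-trial by the design's balanced side assignment.
#' @return List with `fixations` (participant, visit, phase, trial,
#'   onset_ms, duration_ms, x, y, disgust_side) and `expected` (the
#'   per-trial generative dwell probabilities, for calibration checks).
#' @export
simulate_gaze <- function(design, cfg = gaze_sim_config(),
                          layout = aoi_layout()) {
  stopifnot(inherits(design, "study_design"), inherits(cfg, "gaze_sim_config"))
  part_seeds <- derive_seeds(cfg$seed, design$n_participants)
  fix_list <- vector("list", design$n_participants)
  exp_list <- vector("list", design$n_participants)
  for (p in seq_len(design$n_participants)) {
    set.seed(part_seeds[p])
    grid <- design$trial_grid[design$trial_grid$participant == p, ]
    b_p <- rnorm(1L, 0, cfg$participant_sd)
    lp <- trial_predictors(grid, cfg, b_p)
    probs <- dwell_probs(lp$l_d, lp$l_n)
    fix_list[[p]] <- render_fixations(grid, probs, cfg, layout)
    exp_list[[p]] <- cbind(grid[, c("participant", "visit", "phase", "trial",
                                    "disgust_side")], probs)
  }
  list(fixations = do.call(rbind, fix_list),
       expected = do.call(rbind, exp_list))
}

#' Simulate self-reported disgust ratings
#'
#' Ratings on a 0-100 visual-analogue scale per stimulus category, with a
#' participant random intercept; disgusting images are rated far above
#' neutral ones. Collected once per phase (no trial factor).
#'
#' @param design A [study_design()].
#' @param mean_disgust,mean_neutral Category means (defaults 65 and 10).
#' @param participant_sd,noise_sd Participant-intercept and residual SDs
#'   (defaults 8 and 10).
#' @param seed Integer seed.
#' @return Data frame (participant, visit, phase, category, rating).
#' @export
simulate_self_report <- function(design, mean_disgust = 65, mean_neutral = 10,
                                 participant_sd = 8, noise_sd = 10,
                                 seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  check_nonneg(participant_sd, "participant_sd")
  check_nonneg(noise_sd, "noise_sd")
  part_seeds <- derive_seeds(check_count(seed, "seed", min = 0L),
                             design$n_participants)
  out <- vector("list", design$n_participants)
  cells <- expand.grid(visit = c("placebo", "domperidone"),
                       phase = design$phases,
                       category = c("disgust", "neutral"),
                       stringsAsFactors = FALSE)
  for (p in seq_len(design$n_participants)) {
    set.seed(part_seeds[p])
    b_p <- rnorm(1L, 0, participant_sd)
    mu <- ifelse(cells$category == "disgust", mean_disgust, mean_neutral)
    rating <- pmin(pmax(mu + b_p + rnorm(nrow(cells), 0, noise_sd), 0), 100)
    out[[p]] <- cbind(participant = p, cells, rating = rating)
  }
  do.call(rbind, out)
}

#' Simulate a complete synthetic study
#'
#' Generates every phase of both visits for every participant: fixation
#' streams for the preferential-looking task, choice/outcome tables for the
#' reversal-bandit control task, and self-report ratings, together with the
#' design metadata and the generative ground truth. Identical seeds and
#' configurations give identical output.
#'
#' @param design A [study_design()].
#' @param gaze_cfg A [gaze_sim_config()].
#' @param rl_cfg An [rl_sim_config()].
#' @param layout An [aoi_layout()].
#' @return List of class `synthetic_study` with elements `design`,
#'   `fixations`, `expected_dwell`, `choices`, `true_params`,
#'   `self_report`.
#' @export
simulate_study <- function(design = study_design(),
                           gaze_cfg = gaze_sim_config(),
                           rl_cfg = rl_sim_config(),
                           layout = aoi_layout()) {
  gaze <- simulate_gaze(design, gaze_cfg, layout)
  rl <- simulate_rl_study(design, rl_cfg)
  sr <- simulate_self_report(design, seed = gaze_cfg$seed)
  structure(list(
    design = design,
    fixations = gaze$fixations,
    expected_dwell = gaze$expected,
    choices = rl$choices,
    true_params = rl$true_params,
    self_report = sr
  ), class = "synthetic_study")
}
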
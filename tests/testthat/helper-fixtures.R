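# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from disk.

# A fixation row in package schema; coordinates default to the centre of the
# left image (disgust when disgust_side = "left").
fix_row <- function(x, y, duration_ms = 100, participant = 1L,
                    visit = "placebo", phase = "baseline", trial = 1L,
                    onset_ms = 0, disgust_side = "left") {
  data.frame(participant = participant, visit = visit, phase = phase,
             trial = trial, onset_ms = onset_ms, duration_ms = duration_ms,
             x = x, y = y, disgust_side = disgust_side)
}

# Centres of the two image rectangles for the default layout.
default_centers <- function(layout = aoi_layout()) {
  r <- lookaway:::aoi_rects(layout)
  list(left = c(x = mean(r$left[c("x0", "x1")]),
                y = mean(r$left[c("y0", "y1")])),
       right = c(x = mean(r$right[c("x0", "x1")]),
                 y = mean(r$right[c("y0", "y1")])),
       rects = r)
}

# A short deterministic reward environment for likelihood oracles: reward is
# a fixed function of (trial, chosen arm), so choice sequences enumerate the
# full outcome space.
reward_lookup <- function() {
  # rows = trials 1..5; cols = arm A, arm B
  matrix(c(1, 0,
           1, 1,
           0, 0,
           0, 1,
           1, 0), ncol = 2, byrow = TRUE)
}

choices_from_pattern <- function(pattern, lookup = reward_lookup()) {
  arm <- ifelse(pattern == 0L, "A", "B")
  data.frame(trial = seq_along(pattern), choice = arm,
             reward = lookup[cbind(seq_along(pattern), pattern + 1L)])
}

# Independent sequential probability of a choice pattern, written in plain
# arithmetic (no package internals): the oracle for the likelihood tests.
oracle_pattern_prob <- function(pattern, eta_win, eta_lose, beta,
                                lookup = reward_lookup()) {
  v <- c(0, 0)
  prob <- 1
  for (i in seq_along(pattern)) {
    p_a <- exp(beta * v[1]) / (exp(beta * v[1]) + exp(beta * v[2]))
    p_choice <- if (pattern[i] == 0L) p_a else 1 - p_a
    prob <- prob * p_choice
    r <- lookup[i, pattern[i] + 1L]
    eta <- if (r > 0) eta_win else eta_lose
    v[pattern[i] + 1L] <- v[pattern[i] + 1L] + eta * (r - v[pattern[i] + 1L])
  }
  prob
}

# Session-level measure table with no drug effect, for evidence-machinery
# tests that do not need the RL fitting step.
null_measure_table <- function(n_participants = 20, sd = 1, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(participant = seq_len(n_participants),
                       visit = c("placebo", "domperidone"),
                       phase = c("pre", "post"), stringsAsFactors = FALSE)
  b <- rnorm(n_participants)
  cells$p_win <- 0.55 + 0.1 * b[cells$participant] + rnorm(nrow(cells), 0, sd * 0.05)
  cells
}

# A small complete synthetic study used by several tests.
small_study <- function(n = 6, seed = 11, ...) {
  d <- study_design(n_participants = n, seed = seed)
  simulate_study(d, gaze_sim_config(seed = seed, ...),
                 rl_sim_config(seed = seed + 1))
}
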
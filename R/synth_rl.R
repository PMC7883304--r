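# Synthetic reversal-bandit world: the 88-trial two-armed task in which the
# reward probabilities of the two stimuli swap between 0.8 and 0.2 four times
# (roughly every 20 trials), and delta-rule/softmax agents that play it.

#' Configuration for the reversal-bandit simulation
#'
#' @param n_trials Trials per session (default 88).
#' @param p_high,p_low Reward probabilities of the better and worse arm
#'   (defaults 0.8 / 0.2).
#' @param n_reversals Number of probability swaps per session (default 4),
#'   must be `< n_trials`.
#' @param jitter Reversal positions are evenly spaced at multiples of
#'   `floor(n_trials / (n_reversals + 1))` with a uniform integer jitter of
#'   up to this many trials either way (default 2).
#' @param eta_range,beta_range Ranges from which per-participant generative
#'   learning rates and inverse temperatures are drawn uniformly.
#' @param drug_effect_eta Additive shift applied to the generative learning
#'   rate in post-administration sessions of the domperidone visit (default
#'   0: the drug leaves reward learning untouched).
#' @param seed Integer seed for the session schedules and agents.
#' @return A list of class `rl_sim_config`.
#' @export
rl_sim_config <- function(n_trials = 88L, p_high = 0.8, p_low = 0.2,
                          n_reversals = 4L, jitter = 2L,
                          eta_range = c(0.2, 0.6), beta_range = c(2, 8),
                          drug_effect_eta = 0, seed = 1L) {
  cfg <- list(
    n_trials = check_count(n_trials, "n_trials"),
    p_high = check_prob(p_high, "p_high"),
    p_low = check_prob(p_low, "p_low"),
    n_reversals = check_count(n_reversals, "n_reversals", min = 0L),
    jitter = check_count(jitter, "jitter", min = 0L),
    eta_range = sort(eta_range), beta_range = sort(beta_range),
    drug_effect_eta = drug_effect_eta,
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$n_reversals >= cfg$n_trials)
    stop_config("n_reversals", "must be smaller than n_trials")
  if (any(cfg$eta_range < 0) || any(cfg$eta_range > 1))
    stop_config("eta_range", "must lie in [0, 1]")
  if (any(cfg$beta_range < 0)) stop_config("beta_range", "must be non-negative")
  structure(cfg, class = "rl_sim_config")
}

#' Build a reversal-bandit reward schedule
#'
#' One arm starts at `p_high` and the other at `p_low`; the probabilities
#' swap at `n_reversals` points spaced evenly at multiples of
#' `floor(n_trials / (n_reversals + 1))` with a small uniform jitter, so at
#' every trial the arm probabilities are `{p_high, p_low}` as a set. Which
#' arm starts high is drawn at random.
#'
#' @param cfg An [rl_sim_config()].
#' @return A data frame (`trial`, `p_a`, `p_b`) with the reversal trial
#'   indices in `attr(, "reversals")`.
#' @export
make_reward_schedule <- function(cfg = rl_sim_config()) {
  stopifnot(inherits(cfg, "rl_sim_config"))
  n <- cfg$n_trials
  r <- cfg$n_reversals
  if (r > 0L) {
    base <- floor(n / (r + 1L)) * seq_len(r)
    jit <- if (cfg$jitter > 0L) {
      sample(seq(-cfg$jitter, cfg$jitter), r, replace = TRUE)
    } else {
      rep(0L, r)
    }
    pts <- pmin(pmax(base + jit, 2L), n)
    pts <- sort(unique(pts))
    # jitter collisions are resolved by nudging forward
    while (length(pts) < r) {
      cand <- setdiff(seq(2L, n), pts)
      pts <- sort(c(pts, cand[which.min(abs(cand - base[length(pts) + 1L]))]))
    }
  } else {
    pts <- integer(0)
  }
  a_high <- sample(c(TRUE, FALSE), 1L)
  # block index flips at each reversal point
  block <- findInterval(seq_len(n), pts)
  high_a <- xor(a_high, block %% 2L == 1L)
  sched <- data.frame(
    trial = seq_len(n),
    p_a = ifelse(high_a, cfg$p_high, cfg$p_low),
    p_b = ifelse(high_a, cfg$p_low, cfg$p_high)
  )
  attr(sched, "reversals") <- pts
  sched
}

#' Simulate one agent playing a reward schedule
#'
#' On each trial the agent chooses arm A with the softmax probability of
#' its current values (both start at 0, so trial 1 is a fair coin), the
#' reward is drawn from the chosen arm's scheduled probability, and the
#' chosen arm's value is updated by the delta rule.
#'
#' @param params An [agent_params()] object (generative parameters).
#' @param schedule A schedule from [make_reward_schedule()].
#' @param seed Optional integer seed.
#' @return Data frame (`trial`, `choice`, `reward`) with one row per trial.
#' @export
simulate_agent <- function(params, schedule, seed = NULL) {
  stopifnot(inherits(params, "agent_params"))
  check_columns(schedule, c("trial", "p_a", "p_b"), "schedule")
  if (nrow(schedule) < 1L) stop("schedule must have length >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(schedule)
  v <- c(A = 0, B = 0)
  choice <- character(n)
  reward <- integer(n)
  u_choice <- runif(n)
  u_reward <- runif(n)
  ew <- if (params$variant == "single") params$eta else params$eta_win
  el <- if (params$variant == "single") params$eta else params$eta_lose
  for (i in seq_len(n)) {
    p_a <- softmax_prob(v["A"], v["B"], params$beta)
    ch <- if (u_choice[i] < p_a) "A" else "B"
    p_win <- if (ch == "A") schedule$p_a[i] else schedule$p_b[i]
    r <- as.integer(u_reward[i] < p_win)
    v[ch] <- rw_update_dual(v[[ch]], r, ew, el)
    choice[i] <- ch
    reward[i] <- r
  }
  data.frame(trial = schedule$trial, choice = choice, reward = reward)
}

#' Simulate the control-task choice data for a whole crossover study
#'
#' Each participant plays the bandit before and after drug/placebo
#' administration on both visits (four sessions). Generative learning
#' rates and inverse temperatures are drawn once per participant from
#' `cfg$eta_range` / `cfg$beta_range`; `cfg$drug_effect_eta` shifts the
#' learning rate in the post-administration session of the domperidone
#' visit (0 by default, a true null). Each session gets its own freshly
#' jittered reversal schedule.
#'
#' @param design A [study_design()].
#' @param cfg An [rl_sim_config()].
#' @return List with `choices` (participant, visit, phase `pre`/`post`,
#'   trial, choice, reward) and `true_params` (one row per session).
#' @export
simulate_rl_study <- function(design, cfg = rl_sim_config()) {
  stopifnot(inherits(design, "study_design"), inherits(cfg, "rl_sim_config"))
  n_p <- design$n_participants
  part_seeds <- derive_seeds(cfg$seed, n_p)
  sessions <- expand.grid(phase = c("pre", "post"),
                          visit = c("placebo", "domperidone"),
                          stringsAsFactors = FALSE)
  choices <- vector("list", n_p)
  truth <- vector("list", n_p)
  for (p in seq_len(n_p)) {
    set.seed(part_seeds[p])
    eta_p <- runif(1L, cfg$eta_range[1L], cfg$eta_range[2L])
    beta_p <- runif(1L, cfg$beta_range[1L], cfg$beta_range[2L])
    ch_list <- vector("list", nrow(sessions))
    tr_list <- vector("list", nrow(sessions))
    for (s in seq_len(nrow(sessions))) {
      eta_s <- eta_p
      if (sessions$visit[s] == "domperidone" && sessions$phase[s] == "post")
        eta_s <- min(max(eta_p + cfg$drug_effect_eta, 0), 1)
      sched <- make_reward_schedule(cfg)
      dat <- simulate_agent(agent_params("single", eta = eta_s, beta = beta_p),
                            sched)
      dat$participant <- p
      dat$visit <- sessions$visit[s]
      dat$phase <- sessions$phase[s]
      ch_list[[s]] <- dat[, c("participant", "visit", "phase", "trial",
                              "choice", "reward")]
      tr_list[[s]] <- data.frame(participant = p, visit = sessions$visit[s],
                                 phase = sessions$phase[s],
                                 eta = eta_s, beta = beta_p)
    }
    choices[[p]] <- do.call(rbind, ch_list)
    truth[[p]] <- do.call(rbind, tr_list)
  }
  list(choices = do.call(rbind, choices), true_params = do.call(rbind, truth))
}
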
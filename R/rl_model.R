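# Rescorla-Wagner / softmax model: updates, likelihood, maximum-likelihood
# fitting. Associative values for both arms start at 0, so the first-trial
# softmax probability is exactly 0.5 per arm. Only the chosen arm's value is
# updated on each trial.

#' Agent parameters for the Rescorla-Wagner/softmax model
#'
#' Bundles and validates the free parameters of the delta-rule learner:
#' either a single learning rate `eta`, or separate rates for win and
#' non-win outcomes (`eta_win`, `eta_lose`), plus the softmax inverse
#' choice temperature `beta`.
#'
#' @param variant `"single"` (one learning rate) or `"dual"` (separate
#'   win / non-win rates).
#' @param eta Learning rate in \[0, 1\] (single variant only).
#' @param eta_win,eta_lose Learning rates in \[0, 1\] for win and non-win
#'   outcomes (dual variant only).
#' @param beta Inverse choice temperature, `beta >= 0`. Larger values make
#'   choices more deterministic; `beta = 0` is indifference.
#' @return An object of class `agent_params`.
#' @examples
#' agent_params("single", eta = 0.3, beta = 5)
#' agent_params("dual", eta_win = 0.4, eta_lose = 0.1, beta = 3)
#' @export
agent_params <- function(variant = c("single", "dual"), eta = NULL,
                         eta_win = NULL, eta_lose = NULL, beta = NULL) {
  variant <- match.arg(variant)
  check_rate <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("learning rate '%s' must be in [0, 1]", field), call. = FALSE)
    as.numeric(x)
  }
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0)
    stop("'beta' must be a single number >= 0", call. = FALSE)
  p <- if (variant == "single") {
    if (!is.null(eta_win) || !is.null(eta_lose))
      stop("single variant takes 'eta' only", call. = FALSE)
    list(variant = variant, eta = check_rate(eta, "eta"), beta = as.numeric(beta))
  } else {
    if (!is.null(eta))
      stop("dual variant takes 'eta_win' and 'eta_lose', not 'eta'", call. = FALSE)
    list(variant = variant,
         eta_win = check_rate(eta_win, "eta_win"),
         eta_lose = check_rate(eta_lose, "eta_lose"),
         beta = as.numeric(beta))
  }
  structure(p, class = "agent_params")
}

#' Delta-rule value update (single learning rate)
#'
#' `v + eta * (R - v)`: moves the associative value of the *chosen*
#' stimulus toward the obtained reward by a fraction `eta` of the
#' prediction error. With binary rewards and a start at 0, values stay in
#' \[0, 1\].
#'
#' @param v Current associative value.
#' @param R Obtained reward (1 win, 0 non-win).
#' @param eta Learning rate in \[0, 1\].
#' @return Updated value.
#' @export
rw_update <- function(v, R, eta) {
  if (any(eta < 0 | eta > 1)) stop("'eta' must be in [0, 1]", call. = FALSE)
  v + eta * (R - v)
}

#' Delta-rule value update with separate win / non-win learning rates
#'
#' Applies `eta_win` when `R > 0` and `eta_lose` otherwise; with
#' `eta_win == eta_lose` the trajectory reduces exactly to [rw_update()].
#'
#' @inheritParams rw_update
#' @param eta_win,eta_lose Learning rates in \[0, 1\].
#' @return Updated value.
#' @export
rw_update_dual <- function(v, R, eta_win, eta_lose) {
  if (any(c(eta_win, eta_lose) < 0) || any(c(eta_win, eta_lose) > 1))
    stop("learning rates must be in [0, 1]", call. = FALSE)
  rw_update(v, R, ifelse(R > 0, eta_win, eta_lose))
}

#' Softmax choice probability
#'
#' Probability of choosing stimulus A given both associative values:
#' `exp(beta * v_A) / (exp(beta * v_A) + exp(beta * v_B))`, computed
#' overflow-safely by subtracting the maximum before exponentiating.
#' With `v_A = v_B` (e.g. the start values of 0) the probability is
#' exactly 0.5; `beta = 0` gives 0.5 for any values.
#'
#' @param v_a,v_b Associative values of the two stimuli.
#' @param beta Inverse choice temperature, `>= 0`.
#' @return Probability of choosing A.
#' @export
softmax_prob <- function(v_a, v_b, beta) {
  if (any(beta < 0)) stop("'beta' must be >= 0", call. = FALSE)
  a <- beta * v_a
  b <- beta * v_b
  m <- pmax(a, b)
  exp(a - m) / (exp(a - m) + exp(b - m))
}

# Convert a choice column ("A"/"B" or 0/1) to the 0/1 integer coding the
# C++ likelihood expects.
choice_codes <- function(choice) {
  if (is.numeric(choice)) {
    if (!all(choice %in% c(0, 1))) stop("numeric choices must be 0 (A) or 1 (B)",
                                        call. = FALSE)
    return(as.integer(choice))
  }
  ch <- as.character(choice)
  if (!all(ch %in% c("A", "B"))) stop("choices must be 'A' or 'B'", call. = FALSE)
  as.integer(ch == "B")
}

#' Negative log-likelihood of a choice sequence
#'
#' Sequential negative log-likelihood (nats) of observed choices under the
#' delta-rule/softmax recursion with both start values 0: on each trial
#' the current values give the softmax probability of the observed choice,
#' then the chosen arm's value is updated with the observed reward.
#'
#' @param params An [agent_params()] object.
#' @param data Data frame with columns `choice` (`"A"`/`"B"` or 0/1) and
#'   `reward` (0/1).
#' @return The negative log-likelihood, always `>= 0`.
#' @export
negative_log_likelihood <- function(params, data) {
  stopifnot(inherits(params, "agent_params"))
  check_columns(data, c("choice", "reward"), "choice data")
  if (nrow(data) == 0L) stop("choice data must be non-empty", call. = FALSE)
  if (!all(data$reward %in% c(0, 1))) stop("rewards must be 0 or 1", call. = FALSE)
  ch <- choice_codes(data$choice)
  if (params$variant == "single") {
    rw_nll_cpp(ch, as.numeric(data$reward), params$eta, params$eta, params$beta)
  } else {
    rw_nll_cpp(ch, as.numeric(data$reward), params$eta_win, params$eta_lose,
               params$beta)
  }
}

#' Proportion of won trials
#'
#' @param data Choice data frame with a `reward` column (0/1).
#' @return Mean of the rewards.
#' @export
win_proportion <- function(data) {
  check_columns(data, "reward", "choice data")
  if (nrow(data) == 0L) stop("choice data must be non-empty", call. = FALSE)
  mean(data$reward)
}

# beta is optimised on the log scale with an identifiability guard at 20:
# on an 88-trial session larger values are indistinguishable.
.beta_max <- 20

#' Fit the Rescorla-Wagner/softmax model by multi-start maximum likelihood
#'
#' Minimises [negative_log_likelihood()] over bounded parameters using
#' L-BFGS-B on transformed coordinates (logit for learning rates, log for
#' `beta`), restarted from `n_starts` random initial points: learning-rate
#' starts uniform on \[0, 1\], `beta` starts log-uniform on \[0.1, 20\].
#' `beta` is capped at 20 as an identifiability guard; fits at that bound
#' are flagged.
#'
#' @param data Choice data frame (columns `choice`, `reward`), `>= 10` trials.
#' @param variant `"single"` (k = 2 free parameters) or `"dual"` (k = 3).
#' @param n_starts Number of random restarts (default 20).
#' @return An object of class `rw_fit`: a list with `params`
#'   ([agent_params()]), `nll`, `k`, `n`, `aic = 2k + 2 nll`,
#'   `bic = k log(n) + 2 nll`, `n_starts_converged`, and `at_bound`.
#' @export
fit_rw_model <- function(data, variant = c("single", "dual"), n_starts = 20L) {
  variant <- match.arg(variant)
  check_columns(data, c("choice", "reward"), "choice data")
  n <- nrow(data)
  if (n < 10L) stop("need at least 10 trials to fit", call. = FALSE)
  ch <- choice_codes(data$choice)
  rew <- as.numeric(data$reward)
  k <- if (variant == "single") 2L else 3L
  n_eta <- k - 1L

  obj <- function(theta) {
    etas <- plogis(theta[seq_len(n_eta)])
    beta <- exp(theta[k])
    if (variant == "single") {
      rw_nll_cpp(ch, rew, etas[1L], etas[1L], beta)
    } else {
      rw_nll_cpp(ch, rew, etas[1L], etas[2L], beta)
    }
  }

  lower <- c(rep(qlogis(1e-6), n_eta), log(1e-4))
  upper <- c(rep(qlogis(1 - 1e-6), n_eta), log(.beta_max))

  # the dual model nests the single model: seed one start at the single-rate
  # optimum so the dual fit can never end up worse than it
  starts <- lapply(seq_len(n_starts), function(s)
    c(qlogis(pmin(pmax(runif(n_eta), 1e-5), 1 - 1e-5)),
      runif(1L, log(0.1), log(.beta_max))))
  if (variant == "dual") {
    fs <- fit_rw_model(data, "single", n_starts = max(5L, n_starts %/% 2L))
    eta_t <- qlogis(pmin(pmax(fs$params$eta, 1e-6), 1 - 1e-6))
    beta_t <- log(pmin(pmax(fs$params$beta, 1e-4), .beta_max))
    starts <- c(starts, list(c(eta_t, eta_t, beta_t)))
  }

  best <- NULL
  n_conv <- 0L
  fails <- character(0)
  for (start in starts) {
    res <- tryCatch(
      optim(start, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e7, maxit = 500L)),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails <- c(fails, conditionMessage(res))
      next
    }
    if (res$convergence == 0L) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all optimisation starts failed: ",
         paste(unique(fails), collapse = "; "), call. = FALSE)

  etas <- plogis(best$par[seq_len(n_eta)])
  beta <- exp(best$par[k])
  params <- if (variant == "single") {
    agent_params("single", eta = etas[1L], beta = beta)
  } else {
    agent_params("dual", eta_win = etas[1L], eta_lose = etas[2L], beta = beta)
  }
  nll <- best$value
  structure(list(
    params = params, nll = nll, k = k, n = n,
    aic = 2 * k + 2 * nll, bic = k * log(n) + 2 * nll,
    n_starts_converged = n_conv,
    at_bound = beta > 0.999 * .beta_max
  ), class = "rw_fit")
}

#' @export
print.rw_fit <- function(x, ...) {
  p <- x$params
  par_str <- if (p$variant == "single") {
    sprintf("eta = %.3f, beta = %.3f", p$eta, p$beta)
  } else {
    sprintf("eta_win = %.3f, eta_lose = %.3f, beta = %.3f",
            p$eta_win, p$eta_lose, p$beta)
  }
  cat(sprintf("RW/softmax fit (%s): %s\n", p$variant, par_str))
  cat(sprintf("  n = %d, nll = %.3f, AIC = %.2f, BIC = %.2f (%d starts converged%s)\n",
              x$n, x$nll, x$aic, x$bic, x$n_starts_converged,
              if (x$at_bound) "; beta at bound" else ""))
  invisible(x)
}
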
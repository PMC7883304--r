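# Linear mixed-model inference with participant random intercepts, the post
# hoc drug-difference models, per-trial paired tests with Holm-Bonferroni
# correction.
#
# Coding conventions (documented once, used everywhere): two-level factors
# are sum-to-zero coded with the canonical first level at +1 (stimulus:
# disgust first, drug: domperidone first, phase: the chronologically later
# phase first); the trial index is z-scored; the outcome is z-scored when
# `standardize = TRUE`, so coefficients are standardized betas. Inference is
# by Wald Z (the study reports Z statistics, not t with degrees of freedom).
# Models are fitted by maximum likelihood (REML off) so AIC/BIC comparisons
# against nested null models are valid.

phase_chronology <- c("baseline", "post_admin", "pre_incentive", "incentive",
                      "post_incentive", "pre", "post")

canonical_levels <- function(col, values) {
  present <- unique(as.character(values))
  ord <- switch(col,
    stimulus = c("disgust", "neutral"),
    category = c("disgust", "neutral"),
    drug = ,
    visit = c("domperidone", "placebo"),
    phase = rev(phase_chronology),
    sort(present))
  c(intersect(ord, present), setdiff(present, ord))
}

# Returns the factor with sum-to-zero contrasts and canonical level order.
sum_coded <- function(col, values) {
  f <- factor(as.character(values), levels = canonical_levels(col, values))
  if (nlevels(f) < 2L)
    stop(sprintf("factor '%s' needs >= 2 levels in the data", col),
         call. = FALSE)
  stats::contrasts(f) <- contr.sum(nlevels(f))
  f
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Specify a mixed model
#'
#' @param outcome Name of the outcome column (e.g. `"dwell"`,
#'   `"avoidance"`, `"rating"`, or a fitted RL parameter).
#' @param fixed Character vector of fixed-effect variables; all
#'   interactions among them are included. `"trial"` enters as a z-scored
#'   numeric covariate, everything else as a sum-coded factor. For
#'   self-report models, leave `"trial"` out (ratings have no trial
#'   factor).
#' @param random Grouping variable for the random intercept (default
#'   `"participant"`).
#' @param standardize Z-score the outcome so coefficients are standardized
#'   betas (default `TRUE`).
#' @param logit_outcome Optionally model the outcome on the empirical-logit
#'   scale instead of the raw proportion scale (default `FALSE`; the
#'   primary analyses model raw proportions).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome, fixed, random = "participant",
                       standardize = TRUE, logit_outcome = FALSE) {
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(fixed), length(fixed) >= 0L,
            is.character(random), length(random) == 1L)
  structure(list(outcome = outcome, fixed = fixed, random = random,
                 standardize = isTRUE(standardize),
                 logit_outcome = isTRUE(logit_outcome)),
            class = "model_spec")
}

#' Fit a linear mixed model with a participant random intercept
#'
#' Fits `outcome ~ f1 * f2 * ... + (1 | participant)` by maximum
#' likelihood (lme4), with the coding conventions above, and summarises
#' every fixed-effect term as a standardized coefficient with Wald 95%
#' confidence interval, Z statistic and two-sided p-value.
#'
#' @param data Data frame containing all variables named in the spec.
#' @param spec A [model_spec()].
#' @return List with `effects` (data frame: term, beta, ci_low, ci_high,
#'   z, p), `aic`, `bic`, `n_obs`, `singular`, and the underlying `fit`.
#' @export
fit_mixed_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  check_columns(data, c(spec$outcome, spec$fixed, spec$random), "model data")
  df <- data[stats::complete.cases(data[, c(spec$outcome, spec$fixed,
                                            spec$random), drop = FALSE]), ,
             drop = FALSE]
  if (length(unique(df[[spec$random]])) < 2L)
    stop("need >= 2 grouping units for a random intercept", call. = FALSE)

  y <- df[[spec$outcome]]
  if (spec$logit_outcome) {
    eps <- 0.5 / max(table(df[[spec$random]]))
    y <- qlogis(pmin(pmax(y, eps), 1 - eps))
  }
  df$.y <- if (spec$standardize) zscore(y) else y
  for (v in spec$fixed) {
    df[[v]] <- if (v == "trial") zscore(as.numeric(df[[v]]))
               else sum_coded(v, df[[v]])
  }

  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " * ") else "1"
  form <- as.formula(sprintf(".y ~ %s + (1 | %s)", rhs, spec$random))
  fit <- lme4::lmer(form, data = df, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0L)
    stop(sprintf("mixed model failed to converge (optimizer code %d): %s",
                 conv, paste(unlist(fit@optinfo$conv$lme4), collapse = "; ")),
         call. = FALSE)
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("random-intercept variance is singular (estimated at zero); fit retained",
            call. = FALSE)

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  crit <- qnorm(0.975)
  effects <- data.frame(
    term = clean_term_names(names(est), df, spec$fixed),
    beta = as.numeric(est),
    ci_low = as.numeric(est - crit * se),
    ci_high = as.numeric(est + crit * se),
    z = as.numeric(z), p = as.numeric(p),
    row.names = NULL
  )
  list(effects = effects, aic = AIC(fit), bic = BIC(fit),
       n_obs = nrow(df), singular = singular, fit = fit)
}

# lme4 names sum-coded terms "stimulus1"; for two-level factors that suffix
# is redundant, so "stimulus1:drug1" becomes "stimulus:drug".
clean_term_names <- function(terms, df, fixed) {
  for (v in fixed) {
    if (is.factor(df[[v]]) && nlevels(df[[v]]) == 2L)
      terms <- gsub(paste0("\\b", v, "1\\b"), v, terms)
  }
  terms
}

# Pull one term's row from an effects table.
effect_row <- function(effects, term) {
  i <- match(term, effects$term)
  if (is.na(i)) stop(sprintf("term '%s' not in the fitted model", term),
                     call. = FALSE)
  effects[i, , drop = FALSE]
}

#' Reshape dwell records to one row per stimulus
#'
#' The trial-level mixed models treat stimulus as a factor, so each dwell
#' record contributes two rows: the disgust-image proportion and the
#' neutral-image proportion.
#'
#' @param records Dwell records from [compute_dwell()].
#' @return Long data frame with `stimulus` and `dwell` columns.
#' @export
dwell_long <- function(records) {
  check_columns(records, c("participant", "visit", "phase", "trial",
                           "p_disgust", "p_neutral"), "dwell records")
  id <- records[, c("participant", "visit", "phase", "trial")]
  out <- rbind(
    cbind(id, stimulus = "disgust", dwell = records$p_disgust),
    cbind(id, stimulus = "neutral", dwell = records$p_neutral)
  )
  names(out)[names(out) == "visit"] <- "visit"
  out$drug <- out$visit
  out
}

#' Trial-level avoidance mixed model
#'
#' The calibrated parametrization of the drug x phase x stimulus question:
#' because the disgust and neutral dwell rows of one trial are
#' compositionally dependent (they share the trial's fixation budget, so
#' their residuals correlate negatively), Wald tests on the two-row dwell
#' model are anticonservative for stimulus-involving terms. The exact
#' within-trial stimulus contrast is the avoidance score (neutral minus
#' disgust), one observation per trial; fitting it on drug, phase and
#' trial with a participant random intercept gives a `drug:phase` term
#' that carries the three-way interaction with nominal type-I error. A
#' *negative* `drug:phase` coefficient means avoidance falls more under
#' domperidone in the later phase.
#'
#' @param records Filtered dwell records with an `avoidance` column (see
#'   [avoidance()]).
#' @param phases Which two phases to contrast (default the pre- vs
#'   post-incentive exposure pair).
#' @param fixed Fixed effects (default drug, phase and the trial index).
#' @return A [fit_mixed_model()] result.
#' @export
fit_avoidance_model <- function(records,
                                phases = c("pre_incentive", "post_incentive"),
                                fixed = c("drug", "phase", "trial")) {
  check_columns(records, c("participant", "visit", "phase", "trial",
                           "avoidance"), "avoidance records")
  dat <- records[records$phase %in% phases & !is.na(records$avoidance), ]
  if (!nrow(dat)) stop("no usable trials in the requested phases",
                       call. = FALSE)
  dat$drug <- dat$visit
  fit_mixed_model(dat, model_spec("avoidance", fixed))
}

#' Post hoc drug-difference model
#'
#' Fits the difference outcome (avoidance, or an RL parameter's post-minus-
#' pre-administration difference) on the drug factor with a participant
#' random intercept, and compares the model against its intercept-only null
#' with the evidence machinery, reproducing the "evidence against drug"
#' columns of the control-task summary.
#'
#' @param data Data frame with `participant`, `drug`, and the outcome.
#' @param value Name of the outcome column (default `"value"`).
#' @param standardize Standardize the outcome (default `TRUE`).
#' @return List with `effect` (the drug row), `model` (full fit summary),
#'   `null` (null fit summary) and `comparison` (a [compare_models()]
#'   result; `er_0`/`bf_01` > 1 favour no drug effect).
#' @export
posthoc_drug_difference <- function(data, value = "value", standardize = TRUE) {
  check_columns(data, c("participant", "drug", value), "difference data")
  if (length(unique(data$drug)) != 2L)
    stop("both drug conditions must be present", call. = FALSE)
  alt <- fit_mixed_model(data, model_spec(value, "drug",
                                          standardize = standardize))
  null <- fit_mixed_model(data, model_spec(value, character(0),
                                           standardize = standardize))
  list(effect = effect_row(alt$effects, "drug"),
       model = alt, null = null,
       comparison = compare_models(null$aic, alt$aic, null$bic, alt$bic))
}

#' Per-trial paired tests of disgust vs neutral dwell
#'
#' For each trial and medication condition, a paired two-sided t-test of
#' the disgust vs neutral dwell proportion across participants. Trials
#' with fewer than 3 contributing pairs, or zero variance of the paired
#' differences, are flagged untestable (`p = NA`) rather than given an
#' arbitrary p-value.
#'
#' @param records Dwell records (filtered), one row per participant x
#'   visit x phase x trial.
#' @return Data frame: visit, phase, trial, n_pairs, statistic, p,
#'   testable.
#' @export
per_trial_tests <- function(records) {
  check_columns(records, c("participant", "visit", "phase", "trial",
                           "p_disgust", "p_neutral"), "dwell records")
  cells <- unique(records[, c("visit", "phase", "trial")])
  cells <- cells[order(cells$visit, cells$phase, cells$trial), ]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- records$visit == cells$visit[i] & records$phase == cells$phase[i] &
      records$trial == cells$trial[i]
    d <- records[sel & !is.na(records$p_disgust), ]
    diffs <- d$p_disgust - d$p_neutral
    n <- length(diffs)
    testable <- n >= 3L && sd(diffs) > 0
    if (testable) {
      tt <- t.test(diffs)
      stat <- unname(tt$statistic)
      p <- tt$p.value
    } else {
      stat <- NA_real_
      p <- NA_real_
    }
    out[[i]] <- data.frame(visit = cells$visit[i], phase = cells$phase[i],
                           trial = cells$trial[i], n_pairs = n,
                           statistic = stat, p = p, testable = testable)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the m p-values ascending and rejects `p_(i)` while
#' `p_(i) <= alpha / (m - i + 1)`, stopping at the first failure; flags are
#' returned in input order. Controls the family-wise error rate at
#' `alpha`. `NA` p-values (untestable trials) are excluded from the family
#' and returned as `NA`.
#'
#' @param p Vector of p-values in (0, 1\].
#' @param alpha Family-wise error rate (default 0.05).
#' @return Logical rejection flags in input order.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  check_prob(alpha, "alpha")
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must be in (0, 1]",
                                        call. = FALSE)
  flags <- rep(NA, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(flags)
  ord <- order(pv)
  rej <- logical(m)
  for (i in seq_len(m)) {
    if (pv[ord[i]] <= alpha / (m - i + 1)) rej[ord[i]] <- TRUE else break
  }
  flags[ok] <- rej
  flags
}
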
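# The control-task null-evidence workflow: per-session model fits, mixed
# models of drug, phase and their interaction on each derived measure,
# evidence for the null model, and the post hoc drug-difference evidence.

#' Fit RL models to every session of a study
#'
#' Fits the single- and dual-learning-rate models to each participant x
#' visit x phase choice sequence by multi-start maximum likelihood and
#' collects the derived measures: P(win), eta, beta (single), eta_win,
#' eta_lose, beta_winlose (dual).
#'
#' @param choices Choice table (participant, visit, phase, trial, choice,
#'   reward).
#' @param n_starts Restarts per fit (default 10; raise for final runs).
#' @param variants Model variants to fit (default both; calibration runs
#'   that only need P(win) and the single-rate parameters can skip
#'   `"dual"`).
#' @return Data frame with one row per session and one column per measure,
#'   plus `nll_single`, `nll_dual`, `aic_single`, `aic_dual`,
#'   `bic_single`, `bic_dual`.
#' @export
fit_rl_sessions <- function(choices, n_starts = 10L,
                            variants = c("single", "dual")) {
  check_columns(choices, c("participant", "visit", "phase", "trial",
                           "choice", "reward"), "choice table")
  variants <- match.arg(variants, several.ok = TRUE)
  cells <- unique(choices[, c("participant", "visit", "phase")])
  cells <- cells[order(cells$participant, cells$visit, cells$phase), ]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- choices$participant == cells$participant[i] &
      choices$visit == cells$visit[i] & choices$phase == cells$phase[i]
    dat <- choices[sel, ]
    row <- data.frame(
      participant = cells$participant[i], visit = cells$visit[i],
      phase = cells$phase[i],
      p_win = win_proportion(dat))
    if ("single" %in% variants) {
      fs <- fit_rw_model(dat, "single", n_starts = n_starts)
      row <- cbind(row, eta = fs$params$eta, beta = fs$params$beta,
                   nll_single = fs$nll, aic_single = fs$aic,
                   bic_single = fs$bic)
    }
    if ("dual" %in% variants) {
      fd <- fit_rw_model(dat, "dual", n_starts = n_starts)
      row <- cbind(row, eta_win = fd$params$eta_win,
                   eta_lose = fd$params$eta_lose,
                   beta_winlose = fd$params$beta,
                   nll_dual = fd$nll, aic_dual = fd$aic, bic_dual = fd$bic)
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Null-evidence summary table for the control task
#'
#' For each derived measure (P(win) and the fitted RL parameters), fits a
#' mixed model of drug, phase and their interaction with a participant
#' random intercept, reports the standardized coefficients and p-values,
#' the evidence ratio and BIC Bayes factor for the intercept-only null
#' model against that full model, and -- from a separate post hoc model of
#' the post-minus-pre-administration difference on drug -- the evidence
#' against a specific drug effect.
#'
#' @param measures Session-level measures from [fit_rl_sessions()] (or any
#'   data frame with participant, visit, phase and measure columns).
#' @param measure_cols Which measure columns to summarise.
#' @return Data frame with one row per measure: `beta_drug`/`p_drug`,
#'   `beta_phase`/`p_phase`, `beta_interaction`/`p_interaction`,
#'   `er0_null`/`bf01_null` (full model vs intercept-only null; > 1
#'   favours the null) and `er0_drug`/`bf01_drug` (post hoc
#'   drug-difference model vs its null).
#' @export
rl_evidence_table <- function(measures,
                              measure_cols = c("p_win", "eta", "beta",
                                               "eta_win", "eta_lose",
                                               "beta_winlose")) {
  check_columns(measures, c("participant", "visit", "phase", measure_cols),
                "measure table")
  measures$drug <- measures$visit
  rows <- vector("list", length(measure_cols))
  for (j in seq_along(measure_cols)) {
    m <- measure_cols[j]
    full <- fit_mixed_model(measures, model_spec(m, c("drug", "phase")))
    null <- fit_mixed_model(measures, model_spec(m, character(0)))
    cmp_null <- compare_models(null$aic, full$aic, null$bic, full$bic)

    # post hoc: post-minus-pre difference per participant x visit, on drug
    wide <- merge(
      measures[measures$phase == canonical_levels("phase",
                                                  measures$phase)[1L],
               c("participant", "drug", m)],
      measures[measures$phase != canonical_levels("phase",
                                                  measures$phase)[1L],
               c("participant", "drug", m)],
      by = c("participant", "drug"), suffixes = c("_post", "_pre"))
    wide$value <- wide[[paste0(m, "_post")]] - wide[[paste0(m, "_pre")]]
    ph <- posthoc_drug_difference(wide)

    eff <- function(term) effect_row(full$effects, term)
    rows[[j]] <- data.frame(
      measure = m,
      beta_drug = eff("drug")$beta, p_drug = eff("drug")$p,
      beta_phase = eff("phase")$beta, p_phase = eff("phase")$p,
      beta_interaction = eff("drug:phase")$beta,
      p_interaction = eff("drug:phase")$p,
      er0_null = cmp_null$er_0, bf01_null = cmp_null$bf_01,
      er0_drug = ph$comparison$er_0, bf01_drug = ph$comparison$bf_01
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
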
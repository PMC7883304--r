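# Evidence for null hypotheses from information criteria. All quantities are
# carried in natural-log space so that astronomically large ratios (the study
# reports values like 3.02e145) survive; the exponentiated values are
# provided for display.

#' Akaike weights for a model pair
#'
#' `w_i = exp(-0.5 (AIC_i - AIC_min)) / sum_j exp(-0.5 (AIC_j - AIC_min))`,
#' computed in log space. For two models the weights are the relative
#' likelihoods of the null (index 0) and the alternative (index 1).
#'
#' @param aic Numeric vector of AIC values (any length >= 2).
#' @return Weights summing to 1, in input order.
#' @export
akaike_weights <- function(aic) {
  if (length(aic) < 2L || any(!is.finite(aic)))
    stop("'aic' must be >= 2 finite values", call. = FALSE)
  d <- -0.5 * (aic - min(aic))
  w <- exp(d - max(d))
  w / sum(w)
}

#' Evidence ratio for the null model
#'
#' `ER_0 = w_0 / w_1`: how many times more likely the null model is than
#' the alternative given their Akaike weights. Values over 1 favour the
#' null. For two models this collapses to `exp(0.5 (AIC_1 - AIC_0))`.
#'
#' @param w_0,w_1 Akaike weights of the null and alternative model.
#' @return The ratio; `Inf` if `w_1` is zero.
#' @export
evidence_ratio <- function(w_0, w_1) {
  if (any(c(w_0, w_1) < 0)) stop("weights must be non-negative", call. = FALSE)
  ifelse(w_1 == 0, Inf, w_0 / w_1)
}

#' BIC-approximated Bayes factor for the null model
#'
#' `BF_01 = exp(0.5 (BIC_1 - BIC_0))`: a Bayes-factor approximation
#' computed from the Bayesian information criteria of the alternative
#' (index 1) and null (index 0) models, without the need for priors.
#' Values over 1 favour the null.
#'
#' @param bic_0,bic_1 BIC of the null and alternative model.
#' @param log Return the natural log of the Bayes factor instead
#'   (exact for extreme magnitudes).
#' @return `bf_01`, or its log.
#' @export
bic_bayes_factor <- function(bic_0, bic_1, log = FALSE) {
  if (any(!is.finite(c(bic_0, bic_1))))
    stop("BIC values must be finite", call. = FALSE)
  lbf <- 0.5 * (bic_1 - bic_0)
  if (log) lbf else exp(lbf)
}

#' Jeffreys-style interpretation of an evidence ratio or Bayes factor
#'
#' Values up to and including 3 are `inconclusive`; strictly over 3 is
#' `evidence` (the "over 3" convention), over 10 `strong`, over 100
#' `decisive`.
#'
#' @param x Positive evidence ratio or Bayes factor (vectorised).
#' @return Character vector of category labels.
#' @export
interpret_evidence <- function(x) {
  if (any(x <= 0, na.rm = TRUE)) stop("evidence must be positive", call. = FALSE)
  out <- rep("inconclusive", length(x))
  out[x > 3] <- "evidence"
  out[x > 10] <- "strong"
  out[x > 100] <- "decisive"
  out[is.na(x)] <- NA_character_
  out
}

#' Compare a model against its null on AIC and BIC
#'
#' Bundles the study's evidence machinery for one (model, null) pair:
#' Akaike weights and the evidence ratio for the null (`ER_0`), the
#' BIC-approximated Bayes factor for the null (`BF_01`), their reciprocals
#' and logs, and the Jeffreys category of `ER_0`.
#'
#' @param aic_0,bic_0 Criteria of the null model.
#' @param aic_1,bic_1 Criteria of the alternative model.
#' @return An object of class `comparison_result`.
#' @export
compare_models <- function(aic_0, aic_1, bic_0, bic_1) {
  w <- akaike_weights(c(aic_0, aic_1))
  log_er0 <- 0.5 * (aic_1 - aic_0)
  log_bf01 <- bic_bayes_factor(bic_0, bic_1, log = TRUE)
  structure(list(
    aic_0 = aic_0, aic_1 = aic_1, bic_0 = bic_0, bic_1 = bic_1,
    w_0 = w[1L], w_1 = w[2L],
    er_0 = exp(log_er0), er_1 = exp(-log_er0),
    bf_01 = exp(log_bf01), bf_10 = exp(-log_bf01),
    log_er0 = log_er0, log_bf01 = log_bf01,
    category = interpret_evidence(exp(log_er0))
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Model vs null: ER_0 = %.4g, BF_01 = %.4g (%s for the null)\n",
              x$er_0, x$bf_01, x$category))
  invisible(x)
}
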
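---
title: "Models and methods behind lookaway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lookaway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lookaway re-implements, as a tested pipeline, the computational analysis of a
randomized placebo-controlled crossover experiment on oculomotor disgust
avoidance: whether a peripheral D2 antagonist (domperidone), paired with
gaze-contingent incentivized exposure, reduces the tendency to look away from
disgusting images, while leaving reward learning untouched. The package
contains four analysis layers — gaze metrics, a Rescorla–Wagner model of the
control task, evidence quantification for null hypotheses, and linear mixed
models — plus a synthetic-data generator with known ground truth, so every
layer is testable without access to the original data deposit.

## The measurement model: from fixations to avoidance

Each preferential-looking trial shows two images, 400 × 300 px, horizontally
centred 640 px apart on a 1280 × 1024 screen. Pixel geometry uses a top-left
origin and *half-open* rectangles (left/top edge inside, right/bottom edge
outside), so every fixation point receives exactly one of three labels:
`disgust`, `neutral`, or `nonstim`. Fixations spanning a boundary are
assigned by their point coordinate only; no duration splitting.

Dwell proportions divide the summed fixation duration per label by the
trial's **total fixation time** (not wall-clock time), so the three
proportions sum to 1 by construction and the three-way split of the original
figure is reproduced. Tracking quality is carried separately as
`valid_fraction` = tracked time / nominal trial duration, and a trial is
dropped iff its missing fraction *strictly exceeds* 50% — a trial missing
exactly half its data is retained. The outcome measure is the avoidance
score, `p_neutral - p_disgust`, in [-1, 1]; positive values mean the gaze
avoided the disgusting image.

## The learning model

The control task is an 88-trial two-armed bandit whose reward probabilities
(0.8 / 0.2) swap four times, roughly every 20 trials. Choices are modelled by
a delta rule with softmax choice. Only the chosen stimulus's associative
value updates:

$$v_{c,i} = v_{c,i-1} + \eta\,(R_{i-1} - v_{c,i-1}),$$

with a dual-rate variant applying $\eta_{win}$ after wins ($R > 0$) and
$\eta_{lose}$ otherwise, and choice probabilities

$$P(A)_i = \frac{e^{\beta v_{A,i}}}{e^{\beta v_{A,i}} + e^{\beta v_{B,i}}}.$$

Both values start at 0, so the first-trial probability is exactly 0.5 per
arm — an identity the tests assert exactly. The likelihood is the sequential
product of softmax probabilities of the observed choices; it is computed in
C++ with log-sum-exp so large $\beta$ cannot overflow, and is checked in the
suite against a brute-force enumeration of all $2^5$ outcome sequences of a
5-trial fixture.

**Estimation.** The original report does not name its estimator, so the
package uses the simplest scheme consistent with "a basic reinforcement
learning model": multi-start bounded maximum likelihood. Learning rates are
optimized through a logit transform, $\beta$ through a log transform with an
upper bound of 20 (an identifiability guard for 88-trial sessions; fits at
the bound are flagged). Default 20 restarts, learning-rate starts uniform on
[0, 1], $\beta$ starts log-uniform on [0.1, 20], L-BFGS-B. Because the dual
model nests the single model, one extra start is seeded at the single-rate
optimum, which guarantees the dual fit never ends worse — a property the
acceptance suite checks across 200 agents. AIC and BIC use the conventions
$2k + 2\,\mathrm{nll}$ and $k \ln n + 2\,\mathrm{nll}$ with $n$ the trial
count and $k$ = 2 (single) or 3 (dual). Fits are per participant × visit ×
phase, matching the pre/post-administration structure of the original
summary table.

## Evidence for null hypotheses

Support for "no drug effect" is quantified from information criteria of a
model and its intercept-only null. For the pair (null = 0, alternative = 1):
Akaike weights $w_i \propto e^{-0.5(AIC_i - AIC_{min})}$, the evidence ratio
$ER_0 = w_0 / w_1$ (which collapses exactly to $e^{0.5(AIC_1 - AIC_0)}$),
and the prior-free Bayes-factor approximation
$BF_{01} = e^{0.5(BIC_1 - BIC_0)}$. All quantities are carried in natural-log
space, since real comparisons can reach magnitudes like $10^{145}$.
Interpretation uses the strict "over 3" convention: values up to and
including 3 are inconclusive; the additional cut points 10 (strong) and 100
(decisive) follow the cited guideline convention, since the source names
only the 3 threshold.

## Mixed-model inference

Trial-level outcomes are fitted with lme4 by maximum likelihood (REML off,
so criterion comparisons against nested nulls are valid), with a participant
random intercept. Coding is fixed once and used everywhere: sum-to-zero
contrasts with the canonical first level at +1 (disgust, domperidone, and
the chronologically later phase), trial index z-scored, outcome z-scored, so
coefficients are standardized betas. Inference is by Wald Z with 95% Wald
intervals (the original results report Z statistics, not t with degrees of
freedom). Dwell proportions are modelled on the raw proportion scale; an
empirical-logit option exists but is off by default. Singular
random-intercept variances warn and keep the fit; hard optimizer failures
error with the optimizer code. For self-report ratings, trial number is not
a factor.

**A calibration caveat that shaped the design.** The two stimulus rows of
one trial share that trial's fixation budget, so their residuals are
strongly negatively correlated (about -0.66 under the default generator). A
Wald test of stimulus-involving interactions on those paired rows is
therefore anticonservative: under the null generator the
stimulus × drug × phase test rejected at ~0.11–0.17 instead of 0.05, and a
per-trial stimulus random slope only brought it to ~0.10. The package's
calibrated parametrization of the same question is `fit_avoidance_model()`:
the within-trial paired difference (the avoidance score) carries the
stimulus contrast exactly, one observation per trial, and its `drug:phase`
term tests the three-way interaction with measured type-I error at the
nominal level (0.05 over seeded null replicates). The full dwell model with
the stimulus factor remains implemented and reported — it is the original
study's primary structure, and its coefficient estimates and signs are
meaningful — but family-wise conclusions about stimulus-involving
interactions should rest on the difference-scale test. The original study's
own post hoc confirmation used exactly this difference parametrization.

Per-trial disgust-vs-neutral comparisons use paired two-sided t-tests across
participants (the test family is not named in the source figure; the paired
t is the convention for such panels), flagged untestable below 3 pairs or
under zero variance rather than assigned an arbitrary p, and corrected with
a hand-rolled Holm–Bonferroni step-down whose agreement with
`stats::p.adjust` is a property test.

## The synthetic world

The generator's defaults are the study's stated conditions wherever stated:
25 participants, two counterbalanced visits, phases of 24/24/10/10/10
trials, 88-trial bandit sessions with four 80/20 reversals, binary rewards.
Where the source is silent, one realistic choice was made and fixed:

- **Trial duration** 15 s (the source gives only "24 trials (7 min)"
  including inter-trial intervals), configurable.
- **Dwell generation.** Per-trial expected proportions come from a
  three-category multinomial-logit map: weights $e^{\ell_d}, e^{\ell_n}, 1$
  for disgust, neutral, non-stimulus. This is the stated "logit scale with
  additive Gaussian participant and trial noise, mapped through the
  logistic" generalised to three categories, so effects compose additively
  and proportions always lie in [0, 1] and sum to 1. Defaults: neutral
  predictor 0.8, disgust decrement -1.5 (strong avoidance), participant and
  trial SDs 0.5, an incentive-phase boost of +2 on the disgust predictor
  (emulating paid fixation of the disgusting image), and a
  drug × phase interaction of +0.5 added to the disgust predictor in the
  domperidone post-incentive cell (the exposure-facilitation effect).
- **Fixation rendering.** Fixations have log-normal durations (median ~280
  ms) separated by 50 ms saccade gaps and land in an AOI with the trial's
  expected probabilities; non-stimulus fixations are placed in the central
  gap between the images. Raw 1000-Hz gaze samples are *not* simulated.
- **Tracking loss.** Per-trial loss rates are Beta-distributed
  (concentration 5) around the configured mean of 0.05, chosen so that
  roughly 1–2% of trials exceed the 50%-missing filter — the dropout rate
  the study reports (26/2496 ≈ 1%).
- **Reversal spacing** at multiples of $\lfloor n/(r+1) \rfloor$ with ±2
  trials of uniform jitter ("roughly every 20 trials"); which arm starts
  high is random.
- **Self-report** on a 0–100 scale (the source never states its scale),
  disgust mean 65 vs neutral 10, participant SD 8, residual SD 10.
- **RNG discipline.** One master seed per simulate call; per-participant
  sub-stream seeds are a deterministic arithmetic mix of it, so any subset
  of participants reproduces exactly and identical configurations are
  byte-identical.
- **RL ground truth**: per-participant $\eta \sim U(0.2, 0.6)$,
  $\beta \sim U(2, 8)$, constant across sessions — the drug leaves learning
  untouched by default, which is the study's conclusion and the null world
  the evidence machinery is calibrated on. An injectable
  `drug_effect_eta` exists for power studies.

What a green suite does **not** establish: the generator emulates effect
structure, not the texture of real eye-tracking data — no saccade dynamics,
no blink artefacts, no spatial bias within an image, no serial dependence
across trials, no learning or fatigue in the gaze task beyond the injected
phase effects. Agreement of recovered parameters with these synthetic truths
does not certify agreement with the original deposit, whose unstated factor
coding and normalization choices the desk build cannot resolve.

## Numerical choices and degenerate inputs

Softmax and likelihood use max-subtraction / log-sum-exp throughout.
Optimizer tolerance is L-BFGS-B `factr = 1e7` (≈ 2e-9 relative). Zero-valid
trials yield a flagged missing record rather than NaNs; off-screen fixations
are non-stimulus; choice-simulation ties are broken by the RNG draw, never
deterministically. Evidence ratios with a zero denominator report `Inf`.
The Jeffreys boundary at exactly 3 is inconclusive (strict "over 3"); the
missing-data boundary at exactly 50% is retained (strict "> 50%").

## Known limitations

- Wald Z inference has no small-sample df correction by design (the source
  reports Z); with 25 participants this is mildly liberal for
  between-participant contrasts.
- The dwell-with-stimulus-factor model's anticonservativity discussed above
  is a property of the original analysis structure that the package
  reproduces deliberately; use the difference-scale test for calibrated
  decisions.
- BIC Bayes factors are the unit-information approximation, not prior-based
  Bayes factors.
- The pipeline fits per-session RL parameters by independent MLE; no
  hierarchical shrinkage.
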
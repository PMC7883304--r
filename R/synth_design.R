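# Crossover study design: every participant visits twice (domperidone and
# placebo, order counterbalanced) and runs through five eye-tracking phases
# per visit; the disgusting image's side is balanced within each phase.

#' Build a randomized placebo-controlled crossover design
#'
#' @param n_participants Number of participants (default 25, the study size).
#' @param trials_per_phase Named counts of preferential-looking trials per
#'   phase, in chronological order. Defaults: 24 baseline, 24
#'   post-administration, then 10 each before, during and after the
#'   gaze-contingent incentivized-exposure block.
#' @param seed Integer seed for the visit-order counterbalancing and the
#'   side randomization.
#' @return An object of class `study_design`: a list with
#'   `n_participants`, `phases`, `trials_per_phase`, `visit_order` (one row
#'   per participant x visit index) and `trial_grid` (one row per
#'   participant x visit x phase x trial, with the disgust image's side,
#'   balanced within phase up to rounding).
#' @export
study_design <- function(n_participants = 25L,
                         trials_per_phase = c(baseline = 24L, post_admin = 24L,
                                              pre_incentive = 10L,
                                              incentive = 10L,
                                              post_incentive = 10L),
                         seed = 1L) {
  n_p <- check_count(n_participants, "n_participants")
  if (is.null(names(trials_per_phase)) || any(!nzchar(names(trials_per_phase))))
    stop_config("trials_per_phase", "must be a named vector of phase counts")
  for (ph in names(trials_per_phase))
    check_count(trials_per_phase[[ph]], paste0("trials_per_phase[", ph, "]"))
  seed <- check_count(seed, "seed", min = 0L)

  set.seed(seed)
  # counterbalanced drug order: half (up to rounding) get domperidone first
  first_drug <- sample(rep(c("domperidone", "placebo"), length.out = n_p))
  visit_order <- data.frame(
    participant = rep(seq_len(n_p), each = 2L),
    visit_index = rep(1:2, n_p),
    visit = as.vector(vapply(first_drug, function(d) {
      c(d, setdiff(c("domperidone", "placebo"), d))
    }, character(2L)))
  )

  phases <- names(trials_per_phase)
  one_visit <- do.call(rbind, lapply(phases, function(ph) {
    data.frame(phase = ph, trial = seq_len(trials_per_phase[[ph]]))
  }))
  grid <- merge(visit_order, one_visit, by = NULL)
  grid <- grid[order(grid$participant, grid$visit_index,
                     match(grid$phase, phases), grid$trial), ]
  # balanced left/right disgust placement within each participant-visit-phase
  key <- paste(grid$participant, grid$visit_index, grid$phase)
  grid$disgust_side <- NA_character_
  for (k in unique(key)) {
    idx <- which(key == k)
    grid$disgust_side[idx] <- sample(rep(c("left", "right"),
                                         length.out = length(idx)))
  }
  rownames(grid) <- NULL
  structure(list(
    n_participants = n_p,
    phases = phases,
    trials_per_phase = trials_per_phase,
    visit_order = visit_order,
    trial_grid = grid[, c("participant", "visit_index", "visit", "phase",
                          "trial", "disgust_side")]
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Crossover study design: %d participants, 2 visits, phases %s\n",
              x$n_participants,
              paste(sprintf("%s(%d)", x$phases, x$trials_per_phase),
                    collapse = ", ")))
  invisible(x)
}
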
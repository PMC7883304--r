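# From fixations to dwell-time proportions and the avoidance score.
#
# Geometry convention, used everywhere: pixel coordinates with origin at the
# screen's top-left, 0-based; AOI rectangles are half-open ([x0, x1) x
# [y0, y1)) so every point gets exactly one label. The proportion
# denominator is the total fixation time within the trial (not wall-clock),
# so the three proportions sum to 1; missingness is tracked separately as
# 1 - tracked_time / trial_duration.

#' Screen layout of the two stimulus areas of interest
#'
#' Two images (400 x 300 px), horizontally centred 640 px apart on the
#' screen, vertically centred.
#'
#' @param screen_size Screen width and height in pixels (default 1280 x 1024).
#' @param image_size Image width and height in pixels (default 400 x 300).
#' @param center_separation Horizontal distance between image centres
#'   (default 640 px).
#' @param disgust_side Which image is the disgusting one, `"left"` or
#'   `"right"`.
#' @return An object of class `aoi_layout`.
#' @export
aoi_layout <- function(screen_size = c(1280L, 1024L),
                       image_size = c(400L, 300L),
                       center_separation = 640L,
                       disgust_side = c("left", "right")) {
  disgust_side <- match.arg(disgust_side)
  layout <- structure(list(screen_size = as.numeric(screen_size),
                           image_size = as.numeric(image_size),
                           center_separation = as.numeric(center_separation),
                           disgust_side = disgust_side),
                      class = "aoi_layout")
  r <- aoi_rects(layout)
  for (rc in r) {
    if (rc["x0"] < 0 || rc["y0"] < 0 || rc["x1"] > layout$screen_size[1] ||
        rc["y1"] > layout$screen_size[2])
      stop_config("image_size/center_separation",
                  "places an image rectangle off screen")
  }
  if (r$left["x1"] > r$right["x0"])
    stop_config("center_separation", "makes the image rectangles overlap")
  layout
}

# Half-open pixel rectangles of the left and right image.
aoi_rects <- function(layout) {
  cx <- layout$screen_size[1] / 2
  cy <- layout$screen_size[2] / 2
  hw <- layout$image_size[1] / 2
  hh <- layout$image_size[2] / 2
  centers <- c(left = cx - layout$center_separation / 2,
               right = cx + layout$center_separation / 2)
  lapply(as.list(centers), function(c_x) {
    c(x0 = c_x - hw, x1 = c_x + hw, y0 = cy - hh, y1 = cy + hh)
  })
}

#' Assign fixations to areas of interest
#'
#' A fixation is labelled `disgust` or `neutral` if its point falls inside
#' that image's half-open rectangle (left/top edge inclusive, right/bottom
#' exclusive) and `nonstim` otherwise; off-screen points are `nonstim`.
#'
#' @param x,y Fixation coordinates in pixels (vectorised).
#' @param layout An [aoi_layout()]; its `disgust_side` decides which
#'   rectangle is the disgusting image. Pass `disgust_side` to override it
#'   per fixation.
#' @param disgust_side Optional vector (`"left"`/`"right"`) recycled over
#'   fixations, for designs that randomise the side per trial.
#' @return Character vector in `{"disgust", "neutral", "nonstim"}`.
#' @export
assign_fixation <- function(x, y, layout = aoi_layout(), disgust_side = NULL) {
  stopifnot(inherits(layout, "aoi_layout"))
  if (is.null(disgust_side)) disgust_side <- layout$disgust_side
  side <- rep_len(as.character(disgust_side), length(x))
  r <- aoi_rects(layout)
  in_rect <- function(rc) x >= rc["x0"] & x < rc["x1"] &
    y >= rc["y0"] & y < rc["y1"]
  in_left <- in_rect(r$left)
  in_right <- in_rect(r$right)
  label <- rep("nonstim", length(x))
  label[in_left] <- ifelse(side[in_left] == "left", "disgust", "neutral")
  label[in_right] <- ifelse(side[in_right] == "right", "disgust", "neutral")
  label
}

#' Dwell-time proportions per trial
#'
#' Sums fixation durations per AOI within each trial and divides by the
#' trial's total fixation time, yielding proportions for the disgusting
#' image, the neutral image, and non-stimulus fixations that sum to 1.
#' Fixations spanning an AOI boundary are assigned by their point
#' coordinate only. `valid_fraction` is tracked time over the nominal
#' trial duration; trials absent from the fixation table (fully lost) can
#' be reinstated as missing via `all_trials`.
#'
#' @param fixations Data frame with columns `participant`, `visit`,
#'   `phase`, `trial`, `onset_ms`, `duration_ms`, `x`, `y`,
#'   `disgust_side`.
#' @param layout An [aoi_layout()].
#' @param trial_duration_ms Nominal trial duration used for
#'   `valid_fraction` (default 15000).
#' @param all_trials Optional data frame of the full trial grid
#'   (`participant`, `visit`, `phase`, `trial`); trials with no tracked
#'   fixations are returned with `missing = TRUE` and `NA` proportions.
#' @return Data frame of dwell records: identifiers plus `p_disgust`,
#'   `p_neutral`, `p_nonstim`, `valid_fraction`, `missing`.
#' @export
compute_dwell <- function(fixations, layout = aoi_layout(),
                          trial_duration_ms = 15000, all_trials = NULL) {
  check_columns(fixations,
                c("participant", "visit", "phase", "trial", "onset_ms",
                  "duration_ms", "x", "y", "disgust_side"),
                "fixation table")
  if (nrow(fixations) && any(fixations$duration_ms <= 0))
    stop("fixation durations must be positive", call. = FALSE)

  if (nrow(fixations) == 0L) {
    rec <- data.frame(participant = integer(0), visit = character(0),
                      phase = character(0), trial = integer(0),
                      p_disgust = numeric(0), p_neutral = numeric(0),
                      p_nonstim = numeric(0), valid_fraction = numeric(0),
                      missing = logical(0))
    if (!is.null(all_trials)) {
      rec <- cbind(all_trials[, c("participant", "visit", "phase", "trial")],
                   p_disgust = NA_real_, p_neutral = NA_real_,
                   p_nonstim = NA_real_, valid_fraction = 0, missing = TRUE)
    }
    return(rec)
  }
  lab <- assign_fixation(fixations$x, fixations$y, layout,
                         disgust_side = fixations$disgust_side)
  key <- interaction(fixations$participant, fixations$visit, fixations$phase,
                     fixations$trial, drop = TRUE, sep = "\r")
  sum_by <- function(w) {
    out <- tapply(fixations$duration_ms * w, key, sum)
    out[is.na(out)] <- 0
    out
  }
  d_dis <- sum_by(lab == "disgust")
  d_neu <- sum_by(lab == "neutral")
  d_non <- sum_by(lab == "nonstim")
  total <- d_dis + d_neu + d_non

  ids <- do.call(rbind, strsplit(names(total), "\r", fixed = TRUE))
  rec <- data.frame(
    participant = as.integer(ids[, 1]),
    visit = ids[, 2], phase = ids[, 3], trial = as.integer(ids[, 4]),
    p_disgust = as.numeric(d_dis / total),
    p_neutral = as.numeric(d_neu / total),
    p_nonstim = as.numeric(d_non / total),
    valid_fraction = pmin(as.numeric(total) / trial_duration_ms, 1),
    missing = as.numeric(total) <= 0
  )
  if (!is.null(all_trials)) {
    check_columns(all_trials, c("participant", "visit", "phase", "trial"),
                  "trial grid")
    rec <- merge(all_trials[, c("participant", "visit", "phase", "trial")],
                 rec, all.x = TRUE,
                 by = c("participant", "visit", "phase", "trial"))
    lost <- is.na(rec$missing)
    rec$missing[lost] <- TRUE
    rec$valid_fraction[lost] <- 0
  }
  rec <- rec[order(rec$participant, rec$visit, rec$phase, rec$trial), ]
  rownames(rec) <- NULL
  rec
}

#' Drop trials with too much missing data
#'
#' A trial is dropped iff its missing fraction `1 - valid_fraction`
#' *strictly exceeds* `max_missing`; a trial missing exactly 50% of its
#' data is retained under the default threshold.
#'
#' @param records Dwell records with a `valid_fraction` column.
#' @param max_missing Missingness threshold (default 0.5).
#' @return List with `records` (retained rows) and `n_dropped`.
#' @export
filter_trials <- function(records, max_missing = 0.5) {
  check_columns(records, "valid_fraction", "dwell records")
  check_prob(max_missing, "max_missing")
  drop <- (1 - records$valid_fraction) > max_missing
  list(records = records[!drop, , drop = FALSE], n_dropped = sum(drop))
}

#' Oculomotor avoidance score
#'
#' The study's outcome measure: the difference in dwell-time proportions
#' between the neutral and the disgusting stimulus, `p_neutral -
#' p_disgust`, in \[-1, 1\]. Positive values indicate avoidance of the
#' disgusting image. Missing records propagate `NA`.
#'
#' @param records Dwell records from [compute_dwell()].
#' @return The records with an `avoidance` column appended.
#' @export
avoidance <- function(records) {
  check_columns(records, c("p_disgust", "p_neutral"), "dwell records")
  records$avoidance <- records$p_neutral - records$p_disgust
  if ("missing" %in% names(records))
    records$avoidance[records$missing] <- NA_real_
  records
}
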
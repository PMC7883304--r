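# AOI assignment, dwell proportions, the missing-data filter and the
# avoidance score.

test_that("fixations inside, between and on the edge of the images label correctly", {
  ctr <- default_centers()
  lay <- aoi_layout(disgust_side = "left")
  # interior points
  expect_equal(assign_fixation(ctr$left["x"], ctr$left["y"], lay), "disgust")
  expect_equal(assign_fixation(ctr$right["x"], ctr$right["y"], lay), "neutral")
  # screen midpoint falls in the gap between the images
  expect_equal(assign_fixation(640, 512, lay), "nonstim")
  # half-open rule: right edge of an image is outside it, left edge inside
  r <- ctr$rects
  expect_equal(assign_fixation(r$left["x1"], ctr$left["y"], lay), "nonstim")
  expect_equal(assign_fixation(r$left["x0"], ctr$left["y"], lay), "disgust")
  expect_equal(assign_fixation(r$left["x0"], r$left["y1"], lay), "nonstim")
  # off screen
  expect_equal(assign_fixation(-50, 512, lay), "nonstim")
  expect_equal(assign_fixation(2000, 512, lay), "nonstim")
  # side flag swaps the labels
  lay_r <- aoi_layout(disgust_side = "right")
  expect_equal(assign_fixation(ctr$left["x"], ctr$left["y"], lay_r), "neutral")
})

test_that("layout validation rejects impossible geometry", {
  expect_error(aoi_layout(center_separation = 300), "overlap")
  expect_error(aoi_layout(center_separation = 1000), "off screen")
})

test_that("dwell proportions follow hand arithmetic on a constructed trial", {
  ctr <- default_centers()
  fx <- rbind(
    fix_row(ctr$left["x"], ctr$left["y"], 300),       # disgust (side = left)
    fix_row(ctr$right["x"], ctr$right["y"], 500),     # neutral
    fix_row(640, 100, 200))                           # non-stimulus
  rec <- compute_dwell(fx, trial_duration_ms = 2000)
  expect_equal(rec$p_disgust, 0.3)
  expect_equal(rec$p_neutral, 0.5)
  expect_equal(rec$p_nonstim, 0.2)
  expect_equal(rec$valid_fraction, 0.5)
  expect_false(rec$missing)
})

test_that("a trial spent entirely on one image is a degenerate allocation", {
  ctr <- default_centers()
  fx <- rbind(fix_row(ctr$right["x"], ctr$right["y"], 400),
              fix_row(ctr$right["x"] + 10, ctr$right["y"] - 5, 350))
  rec <- compute_dwell(fx)
  expect_equal(rec$p_neutral, 1)
  expect_equal(rec$p_disgust, 0)
  expect_equal(rec$p_nonstim, 0)
})

test_that("proportions always sum to 1 and partition the fixation time", {
  set.seed(15)
  lay <- aoi_layout()
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    fx <- fix_row(runif(n, -100, 1400), runif(n, -100, 1100),
                  duration_ms = sample(50:600, n, replace = TRUE),
                  trial = sample(1:3, n, replace = TRUE),
                  disgust_side = sample(c("left", "right"), 1))
    rec <- compute_dwell(fx, lay, trial_duration_ms = 50000)
    expect_true(all(abs(rec$p_disgust + rec$p_neutral + rec$p_nonstim - 1) < 1e-9))
    # every fixation gets exactly one label; labeled time partitions total time
    lab <- assign_fixation(fx$x, fx$y, lay, disgust_side = fx$disgust_side)
    expect_true(all(lab %in% c("disgust", "neutral", "nonstim")))
    expect_equal(sum(rec$valid_fraction) * 50000, sum(fx$duration_ms))
  }
})

test_that("mirroring x and swapping the disgust side leaves dwell unchanged", {
  set.seed(16)
  lay <- aoi_layout()
  w <- lay$screen_size[1]
  n <- 60
  fx <- fix_row(runif(n, 0, w), runif(n, 0, 1024),
                duration_ms = sample(80:400, n, replace = TRUE),
                trial = sample(1:4, n, replace = TRUE),
                disgust_side = "left")
  mirrored <- fx
  mirrored$x <- w - fx$x
  mirrored$disgust_side <- "right"
  a <- compute_dwell(fx, lay)
  b <- compute_dwell(mirrored, lay)
  expect_equal(a[, c("p_disgust", "p_neutral", "p_nonstim")],
               b[, c("p_disgust", "p_neutral", "p_nonstim")])
})

test_that("negative durations are a data error", {
  expect_error(compute_dwell(fix_row(640, 512, -10)), "positive")
})

test_that("the > 50% missing rule is strict and counted", {
  rec <- data.frame(valid_fraction = c(0.4, 0.5, 0.51, 1))
  f <- filter_trials(rec)
  expect_equal(f$n_dropped, 1L)                    # only 60% missing dropped
  expect_equal(f$records$valid_fraction, c(0.5, 0.51, 1))  # 50% exactly stays

  # constructed 100-trial fixture with 17 trials over threshold
  set.seed(3)
  vf <- c(runif(17, 0, 0.49), runif(83, 0.51, 1))[sample(100)]
  expect_equal(filter_trials(data.frame(valid_fraction = vf))$n_dropped, 17L)
})

test_that("tightening the filter never retains more trials", {
  set.seed(5)
  rec <- data.frame(valid_fraction = runif(200))
  kept <- sapply(seq(0, 1, by = 0.05), function(mm)
    nrow(filter_trials(rec, mm)$records))
  expect_true(all(diff(kept) >= 0))  # kept grows with the allowed missingness
})

test_that("avoidance is the neutral-minus-disgust difference", {
  rec <- data.frame(p_disgust = c(0.4, 0.1), p_neutral = c(0.4, 0.7),
                    p_nonstim = c(0.2, 0.2), missing = c(FALSE, FALSE))
  av <- avoidance(rec)
  expect_equal(av$avoidance, c(0, 0.6))
  rec$missing[1] <- TRUE
  rec$p_disgust[1] <- NA
  rec$p_neutral[1] <- NA
  expect_true(is.na(avoidance(rec)$avoidance[1]))
})

test_that("fully lost trials are reinstated as missing from the trial grid", {
  fx <- fix_row(default_centers()$left["x"], 512, 200, trial = 1L)
  grid <- data.frame(participant = 1L, visit = "placebo", phase = "baseline",
                     trial = 1:3)
  rec <- compute_dwell(fx, all_trials = grid)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$missing, c(FALSE, TRUE, TRUE))
  expect_equal(rec$valid_fraction[2:3], c(0, 0))
  # a trial may legitimately have zero fixations at all
  none <- compute_dwell(fx[0, ], all_trials = grid)
  expect_equal(nrow(none), 3L)
  expect_true(all(none$missing))
  expect_equal(nrow(compute_dwell(fx[0, ])), 0L)
})
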
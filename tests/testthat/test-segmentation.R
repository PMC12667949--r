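test_that("speed computation matches its definition and a brute-force oracle", {
  fr <- 166
  n <- 400
  # constant position -> zero speed
  still <- track_series("s", (0:(n - 1)) / fr, rep(1, n), rep(2, n),
                        rep(0, n), fr)
  expect_equal(compute_speed(still, 1), rep(0, n))

  # uniform advance of 0.06 mm/frame -> 9.96 mm/s at interior samples
  adv <- track_series("a", (0:(n - 1)) / fr, (0:(n - 1)) * 0.06,
                      rep(0, n), rep(0, n), fr)
  sp <- compute_speed(adv, 1)
  expect_equal(sp[2:(n - 1)], rep(0.06 * fr, n - 2))
  expect_equal(sp[1], 0.06 * fr)

  # random-walk track vs per-frame finite differences computed independently
  set.seed(11)
  x <- cumsum(rnorm(n, 0, 0.05)); z <- cumsum(rnorm(n, 0, 0.05))
  tr <- track_series("r", (0:(n - 1)) / fr, x, z, rnorm(n), fr)
  got <- compute_speed(tr, 1)
  oracle <- numeric(n)
  for (i in 2:(n - 1))
    oracle[i] <- fr * sqrt((x[i + 1] - x[i - 1])^2 +
                           (z[i + 1] - z[i - 1])^2) / 2
  oracle[1] <- fr * sqrt((x[2] - x[1])^2 + (z[2] - z[1])^2)
  oracle[n] <- fr * sqrt((x[n] - x[n - 1])^2 + (z[n] - z[n - 1])^2)
  expect_equal(got, oracle)
  expect_true(all(got >= 0))
  expect_error(compute_speed(tr, 2), "odd")
})

test_that("bout detection obeys threshold, peak and merge semantics", {
  fr <- 166
  p <- segmentation_params(min_duration_s = 0, merge_gap_s = 0)
  expect_equal(nrow(detect_bouts(rep(4.9, 100), fr, p)), 0)

  tr <- pulse_track(peak = 12, fwhm_ms = 120, fr = fr)
  sp <- compute_speed(tr, 1)
  runs <- detect_bouts(sp, fr, segmentation_params())
  expect_equal(nrow(runs), 1)
  expect_equal(runs$peak, which.max(sp))

  # two pulses separated by a 20 ms sub-threshold dip
  blk <- function(ms, v) rep(v, round(ms / 1000 * fr))
  spd <- c(blk(300, 1), blk(60, 10), blk(20, 3), blk(60, 11), blk(300, 1))
  merged <- detect_bouts(spd, fr, segmentation_params(merge_gap_s = 0.030,
                                                      min_duration_s = 0))
  split <- detect_bouts(spd, fr, segmentation_params(merge_gap_s = 0,
                                                     min_duration_s = 0))
  expect_equal(nrow(merged), 1)
  expect_equal(nrow(split), 2)
  # peak of the merged run is the overall max (11), earliest index on ties
  expect_equal(spd[merged$peak], 11)

  # run-length oracle: recompute split runs directly
  r <- rle(spd > 5)
  expect_equal(nrow(split), sum(r$values))
})

test_that("bout count is non-increasing in merge_gap", {
  set.seed(21)
  fr <- 166
  spd <- pmax(0, rnorm(3000, 3.5, 2.5))
  gaps <- c(0, 0.01, 0.03, 0.06, 0.12, 0.3)
  counts <- vapply(gaps, function(g)
    nrow(detect_bouts(spd, fr, segmentation_params(merge_gap_s = g,
                                                   min_duration_s = 0))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("short runs are discarded and boundary-crossing bouts flagged truncated", {
  fr <- 166
  spd <- rep(1, 600)
  spd[300] <- 10                       # single-frame crossing
  p <- segmentation_params(min_duration_s = 3 / fr, merge_gap_s = 0)
  expect_equal(nrow(detect_bouts(spd, fr, p)), 0)

  spd2 <- rep(1, 600)
  spd2[10:20] <- 10                    # peak < 250 ms after epoch start
  runs <- detect_bouts(spd2, fr, p)
  expect_true(runs$truncated[1])
  tr <- speed_track(spd2, fr)
  seg <- segment_epoch(tr, params = p)
  expect_equal(nrow(seg$bouts), 0)
  expect_equal(seg$n_truncated, 1)
})

test_that("segmentation window is peak-aligned and 75 samples at 166 Hz", {
  tr <- pulse_track(peak = 14, fwhm_ms = 150, fr = 166)
  seg <- segment_epoch(tr, params = segmentation_params())
  expect_equal(nrow(seg$bouts), 1)
  expect_equal(nrow(seg$ibis), 0)
  expect_equal(ncol(seg$windows$speed), 75)
  expect_equal(sum(seg$rel_t < 0), 41)
  expect_equal(sum(seg$rel_t > 0), 33)
  # max of the window speed occurs at relative time 0
  expect_equal(which.max(seg$windows$speed[1, ]), which(seg$rel_t == 0))
})

test_that("generated epochs yield bouts = IBIs + 1 and IBI durations match the programmed gaps", {
  p <- swimmer_params(duration_h = 1, seed = 5, max_bouts = 10,
                      dark = strategy_params(drift_noise = 0,
                                             peak_speed_mean = 15,
                                             peak_speed_cv = 0.1),
                      x_jitter = 0)
  rec <- generate_recording(p)
  sp <- segmentation_params(smooth_window = 1)
  seg <- segment_epoch(rec$tracks[[1]], rec$meta, sp)
  expect_equal(nrow(seg$bouts), 10)
  expect_equal(nrow(seg$ibis), 9)
  # programmed run gaps (truth log, bouts 2..10) vs measured IBI durations
  truth_gap <- rec$log$ibis$duration[-1]
  expect_lt(max(abs(seg$ibis$duration_s - truth_gap)),
            2 / rec$meta$frame_rate + 1e-9)
  # window alignment holds for every emitted bout
  peak_col <- which(seg$rel_t == 0)
  expect_true(all(max.col(seg$windows$speed, "first") == peak_col))
})

test_that("detection recall and precision reach 0.99 on well-separated synthetic bouts", {
  # ~500+ bouts pooled over three seeds
  tot_true <- 0; tot_det <- 0; tot_match <- 0
  for (s in c(101, 102, 103)) {
    rec <- generate_recording(swimmer_params(
      duration_h = 0.25, seed = s, ibi_min = 0.3,
      dark = strategy_params(ibi_mean = 1.0, ibi_shape = 4,
                             peak_speed_mean = 15, peak_speed_cv = 0.1)))
    seg <- seg_of(rec)
    rep <- truth_vs_pipeline(rec, seg)
    tot_true <- tot_true + rep$n_true
    tot_det <- tot_det + rep$n_detected
    tot_match <- tot_match + rep$n_matched
  }
  expect_gte(tot_true, 500)
  expect_gte(tot_match / tot_true, 0.99)    # recall
  expect_gte(tot_match / tot_det, 0.99)     # precision
})
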
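test_that("FWHM of analytic pulse shapes is recovered", {
  fr <- 166
  pre <- 41; post <- 33
  rel <- (-pre:post) / fr

  # symmetric triangle: 100 ms rise, 100 ms fall -> FWHM = 100 ms (exact,
  # linear interpolation is exact on a piecewise-linear profile)
  tri <- manual_bout(12 * pmax(0, 1 - abs(rel) / 0.1), fr = fr, pre = pre)
  expect_equal(as.numeric(bout_duration_fwhm(tri)), 100, tolerance = 1e-12)

  # rectangle of width w frames -> w frame-periods within one frame
  w <- 21
  spd <- rep(0.5, pre + post + 1)
  spd[(pre + 1 - (w - 1) / 2):(pre + 1 + (w - 1) / 2)] <- 10
  rect <- manual_bout(spd, fr = fr, pre = pre)
  expect_lt(abs(as.numeric(bout_duration_fwhm(rect)) - w * 1000 / fr),
            1000 / fr)

  # Gaussian sigma = 42.47 ms -> FWHM = 2*sqrt(2*log(2))*sigma ~ 100 ms
  g <- manual_bout(10 * exp(-rel^2 / (2 * 0.04247^2)), fr = fr, pre = pre)
  expect_lt(abs(as.numeric(bout_duration_fwhm(g)) - 100), 2 * 1000 / fr)
  expect_false(attr(bout_duration_fwhm(g), "censored"))

  # profile never below half-max -> censored at the window edge
  flat <- manual_bout(10 - 0.01 * abs(rel), fr = fr, pre = pre)
  expect_true(attr(bout_duration_fwhm(flat), "censored"))
  expect_error(bout_duration_fwhm(manual_bout(rep(0, 75), pre = 41)),
               "peak")
})

test_that("displacement sums steps inside the super-threshold span", {
  fr <- 166
  pre <- 41; post <- 33; n <- pre + post + 1
  rel <- (-pre:post) / fr
  # straight horizontal run at constant speed 10 mm/s, span = whole window
  x <- (0:(n - 1)) * 10 / fr
  b <- manual_bout(rep(10, n), x = x, fr = fr, pre = pre)
  expect_equal(bout_displacement(b), (n - 1) * 10 / fr)

  # restricting the span cuts the summed steps accordingly
  b2 <- manual_bout(rep(10, n), x = x, fr = fr, pre = pre,
                    span = c(rel[11], rel[n - 10]))
  expect_equal(bout_displacement(b2), (n - 21) * 10 / fr)

  # curved path: independent brute-force step summation
  set.seed(31)
  for (k in 1:20) {
    xs <- cumsum(rnorm(n, 0, 0.1)); zs <- cumsum(rnorm(n, 0, 0.1))
    b3 <- manual_bout(rep(10, n), x = xs, z = zs, fr = fr, pre = pre)
    brute <- 0
    for (i in 2:n)
      brute <- brute + sqrt((xs[i] - xs[i - 1])^2 + (zs[i] - zs[i - 1])^2)
    expect_equal(bout_displacement(b3), brute)
  }
})

test_that("direction is the elevation at the peak with the left/right fold", {
  fr <- 166; pre <- 41; post <- 33; n <- pre + post + 1
  rel <- (-pre:post) / fr
  spd <- 10 * exp(-rel^2 / (2 * 0.05^2))
  up45 <- manual_bout(spd, x = (0:(n - 1)) * 0.05, z = (0:(n - 1)) * 0.05,
                      fr = fr, pre = pre)
  expect_equal(as.numeric(bout_direction(up45)), 45)
  flat <- manual_bout(spd, x = (0:(n - 1)) * 0.05, fr = fr, pre = pre)
  expect_equal(as.numeric(bout_direction(flat)), 0)
  # swimming leftwards maps to the same vertical direction
  left45 <- manual_bout(spd, x = -(0:(n - 1)) * 0.05,
                        z = (0:(n - 1)) * 0.05, fr = fr, pre = pre)
  expect_equal(as.numeric(bout_direction(left45)), 45)
  still <- manual_bout(spd, x = rep(0, n), fr = fr, pre = pre)
  expect_true(is.na(bout_direction(still)))
  expect_false(attr(bout_direction(still), "defined"))
})

test_that("rotation is the window endpoint pitch difference", {
  # at 200 Hz the window spans exactly -250..+200 ms, so a 10 deg/s ramp
  # gives 10 * 0.45 = 4.5 deg
  fr <- 200
  pre <- floor(0.25 * fr); post <- floor(0.20 * fr)
  rel <- (-pre:post) / fr
  n <- length(rel)
  spd <- 10 * exp(-rel^2 / (2 * 0.05^2))
  b <- manual_bout(spd, pitch = 10 * rel, fr = fr, pre = pre)
  expect_equal(bout_rotation(b), 4.5)
  expect_equal(bout_rotation(manual_bout(spd, pitch = rep(3, n),
                                         fr = fr, pre = pre)), 0)
})

test_that("ibi drift uses flanking window edges and is negative for nose-down drift", {
  fr <- 166; pre <- 41; post <- 33; n <- pre + post + 1
  spd <- 10 * exp(-((-pre:post) / fr)^2 / (2 * 0.05^2))
  b1 <- manual_bout(spd, pitch = seq(5, 4, length.out = n), fr = fr, pre = pre)
  b2 <- manual_bout(spd, pitch = seq(-2, 0, length.out = n), fr = fr, pre = pre)
  expect_equal(ibi_drift(b1, b2), -2 - 4)
  expect_equal(ibi_drift(b1, b1), 5 - 4)

  # generator with nose-down drift: median measured drift < 0
  rec <- generate_recording(swimmer_params(duration_h = 0.2, seed = 9))
  seg <- seg_of(rec)
  expect_lt(median(seg$ibis$drift_deg), 0)
  # programmed drift: -3 deg/s over the inter-window gap (noise-free)
  rec2 <- generate_recording(swimmer_params(
    duration_h = 0.2, seed = 10,
    dark = strategy_params(drift_rate = 3, drift_noise = 0,
                           rotation_noise = 0, peak_speed_mean = 15,
                           peak_speed_cv = 0.1)))
  seg2 <- seg_of(rec2)
  # drift ~ -3 * (window gap); compare against the generator's own truth
  rep <- truth_vs_pipeline(rec2, seg2)
  pd <- rep$recovery[rep$recovery$parameter == "prev_drift", ]
  expect_lt(pd$rmse, 0.15)
})

test_that("noise-free synthetic bouts recover all parameters at ground truth", {
  p <- swimmer_params(duration_h = 0.2, seed = 12, x_jitter = 0,
                      dark = strategy_params(drift_noise = 0,
                                             rotation_noise = 0,
                                             peak_speed_mean = 15,
                                             peak_speed_cv = 0.1))
  rec <- generate_recording(p)
  seg <- seg_of(rec)
  rep <- truth_vs_pipeline(rec, seg)
  expect_equal(rep$n_false, 0)
  expect_equal(rep$n_missed, 0)
  rc <- rep$recovery
  get <- function(p, f) rc[rc$parameter == p, f]
  expect_lt(get("fwhm_ms", "rmse"), 1000 / rec$meta$frame_rate)
  expect_lt(get("direction", "rmse"), 1e-6)
  expect_lt(get("rotation", "rmse"), 1e-2)
  expect_lt(get("peak_time", "rmse"), 2 / rec$meta$frame_rate)
})

test_that("kinematics respect mirror symmetries", {
  rec <- generate_recording(swimmer_params(duration_h = 0.1, seed = 13))
  tr <- rec$tracks[[1]]
  seg <- segment_epoch(tr, rec$meta)
  mirror_x <- track_series(tr$epoch_id, tr$t, -tr$x, tr$z, tr$pitch,
                           tr$frame_rate)
  seg_mx <- segment_epoch(attach_clock(mirror_x, rec$meta), rec$meta)
  expect_equal(seg_mx$bouts$displacement_mm, seg$bouts$displacement_mm)
  expect_equal(seg_mx$bouts$direction_deg, seg$bouts$direction_deg)
  expect_equal(seg_mx$bouts$rotation_deg, seg$bouts$rotation_deg)
  # vertical mirror flips direction sign (pitch convention flips with it)
  mirror_z <- track_series(tr$epoch_id, tr$t, tr$x, -tr$z, -tr$pitch,
                           tr$frame_rate)
  seg_mz <- segment_epoch(attach_clock(mirror_z, rec$meta), rec$meta)
  expect_equal(seg_mz$bouts$direction_deg, -seg$bouts$direction_deg)
})

test_that("FWHM does not exceed the super-threshold span for strong bouts", {
  rec <- generate_recording(swimmer_params(
    duration_h = 0.2, seed = 14,
    dark = strategy_params(peak_speed_mean = 15, peak_speed_cv = 0.1)))
  seg <- seg_of(rec)
  b <- seg$bouts
  strong <- b$peak_speed >= 2 * seg$threshold & !b$fwhm_censored
  span_ms <- (b$span_end - b$span_start) * 1000
  expect_true(all(b$duration_fwhm_ms[strong] <=
                  span_ms[strong] + 2000 / seg$frame_rate))
})
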
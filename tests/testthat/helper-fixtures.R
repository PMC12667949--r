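# Small deterministic fixtures shared across test files.

# Track whose speed is a single smooth pulse: x advances with a Gaussian
# speed profile of peak `peak` mm/s and FWHM `fwhm_ms`, centered mid-epoch.
pulse_track <- function(peak = 12, fwhm_ms = 120, fr = 166, dur_s = 2,
                        epoch_id = "p1") {
  n <- round(dur_s * fr) + 1
  t <- (0:(n - 1)) / fr
  sigma <- fwhm_ms / 1000 / (2 * sqrt(2 * log(2)))
  v <- peak * exp(-((t - dur_s / 2)^2) / (2 * sigma^2))
  x <- cumsum(v) / fr
  track_series(epoch_id, t, x, rep(0, n), rep(0, n), fr)
}

# Track from an explicit speed trace (pure horizontal motion).
speed_track <- function(speed, fr = 166, epoch_id = "s1") {
  x <- cumsum(speed) / fr
  n <- length(speed)
  track_series(epoch_id, (0:(n - 1)) / fr, x, rep(0, n), rep(0, n), fr)
}

# A swim_bout built directly from window traces (no segmentation), for
# analytic kinematics checks. rel_t follows the -pre..+post frame grid.
manual_bout <- function(speed, pitch = NULL, x = NULL, z = NULL, fr = 166,
                        pre = NULL, span = NULL, threshold = 5) {
  n <- length(speed)
  if (is.null(pre)) pre <- which.max(speed) - 1L
  rel_t <- ((0:(n - 1)) - pre) / fr
  if (is.null(pitch)) pitch <- rep(0, n)
  if (is.null(x)) x <- rel_t * 0
  if (is.null(z)) z <- rep(0, n)
  if (is.null(span)) span <- range(rel_t)
  structure(list(epoch_id = "m", peak_time = 0, rel_t = rel_t,
                 speed = speed, pitch = pitch, x = x, z = z,
                 span_start = span[1], span_end = span[2],
                 frame_rate = fr, threshold = threshold),
            class = "swim_bout")
}

default_meta <- function(...) recording_meta(condition = "LD", ...)

# Fast standard segmentation of a synthetic recording.
seg_of <- function(rec, ...) {
  segment_recording(rec$tracks, rec$meta, keep_windows = TRUE, ...)
}
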
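# Core per-window kinematics. Each .kin_* works on raw window vectors so the
# exported per-bout accessors and the vectorized segmentation path share one
# implementation.

.kin_fwhm <- function(rel_t, speed, pre) {
  p0 <- pre + 1L
  pk <- speed[p0]
  if (!is.finite(pk) || pk <= 0) stop("non-positive peak speed")
  half <- pk / 2
  n <- length(speed)
  # left: last sub-half sample before the peak
  left <- which(speed[seq_len(p0 - 1L)] < half)
  if (length(left)) {
    j <- max(left)
    frac <- (half - speed[j]) / (speed[j + 1L] - speed[j])
    t_left <- rel_t[j] + frac * (rel_t[j + 1L] - rel_t[j])
    cens_l <- FALSE
  } else {
    t_left <- rel_t[1L]; cens_l <- TRUE
  }
  right <- which(speed[(p0 + 1L):n] < half)
  if (length(right)) {
    j <- p0 + min(right)          # first sub-half sample after the peak
    frac <- (speed[j - 1L] - half) / (speed[j - 1L] - speed[j])
    t_right <- rel_t[j - 1L] + frac * (rel_t[j] - rel_t[j - 1L])
    cens_r <- FALSE
  } else {
    t_right <- rel_t[n]; cens_r <- TRUE
  }
  c(fwhm_ms = (t_right - t_left) * 1000, censored = cens_l || cens_r)
}

.kin_displacement <- function(x, z, in_span) {
  idx <- which(in_span)
  if (length(idx) < 2) return(0)
  # steps between consecutive retained frames (runs are contiguous, but a
  # merged run may bridge a sub-threshold dip; all frames in the span count)
  i <- idx[-length(idx)]
  j <- idx[-1L]
  sum(sqrt((x[j] - x[i])^2 + (z[j] - z[i])^2))
}

.kin_direction <- function(x, z, pre) {
  p0 <- pre + 1L
  dx <- x[p0 + 1L] - x[p0 - 1L]
  dz <- z[p0 + 1L] - z[p0 - 1L]
  if (dx == 0 && dz == 0) return(c(dir = NA_real_, defined = FALSE))
  c(dir = atan2(dz, abs(dx)) * 180 / pi, defined = TRUE)
}

.kin_rotation <- function(pitch) pitch[length(pitch)] - pitch[1L]

# Vectorized kinematics over the window matrices of one epoch.
.window_kinematics <- function(W, runs, track, speed, params, pre) {
  nb <- nrow(runs)
  rel_t <- W$rel_t
  nwin <- length(rel_t)
  peak_t <- track$t[runs$peak]
  fw <- matrix(0, nb, 2)
  disp <- numeric(nb)
  dir <- matrix(0, nb, 2)
  rot <- numeric(nb)
  for (i in seq_len(nb)) {
    fw[i, ] <- .kin_fwhm(rel_t, W$speed[i, ], pre)
    t_abs <- peak_t[i] + rel_t
    in_span <- t_abs >= track$t[runs$start[i]] - 1e-9 &
               t_abs <= track$t[runs$end[i]] + 1e-9
    disp[i] <- .kin_displacement(W$x[i, ], W$z[i, ], in_span)
    dir[i, ] <- .kin_direction(W$x[i, ], W$z[i, ], pre)
    rot[i] <- .kin_rotation(W$pitch[i, ])
  }
  data.frame(peak_speed = W$speed[cbind(seq_len(nb), rep(pre + 1L, nb))],
             duration_fwhm_ms = fw[, 1], fwhm_censored = as.logical(fw[, 2]),
             displacement_mm = disp,
             direction_deg = dir[, 1], direction_defined = as.logical(dir[, 2]),
             rotation_deg = rot)
}

#' Bout duration: full width at half maximum of the speed profile
#'
#' The duration for which speed stays above half its peak, with the two
#' half-maximum crossings located by linear interpolation between the
#' straddling frames. If the profile never falls below half-maximum within
#' the window on one side, the window edge is used and the bout is flagged
#' censored (attribute `censored`).
#'
#' @param bout A `swim_bout` (see [swim_bout()]).
#' @return Duration in ms, with logical attribute `censored`.
#' @export
bout_duration_fwhm <- function(bout) {
  stopifnot(inherits(bout, "swim_bout"))
  pre <- sum(bout$rel_t < 0)
  v <- .kin_fwhm(bout$rel_t, bout$speed, pre)
  structure(unname(v["fwhm_ms"]), censored = as.logical(v["censored"]))
}

#' Bout displacement: path length while speed exceeds the threshold
#'
#' Sum of per-frame Euclidean step lengths over the frames inside the bout's
#' super-threshold span.
#'
#' @param bout A `swim_bout`.
#' @return Displacement in mm (non-negative).
#' @export
bout_displacement <- function(bout) {
  stopifnot(inherits(bout, "swim_bout"))
  t_abs <- bout$peak_time + bout$rel_t
  in_span <- t_abs >= bout$span_start - 1e-9 & t_abs <= bout$span_end + 1e-9
  .kin_displacement(bout$x, bout$z, in_span)
}

#' Bout direction: elevation of the trajectory at peak speed
#'
#' Elevation angle `atan2(dz, |dx|)` in degrees of the centrally differenced
#' velocity at the peak frame; positive is upward. The absolute value of the
#' horizontal component maps left- and right-swimming fish onto the same
#' vertical-direction convention.
#'
#' @param bout A `swim_bout`.
#' @return Direction in degrees in `[-90, 90]`; `NA` with attribute
#'   `defined = FALSE` when there is zero net motion at the peak.
#' @export
bout_direction <- function(bout) {
  stopifnot(inherits(bout, "swim_bout"))
  pre <- sum(bout$rel_t < 0)
  v <- .kin_direction(bout$x, bout$z, pre)
  structure(unname(v["dir"]), defined = as.logical(v["defined"]))
}

#' Bout rotation: net pitch change across the bout window
#'
#' Pitch at the window end (+200 ms by default) minus pitch at the window
#' start (-250 ms); nose-up positive.
#'
#' @param bout A `swim_bout`.
#' @return Rotation in degrees.
#' @export
bout_rotation <- function(bout) {
  stopifnot(inherits(bout, "swim_bout"))
  .kin_rotation(bout$pitch)
}

#' Inter-bout-interval postural drift
#'
#' Pitch at the start of the following bout's window minus pitch at the end
#' of the preceding bout's window; the passive nose-down drift between two
#' bouts yields negative values. Already computed per IBI by
#' [segment_epoch()]; this accessor recomputes it from the two flanking
#' `swim_bout` windows.
#'
#' @param prev_bout,next_bout The flanking `swim_bout`s.
#' @return Drift in degrees (signed, nose-down negative).
#' @export
ibi_drift <- function(prev_bout, next_bout) {
  stopifnot(inherits(prev_bout, "swim_bout"), inherits(next_bout, "swim_bout"))
  next_bout$pitch[1L] - prev_bout$pitch[length(prev_bout$pitch)]
}
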
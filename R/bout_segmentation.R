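#' Segmentation parameters
#'
#' @param threshold Speed threshold for bout detection, mm/s.
#' @param smooth_window Centered moving-average width in frames (odd, >= 1)
#'   applied to the speed trace before detection.
#' @param min_duration_s Minimum super-threshold run length in seconds; runs
#'   shorter than this are discarded as single-frame noise crossings.
#' @param merge_gap_s Sub-threshold gaps shorter than this (strictly) between
#'   two runs are bridged and the runs merged.
#' @param window_pre_s,window_post_s Extent of the peak-aligned bout window
#'   before and after the peak, seconds. The defaults span -250 ms to
#'   +200 ms, the span over which bout rotation is defined.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold = 5, smooth_window = 3,
                                min_duration_s = 3 / 166,
                                merge_gap_s = 0.050,
                                window_pre_s = 0.250, window_post_s = 0.200) {
  stopifnot(threshold > 0, smooth_window >= 1, smooth_window %% 2 == 1,
            min_duration_s >= 0, merge_gap_s >= 0,
            window_pre_s > 0, window_post_s > 0)
  structure(list(threshold = threshold, smooth_window = smooth_window,
                 min_duration_s = min_duration_s, merge_gap_s = merge_gap_s,
                 window_pre_s = window_pre_s, window_post_s = window_post_s),
            class = "segmentation_params")
}

#' Number of window frames before/after the peak at a given frame rate
#'
#' The window grid has `floor(pre * fr) + floor(post * fr) + 1` samples; at
#' 166 Hz with the default -250/+200 ms span this is 41 + 33 + 1 = 75.
#' @param frame_rate Hz.
#' @param params A `segmentation_params`.
#' @return Integer vector `c(pre, post)` of frame counts.
#' @export
window_frames <- function(frame_rate, params = segmentation_params()) {
  c(pre = floor(params$window_pre_s * frame_rate),
    post = floor(params$window_post_s * frame_rate))
}

#' Compute swim speed from positions
#'
#' Speed is the magnitude of the centrally differenced planar velocity,
#' `frame_rate * sqrt(dx^2 + dz^2) / 2` with `dx = x[i+1] - x[i-1]`
#' (one-sided differences at the endpoints), optionally smoothed by a
#' centered moving average.
#'
#' @param track A `track_series`.
#' @param smooth_window Odd moving-average width in frames; 1 disables
#'   smoothing.
#' @return Numeric vector of speeds (mm/s), same length as the track.
#' @export
compute_speed <- function(track, smooth_window = 3) {
  validate_track(track)
  if (smooth_window < 1 || smooth_window %% 2 != 1)
    stop("smooth_window must be odd and >= 1")
  n <- length(track$t)
  if (n < smooth_window) stop("epoch shorter than smooth_window")
  fr <- track$frame_rate
  x <- track$x; z <- track$z
  sp <- numeric(n)
  if (n > 2) {
    i <- 2:(n - 1)
    sp[i] <- fr * sqrt((x[i + 1] - x[i - 1])^2 + (z[i + 1] - z[i - 1])^2) / 2
  }
  sp[1] <- fr * sqrt((x[2] - x[1])^2 + (z[2] - z[1])^2)
  sp[n] <- fr * sqrt((x[n] - x[n - 1])^2 + (z[n] - z[n - 1])^2)
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(sp, k, sides = 2)
    # keep raw values where the centered window does not fit
    sm <- as.numeric(sm)
    bad <- is.na(sm)
    sm[bad] <- sp[bad]
    sp <- sm
  }
  sp
}

#' Detect swim bouts as super-threshold runs of the speed trace
#'
#' Maximal runs with `speed > threshold` are found; two runs separated by a
#' sub-threshold gap strictly shorter than `merge_gap_s` are merged; runs
#' shorter than `min_duration_s` are discarded. Each surviving run gets one
#' peak, the earliest index attaining the run maximum. Runs whose
#' peak-aligned window would cross the epoch boundary are flagged truncated.
#'
#' @param speed Numeric speed trace (mm/s).
#' @param frame_rate Hz.
#' @param params A `segmentation_params`.
#' @return A data.frame with integer columns `start`, `end`, `peak` (frame
#'   indices, inclusive run bounds) and logical `truncated`, ordered by time.
#' @export
detect_bouts <- function(speed, frame_rate, params = segmentation_params()) {
  above <- speed > params$threshold
  n <- length(above)
  if (!any(above))
    return(data.frame(start = integer(0), end = integer(0),
                      peak = integer(0), truncated = logical(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs across short sub-threshold gaps
  if (nrow(runs) > 1 && params$merge_gap_s > 0) {
    gap_frames <- (runs$start[-1] - runs$end[-nrow(runs)] - 1L) / frame_rate
    keep_start <- c(TRUE, gap_frames >= params$merge_gap_s)
    grp <- cumsum(keep_start)
    runs <- data.frame(start = tapply(runs$start, grp, min),
                       end = tapply(runs$end, grp, max))
  }
  dur <- (runs$end - runs$start + 1L) / frame_rate
  runs <- runs[dur >= params$min_duration_s, , drop = FALSE]
  if (nrow(runs) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      peak = integer(0), truncated = logical(0)))
  runs$peak <- vapply(seq_len(nrow(runs)), function(i) {
    seg <- speed[runs$start[i]:runs$end[i]]
    runs$start[i] + which.max(seg) - 1L   # which.max: earliest on ties
  }, integer(1))
  wf <- window_frames(frame_rate, params)
  runs$truncated <- runs$peak - wf[["pre"]] < 1L | runs$peak + wf[["post"]] > n
  rownames(runs) <- NULL
  runs[order(runs$start), , drop = FALSE]
}

#' Segment one epoch into swim bouts and inter-bout intervals
#'
#' Builds the peak-aligned bout window for every non-truncated detected run
#' and the inter-bout intervals (IBIs) between consecutive non-truncated
#' bouts. IBI duration is the time from the end of the previous bout's
#' super-threshold run to the start of the next run; IBI drift is the pitch
#' difference between the following bout's window start and the preceding
#' bout's window end, so bout rotation and IBI drift tile the pitch
#' trajectory without overlap.
#'
#' @param track A `track_series` (with `clock_t` attached for phase labels).
#' @param meta A `recording_meta` (phase assignment); may be `NULL`, in which
#'   case phases are `NA`.
#' @param params A `segmentation_params`.
#' @param keep_windows Retain the per-bout window matrices (speed, pitch, x,
#'   z) in the result. Required by the per-bout kinematics accessors; can be
#'   disabled to save memory on very long recordings once kinematics are
#'   computed.
#' @return A list of class `segmentation` with elements:
#'   \describe{
#'     \item{bouts}{data.frame, one row per emitted bout: `epoch_id`,
#'       `bout_id`, `peak_time`, `peak_clock`, `phase`, `span_start`,
#'       `span_end` (super-threshold run bounds, s), kinematics columns
#'       (`peak_speed`, `duration_fwhm_ms`, `fwhm_censored`,
#'       `displacement_mm`, `direction_deg`, `direction_defined`,
#'       `rotation_deg`), and `prev_ibi` / `next_ibi` row indices into
#'       `ibis` (NA when absent).}
#'     \item{ibis}{data.frame, one row per IBI: `epoch_id`, `duration_s`,
#'       `drift_deg`, `start_pitch`, `end_pitch`, `phase` (from the midpoint
#'       clock time), `prev_bout`, `next_bout` row indices into `bouts`.}
#'     \item{windows}{list of matrices `speed`, `pitch`, `x`, `z` (bout rows
#'       by window frames) and the relative time grid `rel_t`; `NULL` when
#'       `keep_windows = FALSE`.}
#'     \item{n_truncated}{count of detected runs excluded as truncated.}
#'   }
#' @export
segment_epoch <- function(track, meta = NULL, params = segmentation_params(),
                          keep_windows = TRUE) {
  validate_track(track)
  fr <- track$frame_rate
  speed <- compute_speed(track, params$smooth_window)
  runs <- detect_bouts(speed, fr, params)
  wf <- window_frames(fr, params)
  pre <- wf[["pre"]]; post <- wf[["post"]]
  keep <- !runs$truncated
  n_trunc <- sum(runs$truncated)
  runs <- runs[keep, , drop = FALSE]
  nb <- nrow(runs)
  rel_t <- (-pre:post) / fr

  empty <- function() {
    list(bouts = data.frame(), ibis = data.frame(),
         windows = NULL, n_truncated = n_trunc, rel_t = rel_t,
         frame_rate = fr, threshold = params$threshold)
  }
  if (nb == 0) return(structure(empty(), class = "segmentation"))

  idx <- outer(runs$peak, -pre:post, `+`)   # nb x nwin frame indices
  W <- list(speed = matrix(speed[idx], nb),
            pitch = matrix(track$pitch[idx], nb),
            x = matrix(track$x[idx], nb),
            z = matrix(track$z[idx], nb),
            rel_t = rel_t)

  peak_time <- track$t[runs$peak]
  peak_clock <- if (!is.null(track$clock_t)) track$clock_t[runs$peak]
                else rep(NA_real_, nb)
  phase <- if (!is.null(meta) && !all(is.na(peak_clock)))
    assign_phase(peak_clock, meta) else rep(NA_character_, nb)

  kin <- .window_kinematics(W, runs, track, speed, params, pre)

  bouts <- data.frame(
    epoch_id = track$epoch_id, bout_id = seq_len(nb),
    peak_time = peak_time, peak_clock = peak_clock, phase = phase,
    span_start = track$t[runs$start], span_end = track$t[runs$end],
    kin,
    prev_ibi = c(NA_integer_, seq_len(nb - 1L)),
    next_ibi = c(seq_len(nb - 1L), NA_integer_),
    stringsAsFactors = FALSE)

  if (nb >= 2) {
    i <- seq_len(nb - 1L)
    # pitch at window edges of the flanking bouts
    end_pitch_prev <- W$pitch[i, pre + 1L + post]
    start_pitch_next <- W$pitch[i + 1L, 1L]
    mid_clock <- if (!all(is.na(peak_clock)))
      ((peak_clock[i] + ((track$t[runs$start[i + 1L]] +
                          track$t[runs$end[i]]) / 2 - peak_time[i]) / 3600)
       %% 24) else rep(NA_real_, nb - 1L)
    ibis <- data.frame(
      epoch_id = track$epoch_id,
      duration_s = track$t[runs$start[i + 1L]] - track$t[runs$end[i]],
      drift_deg = start_pitch_next - end_pitch_prev,
      start_pitch = end_pitch_prev, end_pitch = start_pitch_next,
      phase = if (!is.null(meta) && !all(is.na(mid_clock)))
        assign_phase(mid_clock, meta) else NA_character_,
      prev_bout = i, next_bout = i + 1L,
      stringsAsFactors = FALSE)
  } else {
    ibis <- data.frame()
  }

  structure(list(bouts = bouts, ibis = ibis,
                 windows = if (keep_windows) W else NULL,
                 n_truncated = n_trunc, rel_t = rel_t, frame_rate = fr,
                 threshold = params$threshold),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d bouts, %d IBIs, %d truncated run(s)\n",
              nrow(x$bouts), nrow(x$ibis), x$n_truncated))
  invisible(x)
}

#' Extract one peak-aligned swim bout from a segmentation
#'
#' @param seg A `segmentation` built with `keep_windows = TRUE`.
#' @param i Bout row index.
#' @return A list of class `swim_bout` with the window traces (`rel_t`,
#'   `speed`, `pitch`, `x`, `z`), the super-threshold span, frame rate and
#'   detection threshold.
#' @export
swim_bout <- function(seg, i) {
  if (is.null(seg$windows)) stop("segmentation was built without windows")
  b <- seg$bouts[i, ]
  structure(list(epoch_id = b$epoch_id, peak_time = b$peak_time,
                 rel_t = seg$rel_t,
                 speed = seg$windows$speed[i, ],
                 pitch = seg$windows$pitch[i, ],
                 x = seg$windows$x[i, ], z = seg$windows$z[i, ],
                 span_start = b$span_start, span_end = b$span_end,
                 frame_rate = seg$frame_rate, threshold = seg$threshold),
            class = "swim_bout")
}

#' Segment every epoch of a recording
#'
#' Applies [segment_epoch()] to each track and concatenates the bout and IBI
#' tables, re-indexing the bout/IBI cross-links and adding recording metadata
#' columns (`condition`, `repeat_id`, `group_label`).
#'
#' @param tracks List of `track_series`.
#' @param meta A `recording_meta`.
#' @param params A `segmentation_params`.
#' @param keep_windows Retain window matrices (per epoch, concatenated).
#' @return A `segmentation` spanning all epochs.
#' @export
segment_recording <- function(tracks, meta, params = segmentation_params(),
                              keep_windows = FALSE) {
  segs <- lapply(tracks, segment_epoch, meta = meta, params = params,
                 keep_windows = keep_windows)
  bout_off <- 0L; ibi_off <- 0L
  bouts <- list(); ibis <- list(); wins <- list()
  n_trunc <- 0L
  for (s in segs) {
    n_trunc <- n_trunc + s$n_truncated
    if (nrow(s$bouts) > 0) {
      b <- s$bouts
      b$bout_id <- b$bout_id + bout_off
      b$prev_ibi <- b$prev_ibi + ibi_off
      b$next_ibi <- b$next_ibi + ibi_off
      bouts[[length(bouts) + 1L]] <- b
      if (keep_windows) wins[[length(wins) + 1L]] <- s$windows
    }
    if (nrow(s$ibis) > 0) {
      ib <- s$ibis
      ib$prev_bout <- ib$prev_bout + bout_off
      ib$next_bout <- ib$next_bout + bout_off
      ibis[[length(ibis) + 1L]] <- ib
    }
    bout_off <- bout_off + nrow(s$bouts)
    ibi_off <- ibi_off + nrow(s$ibis)
  }
  bouts <- if (length(bouts)) do.call(rbind, bouts) else data.frame()
  ibis <- if (length(ibis)) do.call(rbind, ibis) else data.frame()
  if (nrow(bouts) > 0) {
    bouts$condition <- meta$condition
    bouts$repeat_id <- meta$repeat_id
    bouts$group_label <- meta$group_label
  }
  if (nrow(ibis) > 0) {
    ibis$condition <- meta$condition
    ibis$repeat_id <- meta$repeat_id
    ibis$group_label <- meta$group_label
  }
  W <- NULL
  if (keep_windows && length(wins)) {
    W <- list(speed = do.call(rbind, lapply(wins, `[[`, "speed")),
              pitch = do.call(rbind, lapply(wins, `[[`, "pitch")),
              x = do.call(rbind, lapply(wins, `[[`, "x")),
              z = do.call(rbind, lapply(wins, `[[`, "z")),
              rel_t = wins[[1]]$rel_t)
  }
  rel_t <- if (length(segs)) segs[[1]]$rel_t else numeric(0)
  fr <- if (length(segs)) segs[[1]]$frame_rate else meta$frame_rate
  structure(list(bouts = bouts, ibis = ibis, windows = W,
                 n_truncated = n_trunc, rel_t = rel_t, frame_rate = fr,
                 threshold = params$threshold),
            class = "segmentation")
}
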
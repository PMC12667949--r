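#' Construct a pose track series for one continuous tracking epoch
#'
#' A track series holds a uniformly sampled side-view pose record for a single
#' continuous tracking epoch: time, horizontal position, vertical position and
#' pitch angle. Epochs end whenever tracking is interrupted (a fish leaving
#' the field of view, a feeding pause); no interpolation is ever done across
#' epoch boundaries.
#'
#' @param epoch_id Identifier of the epoch (coerced to character).
#' @param t Numeric vector, seconds since recording start, on a uniform grid.
#' @param x Numeric vector, horizontal position in mm.
#' @param z Numeric vector, vertical position in mm (up positive).
#' @param pitch Numeric vector, body pitch angle in degrees relative to
#'   horizontal (nose-up positive).
#' @param frame_rate Sampling rate in Hz.
#' @param clock_t Optional numeric vector of wall-clock times (hours, in
#'   `[0, 24)`) for each sample. Computed from `recording_start_clock` when a
#'   [recording_meta()] is available via [attach_clock()].
#'
#' @return An object of class `track_series`.
#' @export
track_series <- function(epoch_id, t, x, z, pitch, frame_rate, clock_t = NULL) {
  ts <- structure(
    list(epoch_id = as.character(epoch_id)[1], t = as.numeric(t),
         x = as.numeric(x), z = as.numeric(z), pitch = as.numeric(pitch),
         frame_rate = as.numeric(frame_rate)[1], clock_t = clock_t),
    class = "track_series")
  validate_track(ts)
  ts
}

#' Validate a track series against its structural invariants
#'
#' Checks uniform sampling (consecutive times differ by `1/frame_rate` within
#' `tol`), absence of missing values, equal field lengths, a positive frame
#' rate and at least two samples.
#'
#' @param ts A `track_series`.
#' @param tol Tolerance in seconds on the sampling interval.
#' @return `ts`, invisibly. Throws an error describing the first violated
#'   invariant otherwise.
#' @export
validate_track <- function(ts, tol = 1e-6) {
  stopifnot(inherits(ts, "track_series"))
  n <- length(ts$t)
  if (n < 2L) stop("epoch '", ts$epoch_id, "': needs >= 2 samples")
  if (!is.finite(ts$frame_rate) || ts$frame_rate <= 0)
    stop("epoch '", ts$epoch_id, "': frame_rate must be > 0")
  for (f in c("x", "z", "pitch")) {
    if (length(ts[[f]]) != n)
      stop("epoch '", ts$epoch_id, "': field '", f, "' length mismatch")
    if (anyNA(ts[[f]]) || any(!is.finite(ts[[f]])))
      stop("epoch '", ts$epoch_id, "': missing values in '", f, "'")
  }
  if (anyNA(ts$t)) stop("epoch '", ts$epoch_id, "': missing values in 't'")
  dt <- diff(ts$t)
  if (any(abs(dt - 1 / ts$frame_rate) > tol))
    stop("epoch '", ts$epoch_id, "': non-uniform sampling beyond tolerance")
  invisible(ts)
}

#' @export
print.track_series <- function(x, ...) {
  cat(sprintf("<track_series> epoch '%s': %d frames @ %.4g Hz (%.1f s)\n",
              x$epoch_id, length(x$t), x$frame_rate,
              length(x$t) / x$frame_rate))
  invisible(x)
}

#' Recording metadata
#'
#' Describes one recording: the photoperiod condition, identifiers, the light
#' schedule and the clock-anchored analysis window. Light-schedule clocks use
#' decimal hours in `[0, 24)` with midnight = 0.
#'
#' @param condition One of `"DD"`, `"LD"`, `"LL"` (constant dark, light/dark
#'   cycle, constant light). For DD and LL the schedule clocks define
#'   zeitgeber (circadian) day and night even though illumination is constant.
#' @param repeat_id Experimental repeat identifier.
#' @param box_id Apparatus identifier.
#' @param group_label Free-text group label (e.g. "wild-type", "lesion").
#' @param lights_on_clock,lights_off_clock Schedule clocks in hours; defaults
#'   9.0 and 23.0 (lights on 9 a.m. to 11 p.m.).
#' @param frame_rate Acquisition rate in Hz (default 166).
#' @param recording_start_clock Clock time (hours) of sample `t = 0`.
#' @param analysis_window Length-2 numeric, hours since recording start
#'   delimiting the analysis span (default `c(0, 48)`).
#' @return An object of class `recording_meta`.
#' @export
recording_meta <- function(condition = c("DD", "LD", "LL"), repeat_id = "r1",
                           box_id = "b1", group_label = "wild-type",
                           lights_on_clock = 9, lights_off_clock = 23,
                           frame_rate = 166, recording_start_clock = 10,
                           analysis_window = c(0, 48)) {
  condition <- match.arg(condition)
  if (!(lights_on_clock >= 0 && lights_on_clock < lights_off_clock &&
        lights_off_clock <= 24))
    stop("require 0 <= lights_on_clock < lights_off_clock <= 24")
  structure(
    list(condition = condition, repeat_id = as.character(repeat_id),
         box_id = as.character(box_id), group_label = as.character(group_label),
         lights_on_clock = lights_on_clock, lights_off_clock = lights_off_clock,
         frame_rate = frame_rate,
         recording_start_clock = recording_start_clock,
         analysis_window = analysis_window),
    class = "recording_meta")
}

#' @export
print.recording_meta <- function(x, ...) {
  cat(sprintf("<recording_meta> %s repeat=%s box=%s group=%s lights %g-%g h\n",
              x$condition, x$repeat_id, x$box_id, x$group_label,
              x$lights_on_clock, x$lights_off_clock))
  invisible(x)
}

#' Attach wall-clock timestamps to a track series
#'
#' @param ts A `track_series`.
#' @param meta A `recording_meta` supplying `recording_start_clock`.
#' @return `ts` with the `clock_t` field populated (hours, wrapped to
#'   `[0, 24)`).
#' @export
attach_clock <- function(ts, meta) {
  ts$clock_t <- (meta$recording_start_clock + ts$t / 3600) %% 24
  ts
}

#' Classify clock times into day, night, or transition phase
#'
#' Transition covers the hour before and after each day-night boundary
#' (modulo 24 h); within the remainder, day is the lights-on span
#' `[lights_on, lights_off)` and night its complement. The same labels apply
#' to zeitgeber time under constant conditions (DD, LL), where "day" means
#' circadian day.
#'
#' @param clock_t Numeric vector of clock times in hours, each in `[0, 24)`.
#' @param meta A `recording_meta`.
#' @return Character vector with values `"day"`, `"night"`, `"transition"`.
#' @export
assign_phase <- function(clock_t, meta) {
  if (any(clock_t < 0 | clock_t >= 24, na.rm = TRUE))
    stop("clock_t must lie in [0, 24)")
  # transition = [boundary - 1, boundary + 1): half-open towards later times
  near <- function(b) {
    d <- (clock_t - (b - 1)) %% 24
    d >= 0 & d < 2
  }
  trans <- near(meta$lights_on_clock) | near(meta$lights_off_clock)
  day <- clock_t >= meta$lights_on_clock & clock_t < meta$lights_off_clock
  out <- ifelse(trans, "transition", ifelse(day, "day", "night"))
  out[is.na(clock_t)] <- NA_character_
  out
}

.track_csv_header <- "epoch_id,t,x,z,pitch"
.track_schema_version <- "swimbout-track-v1"

#' Write pose tracks to a CSV file with a YAML metadata sidecar
#'
#' The CSV has columns `epoch_id,t,x,z,pitch` preceded by a schema-version
#' comment line; numeric values are written with 17 significant digits so a
#' read/write round trip is bitwise exact. Metadata is written to
#' `<path>.yaml`.
#'
#' @param tracks A list of `track_series` (may be empty).
#' @param meta A `recording_meta`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, meta, path) {
  stopifnot(inherits(meta, "recording_meta"))
  for (ts in tracks) validate_track(ts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .track_schema_version), con)
  writeLines(.track_csv_header, con)
  for (ts in tracks) {
    lines <- sprintf("%s,%.17g,%.17g,%.17g,%.17g",
                     ts$epoch_id, ts$t, ts$x, ts$z, ts$pitch)
    writeLines(lines, con)
  }
  side <- list(schema = .track_schema_version,
               condition = meta$condition, repeat_id = meta$repeat_id,
               box_id = meta$box_id, group_label = meta$group_label,
               lights_on = meta$lights_on_clock,
               lights_off = meta$lights_off_clock,
               frame_rate = meta$frame_rate,
               recording_start_clock = meta$recording_start_clock,
               analysis_window = as.numeric(meta$analysis_window))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' Read pose tracks from a CSV file written by [write_tracks()]
#'
#' Epochs violating the track invariants (missing values, non-uniform
#' sampling) are rejected individually with a reported reason rather than
#' silently dropped; valid epochs are returned in time order.
#'
#' @param path CSV path; the YAML sidecar `<path>.yaml` must exist.
#' @param tol Sampling-uniformity tolerance in seconds.
#' @return A list with elements `tracks` (list of `track_series`, clock times
#'   attached), `meta` (`recording_meta`) and `rejected` (data.frame of
#'   epoch_id, reason for every rejected epoch).
#' @export
read_tracks <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path)
  side_path <- paste0(path, ".yaml")
  if (!file.exists(side_path)) stop("missing metadata sidecar: ", side_path)
  side <- yaml::read_yaml(side_path)
  req <- c("condition", "repeat_id", "frame_rate", "recording_start_clock")
  miss <- setdiff(req, names(side))
  if (length(miss))
    stop("metadata sidecar missing field(s): ", paste(miss, collapse = ", "))
  meta <- recording_meta(
    condition = side$condition, repeat_id = side$repeat_id,
    box_id = side$box_id %||% "b1",
    group_label = side$group_label %||% "wild-type",
    lights_on_clock = side$lights_on %||% 9,
    lights_off_clock = side$lights_off %||% 23,
    frame_rate = side$frame_rate,
    recording_start_clock = side$recording_start_clock,
    analysis_window = side$analysis_window %||% c(0, 48))

  dt <- data.table::fread(path, skip = "epoch_id,t", header = TRUE,
                          na.strings = c("NA", "NaN", ""))
  need <- c("epoch_id", "t", "x", "z", "pitch")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("track schema error: missing column(s): ", paste(miss, collapse = ", "))

  tracks <- list()
  rej_id <- character(0); rej_reason <- character(0)
  if (nrow(dt) > 0) {
    first_t <- vapply(split(dt$t, dt$epoch_id), function(v) v[1], 0)
    for (eid in names(sort(first_t))) {
      sub <- dt[dt$epoch_id == eid, ]
      ts <- try(track_series(eid, sub$t, sub$x, sub$z, sub$pitch,
                             meta$frame_rate), silent = TRUE)
      if (inherits(ts, "try-error")) {
        rej_id <- c(rej_id, eid)
        rej_reason <- c(rej_reason, conditionMessage(attr(ts, "condition")))
        next
      }
      tracks[[length(tracks) + 1L]] <- attach_clock(ts, meta)
    }
  }
  if (length(rej_id))
    message(length(rej_id), " epoch(s) rejected: ",
            paste(rej_id, collapse = ", "))
  list(tracks = tracks, meta = meta,
       rejected = data.frame(epoch_id = rej_id, reason = rej_reason,
                             stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
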
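#' Per-strategy parameter set for the synthetic swimmer
#'
#' One strategy (light or dark) of the generative bout-based swimmer:
#' inter-bout-interval (IBI) and bout distributions, the compensation gain
#' linking bout rotation to accrued drift, and the passive dynamics during
#' inactivity.
#'
#' @param ibi_mean Mean IBI duration, s (gamma distributed).
#' @param ibi_shape Gamma shape of the IBI distribution.
#' @param fwhm_mean_ms Mean bout duration (full width at half maximum of the
#'   Gaussian speed profile), ms (log-normal).
#' @param fwhm_cv Coefficient of variation of the bout duration.
#' @param peak_speed_mean Mean peak speed, mm/s (log-normal).
#' @param peak_speed_cv Coefficient of variation of peak speed.
#' @param direction_mean Mean swim direction (trajectory elevation), degrees.
#' @param direction_sd SD of swim direction, degrees.
#' @param gain Compensation gain g: the bout rotation is
#'   `-g * (pitch drift accrued since the previous bout window)` plus noise.
#' @param rotation_noise SD of the bout-rotation noise, degrees.
#' @param drift_rate Nose-down pitch drift rate during IBIs, deg/s
#'   (positive values mean pitch decreases).
#' @param drift_noise Diffusion of the pitch drift, deg/sqrt(s).
#' @param sink_rate Passive sinking speed during IBIs, mm/s.
#' @return A named list of class `strategy_params`.
#' @export
strategy_params <- function(ibi_mean = 2.29, ibi_shape = 1,
                            fwhm_mean_ms = 145, fwhm_cv = 0.30,
                            peak_speed_mean = 11.4, peak_speed_cv = 0.40,
                            direction_mean = 13, direction_sd = 10,
                            gain = 0.86, rotation_noise = 4.65,
                            drift_rate = 2.7, drift_noise = 0.3,
                            sink_rate = 0.3) {
  p <- list(ibi_mean = ibi_mean, ibi_shape = ibi_shape,
            fwhm_mean_ms = fwhm_mean_ms, fwhm_cv = fwhm_cv,
            peak_speed_mean = peak_speed_mean,
            peak_speed_cv = peak_speed_cv,
            direction_mean = direction_mean, direction_sd = direction_sd,
            gain = gain, rotation_noise = rotation_noise,
            drift_rate = drift_rate, drift_noise = drift_noise,
            sink_rate = sink_rate)
  pos <- c("ibi_mean", "ibi_shape", "fwhm_mean_ms", "fwhm_cv",
           "peak_speed_mean", "peak_speed_cv", "drift_rate", "sink_rate")
  for (f in pos) if (!is.finite(p[[f]]) || p[[f]] <= 0)
    stop("strategy parameter '", f, "' must be > 0")
  for (f in c("gain", "rotation_noise", "drift_noise", "direction_sd"))
    if (!is.finite(p[[f]]) || p[[f]] < 0)
      stop("strategy parameter '", f, "' must be >= 0")
  structure(p, class = "strategy_params")
}

#' Full parameter set of the synthetic swimmer
#'
#' The swimmer is an alternating renewal process: gamma-distributed IBIs
#' during which pitch drifts nose-down (with Brownian noise) and the body
#' sinks, alternating with bouts whose Gaussian speed profile, direction and
#' compensatory pitch rotation are drawn from the active strategy's
#' distributions. A light schedule selects the strategy (dark strategy when
#' the schedule says lights off), and an optional circadian modulation
#' multiplies the IBI mean and bout-duration mean by
#' `1 + A * cos(2 * pi * (clock - phase) / period)`.
#'
#' @param frame_rate Sampling rate, Hz.
#' @param duration_h Recording length, hours.
#' @param seed Integer RNG seed; generation is fully deterministic given the
#'   seed.
#' @param schedule `"DD"`, `"LD"` or `"LL"`.
#' @param lights_on,lights_off Schedule clocks, hours.
#' @param start_clock Clock time at `t = 0`, hours.
#' @param dark,light `strategy_params` for the two strategies.
#' @param circadian_amplitude Modulation amplitude `A` in `[0, 1)`.
#' @param circadian_period Modulation period, hours.
#' @param circadian_phase Clock time (hours) at which the modulation peaks.
#' @param ibi_min Lower bound on drawn IBI durations, s.
#' @param x_jitter Horizontal position jitter during IBIs, mm/sqrt(s).
#' @param pause_after_h Insert a tracking pause (epoch break) after this many
#'   hours; `NULL` for none.
#' @param pause_duration_h Pause length, hours.
#' @param max_bouts Cap on emitted bouts (0 gives a pure drift trace).
#' @return A list of class `swimmer_params`.
#' @export
swimmer_params <- function(frame_rate = 166, duration_h = 1, seed = 1L,
                           schedule = c("DD", "LD", "LL"),
                           lights_on = 9, lights_off = 23, start_clock = 10,
                           dark = strategy_params(),
                           light = strategy_params(
                             ibi_mean = 0.62, ibi_shape = 3,
                             fwhm_mean_ms = 71, fwhm_cv = 0.25,
                             peak_speed_mean = 13.0, peak_speed_cv = 0.35,
                             direction_mean = 0, direction_sd = 16,
                             gain = 0.36, rotation_noise = 2.5,
                             drift_rate = 1.5),
                           circadian_amplitude = 0, circadian_period = 24,
                           circadian_phase = 4, ibi_min = 0.3,
                           x_jitter = 0.02, pause_after_h = NULL,
                           pause_duration_h = 0.5, max_bouts = Inf) {
  schedule <- match.arg(schedule)
  stopifnot(frame_rate > 0, duration_h > 0,
            circadian_amplitude >= 0, circadian_amplitude < 1,
            circadian_period > 0, ibi_min >= 0, x_jitter >= 0,
            max_bouts >= 0)
  if (!(lights_on >= 0 && lights_on < lights_off && lights_off <= 24))
    stop("require 0 <= lights_on < lights_off <= 24")
  stopifnot(inherits(dark, "strategy_params"),
            inherits(light, "strategy_params"))
  structure(
    list(frame_rate = frame_rate, duration_h = duration_h,
         seed = as.integer(seed), schedule = schedule,
         lights_on = lights_on, lights_off = lights_off,
         start_clock = start_clock, dark = dark, light = light,
         circadian_amplitude = circadian_amplitude,
         circadian_period = circadian_period,
         circadian_phase = circadian_phase, ibi_min = ibi_min,
         x_jitter = x_jitter, pause_after_h = pause_after_h,
         pause_duration_h = pause_duration_h, max_bouts = max_bouts),
    class = "swimmer_params")
}

#' Named swimmer presets
#'
#' Documented parameter sets for the standard scenarios:
#' \describe{
#'   \item{dark_strategy}{Constant dark; long, infrequent bouts with large
#'     nose-up compensatory rotations and small direction variability.}
#'   \item{light_strategy}{Constant light; short, frequent,
#'     direction-variable bouts with weak compensation.}
#'   \item{ld_masking}{14/10 light-dark schedule (lights on 9 to 23 h); the
#'     strategy switches with the lights, masking any internal rhythm.}
#'   \item{circadian_dd}{Constant dark with a 24 h modulation (amplitude
#'     0.15, peaking at 4 h, the middle of circadian night) of the IBI and
#'     bout-duration means over a 48 h recording.}
#' }
#'
#' @param name Preset name.
#' @param ... Overrides passed to [swimmer_params()].
#' @return A `swimmer_params`.
#' @export
swimmer_preset <- function(name, ...) {
  presets <- c("dark_strategy", "light_strategy", "ld_masking",
               "circadian_dd")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  base <- switch(name,
    dark_strategy = list(schedule = "DD", duration_h = 1),
    light_strategy = list(schedule = "LL", duration_h = 1),
    ld_masking = list(schedule = "LD", duration_h = 24,
                      pause_after_h = NULL),
    circadian_dd = list(schedule = "DD", duration_h = 48,
                        circadian_amplitude = 0.15,
                        circadian_period = 24, circadian_phase = 4))
  do.call(swimmer_params, utils::modifyList(base, list(...)))
}

# strategy in force at a given clock time
.strategy_at <- function(params, clock) {
  if (params$schedule == "DD") return("dark")
  if (params$schedule == "LL") return("light")
  if (clock >= params$lights_on && clock < params$lights_off) "light"
  else "dark"
}

.circ_mult <- function(params, clock) {
  1 + params$circadian_amplitude *
    cos(2 * pi * (clock - params$circadian_phase) / params$circadian_period)
}

# log-normal with given mean and coefficient of variation
.rlnorm_mcv <- function(n, m, cv) {
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic recording with ground-truth event logs
#'
#' Simulates the alternating renewal process described in
#' [swimmer_params()] on the frame grid and returns raw pose tracks (one
#' `track_series` per uninterrupted tracking epoch), recording metadata, and
#' a ground-truth log of every emitted bout and IBI for pipeline validation.
#'
#' The bout's compensatory rotation, `-gain * drift + noise` where drift is
#' the pitch change accrued since the previous bout's window end, is applied
#' as a raised-cosine ramp across the -250 to +200 ms bout window, so the
#' endpoint-difference rotation measured downstream recovers it exactly.
#' Bout placement keeps consecutive bout windows disjoint; the drawn IBI is
#' the gap between super-threshold runs (peak distance minus the two
#' half-widths at the 5 mm/s threshold).
#'
#' @param params A `swimmer_params`.
#' @param detection_threshold Speed threshold (mm/s) used to compute true
#'   super-threshold half-widths for bout placement; match the segmentation
#'   threshold.
#' @param window_pre_s,window_post_s Bout window extent, matching the
#'   segmentation convention.
#' @return A list of class `synthetic_recording`: `tracks` (list of
#'   `track_series`), `meta` (`recording_meta`), `log` (list of data.frames
#'   `bouts` and `ibis`), `params`.
#' @export
generate_recording <- function(params, detection_threshold = 5,
                               window_pre_s = 0.250,
                               window_post_s = 0.200) {
  stopifnot(inherits(params, "swimmer_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  fr <- params$frame_rate
  dt <- 1 / fr
  pre <- floor(window_pre_s * fr)
  post <- floor(window_post_s * fr)
  nwin <- pre + post + 1L
  total_s <- params$duration_h * 3600

  spans <- list(c(0, total_s))
  if (!is.null(params$pause_after_h) &&
      params$pause_after_h * 3600 < total_s) {
    p0 <- params$pause_after_h * 3600
    p1 <- p0 + params$pause_duration_h * 3600
    spans <- if (p1 < total_s) list(c(0, p0), c(p1, total_s))
             else list(c(0, p0))
  }

  meta <- recording_meta(
    condition = params$schedule, repeat_id = "sim",
    box_id = "sim", group_label = "synthetic",
    lights_on_clock = params$lights_on,
    lights_off_clock = params$lights_off, frame_rate = fr,
    recording_start_clock = params$start_clock)

  tracks <- list()
  # ground-truth log accumulators (grown geometrically)
  cap <- 4096L; ln <- 0L
  L_peak <- L_fwhm <- L_speed <- L_dir <- L_rot <- L_drift <-
    L_circ <- L_ist <- L_ien <- L_idur <- numeric(cap)
  L_epoch <- integer(cap)
  L_strat <- character(cap)
  n_bouts_total <- 0L

  for (sp_i in seq_along(spans)) {
    s0 <- spans[[sp_i]][1]; s1 <- spans[[sp_i]][2]
    n_ep <- floor((s1 - s0) * fr) + 1L
    t_ep <- s0 + (0:(n_ep - 1L)) * dt
    pitch <- numeric(n_ep); xx <- numeric(n_ep); zz <- numeric(n_ep)
    pitch_cur <- 0; x_cur <- 10; z_cur <- 30
    pitch[1] <- pitch_cur; xx[1] <- x_cur; zz[1] <- z_cur
    cf <- 1L                        # last filled frame
    prev_run_end <- s0              # time the previous bout's run ended
    pitch_ref <- pitch_cur          # pitch at previous bout's window end
    drift_started <- s0

    fill_drift <- function(from, to, strat) {
      # fills frames from..to with passive drift; returns new state
      nI <- to - from + 1L
      if (nI <= 0) return(invisible(NULL))
      inc <- -strat$drift_rate * dt +
        stats::rnorm(nI, 0, strat$drift_noise * sqrt(dt))
      pitch[from:to] <<- pitch_cur + cumsum(inc)
      zz[from:to] <<- z_cur - strat$sink_rate * dt * seq_len(nI)
      xx[from:to] <<- x_cur +
        cumsum(stats::rnorm(nI, 0, params$x_jitter * sqrt(dt)))
      pitch_cur <<- pitch[to]; x_cur <<- xx[to]; z_cur <<- zz[to]
      invisible(NULL)
    }

    repeat {
      if (n_bouts_total >= params$max_bouts) break
      clock_ref <- (params$start_clock + prev_run_end / 3600) %% 24
      strat_ibi <- params[[.strategy_at(params, clock_ref)]]
      circ_ibi <- .circ_mult(params, clock_ref)
      d <- stats::rgamma(1, shape = strat_ibi$ibi_shape,
                         scale = strat_ibi$ibi_mean * circ_ibi /
                                 strat_ibi$ibi_shape)
      d <- max(d, params$ibi_min)

      clock_bout <- (params$start_clock + (prev_run_end + d) / 3600) %% 24
      strat_name <- .strategy_at(params, clock_bout)
      strat <- params[[strat_name]]
      circ <- .circ_mult(params, clock_bout)
      tau_ms <- .rlnorm_mcv(1, strat$fwhm_mean_ms * circ, strat$fwhm_cv)
      sigma_s <- tau_ms / 1000 / (2 * sqrt(2 * log(2)))
      P <- .rlnorm_mcv(1, strat$peak_speed_mean, strat$peak_speed_cv)
      half_w <- if (P > detection_threshold)
        sigma_s * sqrt(2 * log(P / detection_threshold)) else 0

      ip <- as.integer(round((prev_run_end + d + half_w - s0) * fr)) + 1L
      if (ip - pre <= cf) ip <- cf + pre + 1L   # keep windows disjoint
      iw0 <- ip - pre; iw1 <- ip + post
      if (iw1 > n_ep) break                     # no room for another bout

      strat_drift <- params[[.strategy_at(
        params, (params$start_clock + t_ep[cf] / 3600) %% 24)]]
      fill_drift(cf + 1L, iw0 - 1L, strat_drift)

      drift_acc <- pitch_cur - pitch_ref
      rotation <- -strat$gain * drift_acc +
        stats::rnorm(1, 0, strat$rotation_noise)
      ramp <- rotation *
        (1 - cos(pi * (0:(nwin - 1L)) / (nwin - 1L))) / 2
      pitch[iw0:iw1] <- pitch_cur + ramp

      p_t <- t_ep[ip]
      prof <- P * exp(-((t_ep[iw0:iw1] - p_t)^2) / (2 * sigma_s^2))
      phi <- stats::rnorm(1, strat$direction_mean, strat$direction_sd)
      head_sign <- if (stats::runif(1) < 0.5) -1 else 1
      dx <- head_sign * cos(phi * pi / 180) * prof * dt
      dz <- sin(phi * pi / 180) * prof * dt
      xx[iw0:iw1] <- x_cur + cumsum(dx)
      zz[iw0:iw1] <- z_cur + cumsum(dz)

      pitch_cur <- pitch[iw1]; x_cur <- xx[iw1]; z_cur <- zz[iw1]
      cf <- iw1
      run_start <- p_t - half_w
      realized_ibi <- run_start - prev_run_end
      n_bouts_total <- n_bouts_total + 1L
      ln <- ln + 1L
      if (ln > cap) {
        g <- numeric(cap)
        L_peak <- c(L_peak, g); L_fwhm <- c(L_fwhm, g)
        L_speed <- c(L_speed, g); L_dir <- c(L_dir, g)
        L_rot <- c(L_rot, g); L_drift <- c(L_drift, g)
        L_circ <- c(L_circ, g); L_ist <- c(L_ist, g)
        L_ien <- c(L_ien, g); L_idur <- c(L_idur, g)
        L_epoch <- c(L_epoch, integer(cap))
        L_strat <- c(L_strat, character(cap))
        cap <- cap * 2L
      }
      L_epoch[ln] <- sp_i; L_peak[ln] <- p_t; L_fwhm[ln] <- tau_ms
      L_speed[ln] <- P; L_dir[ln] <- phi; L_rot[ln] <- rotation
      L_drift[ln] <- drift_acc; L_strat[ln] <- strat_name
      L_circ[ln] <- circ; L_ist[ln] <- prev_run_end
      L_ien[ln] <- run_start; L_idur[ln] <- realized_ibi
      prev_run_end <- p_t + half_w
      pitch_ref <- pitch_cur
    }

    if (cf < n_ep) {
      strat_drift <- params[[.strategy_at(
        params, (params$start_clock + t_ep[cf] / 3600) %% 24)]]
      fill_drift(cf + 1L, n_ep, strat_drift)
    }
    ts <- track_series(sprintf("e%d", sp_i), t_ep, xx, zz, pitch, fr)
    tracks[[sp_i]] <- attach_clock(ts, meta)
  }

  if (ln > 0) {
    k <- seq_len(ln)
    eid <- sprintf("e%d", L_epoch[k])
    lb <- data.frame(epoch_id = eid, peak_time = L_peak[k],
                     fwhm_ms = L_fwhm[k], peak_speed = L_speed[k],
                     direction = L_dir[k], rotation = L_rot[k],
                     prev_drift = L_drift[k], strategy = L_strat[k],
                     circ_mult = L_circ[k], stringsAsFactors = FALSE)
    li <- data.frame(epoch_id = eid, start = L_ist[k], end = L_ien[k],
                     duration = L_idur[k], drift = L_drift[k],
                     stringsAsFactors = FALSE)
  } else {
    lb <- data.frame(); li <- data.frame()
  }
  structure(list(tracks = tracks, meta = meta,
                 log = list(bouts = lb, ibis = li), params = params),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "<synthetic_recording> %s, %g h @ %g Hz: %d epoch(s), %d true bout(s)\n",
    x$params$schedule, x$params$duration_h, x$params$frame_rate,
    length(x$tracks), nrow(x$log$bouts)))
  invisible(x)
}

#' Compare pipeline estimates against the generator's ground truth
#'
#' Matches true bouts to pipeline bouts by nearest peak time within
#' `match_tol_s` (greedy one-to-one in time order) and reports per-parameter
#' bias and RMSE of the pipeline estimates, plus detection counts.
#'
#' @param rec A `synthetic_recording`.
#' @param seg A `segmentation` of `rec$tracks`.
#' @param match_tol_s Matching tolerance on peak times, s.
#' @return A list of class `recovery_report`: `recovery` (data.frame
#'   parameter, bias, rmse, n), `n_true`, `n_detected`, `n_matched`,
#'   `n_missed`, `n_false`.
#' @export
truth_vs_pipeline <- function(rec, seg, match_tol_s = 0.1) {
  truth <- rec$log$bouts
  est <- seg$bouts
  if (nrow(truth) == 0 || nrow(est) == 0)
    stop("nothing to compare: empty truth or pipeline bout table")
  matched_t <- integer(0); matched_e <- integer(0)
  used <- rep(FALSE, nrow(est))
  for (i in seq_len(nrow(truth))) {
    same <- est$epoch_id == truth$epoch_id[i] & !used
    if (!any(same)) next
    dtm <- abs(est$peak_time - truth$peak_time[i])
    dtm[!same] <- Inf
    j <- which.min(dtm)
    if (dtm[j] <= match_tol_s) {
      matched_t <- c(matched_t, i); matched_e <- c(matched_e, j)
      used[j] <- TRUE
    }
  }
  cmp <- function(true_v, est_v) {
    err <- est_v - true_v
    ok <- is.finite(err)
    c(bias = mean(err[ok]), rmse = sqrt(mean(err[ok]^2)), n = sum(ok))
  }
  tt <- truth[matched_t, ]; ee <- est[matched_e, ]
  rows <- rbind(
    peak_time = cmp(tt$peak_time, ee$peak_time),
    fwhm_ms = cmp(tt$fwhm_ms, ee$duration_fwhm_ms),
    peak_speed = cmp(tt$peak_speed, ee$peak_speed),
    direction = cmp(tt$direction, ee$direction_deg),
    rotation = cmp(tt$rotation, ee$rotation_deg))
  if ("prev_ibi" %in% names(ee)) {
    has_prev <- !is.na(ee$prev_ibi)
    if (any(has_prev))
      rows <- rbind(rows, prev_drift = cmp(
        tt$prev_drift[has_prev],
        seg$ibis$drift_deg[ee$prev_ibi[has_prev]]))
  }
  recovery <- data.frame(parameter = rownames(rows), rows,
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(recovery = recovery, n_true = nrow(truth),
                 n_detected = nrow(est), n_matched = length(matched_t),
                 n_missed = nrow(truth) - length(matched_t),
                 n_false = nrow(est) - length(matched_t)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> matched %d/%d true bouts (%d false positives)\n",
    x$n_matched, x$n_true, x$n_false))
  print(x$recovery, digits = 4)
  invisible(x)
}
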
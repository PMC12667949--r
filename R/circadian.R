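#' Restrict records to the clock-anchored analysis window
#'
#' Keeps records whose time (hours since recording start) lies in
#' `[window[1], window[2])`; the left edge is closed. The default 48 h
#' window starts at the recording's analysis anchor (10 a.m. on day 1 under
#' the standard schedule).
#'
#' @param time_h Numeric vector, hours since the analysis-window start.
#' @param window Length-2 numeric, hours.
#' @return Logical keep-mask.
#' @export
extract_analysis_window <- function(time_h, window = c(0, 48)) {
  if (max(time_h, na.rm = TRUE) < window[2])
    warning("record span shorter than the analysis window; retained as-is")
  time_h >= window[1] & time_h < window[2]
}

#' Binned per-repeat medians of a kinematic parameter
#'
#' Bins values by time into `bin_width`-hour intervals over the analysis
#' window and takes the median per repeat per bin; empty bins are `NA`
#' (missing), never zero. z-scores are computed per repeat over that
#' repeat's non-empty bins.
#'
#' @param values Numeric parameter values.
#' @param time_h Hours since analysis-window start for each value.
#' @param repeat_id Repeat identifier for each value.
#' @param bin_width Bin width in hours (default 2).
#' @param window_h Analysis-window length in hours (default 48).
#' @return Object of class `binned_series`: `bin_width`, `bin_centers`,
#'   `medians` and `z` (repeat-by-bin matrices), `repeat_ids`, `n` (counts
#'   per cell).
#' @export
bin_medians <- function(values, time_h, repeat_id, bin_width = 2,
                        window_h = 48) {
  stopifnot(length(values) == length(time_h),
            length(values) == length(repeat_id))
  if (abs(24 / bin_width - round(24 / bin_width)) > 1e-9)
    warning("bin_width does not divide 24 h evenly; ",
            "bins straddle phase boundaries")
  keep <- is.finite(values) & is.finite(time_h) &
          time_h >= 0 & time_h < window_h
  values <- values[keep]; time_h <- time_h[keep]
  repeat_id <- as.character(repeat_id)[keep]
  edges <- seq(0, window_h, by = bin_width)
  nb <- length(edges) - 1L
  centers <- edges[-1] - bin_width / 2
  reps <- sort(unique(repeat_id))
  med <- matrix(NA_real_, length(reps), nb,
                dimnames = list(reps, sprintf("%.2f", centers)))
  cnt <- matrix(0L, length(reps), nb, dimnames = dimnames(med))
  bin <- findInterval(time_h, edges, rightmost.closed = FALSE)
  for (r in seq_along(reps)) {
    sel <- repeat_id == reps[r]
    for (k in unique(bin[sel])) {
      v <- values[sel & bin == k]
      med[r, k] <- stats::median(v)
      cnt[r, k] <- length(v)
    }
  }
  z <- med
  for (r in seq_len(nrow(z))) {
    v <- med[r, ]
    ok <- is.finite(v)
    if (sum(ok) >= 2 && stats::sd(v[ok]) > 0)
      z[r, ok] <- (v[ok] - mean(v[ok])) / stats::sd(v[ok])
    else z[r, ] <- NA_real_
  }
  structure(list(bin_width = bin_width, bin_centers = centers,
                 medians = med, z = z, repeat_ids = reps, n = cnt),
            class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("<binned_series> %d repeat(s) x %d bins of %g h\n",
              length(x$repeat_ids), length(x$bin_centers), x$bin_width))
  invisible(x)
}

#' Day/night summary with transition exclusion
#'
#' Drops transition-phase records (the hour before and after each day-night
#' boundary), then reports the pooled median and IQR per phase together with
#' per-repeat medians (the inputs for per-repeat t-tests).
#'
#' @param values Numeric parameter values.
#' @param phase Phase label per value (`"day"`, `"night"`, `"transition"`).
#' @param repeat_id Repeat identifier per value.
#' @return A list of class `day_night_summary`: `pooled` (data.frame phase,
#'   n, median, iqr) and `per_repeat` (data.frame phase, repeat_id, median).
#'   Phases with zero records are reported as missing with a message.
#' @export
day_night_summary <- function(values, phase, repeat_id) {
  keep <- phase %in% c("day", "night") & is.finite(values)
  v <- values[keep]; ph <- phase[keep]
  rid <- as.character(repeat_id)[keep]
  pooled <- do.call(rbind, lapply(c("day", "night"), function(p) {
    sel <- ph == p
    if (!any(sel)) {
      message("phase '", p, "' has zero records")
      return(data.frame(phase = p, n = 0L, median = NA_real_,
                        iqr = NA_real_))
    }
    data.frame(phase = p, n = sum(sel), median = stats::median(v[sel]),
               iqr = stats::IQR(v[sel]))
  }))
  pr <- expand.grid(phase = c("day", "night"),
                    repeat_id = sort(unique(rid)),
                    stringsAsFactors = FALSE)
  pr$median <- mapply(function(p, r) {
    sel <- ph == p & rid == r
    if (any(sel)) stats::median(v[sel]) else NA_real_
  }, pr$phase, pr$repeat_id)
  structure(list(pooled = pooled, per_repeat = pr),
            class = "day_night_summary")
}

#' @export
print.day_night_summary <- function(x, ...) {
  print(x$pooled)
  invisible(x)
}

#' Autocorrelation-based rhythm detection on a binned series
#'
#' Per repeat: missing bins (at most `max_missing` of the series) are filled
#' by linear interpolation, the series is demeaned, and the coefficient at
#' each lag `k` is the correlation of the two overlapping segments
#' (covariance and scales over the `n - k` overlapping pairs). This per-lag
#' normalization equals 1 at lag 0 by construction, is bounded by 1 at every
#' lag, and a pure periodic series attains exactly 1 at its period, making
#' the period the band argmax. The peak lag is the argmax of the coefficient
#' within the search band.
#'
#' @param bs A `binned_series` (0.5 h bins for the standard analysis).
#' @param max_lag_h Largest lag examined, hours (default 36; capped to bound
#'   variance inflation of the unbiased estimator).
#' @param band Length-2 numeric, hours: search band for the peak lag.
#' @param max_missing Maximum tolerated fraction of missing bins per repeat;
#'   repeats above it are excluded with a message.
#' @return Object of class `autocorr_result`: `lags` (h), `coefficients`
#'   (repeat-by-lag matrix), `mean_coef`, `peak_lag` (per repeat),
#'   `peak_lag_mean` (from the repeat-averaged curve), `excluded` repeat ids.
#' @export
circadian_autocorrelation <- function(bs, max_lag_h = 36, band = c(18, 30),
                                      max_missing = 0.2) {
  stopifnot(inherits(bs, "binned_series"))
  nb <- length(bs$bin_centers)
  # retain lags with at least nb/3 overlapping pairs so the unbiased
  # estimator's variance stays bounded
  max_lag <- min(floor(max_lag_h / bs$bin_width), floor(2 * nb / 3))
  if (max_lag * bs$bin_width < band[2])
    stop("series too short to search lags up to ", band[2], " h: only ",
         nb, " bins of ", bs$bin_width, " h")
  lags <- (0:max_lag) * bs$bin_width
  reps <- bs$repeat_ids
  coefs <- matrix(NA_real_, length(reps), max_lag + 1L,
                  dimnames = list(reps, NULL))
  excluded <- character(0)
  for (r in seq_along(reps)) {
    y <- bs$medians[r, ]
    miss <- !is.finite(y)
    if (mean(miss) > max_missing) {
      excluded <- c(excluded, reps[r])
      message("repeat '", reps[r], "' excluded: ",
              round(100 * mean(miss)), "% missing bins")
      next
    }
    if (any(miss)) {
      ok <- which(!miss)
      y <- stats::approx(ok, y[ok], xout = seq_len(nb), rule = 2)$y
    }
    if (stats::sd(y) == 0)
      stop("zero-variance series for repeat '", reps[r],
           "': flat behavior has no rhythm")
    y <- y - mean(y)
    n <- length(y)
    # per-lag segment correlation: covariance and scales are computed over
    # the n - k overlapping pairs, so a pure periodic series attains
    # exactly 1 at its period and every coefficient is bounded by 1
    coefs[r, ] <- vapply(0:max_lag, function(k) {
      a <- y[1:(n - k)]; b <- y[(1 + k):n]
      am <- a - mean(a); bm <- b - mean(b)
      den <- sqrt(sum(am^2) * sum(bm^2))
      if (den == 0) return(NA_real_)
      sum(am * bm) / den
    }, 0)
  }
  used <- rowSums(is.finite(coefs)) > 0
  if (!any(used)) stop("no repeat usable for autocorrelation")
  mean_coef <- colMeans(coefs[used, , drop = FALSE])
  in_band <- lags >= band[1] & lags <= band[2]
  peak_of <- function(v) {
    vb <- v[in_band]
    lags[in_band][which.max(vb)]
  }
  peak_lag <- apply(coefs, 1, function(v)
    if (all(is.finite(v))) peak_of(v) else NA_real_)
  structure(list(lags = lags, coefficients = coefs, mean_coef = mean_coef,
                 peak_lag = peak_lag, peak_lag_mean = peak_of(mean_coef),
                 band = band, excluded = excluded),
            class = "autocorr_result")
}

#' @export
print.autocorr_result <- function(x, ...) {
  cat(sprintf(
    "<autocorr_result> lags 0-%g h, peak lag (mean curve) = %g h\n",
    max(x$lags), x$peak_lag_mean))
  invisible(x)
}
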
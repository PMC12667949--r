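#' Build five-bout navigation epochs
#'
#' Sliding windows of five consecutive bouts (stride 1) within each tracking
#' epoch: a tracking epoch with `k >= 5` bouts yields `k - 4` navigation
#' epochs. Start positions are taken at each bout's window start; elapsed
#' time is between the window starts of bouts 1 and 5.
#'
#' @param seg A `segmentation` built with `keep_windows = TRUE` (window start
#'   positions are needed).
#' @return data.frame, one row per navigation epoch: `epoch_id`, member bout
#'   ids `b1..b5`, `start_clock`, `phase` (of the first bout),
#'   `elapsed_s`, `displacement_per_s` (mm/s), `dirchange_per_s` (deg/s,
#'   `NA` when any member direction is undefined), plus `condition` /
#'   `repeat_id` when present on the bout table.
#' @export
build_navigation_epochs <- function(seg) {
  b <- seg$bouts
  if (is.null(seg$windows)) stop("segmentation was built without windows")
  if (nrow(b) < 5) return(data.frame())
  x0 <- seg$windows$x[, 1L]
  z0 <- seg$windows$z[, 1L]
  t0 <- b$peak_time + seg$rel_t[1L]
  out <- list()
  for (eid in unique(b$epoch_id)) {
    idx <- which(b$epoch_id == eid)
    k <- length(idx)
    if (k < 5) next
    for (s in 1:(k - 4L)) {
      m <- idx[s:(s + 4L)]
      elapsed <- t0[m[5]] - t0[m[1]]
      disp <- sqrt((x0[m[5]] - x0[m[1]])^2 + (z0[m[5]] - z0[m[1]])^2)
      dirs <- b$direction_deg[m]
      dc <- if (any(!b$direction_defined[m])) NA_real_
            else sum(abs(diff(dirs))) / elapsed
      out[[length(out) + 1L]] <- data.frame(
        epoch_id = eid, b1 = m[1], b2 = m[2], b3 = m[3], b4 = m[4],
        b5 = m[5], start_clock = b$peak_clock[m[1]], phase = b$phase[m[1]],
        elapsed_s = elapsed, displacement_per_s = disp / elapsed,
        dirchange_per_s = dc, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  ne <- do.call(rbind, out)
  for (col in c("condition", "repeat_id", "group_label"))
    if (col %in% names(b)) ne[[col]] <- b[[col]][ne$b1]
  skipped <- sum(is.na(ne$dirchange_per_s))
  if (skipped > 0)
    message(skipped,
            " navigation epoch(s) lack a defined directional change")
  ne
}

#' Displacement per second over a five-bout epoch
#'
#' Straight-line (Euclidean, not path) distance between the start positions
#' of the first and fifth bouts, divided by the time elapsed between them.
#'
#' @param x,z Start positions (mm) of the five bouts.
#' @param t Window start times (s) of the five bouts.
#' @return mm/s.
#' @export
displacement_per_second <- function(x, z, t) {
  stopifnot(length(x) == 5, length(z) == 5, length(t) == 5)
  elapsed <- t[5] - t[1]
  if (elapsed <= 0) stop("elapsed time must be positive")
  sqrt((x[5] - x[1])^2 + (z[5] - z[1])^2) / elapsed
}

#' Directional change per second over a five-bout epoch
#'
#' Sum of the absolute changes in swim direction between consecutive bouts,
#' divided by the elapsed time.
#'
#' @param directions The five bout directions, degrees.
#' @param elapsed Elapsed time between bouts 1 and 5, seconds.
#' @return deg/s.
#' @export
directional_change_per_second <- function(directions, elapsed) {
  stopifnot(length(directions) == 5)
  if (any(!is.finite(directions))) stop("undefined bout direction")
  if (elapsed <= 0) stop("elapsed time must be positive")
  sum(abs(diff(directions))) / elapsed
}

#' Histogram of bout directions
#'
#' Counts over angular bins covering `[-90, 90]` degrees, with bin widths
#' from Scott's rule (computed on the data, clipped to the angular range) or
#' a fixed width.
#'
#' @param directions Bout directions in degrees, each in `[-90, 90]`.
#' @param bin_rule `"scott"` or a fixed numeric bin width in degrees.
#' @return A list of class `direction_histogram`: `breaks`, `counts`,
#'   `mids`; counts sum to `length(directions)` (after NA removal).
#' @export
direction_histogram <- function(directions, bin_rule = "scott") {
  d <- directions[is.finite(directions)]
  if (any(d < -90 | d > 90)) stop("directions must lie in [-90, 90]")
  if (length(d) == 0)
    return(structure(list(breaks = numeric(0), counts = integer(0),
                          mids = numeric(0)), class = "direction_histogram"))
  if (identical(bin_rule, "scott")) {
    if (length(d) >= 2 && stats::sd(d) > 0) {
      breaks <- scott_bins(d)
    } else {
      breaks <- c(min(d) - 0.5, max(d) + 0.5)
    }
  } else {
    w <- as.numeric(bin_rule)
    stopifnot(w > 0)
    breaks <- seq(-90, 90, by = w)
    if (breaks[length(breaks)] < 90) breaks <- c(breaks, 90)
  }
  h <- graphics::hist(d, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids),
            class = "direction_histogram")
}

#' @export
print.direction_histogram <- function(x, ...) {
  cat(sprintf("<direction_histogram> %d bins, %d bouts\n",
              length(x$counts), sum(x$counts)))
  invisible(x)
}
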
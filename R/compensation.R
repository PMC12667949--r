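#' Select middle bouts of 3-bout sequences
#'
#' Returns the bout rows that have both a preceding and a following IBI
#' within the same epoch, i.e. are the middle bout of three consecutive
#' bouts. These are the bouts for which both previous- and next-IBI drift
#' are defined.
#'
#' @param seg A `segmentation` (from [segment_epoch()] or
#'   [segment_recording()]).
#' @return The subset of `seg$bouts` (possibly empty) with columns
#'   `prev_drift`, `prev_duration`, `next_drift`, `next_duration` appended
#'   from the flanking IBIs.
#' @export
select_middle_bouts <- function(seg) {
  b <- seg$bouts
  if (nrow(b) == 0) return(b)
  sel <- !is.na(b$prev_ibi) & !is.na(b$next_ibi)
  b <- b[sel, , drop = FALSE]
  if (nrow(b) == 0) return(b)
  b$prev_drift <- seg$ibis$drift_deg[b$prev_ibi]
  b$prev_duration <- seg$ibis$duration_s[b$prev_ibi]
  b$next_drift <- seg$ibis$drift_deg[b$next_ibi]
  b$next_duration <- seg$ibis$duration_s[b$next_ibi]
  b
}

#' Classify inter-bout intervals as long or short
#'
#' The threshold is the median of the reference durations (by convention the
#' dark-condition IBI durations); an IBI is long iff its duration strictly
#' exceeds the threshold (ties count as short).
#'
#' @param durations Numeric IBI durations to classify, seconds.
#' @param reference Numeric reference durations defining the threshold.
#' @return Character vector `"long"`/`"short"` with attribute `threshold`.
#' @export
classify_ibi <- function(durations, reference) {
  if (length(reference) == 0 || all(is.na(reference)))
    stop("empty reference: cannot compute long/short IBI threshold")
  thr <- stats::median(reference, na.rm = TRUE)
  structure(ifelse(durations > thr, "long", "short"), threshold = thr)
}

#' Robust bi-square (Tukey bisquare) regression of rotation on drift
#'
#' Fits `rotation = intercept + slope * drift` by iteratively reweighted
#' least squares with Tukey bisquare weights (tuning constant 4.685), the
#' scale re-estimated each iteration as 1.4826 times the median absolute
#' deviation of the residuals. The absolute slope is the compensation gain:
#' a gain of 1 means a bout fully corrects the postural drift accrued during
#' the flanking interval. `r_squared` is the unweighted
#' `1 - SS_res / SS_tot` of all points about the robust line (it can be
#' negative when the robust line, by down-weighting outliers, fits the bulk
#' at the expense of total squared error).
#'
#' @param drift Numeric vector, IBI postural drift in degrees.
#' @param rotation Numeric vector, bout rotation in degrees.
#' @param tuning Bisquare tuning constant.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @return An object of class `compensation_fit`: slope, intercept,
#'   `gain = |slope|`, `r_squared`, `n`, `converged`, `iterations`,
#'   `weights`, fitted values and residuals. `bootstrap_p` is `NA` until
#'   filled in by [bootstrap_slope_p()].
#' @export
fit_compensation <- function(drift, rotation, tuning = 4.685,
                             max_iter = 50L, tol = 1e-8) {
  ok <- is.finite(drift) & is.finite(rotation)
  x <- drift[ok]; y <- rotation[ok]
  n <- length(x)
  if (n < 10L) stop("need at least 10 paired observations, got ", n)
  if (stats::var(x) == 0) stop("zero variance in drift")

  X <- cbind(1, x)
  beta <- stats::lm.fit(X, y)$coefficients   # OLS start
  converged <- FALSE
  iter <- 0L
  w <- rep(1, n)
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- drop(y - X %*% beta)
    s <- 1.4826 * stats::median(abs(r - stats::median(r)))
    if (s <= .Machine$double.eps) { converged <- TRUE; break }  # exact fit
    u <- r / (tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 2) break
    fit <- stats::lm.wfit(X, y, w)
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta; converged <- TRUE; break
    }
    beta <- new_beta
  }
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(slope = unname(beta[2]), intercept = unname(beta[1]),
         gain = abs(unname(beta[2])),
         r_squared = 1 - ss_res / ss_tot, n = n,
         converged = converged, iterations = iter,
         weights = as.numeric(w), fitted = fitted, residuals = resid,
         x = x, y = y, tuning = tuning, bootstrap_p = NA_real_),
    class = "compensation_fit")
}

#' @export
print.compensation_fit <- function(x, ...) {
  cat(sprintf(
    "<compensation_fit> slope = %.4f (gain %.3f), intercept = %.4f\n",
    x$slope, x$gain, x$intercept))
  cat(sprintf("  R^2 = %.3f, n = %d%s%s\n", x$r_squared, x$n,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (!is.na(x$bootstrap_p))
                sprintf(", bootstrap p = %.4g", x$bootstrap_p) else ""))
  invisible(x)
}

#' @export
coef.compensation_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.compensation_fit <- function(object, ...) object$residuals

#' @export
predict.compensation_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  object$intercept + object$slope * x
}

#' @export
summary.compensation_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  %d/%d points at zero weight, %d iterations\n",
              sum(object$weights == 0), object$n, object$iterations))
  invisible(object)
}

#' Bootstrap p-value for the compensation slope
#'
#' Case (pairwise) resampling: `B` bootstrap samples of the (drift,
#' rotation) pairs are drawn with replacement and refit; the p-value is
#' twice the add-one-corrected fraction of bootstrap slopes on the opposite
#' side of zero from the point estimate, capped at 1. Deterministic given
#' `seed`.
#'
#' @param drift,rotation Paired numeric vectors.
#' @param B Number of bootstrap replicates (> 0).
#' @param seed Integer RNG seed.
#' @return The p-value, with attribute `slopes` (the bootstrap slopes).
#' @export
bootstrap_slope_p <- function(drift, rotation, B = 1000L, seed = 1L) {
  if (B <= 0) stop("B must be positive")
  ok <- is.finite(drift) & is.finite(rotation)
  x <- drift[ok]; y <- rotation[ok]
  n <- length(x)
  point <- fit_compensation(x, y)$slope
  slopes <- numeric(B)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- try(fit_compensation(x[idx], y[idx]), silent = TRUE)
    slopes[b] <- if (inherits(fb, "try-error")) NA_real_ else fb$slope
  }
  opp <- if (point >= 0) sum(slopes <= 0, na.rm = TRUE)
         else sum(slopes >= 0, na.rm = TRUE)
  p <- min(1, 2 * (opp + 1) / (B + 1))
  structure(p, slopes = slopes)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Compensation residuals and residual variability
#'
#' The compensation residual of a bout is its preceding-IBI drift plus its
#' rotation; zero under perfect compensation. Residual variability is the
#' median absolute deviation (about the median, unscaled) of the residuals.
#'
#' @param drift Preceding-IBI drift per bout, degrees.
#' @param rotation Bout rotation per bout, degrees.
#' @return A list of class `residual_summary`: `residuals`, `variability`.
#' @export
compensation_residuals <- function(drift, rotation) {
  ok <- is.finite(drift) & is.finite(rotation)
  if (!any(ok)) stop("no finite (drift, rotation) pairs")
  r <- drift[ok] + rotation[ok]
  structure(list(residuals = r,
                 variability = stats::median(abs(r - stats::median(r)))),
            class = "residual_summary")
}

#' @export
print.residual_summary <- function(x, ...) {
  cat(sprintf("<residual_summary> n = %d, median = %.3f, MAD = %.3f deg\n",
              length(x$residuals), stats::median(x$residuals),
              x$variability))
  invisible(x)
}

#' Four-way compensation report (long/short IBI x previous/next IBI)
#'
#' Classifies IBIs as long or short against a reference (by default the
#' dark-condition IBI durations of the same data), then fits the bi-square
#' regression of bout rotation on drift for each combination of IBI class
#' and IBI side, mirroring the standard report layout.
#'
#' @param seg A `segmentation`.
#' @param reference Numeric reference IBI durations for the long/short
#'   threshold; default uses all IBIs in `seg` (appropriate when `seg` holds
#'   a dark recording).
#' @param bootstrap_B Bootstrap replicates for the slope p-value; 0 skips
#'   the bootstrap.
#' @param seed RNG seed for the bootstrap.
#' @param min_n Minimum pairs per cell for a fit.
#' @return data.frame with one row per (ibi_class, ibi_side): slope,
#'   gain, r_squared, n, bootstrap_p, threshold_used.
#' @export
compensation_report <- function(seg, reference = NULL, bootstrap_B = 1000L,
                                seed = 1L, min_n = 10L) {
  mid <- select_middle_bouts(seg)
  if (nrow(mid) == 0) stop("no middle bouts available")
  if (is.null(reference)) reference <- seg$ibis$duration_s
  cls_prev <- classify_ibi(mid$prev_duration, reference)
  cls_next <- classify_ibi(mid$next_duration, reference)
  thr <- attr(cls_prev, "threshold")
  rows <- list()
  for (cl in c("long", "short")) for (side in c("previous", "next")) {
    if (side == "previous") {
      sel <- cls_prev == cl
      d <- mid$prev_drift[sel]
    } else {
      sel <- cls_next == cl
      d <- mid$next_drift[sel]
    }
    r <- mid$rotation_deg[sel]
    row <- data.frame(ibi_class = cl, ibi_side = side,
                      slope = NA_real_, gain = NA_real_,
                      r_squared = NA_real_, n = sum(sel),
                      bootstrap_p = NA_real_, threshold_used = thr,
                      stringsAsFactors = FALSE)
    if (sum(is.finite(d) & is.finite(r)) >= min_n) {
      f <- fit_compensation(d, r)
      row$slope <- f$slope; row$gain <- f$gain; row$r_squared <- f$r_squared
      row$n <- f$n
      if (bootstrap_B > 0)
        row$bootstrap_p <- as.numeric(
          bootstrap_slope_p(d, r, B = bootstrap_B, seed = seed))
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
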
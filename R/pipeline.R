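#' Assemble a pipeline run configuration
#'
#' One configuration object drives an end-to-end run; every default is
#' materialized into the object (and therefore into the run manifest), so a
#' saved configuration fully reproduces a run.
#'
#' @param input Path to a track CSV (with YAML sidecar), a
#'   `synthetic_recording`, or a list of `swimmer_params` (one recording is
#'   generated per element).
#' @param outdir Output directory for the result CSVs and manifest.
#' @param segmentation A `segmentation_params`.
#' @param bootstrap_B Bootstrap replicates for compensation slope p-values.
#' @param seed Integer seed for the bootstrap (and any generation).
#' @param bin_width_h Bin width for the circadian binned medians, hours.
#' @param acf_bin_width_h Bin width for the autocorrelation series, hours.
#' @param acf_max_lag_h Maximum autocorrelation lag, hours.
#' @param long_ibi_reference `"dark-day"` (median of dark-condition
#'   zeitgeber-day IBIs, pooled), `"all-dark"` (all dark-phase IBIs) or a
#'   fixed numeric threshold in seconds.
#' @param circadian_parameter Bout column used for the circadian analysis.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, outdir = tempfile("swimbout_run"),
                       segmentation = segmentation_params(),
                       bootstrap_B = 200L, seed = 1L, bin_width_h = 2,
                       acf_bin_width_h = 0.5, acf_max_lag_h = 36,
                       long_ibi_reference = "dark-day",
                       circadian_parameter = "duration_fwhm_ms") {
  structure(list(input = input, outdir = outdir,
                 segmentation = segmentation, bootstrap_B = bootstrap_B,
                 seed = as.integer(seed), bin_width_h = bin_width_h,
                 acf_bin_width_h = acf_bin_width_h,
                 acf_max_lag_h = acf_max_lag_h,
                 long_ibi_reference = long_ibi_reference,
                 circadian_parameter = circadian_parameter),
            class = "run_config")
}

.load_recordings <- function(config) {
  inp <- config$input
  if (inherits(inp, "synthetic_recording")) inp <- list(inp)
  if (is.character(inp)) {
    recs <- lapply(inp, function(p) {
      r <- read_tracks(p)
      list(tracks = r$tracks, meta = r$meta)
    })
  } else if (is.list(inp) && all(vapply(inp, inherits, TRUE,
                                        "swimmer_params"))) {
    recs <- lapply(inp, function(p) {
      r <- generate_recording(p)
      list(tracks = r$tracks, meta = r$meta)
    })
  } else if (is.list(inp) && all(vapply(inp, inherits, TRUE,
                                        "synthetic_recording"))) {
    recs <- lapply(inp, function(r) list(tracks = r$tracks, meta = r$meta))
  } else stop("unrecognized input specification")
  recs
}

#' Run the full analysis pipeline
#'
#' Stages run in order: segmentation and kinematics, compensation report,
#' navigation, circadian binning and autocorrelation, summary tables. Every
#' stage's output CSV is written under `config$outdir` together with a
#' machine-readable JSON manifest (configuration, seed, record counts per
#' stage). Deterministic given the configuration.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list of class `run_result` with the in-memory tables
#'   (`bouts`, `ibis`, `navigation`, `compensation`, `circadian`,
#'   `autocorrelation`, `summary`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  recs <- .load_recordings(config)
  counts <- list()

  bouts <- list(); ibis <- list(); navs <- list()
  for (r in recs) {
    seg <- segment_recording(r$tracks, r$meta, config$segmentation,
                             keep_windows = TRUE)
    if (nrow(seg$bouts) > 0) {
      mid <- select_middle_bouts(seg)
      b <- seg$bouts
      b$prev_drift <- NA_real_; b$prev_duration <- NA_real_
      b$next_drift <- NA_real_; b$next_duration <- NA_real_
      if (nrow(mid) > 0) {
        b[match(mid$bout_id, b$bout_id),
          c("prev_drift", "prev_duration", "next_drift", "next_duration")] <-
          mid[, c("prev_drift", "prev_duration", "next_drift",
                  "next_duration")]
      }
      bouts[[length(bouts) + 1L]] <- b
      nav <- build_navigation_epochs(seg)
      if (nrow(nav) > 0) navs[[length(navs) + 1L]] <- nav
    }
    if (nrow(seg$ibis) > 0) ibis[[length(ibis) + 1L]] <- seg$ibis
  }
  bouts <- if (length(bouts)) do.call(rbind, bouts) else data.frame()
  ibis <- if (length(ibis)) do.call(rbind, ibis) else data.frame()
  navs <- if (length(navs)) do.call(rbind, navs) else data.frame()
  counts$bouts <- nrow(bouts); counts$ibis <- nrow(ibis)
  counts$navigation_epochs <- nrow(navs)
  if (nrow(bouts) == 0) stop("segmentation stage produced no bouts")

  # compensation: bouts with dark-strategy phases, long/short x prev/next
  comp <- NULL
  ref <- .long_ibi_reference(config, bouts, ibis)
  mid_ok <- !is.na(bouts$prev_drift) & !is.na(bouts$next_drift)
  if (sum(mid_ok) >= 10 && !is.null(ref)) {
    comp <- .compensation_stage(bouts[mid_ok, ], ref, config)
  } else {
    message("compensation stage skipped: ",
            if (is.null(ref)) "no reference IBIs for the long/short split"
            else "fewer than 10 middle bouts")
  }
  counts$compensation_rows <- if (is.null(comp)) 0L else nrow(comp)

  # circadian
  par_col <- config$circadian_parameter
  anchor <- recs[[1]]$meta$analysis_window[1]
  time_h <- bouts$peak_time / 3600 - anchor
  keepw <- time_h >= 0 & time_h < diff(recs[[1]]$meta$analysis_window)
  circ <- bin_medians(bouts[[par_col]][keepw], time_h[keepw],
                      bouts$repeat_id[keepw],
                      bin_width = config$bin_width_h,
                      window_h = diff(recs[[1]]$meta$analysis_window))
  acf_bs <- bin_medians(bouts[[par_col]][keepw], time_h[keepw],
                        bouts$repeat_id[keepw],
                        bin_width = config$acf_bin_width_h,
                        window_h = diff(recs[[1]]$meta$analysis_window))
  acf <- try(circadian_autocorrelation(acf_bs,
                                       max_lag_h = config$acf_max_lag_h),
             silent = TRUE)
  if (inherits(acf, "try-error")) {
    message("autocorrelation stage skipped: ",
            conditionMessage(attr(acf, "condition")))
    acf <- NULL
  }

  summary_tab <- make_summary_tables(bouts, ibis)

  # write outputs
  out <- function(name) file.path(config$outdir, name)
  data.table::fwrite(bouts, out("bouts.csv"))
  data.table::fwrite(ibis, out("ibis.csv"))
  if (nrow(navs)) data.table::fwrite(navs, out("navigation.csv"))
  if (!is.null(comp)) data.table::fwrite(comp, out("compensation.csv"))
  circ_df <- .binned_to_df(circ)
  data.table::fwrite(circ_df, out("circadian_bins.csv"))
  if (!is.null(acf)) {
    acf_df <- data.frame(lag_h = rep(acf$lags, each = nrow(acf$coefficients)),
                         repeat_id = rownames(acf$coefficients),
                         coefficient = as.vector(acf$coefficients))
    data.table::fwrite(acf_df, out("autocorrelation.csv"))
  }
  data.table::fwrite(summary_tab, out("summary_kinematics.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("swimbout")),
    seed = config$seed,
    segmentation = unclass(config$segmentation),
    bootstrap_B = config$bootstrap_B,
    bin_width_h = config$bin_width_h,
    acf_bin_width_h = config$acf_bin_width_h,
    acf_max_lag_h = config$acf_max_lag_h,
    long_ibi_reference = as.character(config$long_ibi_reference),
    circadian_parameter = config$circadian_parameter,
    counts = counts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(structure(
    list(bouts = bouts, ibis = ibis, navigation = navs,
         compensation = comp, circadian = circ, autocorrelation = acf,
         summary = summary_tab, manifest = manifest, outdir = config$outdir),
    class = "run_result"))
}

.long_ibi_reference <- function(config, bouts, ibis) {
  ref_spec <- config$long_ibi_reference
  if (is.numeric(ref_spec)) return(ref_spec)
  if (nrow(ibis) == 0) return(NULL)
  dark <- ibis$condition == "DD"
  sel <- if (identical(ref_spec, "dark-day")) {
    dark & ibis$phase == "day"
  } else {
    dark & ibis$phase %in% c("day", "night")
  }
  if (!any(sel, na.rm = TRUE)) {
    # single-condition recordings without a DD arm: fall back to all IBIs
    sel <- rep(TRUE, nrow(ibis))
  }
  ibis$duration_s[which(sel)]
}

.compensation_stage <- function(mid, reference, config) {
  cls_prev <- classify_ibi(mid$prev_duration, reference)
  cls_next <- classify_ibi(mid$next_duration, reference)
  thr <- attr(cls_prev, "threshold")
  rows <- list()
  for (cond in unique(mid$condition))
    for (cl in c("long", "short")) for (side in c("previous", "next")) {
      in_cond <- mid$condition == cond
      if (side == "previous") {
        sel <- in_cond & cls_prev == cl
        d <- mid$prev_drift[sel]
      } else {
        sel <- in_cond & cls_next == cl
        d <- mid$next_drift[sel]
      }
      r <- mid$rotation_deg[sel]
      row <- data.frame(condition = cond, ibi_class = cl, ibi_side = side,
                        slope = NA_real_, gain = NA_real_,
                        r_squared = NA_real_, n = sum(sel),
                        bootstrap_p = NA_real_, threshold_used = thr)
      if (sum(is.finite(d) & is.finite(r)) >= 10) {
        f <- fit_compensation(d, r)
        row$slope <- f$slope; row$gain <- f$gain
        row$r_squared <- f$r_squared; row$n <- f$n
        if (config$bootstrap_B > 0)
          row$bootstrap_p <- as.numeric(bootstrap_slope_p(
            d, r, B = config$bootstrap_B, seed = config$seed))
      }
      rows[[length(rows) + 1L]] <- row
    }
  do.call(rbind, rows)
}

.binned_to_df <- function(bs) {
  data.frame(bin_center_h = rep(bs$bin_centers, each = nrow(bs$medians)),
             repeat_id = rep(bs$repeat_ids, length(bs$bin_centers)),
             median = as.vector(bs$medians), z = as.vector(bs$z),
             n = as.vector(bs$n))
}

#' Summary table of kinematic parameters by condition and phase
#'
#' Pooled median and IQR of each kinematic parameter per condition and phase
#' (transition excluded), with the median-test p-value and chi-squared/N
#' effect size for the across-condition contrast within each phase when two
#' or more conditions are present.
#'
#' @param bouts Bout table (from [run_pipeline()] or
#'   [segment_recording()]'s `bouts` with kinematics columns).
#' @param ibis IBI table.
#' @param parameters Named character vector mapping display names to bout
#'   columns.
#' @return data.frame: parameter, unit, condition, phase, n, median, iqr,
#'   and (per parameter and phase) `median_test_p`, `effect_size` contrasting
#'   the conditions.
#' @export
make_summary_tables <- function(bouts, ibis,
                                parameters = c(
                                  peak_speed = "peak_speed",
                                  displacement = "displacement_mm",
                                  bout_duration = "duration_fwhm_ms",
                                  bout_rotation = "rotation_deg")) {
  units <- c(peak_speed = "mm/s", displacement = "mm",
             bout_duration = "ms", bout_rotation = "deg",
             ibi_duration = "s", ibi_drift = "deg")
  long <- list()
  add <- function(name, values, condition, phase) {
    keep <- phase %in% c("day", "night") & is.finite(values)
    if (!any(keep)) return(invisible(NULL))
    long[[length(long) + 1L]] <<- data.frame(
      parameter = name, value = values[keep],
      condition = condition[keep], phase = phase[keep],
      stringsAsFactors = FALSE)
  }
  for (nm in names(parameters))
    add(nm, bouts[[parameters[nm]]], bouts$condition, bouts$phase)
  if (nrow(ibis) > 0) {
    add("ibi_duration", ibis$duration_s, ibis$condition, ibis$phase)
    add("ibi_drift", ibis$drift_deg, ibis$condition, ibis$phase)
  }
  long <- do.call(rbind, long)
  out <- list()
  for (nm in unique(long$parameter)) for (ph in c("day", "night")) {
    sub <- long[long$parameter == nm & long$phase == ph, ]
    if (nrow(sub) == 0) next
    conds <- sort(unique(sub$condition))
    p <- NA_real_; es <- NA_real_
    if (length(conds) >= 2) {
      mt <- try(median_test(split(sub$value, sub$condition)), silent = TRUE)
      if (!inherits(mt, "try-error")) { p <- mt$p; es <- mt$effect_size }
    }
    for (cd in conds) {
      v <- sub$value[sub$condition == cd]
      out[[length(out) + 1L]] <- data.frame(
        parameter = nm, unit = unname(units[nm]), condition = cd,
        phase = ph, n = length(v), median = stats::median(v),
        iqr = stats::IQR(v), median_test_p = p, effect_size = es,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "<run_result> %d bouts, %d IBIs, %d navigation epochs -> %s\n",
    nrow(x$bouts), nrow(x$ibis),
    if (is.data.frame(x$navigation)) nrow(x$navigation) else 0L,
    x$outdir))
  invisible(x)
}
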
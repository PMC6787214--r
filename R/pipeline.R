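#' Pipeline configuration
#'
#' Bundles every tunable parameter of the end-to-end pipeline with the
#' method defaults: 1 kHz sampling, 1--40 Hz order-4 Butterworth band, Haar
#' depth 5, interval windows of 20 segments, stats windows of 20 counts,
#' 20 ms embedding delay, 100 x 100 line-rasterized portraits, published
#' thresholds, 80/20 train/validation split.
#'
#' @param fs sampling rate (Hz) assumed for synthetic generation.
#' @param hp_hz,lp_hz,filter_order band-limiting parameters, see
#'   [bandlimit()].
#' @param dwt_levels Haar decomposition depth used by delineation.
#' @param w1 interval-window length (feature segments per window).
#' @param stats_w stats-window length (box counts per window).
#' @param delay_ms embedding delay in milliseconds.
#' @param grid_n portrait resolution.
#' @param raster_mode `"line"` or `"point"`.
#' @param thresholds `"published"`, or a named list of [threshold_pair()]s
#'   for `PR`, `QRS`, `QT`.
#' @param train_fraction training fraction for cohort splits.
#' @param seed integer seed for all randomized steps.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 1000, hp_hz = 1, lp_hz = 40,
                            filter_order = 4, dwt_levels = 5, w1 = 20,
                            stats_w = 20, delay_ms = 20, grid_n = 100,
                            raster_mode = c("line", "point"),
                            thresholds = "published", train_fraction = 0.8,
                            seed = 0) {
  raster_mode <- match.arg(raster_mode)
  cfg <- structure(list(fs = fs, hp_hz = hp_hz, lp_hz = lp_hz,
                        filter_order = filter_order,
                        dwt_levels = dwt_levels, w1 = w1, stats_w = stats_w,
                        delay_ms = delay_ms, grid_n = grid_n,
                        raster_mode = raster_mode, thresholds = thresholds,
                        train_fraction = train_fraction, seed = seed),
                   class = "pipeline_config")
  stopifnot(fs >= 250, hp_hz > 0, hp_hz < lp_hz, lp_hz < fs / 2,
            filter_order >= 1, dwt_levels >= 1, w1 >= 1, stats_w >= 2,
            delay_ms > 0, grid_n >= 2,
            train_fraction > 0, train_fraction < 1)
  cfg
}

resolve_thresholds <- function(cfg, kind) {
  if (identical(cfg$thresholds, "published")) published_thresholds(kind)
  else cfg$thresholds[[kind]]
}

#' Run the full screening pipeline on one record
#'
#' Executes preprocessing (band-limit, normalize), beat delineation,
#' feature extraction, interval windowing, delay embedding with box
#' counting, sliding CV statistics and three-class classification for each
#' of the three localized features.
#'
#' @param input an `ecg_record` from [generate_record()], an
#'   [ecg_signal()], or a file path accepted by [read_ecg()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, feature tables, box
#'   counts, CV traces and per-window decisions are persisted as CSV.
#' @return object of class `psr_result`: per-kind list with `counts`
#'   (`box_count_series`), `trace` (`cv_trace`), `decisions`, `subject`;
#'   plus `beats` and `n_beats`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         out_dir = NULL) {
  ecg <- if (inherits(input, "ecg_record")) input$signal
         else if (inherits(input, "ecg_signal")) input
         else read_ecg(input)

  pre <- bandlimit(ecg, config$hp_hz, config$lp_hz, config$filter_order)
  pre <- normalize_ecg(pre)
  beats <- detect_beats(pre)
  if (nrow(beats) == 0) {
    stop("feature_extraction: no beats detected in record ",
         if (!is.null(ecg$meta)) ecg$meta else "<unnamed>", call. = FALSE)
  }
  features <- extract_features(pre, beats)

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  res <- lapply(names(features), function(kind) {
    windows <- make_interval_windows(features[[kind]], config$w1)
    if (!length(windows)) {
      stop("phase_space: record too short for interval windows (", kind,
           ": ", length(features[[kind]]), " segments, need >= ", config$w1,
           ")", call. = FALSE)
    }
    counts <- box_count_series(windows, config$delay_ms, ecg$fs,
                               config$grid_n, config$raster_mode)
    trace <- sliding_stats(counts, config$stats_w)
    cls <- classify_trace(trace, resolve_thresholds(config, kind))
    if (!is.null(out_dir)) {
      write_feature_csv(features[[kind]],
                        file.path(out_dir, paste0(kind, "_features.csv")))
      write.csv(data.frame(window_index = counts$window_index,
                           n_black = counts$counts),
                file.path(out_dir, paste0(kind, "_boxcounts.csv")),
                row.names = FALSE)
      write_trace_csv(trace, file.path(out_dir, paste0(kind, "_trace.csv")))
      write.csv(data.frame(window_index = seq_along(cls$windows),
                           cv = trace$cvs, label = as.character(cls$windows)),
                file.path(out_dir, paste0(kind, "_decisions.csv")),
                row.names = FALSE)
    }
    list(kind = kind, counts = counts, trace = trace,
         decisions = cls$windows, subject = cls$subject)
  })
  names(res) <- names(features)
  structure(c(res, list(beats = beats, n_beats = nrow(beats))),
            class = "psr_result")
}

#' @export
print.psr_result <- function(x, ...) {
  cat("PSR screening result (", x$n_beats, "beats )\n")
  for (kind in c("PR", "QRS", "QT")) {
    cat(sprintf("  %-3s max CV %.4g -> %s\n", kind, max(x[[kind]]$trace$cvs),
                as.character(x[[kind]]$subject)))
  }
  invisible(x)
}

#' Window labels implied by the ground-truth beat labels
#'
#' Maps the per-beat labels of a synthetic record through both windowing
#' stages (interval windows of `w1` beats, stats windows of `stats_w`
#' counts): stats window `m` draws on beats `m ... m + w1 + stats_w - 2`,
#' so it is all-healthy iff that whole beat range is healthy. Returns the
#' annotation needed by [labeled_cv_trace()]: `a_index`, the last
#' all-healthy stats window, and `b_index`, the first all-unhealthy one.
#'
#' @param labels per-beat labels (`"healthy"`/`"unhealthy"`), healthy block
#'   first.
#' @param w1,stats_w the two window lengths.
#' @param clamp when `TRUE`, indices that fall at most one window outside
#'   the trace (as happens when beat detection drops a beat or two) are
#'   clamped into range instead of erroring.
#' @return list with `a_index`, `b_index` and `n_windows`.
#' @export
truth_ab_indices <- function(labels, w1 = 20, stats_w = 20, clamp = FALSE) {
  n <- length(labels)
  n_h <- sum(labels == "healthy")
  span <- w1 + stats_w - 1            # beats feeding one stats window
  n_windows <- n - span + 1
  if (n_windows < 2) stop("record too short for labeled windows",
                          call. = FALSE)
  a <- n_h - span + 1                 # last window inside the healthy block
  b <- n_h + 1                        # first window past the healthy block
  if (clamp) {
    b <- min(b, n_windows)
    a <- max(1L, min(a, b - 1L))
  }
  if (a < 1 || b > n_windows) {
    stop("labels give no all-healthy or no all-unhealthy stats window",
         call. = FALSE)
  }
  list(a_index = as.integer(a), b_index = as.integer(b),
       n_windows = as.integer(n_windows))
}

#' Learn cohort thresholds from synthetic records
#'
#' Runs the pipeline on each record and aggregates per-patient CV extrema
#' into a [threshold_pair()] per feature kind. Transition records
#' (healthy-then-unhealthy) contribute both extrema via their ground-truth
#' window boundaries; healthy-only records contribute their whole trace as
#' the healthy portion, i.e. only to the healthy-side threshold.
#'
#' @param records list of `ecg_record`s.
#' @param config a [pipeline_config()].
#' @return named list of [threshold_pair()]s (`PR`, `QRS`, `QT`).
#' @export
learn_thresholds_from_records <- function(records,
                                          config = pipeline_config()) {
  stopifnot(length(records) >= 1)
  if (!any(vapply(records, function(r) any(r$labels == "unhealthy"),
                  logical(1)))) {
    stop("need at least one record with unhealthy beats", call. = FALSE)
  }
  runs <- lapply(records, run_pipeline, config = config)
  kinds <- c("PR", "QRS", "QT")
  out <- lapply(kinds, function(kind) {
    ex <- vapply(seq_along(records), function(i) {
      trace <- runs[[i]][[kind]]$trace
      if (!any(records[[i]]$labels == "unhealthy")) {
        return(c(th_max = max(trace$cvs), th_min = Inf))
      }
      # label each detected beat by its nearest ground-truth beat, so the
      # window annotation survives occasional dropped beats
      det_r <- runs[[i]]$beats$r_peak
      nearest <- vapply(det_r, function(r) {
        which.min(abs(records[[i]]$truth$r_peak - r))
      }, integer(1))
      ab <- truth_ab_indices(records[[i]]$labels[nearest], config$w1,
                             config$stats_w, clamp = TRUE)
      labeled <- labeled_cv_trace(
        trace, a_index = min(ab$a_index, length(trace) - 1L),
        b_index = min(ab$b_index, length(trace)), patient_id = i)
      patient_extrema(labeled)
    }, numeric(2))
    threshold_pair(kind, th_final_max = max(ex["th_max", ]),
                   th_final_min = min(ex["th_min", ]),
                   n_patients = length(records))
  })
  names(out) <- kinds
  out
}
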
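#' Detect beats and delineate fiducial points
#'
#' Wavelet-guided delineation of a preprocessed (band-limited, normalized)
#' single-lead ECG:
#' \enumerate{
#'   \item R peaks are modulus maxima of the level-3 Haar detail envelope
#'     above an adaptive threshold (0.3 times the rolling RMS of the
#'     envelope over 2 s), with a 200 ms refractory period, refined to the
#'     local extremum of the signal itself.
#'   \item QRS onset/offset are located where the smoothed signal derivative
#'     stays below 3 percent of its QRS maximum for a sustained (12 ms) run,
#'     walking outward from the R peak.
#'   \item P onset is the leading edge of the largest level-5-scale-smoothed
#'     positive bump in a 220 to 40 ms window before QRS onset.
#'   \item T offset uses the tangent method on the level-5-scale-smoothed
#'     descending T flank (tangent through the maximum-slope point crossed
#'     with the local baseline), extended by the apex-to-maximum-slope
#'     distance so the estimate tracks the full extent of a smooth-flanked
#'     T wave rather than stopping at the tangent intersection.
#' }
#' Thresholds are relative to local signal statistics, so detection is
#' invariant to positive rescaling of the input. Beats whose delineation
#' windows cannot be evaluated (falling off the record ends) or whose
#' fiducials violate the ordering `p_on < qrs_on < r_peak < qrs_off < t_off`
#' are dropped with a warning.
#'
#' @param ecg an [ecg_signal()], ideally after [bandlimit()] and
#'   [normalize_ecg()].
#' @return data frame of class `beat_fiducials` with 1-based sample index
#'   columns `p_on`, `qrs_on`, `r_peak`, `qrs_off`, `t_off` (one row per
#'   beat, temporally ordered); zero rows when no beats are found.
#' @export
detect_beats <- function(ecg) {
  stopifnot(inherits(ecg, "ecg_signal"))
  x <- ecg$samples
  fs <- ecg$fs
  empty <- structure(
    data.frame(p_on = integer(0), qrs_on = integer(0), r_peak = integer(0),
               qrs_off = integer(0), t_off = integer(0)),
    class = c("beat_fiducials", "data.frame"))
  n <- length(x)
  if (n < 64) return(empty)

  ms <- function(k) max(1L, as.integer(round(k * fs / 1000)))

  # R-peak candidates from the level-3 detail envelope.
  env <- haar_detail_envelope(x, 3L)
  env <- moving_average(env, ms(25))
  if (max(env) <= 0 || max(env) < 1e-12 * max(abs(x))) return(empty)
  rms <- sqrt(moving_average(env^2, ms(2000)))
  thr <- 0.3 * rms
  is_peak <- env > thr &
    env >= c(-Inf, env[-n]) & env >= c(env[-1], -Inf)
  cand <- which(is_peak)
  if (!length(cand)) return(empty)
  # refractory: greedy by envelope height, 200 ms exclusion
  cand <- cand[order(env[cand], decreasing = TRUE)]
  keep <- integer(0)
  refr <- ms(200)
  for (p in cand) {
    if (!length(keep) || all(abs(keep - p) > refr)) keep <- c(keep, p)
  }
  # reject secondary peaks (T waves, edge transients) well below the QRS
  # envelope scale of the record
  scale_env <- stats::quantile(env[keep], 0.75, names = FALSE)
  keep <- keep[env[keep] >= 0.35 * scale_env]
  if (!length(keep)) return(empty)
  rpk_env <- sort(keep)

  # refine R peak: largest |deviation from median| near the envelope peak
  med <- median(x)
  half <- ms(60)
  r_peaks <- vapply(rpk_env, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    lo - 1L + which.max(abs(x[lo:hi] - med))
  }, integer(1))
  r_peaks <- sort(unique(r_peaks))
  # re-apply refractory after refinement
  if (length(r_peaks) > 1) {
    ok <- c(TRUE, diff(r_peaks) > refr)
    r_peaks <- r_peaks[ok]
  }

  # smoothed signal and derivative for on/offset refinement
  xs <- moving_average(x, ms(8))
  dx <- c(0, abs(diff(xs))) * fs / 1000            # units per ms
  x5 <- moving_average(x, ms(32))                  # level-5-scale smoothing
  run <- ms(12)                                    # quiet-run length

  delineate <- function(r) {
    w <- ms(150)
    lo <- max(1L, r - w); hi <- min(n, r + w)
    # quiet threshold: fraction of the QRS derivative maximum, floored at
    # the local baseline derivative level so noise does not mask quiescence
    dwin <- dx[lo:hi]
    thr_d <- max(0.03 * max(dwin), 1.5 * median(dwin))

    # walk left: first index whose preceding `run` samples are quiet on
    # average
    qrs_on <- NA_integer_
    i <- r
    while (i - run >= lo) {
      if (mean(dx[(i - run):(i - 1)]) < thr_d) { qrs_on <- i; break }
      i <- i - 1L
    }
    # refine to the pointwise threshold crossing (bounded by the run length
    # so noise cannot drag the boundary away)
    if (!is.na(qrs_on)) {
      steps <- 0L
      while (steps < run && qrs_on - 1L >= lo && dx[qrs_on - 1L] > thr_d) {
        qrs_on <- qrs_on - 1L
        steps <- steps + 1L
      }
    }
    # walk right
    qrs_off <- NA_integer_
    i <- r
    while (i + run <= hi) {
      if (mean(dx[(i + 1):(i + run)]) < thr_d) { qrs_off <- i; break }
      i <- i + 1L
    }
    if (!is.na(qrs_off)) {
      steps <- 0L
      while (steps < run && qrs_off + 1L <= hi && dx[qrs_off + 1L] > thr_d) {
        qrs_off <- qrs_off + 1L
        steps <- steps + 1L
      }
    }
    if (is.na(qrs_on) || is.na(qrs_off)) return(NULL)

    # P onset: largest positive smoothed bump in [qrs_on-220, qrs_on-40] ms
    p_lo <- qrs_on - ms(220); p_hi <- qrs_on - ms(40)
    if (p_hi <= p_lo || p_lo < 1) return(NULL)
    seg <- x5[p_lo:p_hi]
    apex <- p_lo - 1L + which.max(seg)
    base <- min(x5[p_lo:apex])          # baseline left of the P apex
    amp <- x5[apex] - base
    p_on <- p_lo
    if (amp > 0) {
      below <- which(x5[p_lo:apex] <= base + 0.05 * amp)
      if (length(below)) p_on <- p_lo - 1L + max(below)
    }

    # T offset: tangent method on the smoothed descending flank
    t_lo <- qrs_off + ms(80); t_hi <- min(n, qrs_off + ms(450))
    if (t_lo >= t_hi) return(NULL)
    seg <- x5[t_lo:t_hi]
    base <- min(seg)
    apex <- t_lo - 1L + which.max(seg)
    if (apex >= t_hi - 2L) return(NULL)
    d5 <- -diff(x5[apex:t_hi])
    mrel <- which.max(d5)
    m <- apex + mrel - 1L                 # max negative-slope sample
    slope <- d5[mrel]                     # units per sample (positive)
    if (slope <= 0) return(NULL)
    t_cross <- m + (x5[m] - base) / slope
    sigma_hat <- m - apex
    t_off <- as.integer(round(t_cross + sigma_hat))
    t_off <- min(t_off, n)

    if (!(p_on < qrs_on && qrs_on < r && r < qrs_off && qrs_off < t_off)) {
      return(NULL)
    }
    c(p_on = p_on, qrs_on = qrs_on, r_peak = r, qrs_off = qrs_off,
      t_off = t_off)
  }

  rows <- lapply(r_peaks, delineate)
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warning(dropped, " beat(s) dropped: delineation window off record ends ",
            "or fiducial ordering violated", call. = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- as.data.frame(do.call(rbind, rows))
  # enforce non-overlapping, ordered beats
  out <- out[order(out$r_peak), , drop = FALSE]
  if (nrow(out) > 1) {
    ok <- c(TRUE, out$qrs_on[-1] > out$qrs_off[-nrow(out)])
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, class = c("beat_fiducials", "data.frame"))
}

#' Extract the localized feature segments of every beat
#'
#' Slices the normalized signal into the three localized features per beat:
#' PR interval (`p_on` to `qrs_on`), QRS complex (`qrs_on` to `qrs_off`) and
#' QT interval (`qrs_on` to `t_off`), each stacked in beat order in its own
#' feature array. Slices are half-open: the sample at the end fiducial is
#' excluded, so the QRS segment is a prefix of the QT segment.
#'
#' @param ecg the [ecg_signal()] the beats were detected on.
#' @param beats a `beat_fiducials` data frame from [detect_beats()].
#' @return named list with elements `PR`, `QRS`, `QT`, each a
#'   `feature_array`: list with `kind`, `beats` (data frame `beat_index`,
#'   `start`, `end`, `duration_ms`) and `segments` (list of numeric slices).
#' @export
extract_features <- function(ecg, beats) {
  stopifnot(inherits(ecg, "ecg_signal"))
  x <- ecg$samples
  fs <- ecg$fs
  bounds <- list(PR = c("p_on", "qrs_on"),
                 QRS = c("qrs_on", "qrs_off"),
                 QT = c("qrs_on", "t_off"))
  valid <- rep(TRUE, nrow(beats))
  if (nrow(beats)) {
    valid <- with(beats, p_on < qrs_on & qrs_on < r_peak & r_peak < qrs_off &
                    qrs_off < t_off)
    if (any(!valid)) {
      warning(sum(!valid), " beat(s) skipped: fiducial ordering violated",
              call. = FALSE)
    }
  }
  kept <- beats[valid, , drop = FALSE]
  out <- lapply(names(bounds), function(kind) {
    b <- bounds[[kind]]
    start <- kept[[b[1]]]
    end <- kept[[b[2]]]
    feature_array(
      kind = kind,
      beat_index = seq_len(nrow(beats))[valid],
      start = start, end = end, fs = fs,
      segments = mapply(function(s, e) x[s:(e - 1)], start, end,
                        SIMPLIFY = FALSE))
  })
  names(out) <- names(bounds)
  out
}

feature_array <- function(kind, beat_index, start, end, fs, segments) {
  structure(list(kind = kind,
                 beats = data.frame(beat_index = beat_index, start = start,
                                    end = end,
                                    duration_ms = (end - start) / fs * 1000),
                 segments = segments, fs = fs),
            class = "feature_array")
}

#' @export
length.feature_array <- function(x) length(x$segments)

#' @export
print.feature_array <- function(x, ...) {
  cat("Feature array:", x$kind, "-", length(x), "segments",
      if (length(x)) sprintf("(mean duration %.1f ms)",
                             mean(x$beats$duration_ms)), "\n")
  invisible(x)
}

#' Write a feature array to CSV
#'
#' One row per segment: `beat_index`, `kind`, `start_sample`, `end_sample`,
#' `duration_ms` (1-based, half-open slice bounds).
#'
#' @param fa a `feature_array`.
#' @param path output path.
#' @export
write_feature_csv <- function(fa, path) {
  stopifnot(inherits(fa, "feature_array"))
  df <- data.frame(beat_index = fa$beats$beat_index, kind = fa$kind,
                   start_sample = fa$beats$start, end_sample = fa$beats$end,
                   duration_ms = fa$beats$duration_ms)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
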
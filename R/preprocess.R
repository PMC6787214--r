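#' Construct a uniformly sampled ECG signal
#'
#' @param samples numeric voltage series (arbitrary units).
#' @param fs sampling rate in Hz (> 0).
#' @param meta optional record id / lead label.
#' @return object of class `ecg_signal` with elements `samples`, `fs`, `meta`.
#' @export
ecg_signal <- function(samples, fs, meta = NULL) {
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  samples <- as.numeric(samples)
  if (length(samples) && any(!is.finite(samples))) {
    stop("samples must be finite", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, meta = meta),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat("ECG signal:", length(x$samples), "samples at", x$fs, "Hz",
      if (!is.null(x$meta)) paste0("(", x$meta, ")"), "\n")
  invisible(x)
}

#' Band-limit an ECG signal with cascaded Butterworth filters
#'
#' Applies a high-pass filter (default 1 Hz, removing baseline wander)
#' followed by a low-pass filter (default 40 Hz, removing high-frequency
#' noise), each a Butterworth design of the given order applied
#' forward-backward (zero phase) so fiducial latencies are not shifted.
#'
#' @param ecg an [ecg_signal()].
#' @param hp_hz high-pass cutoff in Hz.
#' @param lp_hz low-pass cutoff in Hz; must satisfy 0 < hp_hz < lp_hz < fs/2.
#' @param order filter order (default 4).
#' @return filtered `ecg_signal` of equal length and sampling rate.
#' @export
bandlimit <- function(ecg, hp_hz = 1, lp_hz = 40, order = 4) {
  stopifnot(inherits(ecg, "ecg_signal"))
  nyq <- ecg$fs / 2
  if (!(hp_hz > 0 && hp_hz < lp_hz && lp_hz < nyq)) {
    stop("cutoffs must satisfy 0 < hp_hz < lp_hz < fs/2 (Nyquist ", nyq,
         " Hz)", call. = FALSE)
  }
  x <- ecg$samples
  if (length(x) == 0) return(ecg)
  hp <- signal::butter(order, hp_hz / nyq, type = "high")
  lp <- signal::butter(order, lp_hz / nyq, type = "low")
  # reflect the record ends before filtering so the high-pass settling
  # transient (time constant ~1/hp_hz) falls in the padding, not the data
  pad <- min(length(x) - 1, ceiling(2 * ecg$fs / hp_hz))
  xp <- if (pad > 0) {
    c(x[(pad + 1):2], x, x[(length(x) - 1):(length(x) - pad)])
  } else x
  y <- signal::filtfilt(hp, xp)
  y <- signal::filtfilt(lp, y)
  if (pad > 0) y <- y[(pad + 1):(pad + length(x))]
  ecg_signal(y, ecg$fs, ecg$meta)
}

#' Min-max normalize an ECG signal to the unit interval
#'
#' Rescales the record so its global minimum maps to 0 and its global
#' maximum to 1: En(t) = (E(t) - Emin) / (Emax - Emin). Normalization is
#' applied per record (single global min/max). The unit range is required by
#' the phase-portrait rasterizer.
#'
#' @param ecg an [ecg_signal()] with at least 2 samples and max > min.
#' @return normalized `ecg_signal` spanning exactly `[0, 1]`.
#' @export
normalize_ecg <- function(ecg) {
  stopifnot(inherits(ecg, "ecg_signal"))
  x <- ecg$samples
  if (length(x) < 2) stop("need at least 2 samples to normalize",
                          call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("degenerate normalization: max equals min",
                             call. = FALSE)
  ecg_signal((x - rng[1]) / (rng[2] - rng[1]), ecg$fs, ecg$meta)
}
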
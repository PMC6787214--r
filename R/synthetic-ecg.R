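#' Specify the morphology and timing of one synthetic beat class
#'
#' A `beat_spec` fixes the target PR interval, QRS width, QT interval and RR
#' cycle length of a beat together with per-wave peak amplitudes and a
#' morphology regime. Each wave (P, Q, R, S, T) is later rendered as a
#' Gaussian bump whose ±3σ extent realizes the requested durations, so the
#' fiducial ground truth of a generated record is known analytically.
#'
#' Morphology regimes mimic qualitative disease signatures without claiming
#' clinical fidelity:
#' \describe{
#'   \item{healthy}{regular morphology, small beat-to-beat jitter.}
#'   \item{af_like}{P wave suppressed and RR jitter inflated to 15 percent,
#'     as in atrial fibrillation.}
#'   \item{bbb_like}{widened, notched (two-bump) QRS, as in bundle branch
#'     block.}
#'   \item{long_qt_like}{prolonged QT with a widened T wave.}
#' }
#'
#' @param pr_ms,qrs_ms,qt_ms,rr_ms interval durations in milliseconds.
#' @param amplitudes named numeric vector with elements `p`, `q`, `r`, `s`,
#'   `t`: peak heights in arbitrary units (sign included).
#' @param morphology one of `"healthy"`, `"af_like"`, `"bbb_like"`,
#'   `"long_qt_like"`.
#' @return an object of class `beat_spec`.
#' @export
#' @examples
#' healthy <- beat_spec()
#' lqt <- beat_spec(qt_ms = 520, morphology = "long_qt_like")
beat_spec <- function(pr_ms = 160, qrs_ms = 90, qt_ms = 380, rr_ms = 800,
                      amplitudes = c(p = 0.15, q = -0.1, r = 1, s = -0.2,
                                     t = 0.3),
                      morphology = c("healthy", "af_like", "bbb_like",
                                     "long_qt_like")) {
  morphology <- match.arg(morphology)
  spec <- structure(
    list(pr_ms = pr_ms, qrs_ms = qrs_ms, qt_ms = qt_ms, rr_ms = rr_ms,
         amplitudes = amplitudes, morphology = morphology),
    class = "beat_spec")
  validate_beat_spec(spec)
  spec
}

validate_beat_spec <- function(spec) {
  durs <- c(pr_ms = spec$pr_ms, qrs_ms = spec$qrs_ms, qt_ms = spec$qt_ms,
            rr_ms = spec$rr_ms)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("beat_spec invariant violated: all durations must be > 0 (got ",
         paste(names(durs)[durs <= 0 | !is.finite(durs)], collapse = ", "),
         ")", call. = FALSE)
  }
  if (spec$qrs_ms >= spec$qt_ms) {
    stop("beat_spec invariant violated: qrs_ms < qt_ms required", call. = FALSE)
  }
  if (spec$pr_ms + spec$qt_ms >= spec$rr_ms) {
    stop("beat_spec invariant violated: pr_ms + qt_ms < rr_ms required",
         call. = FALSE)
  }
  need <- c("p", "q", "r", "s", "t")
  if (!all(need %in% names(spec$amplitudes))) {
    stop("beat_spec invariant violated: amplitudes must name p, q, r, s, t",
         call. = FALSE)
  }
  invisible(spec)
}

# Gaussian bump evaluated over sample grid (ms units in, samples out).
gauss_bump <- function(t_ms, center_ms, sigma_ms, amp) {
  amp * exp(-((t_ms - center_ms)^2) / (2 * sigma_ms^2))
}

# Render one beat: voltage samples plus fiducial truth in ms from beat start.
# Fiducial truth is placed at the ±3 sigma extent of the wave bumps.
render_beat <- function(spec, fs) {
  rr <- spec$rr_ms
  n <- round(rr * fs / 1000)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  amp <- spec$amplitudes

  qrs_on <- 0.35 * rr
  p_on <- qrs_on - spec$pr_ms
  qrs_off <- qrs_on + spec$qrs_ms
  t_off <- qrs_on + spec$qt_ms

  v <- numeric(n)

  # P wave occupies the first ~60% of the PR interval, leaving a PQ segment.
  if (spec$morphology != "af_like") {
    p_dur <- 0.62 * spec$pr_ms
    sig_p <- p_dur / 6
    v <- v + gauss_bump(t_ms, p_on + 3 * sig_p, sig_p, amp[["p"]])
  }

  # QRS: main R bump spans the whole complex at +-3 sigma; narrow Q and S
  # bumps sit so their outer 3 sigma edges coincide with qrs_on / qrs_off.
  qrs <- spec$qrs_ms
  sig_qs <- qrs / 14
  r_center <- (qrs_on + qrs_off) / 2
  if (spec$morphology == "bbb_like") {
    sig_r <- qrs / 9
    v <- v + gauss_bump(t_ms, qrs_on + qrs / 3, sig_r, amp[["r"]])
    v <- v + gauss_bump(t_ms, qrs_on + 2 * qrs / 3, sig_r, 0.8 * amp[["r"]])
    r_center <- qrs_on + qrs / 3
  } else {
    sig_r <- qrs / 6
    v <- v + gauss_bump(t_ms, r_center, sig_r, amp[["r"]])
  }
  v <- v + gauss_bump(t_ms, qrs_on + 3 * sig_qs, sig_qs, amp[["q"]])
  v <- v + gauss_bump(t_ms, qrs_off - 3 * sig_qs, sig_qs, amp[["s"]])

  # T wave ends exactly at t_off; widened for the long-QT regime.
  t_frac <- if (spec$morphology == "long_qt_like") 0.65 else 0.55
  t_dur <- t_frac * (spec$qt_ms - spec$qrs_ms)
  sig_t <- t_dur / 6
  v <- v + gauss_bump(t_ms, t_off - 3 * sig_t, sig_t, amp[["t"]])

  # optional ST-segment shift (elevation/depression) between QRS offset and
  # T onset -- a signed displacement of the repolarization baseline
  st <- spec$st_shift
  if (!is.null(st) && st != 0) {
    t_on <- t_off - 6 * sig_t
    if (t_on - qrs_off > 40) {
      sig_st <- (t_on - qrs_off) / 5
      v <- v + gauss_bump(t_ms, (qrs_off + t_on) / 2, sig_st, st)
    }
  }

  list(samples = v,
       fid_ms = c(p_on = p_on, qrs_on = qrs_on, r_peak = r_center,
                  qrs_off = qrs_off, t_off = t_off))
}

# Polymorphic ectopic (PVC-like) variant of an unhealthy beat: broad P-less
# QRS with its own amplitude draw, compensatory-pause-like cycle, variable
# T. Each call draws a fresh morphology, so no two ectopics trace the same
# phase-space loop.
ectopic_variant <- function(spec) {
  aj <- exp(rnorm(4, 0, 0.25))
  qrs_e <- min(200, spec$qrs_ms * 1.8 * aj[1])
  s <- spec
  s$qrs_ms <- qrs_e
  s$qt_ms <- max(spec$qt_ms * 1.1, qrs_e + 220)
  s$rr_ms <- max(spec$rr_ms * 1.25, s$pr_ms + s$qt_ms + 250)
  s$amplitudes <- c(p = 0.01, q = unname(spec$amplitudes[["q"]] * aj[4]),
                    r = unname(spec$amplitudes[["r"]] * 1.4 * aj[2]),
                    s = unname(spec$amplitudes[["s"]] * aj[4]),
                    t = unname(spec$amplitudes[["t"]] * 1.3 * aj[3]))
  s$morphology <- "bbb_like"
  s
}

# Multiplicative per-beat jitter of the interval durations and wave
# amplitudes (beat-to-beat morphology variability), re-validated so the
# spec invariants survive jitter.
jitter_spec <- function(spec, frac) {
  if (frac <= 0) return(spec)
  rr_frac <- if (spec$morphology == "af_like") 0.15 else frac
  for (try in 1:20) {
    s <- spec
    s$pr_ms <- spec$pr_ms * exp(rnorm(1, 0, frac))
    s$qrs_ms <- spec$qrs_ms * exp(rnorm(1, 0, frac))
    s$qt_ms <- spec$qt_ms * exp(rnorm(1, 0, frac))
    s$rr_ms <- spec$rr_ms * exp(rnorm(1, 0, rr_frac))
    s$amplitudes <- spec$amplitudes *
      exp(rnorm(length(spec$amplitudes), 0, frac))
    ok <- s$qrs_ms < s$qt_ms && s$pr_ms + s$qt_ms < s$rr_ms
    if (ok) return(s)
  }
  spec
}

#' Generate a reproducible synthetic single-lead ECG record
#'
#' Builds `n_healthy` beats from `healthy_spec` followed by `n_unhealthy`
#' beats from `unhealthy_spec` (the healthy-then-unhealthy concatenation the
#' classifier is trained on), with known per-beat fiducial ground truth.
#' Interval durations receive multiplicative log-normal beat-to-beat jitter;
#' the unhealthy regime jitters more than the healthy one, which is what
#' drives the increased phase-portrait spread downstream. Optional additive
#' white noise and 0.3 Hz sinusoidal baseline wander emulate measurement
#' artifacts.
#'
#' @param n_healthy,n_unhealthy beat counts (>= 0).
#' @param healthy_spec,unhealthy_spec [beat_spec()] objects.
#' @param fs sampling rate in Hz (>= 250; default 1000).
#' @param noise_sd SD of additive white Gaussian noise (signal units).
#' @param wander_amp amplitude of 0.3 Hz baseline wander (signal units).
#' @param jitter_healthy,jitter_unhealthy SD of the log-normal duration
#'   jitter for the two blocks (fraction of the duration).
#' @param ectopy_rate probability that an unhealthy beat is replaced by a
#'   polymorphic ectopic beat (widened P-less QRS, raised R, variable T;
#'   each ectopic drawn with its own morphology). Default 0.15; set 0 for
#'   a stationary unhealthy block.
#' @param modulation_depth depth of the active-episode morphology
#'   displacement in the unhealthy block. The block has a paroxysmal
#'   structure: a quiescent run (`quiescent_len` beats) of regular but
#'   abnormal-interval beats, then an active episode in which a severity
#'   staircase sets signed morphology displacements -- ST
#'   elevation/depression, Q/S seesaw, P inversion -- with inflated jitter
#'   and polymorphic ectopy. The alternation between coherent and chaotic
#'   phase portraits is what keeps the diseased block's box-count
#'   dispersion high, as opposed to the one-off healthy-to-unhealthy step.
#'   Default 0.35.
#' @param quiescent_len length of the quiescent diseased run opening the
#'   unhealthy block, in beats; `NULL` (default) uses half the block,
#'   capped at 20.
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   output. The caller's RNG state is restored on exit.
#' @return an object of class `ecg_record`: a list with elements
#'   \describe{
#'     \item{signal}{an [ecg_signal()] of the concatenated beats;}
#'     \item{truth}{data frame of 1-based fiducial sample indices per beat
#'       (`p_on`, `qrs_on`, `r_peak`, `qrs_off`, `t_off`);}
#'     \item{labels}{character vector, `"healthy"` / `"unhealthy"` per beat.}
#'   }
#' @export
#' @examples
#' rec <- generate_record(5, 5, seed = 1)
#' truth_feature_durations(rec)
generate_record <- function(n_healthy, n_unhealthy,
                            healthy_spec = beat_spec(),
                            unhealthy_spec = beat_spec(
                              qt_ms = 520, morphology = "long_qt_like"),
                            fs = 1000, noise_sd = 0, wander_amp = 0,
                            jitter_healthy = 0.02, jitter_unhealthy = 0.06,
                            ectopy_rate = 0.3, modulation_depth = 0.35,
                            quiescent_len = NULL, seed = 0) {
  if (fs < 250) stop("fs must be >= 250 Hz", call. = FALSE)
  if (n_healthy < 0 || n_unhealthy < 0) stop("beat counts must be >= 0",
                                             call. = FALSE)
  validate_beat_spec(healthy_spec)
  validate_beat_spec(unhealthy_spec)

  with_seed(seed, {
    specs <- c(rep(list(healthy_spec), n_healthy),
               rep(list(unhealthy_spec), n_unhealthy))
    jit <- c(rep(jitter_healthy, n_healthy),
             rep(jitter_unhealthy, n_unhealthy))
    labels <- c(rep("healthy", n_healthy), rep("unhealthy", n_unhealthy))

    samples <- numeric(0)
    rows <- vector("list", length(specs))
    offset <- 0L
    q_len <- if (is.null(quiescent_len)) min(20L, n_unhealthy %/% 2)
             else as.integer(quiescent_len)
    severity_levels <- c(-1, 0.15, 1)
    for (i in seq_along(specs)) {
      s <- specs[[i]]
      jit_i <- jit[i]
      if (labels[i] == "unhealthy") {
        k <- i - n_healthy
        if (k <= q_len) {
          # quiescent diseased run: abnormal intervals, regular morphology
          jit_i <- jitter_healthy
        } else {
          if (modulation_depth > 0) {
            # active episode: severity staircase of signed morphology
            # displacements (ST shift, Q/S seesaw, P inversion) so
            # consecutive portraits occupy distinct pixel regions instead
            # of nesting
            d <- modulation_depth
            m <- severity_levels[1 + ((k - q_len - 1) %/% 7L) %% 3]
            s$amplitudes[["r"]] <- s$amplitudes[["r"]] * exp(0.6 * d * m)
            s$amplitudes[["t"]] <- s$amplitudes[["t"]] * exp(0.9 * d * m)
            s$amplitudes[["q"]] <- s$amplitudes[["q"]] * exp(2.5 * d * m)
            s$amplitudes[["s"]] <- s$amplitudes[["s"]] * exp(-2.5 * d * m)
            s$amplitudes[["p"]] <- s$amplitudes[["p"]] * (0.2 - m) / 0.8
            s$pr_ms <- s$pr_ms * exp(0.45 * d * m)
            s$qt_ms <- s$qt_ms * exp(0.3 * d * m)
            s$rr_ms <- s$rr_ms * exp(0.35 * d * m)
            s$st_shift <- -0.7 * d * m
          }
          if (ectopy_rate > 0 && runif(1) < ectopy_rate) {
            s <- ectopic_variant(s)
          }
        }
      }
      s <- jitter_spec(s, jit_i)
      b <- render_beat(s, fs)
      idx <- offset + round(b$fid_ms * fs / 1000) + 1L
      rows[[i]] <- as.list(idx)
      samples <- c(samples, b$samples)
      offset <- offset + length(b$samples)
    }
    truth <- if (length(rows)) {
      do.call(rbind, lapply(rows, as.data.frame))
    } else {
      data.frame(p_on = integer(0), qrs_on = integer(0), r_peak = integer(0),
                 qrs_off = integer(0), t_off = integer(0))
    }
    truth$beat_index <- seq_len(nrow(truth))

    n_tot <- length(samples)
    if (n_tot > 0) {
      if (noise_sd > 0) samples <- samples + rnorm(n_tot, 0, noise_sd)
      if (wander_amp > 0) {
        tt <- (seq_len(n_tot) - 1) / fs
        samples <- samples + wander_amp * sin(2 * pi * 0.3 * tt)
      }
    }

    structure(list(signal = ecg_signal(samples, fs, meta = "synthetic"),
                   truth = truth, labels = labels),
              class = "ecg_record")
  })
}

#' @export
print.ecg_record <- function(x, ...) {
  cat("Synthetic ECG record:", nrow(x$truth), "beats (",
      sum(x$labels == "healthy"), "healthy /",
      sum(x$labels == "unhealthy"), "unhealthy ),",
      length(x$signal$samples), "samples at", x$signal$fs, "Hz\n")
  invisible(x)
}

#' Ground-truth feature durations of a synthetic record
#'
#' Reads the PR, QRS and QT durations back from the fiducial truth table.
#' This is the oracle the feature-extraction accuracy tests compare against.
#'
#' @param record an `ecg_record` from [generate_record()] with >= 1 beat.
#' @return data frame with one row per beat: `beat_index`, `pr_ms`,
#'   `qrs_ms`, `qt_ms`, `label`.
#' @export
truth_feature_durations <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  if (nrow(record$truth) == 0) stop("record has no beats", call. = FALSE)
  fs <- record$signal$fs
  tr <- record$truth
  data.frame(beat_index = tr$beat_index,
             pr_ms = (tr$qrs_on - tr$p_on) / fs * 1000,
             qrs_ms = (tr$qrs_off - tr$qrs_on) / fs * 1000,
             qt_ms = (tr$t_off - tr$qrs_on) / fs * 1000,
             label = record$labels)
}
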
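#' Orthonormal Haar discrete wavelet transform
#'
#' Multiresolution Haar analysis to the requested depth. At every level the
#' running approximation `a` is split into pairwise averages and differences
#' scaled by 1/sqrt(2), so the transform is orthonormal: total coefficient
#' energy equals signal energy and [haar_idwt()] reconstructs the input
#' exactly. The input is cropped to the largest multiple of `2^levels` (the
#' cropped length is recorded so indices map back to the original timeline).
#'
#' Level-3 detail coefficients live at the QRS time scale for 1 kHz ECG and
#' drive beat boundary detection; level-5 details/approximation live at the
#' P/T-wave scale and drive interval delineation.
#'
#' @param x numeric sample series with `length(x) >= 2^levels`.
#' @param levels decomposition depth (>= 1).
#' @return object of class `haar_dwt`: list with `details` (list of
#'   per-level detail coefficient vectors, level 1 first), `approx` (final
#'   approximation), `levels`, `n_used`, `n_orig`.
#' @export
haar_dwt <- function(x, levels) {
  x <- as.numeric(x)
  if (levels < 1) stop("levels must be >= 1", call. = FALSE)
  n <- length(x)
  if (n < 2^levels) {
    stop("signal shorter than 2^levels (need >= ", 2^levels, " samples)",
         call. = FALSE)
  }
  n_used <- as.integer((n %/% 2^levels) * 2^levels)
  a <- x[seq_len(n_used)]
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    odd <- a[seq(1, length(a), by = 2)]
    even <- a[seq(2, length(a), by = 2)]
    details[[j]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  structure(list(details = details, approx = a, levels = levels,
                 n_used = n_used, n_orig = n),
            class = "haar_dwt")
}

#' Inverse orthonormal Haar transform
#'
#' @param dec a `haar_dwt` object.
#' @return numeric vector of length `dec$n_used` reconstructing the
#'   (cropped) input.
#' @export
haar_idwt <- function(dec) {
  stopifnot(inherits(dec, "haar_dwt"))
  a <- dec$approx
  for (j in rev(seq_len(dec$levels))) {
    d <- dec$details[[j]]
    odd <- (a + d) / sqrt(2)
    even <- (a - d) / sqrt(2)
    out <- numeric(2 * length(a))
    out[seq(1, length(out), by = 2)] <- odd
    out[seq(2, length(out), by = 2)] <- even
    a <- out
  }
  a
}

# Detail magnitude of one level mapped back onto the sample timeline: each
# level-j coefficient covers 2^j samples; the tail beyond the cropped length
# repeats the last value.
haar_detail_envelope <- function(x, level) {
  dec <- haar_dwt(x, level)
  env <- rep(abs(dec$details[[level]]), each = 2^level)
  n <- length(x)
  if (length(env) < n) env <- c(env, rep(env[length(env)], n - length(env)))
  env[seq_len(n)]
}

# Centered moving average (width in samples), edges padded by replication.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  h <- (width - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  cs <- cumsum(xp)
  (cs[(width):length(xp)] - c(0, cs[seq_len(length(xp) - width)])) / width
}
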
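#' Sliding-window mean, SD and coefficient of variation of box counts
#'
#' Window `m` covers counts `m ... m + w - 1`, advancing by one count, so
#' `k` counts give exactly `k - w + 1` windows (`k - 19` at the default
#' `w = 20`). The SD is the population second central moment (divide by
#' `w`), matching the trend definition; the coefficient of variation is
#' `CV = sd / mean`. A window of all-zero counts (all-empty portraits) gets
#' `CV = 0` with a warning.
#'
#' @param counts a `box_count_series` (or bare numeric vector).
#' @param w stats window length (default 20, must satisfy `2 <= w <= k`).
#' @return object of class `cv_trace`: list with numeric vectors `means`,
#'   `sds`, `cvs` (equal lengths), `w`, `kind`.
#' @export
sliding_stats <- function(counts, w = 20) {
  v <- count_values(counts)
  k <- length(v)
  if (w < 2) stop("w must be >= 2", call. = FALSE)
  if (k < w) stop("need at least w counts (k = ", k, ", w = ", w, ")",
                  call. = FALSE)
  cs <- cumsum(c(0, v))
  cs2 <- cumsum(c(0, v^2))
  m <- seq_len(k - w + 1)
  means <- (cs[m + w] - cs[m]) / w
  vars <- pmax((cs2[m + w] - cs2[m]) / w - means^2, 0)
  sds <- sqrt(vars)
  cvs <- ifelse(means > 0, sds / means, 0)
  if (any(means == 0)) {
    warning("window(s) with zero mean box count: CV recorded as 0",
            call. = FALSE)
  }
  cv_trace(means, sds, cvs, w, count_kind(counts))
}

#' Non-overlapping (static) window statistics
#'
#' Same statistics as [sliding_stats()] but with stride `w` (no overlap):
#' `floor(k/w)` windows. Provided for comparing the smooth sliding CV trend
#' with the erratic static-window alternative; the classifier always uses
#' the sliding form.
#'
#' @inheritParams sliding_stats
#' @return a `cv_trace` of length `floor(k/w)`.
#' @export
static_window_stats <- function(counts, w = 20) {
  v <- count_values(counts)
  k <- length(v)
  if (w < 2) stop("w must be >= 2", call. = FALSE)
  if (k < w) stop("need at least w counts", call. = FALSE)
  starts <- seq(1, k - w + 1, by = w)
  means <- vapply(starts, function(s) mean(v[s:(s + w - 1)]), numeric(1))
  sds <- vapply(starts, function(s) {
    seg <- v[s:(s + w - 1)]
    sqrt(mean((seg - mean(seg))^2))
  }, numeric(1))
  cvs <- ifelse(means > 0, sds / means, 0)
  if (any(means == 0)) {
    warning("window(s) with zero mean box count: CV recorded as 0",
            call. = FALSE)
  }
  cv_trace(means, sds, cvs, w, count_kind(counts))
}

count_values <- function(counts) {
  if (inherits(counts, "box_count_series")) as.numeric(counts$counts)
  else as.numeric(counts)
}

count_kind <- function(counts) {
  if (inherits(counts, "box_count_series")) counts$kind else NA_character_
}

cv_trace <- function(means, sds, cvs, w, kind = NA_character_) {
  structure(list(means = means, sds = sds, cvs = cvs, w = w, kind = kind),
            class = "cv_trace")
}

#' @export
length.cv_trace <- function(x) length(x$cvs)

#' @export
print.cv_trace <- function(x, ...) {
  cat("CV trace (", x$kind, "): ", length(x), " windows of ", x$w,
      " counts; CV range [", sprintf("%.4g", min(x$cvs)), ", ",
      sprintf("%.4g", max(x$cvs)), "]\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cv_trace <- function(x, ...) {
  data.frame(window_index = seq_along(x$cvs), mean = x$means, sd = x$sds,
             cv = x$cvs)
}

#' Write a CV trace to CSV
#'
#' @param trace a `cv_trace`.
#' @param path output path.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
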
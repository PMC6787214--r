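#' Build sliding windows of consecutive feature segments
#'
#' Groups `w1` consecutive feature segments (default 20) into one interval
#' window, advancing by `step` segments (default 1, i.e. 19 segments shared
#' with the previous window). Each window's segments are concatenated into
#' one continuous series `SW(t)` for delay embedding. With `n` segments the
#' window count is `floor((n - w1)/step) + 1` (0 when `n < w1`); 109
#' consecutive intervals thus yield 90 windows at the defaults.
#'
#' @param fa a `feature_array` from [extract_features()].
#' @param w1 window length in segments.
#' @param step stride in segments.
#' @return list of `interval_window` objects: `kind`, `window_index`,
#'   `beat_indices`, `series`.
#' @export
make_interval_windows <- function(fa, w1 = 20, step = 1) {
  stopifnot(inherits(fa, "feature_array"))
  if (w1 < 1 || step < 1) stop("w1 and step must be >= 1", call. = FALSE)
  n <- length(fa)
  if (n < w1) return(list())
  starts <- seq(1L, n - w1 + 1L, by = step)
  lapply(seq_along(starts), function(j) {
    idx <- starts[j]:(starts[j] + w1 - 1L)
    structure(list(kind = fa$kind, window_index = j,
                   beat_indices = fa$beats$beat_index[idx],
                   series = unlist(fa$segments[idx], use.names = FALSE)),
              class = "interval_window")
  })
}

#' Delay-embed a series into 2-D phase-space point pairs
#'
#' Pairs the series with its delayed copy: pair `j` is
#' `(series[j + T], series[j])` for delay `T` samples, giving `L - T` points
#' for a series of length `L`. The delay (default 20 ms) is chosen so
#' trajectories span the plane instead of collapsing onto the diagonal.
#'
#' @param window an `interval_window` (or a bare numeric series).
#' @param delay_ms embedding delay in milliseconds.
#' @param fs sampling rate in Hz; delay in samples =
#'   `round(delay_ms * fs / 1000)`.
#' @return two-column matrix (`x` = delayed-ahead value `x(t)`,
#'   `y` = `x(t - T)`).
#' @export
embed_delay <- function(window, delay_ms = 20, fs = 1000) {
  series <- if (inherits(window, "interval_window")) window$series
            else as.numeric(window)
  delay <- as.integer(round(delay_ms * fs / 1000))
  if (delay < 1) stop("delay must be >= 1 sample", call. = FALSE)
  L <- length(series)
  if (L <= delay) stop("segment shorter than delay", call. = FALSE)
  cbind(x = series[(delay + 1):L], y = series[1:(L - delay)])
}

#' Rasterize embedded pairs into an N-by-N phase portrait
#'
#' Maps the unit square onto an `grid_n` by `grid_n` pixel grid (half-open
#' cells `[i/N, (i+1)/N)`, closed at 1.0) and marks as black every pixel the
#' trajectory passes through. In `"line"` mode (default) each pixel crossed
#' by the polyline through consecutive embedded points is black (exact
#' supercover tracing); `"point"` mode marks only pixels containing the
#' sample points themselves.
#'
#' @param pairs two-column matrix of coordinates in `[0, 1]^2`.
#' @param grid_n grid resolution N (>= 2, default 100).
#' @param mode `"line"` or `"point"`.
#' @return object of class `phase_portrait`: list with `grid` (N x N logical
#'   occupancy matrix, rows = y cells, columns = x cells), `n_black`,
#'   `n_white`, `grid_n`, `mode`.
#' @export
rasterize <- function(pairs, grid_n = 100, mode = c("line", "point")) {
  mode <- match.arg(mode)
  if (grid_n < 2) stop("grid_n must be >= 2", call. = FALSE)
  pairs <- as.matrix(pairs)
  if (length(pairs) && (ncol(pairs) != 2 ||
                        any(pairs < 0) || any(pairs > 1))) {
    stop("coordinates must lie within [0, 1]; normalize the signal first",
         call. = FALSE)
  }
  if (nrow(pairs) == 0) {
    grid <- matrix(FALSE, grid_n, grid_n)
  } else if (mode == "line") {
    grid <- raster_line_grid(pairs[, 1], pairs[, 2], grid_n)
  } else {
    cx <- pmin(floor(pairs[, 1] * grid_n), grid_n - 1)
    cy <- pmin(floor(pairs[, 2] * grid_n), grid_n - 1)
    grid <- matrix(FALSE, grid_n, grid_n)
    grid[cbind(cy + 1, cx + 1)] <- TRUE
  }
  nb <- as.integer(sum(grid))
  structure(list(grid = grid, n_black = nb,
                 n_white = as.integer(grid_n * grid_n) - nb,
                 grid_n = grid_n, mode = mode),
            class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat("Phase portrait:", x$grid_n, "x", x$grid_n, "grid,", x$n_black,
      "black /", x$n_white, "white pixels\n")
  invisible(x)
}

#' Box-count series over a sequence of interval windows
#'
#' Delay-embeds and rasterizes every window and records the number of black
#' pixels `n_b` per portrait, in window order. Windows whose concatenated
#' series is not longer than the delay are dropped with a warning.
#'
#' @param windows list of `interval_window`s from [make_interval_windows()].
#' @param delay_ms embedding delay in milliseconds.
#' @param fs sampling rate in Hz.
#' @param grid_n portrait resolution.
#' @param mode rasterization mode, see [rasterize()].
#' @return object of class `box_count_series`: list with `counts` (integer
#'   vector), `window_index`, `kind`, `k` (series length).
#' @export
box_count_series <- function(windows, delay_ms = 20, fs = 1000,
                             grid_n = 100, mode = "line") {
  if (!length(windows)) stop("no windows supplied", call. = FALSE)
  delay <- as.integer(round(delay_ms * fs / 1000))
  ok <- vapply(windows, function(w) length(w$series) > delay, logical(1))
  if (!any(ok)) stop("all windows shorter than the embedding delay",
                     call. = FALSE)
  if (any(!ok)) {
    warning(sum(!ok), " window(s) dropped: series shorter than the delay",
            call. = FALSE)
  }
  windows <- windows[ok]
  counts <- vapply(windows, function(w) {
    rasterize(embed_delay(w, delay_ms, fs), grid_n, mode)$n_black
  }, numeric(1))
  structure(list(counts = as.integer(counts),
                 window_index = vapply(windows, function(w)
                   w$window_index, numeric(1)),
                 kind = windows[[1]]$kind, k = length(counts)),
            class = "box_count_series")
}

#' Export a phase portrait as a PGM (P5) or PNG image
#'
#' Black pixels render as 0 (black), untouched pixels as 255. PNG export
#' requires the `png` package.
#'
#' @param portrait a `phase_portrait`.
#' @param path output path; format chosen by extension (`.pgm` or `.png`).
#' @export
write_portrait <- function(portrait, path) {
  stopifnot(inherits(portrait, "phase_portrait"))
  # image row 1 = top of plot = largest y cell
  img <- 1 - portrait$grid[rev(seq_len(portrait$grid_n)), , drop = FALSE]
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("PNG export requires the 'png' package; use .pgm instead",
           call. = FALSE)
    }
    png::writePNG(img, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", portrait$grid_n, portrait$grid_n),
              con, eos = NULL)
    writeBin(as.raw(t(img) * 255), con)
  }
  invisible(path)
}
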
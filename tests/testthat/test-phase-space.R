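make_fa <- function(n_seg, seg_len = 120) {
  # synthetic feature array with constant segments for window bookkeeping
  feature_array <- getFromNamespace("feature_array", "psrcvd")
  feature_array("QT", seq_len(n_seg), start = seq_len(n_seg) * 1000L,
                end = seq_len(n_seg) * 1000L + seg_len, fs = 1000,
                segments = replicate(n_seg, runif(seg_len), simplify = FALSE))
}

test_that("interval window counts follow floor((n - w1)/step) + 1", {
  set.seed(1)
  expect_length(make_interval_windows(make_fa(109)), 90)
  expect_length(make_interval_windows(make_fa(20)), 1)
  expect_length(make_interval_windows(make_fa(19)), 0)
  w <- make_interval_windows(make_fa(25), w1 = 10, step = 5)
  expect_length(w, 4)
  expect_identical(w[[2]]$beat_indices, 6:15)
  # series is the concatenation of the member segments
  expect_length(w[[1]]$series, 10 * 120)
})

test_that("delay embedding produces the defined point pairs", {
  x <- seq(0, 1, length.out = 120)
  pairs <- embed_delay(x, delay_ms = 20, fs = 1000)
  expect_identical(nrow(pairs), 100L)
  expect_equal(pairs[1, ], c(x = x[21], y = x[1]))
  expect_equal(pairs[100, ], c(x = x[120], y = x[100]))
  const <- embed_delay(rep(0.4, 50), 20, 1000)
  expect_true(all(const == 0.4))
  expect_error(embed_delay(rep(0.4, 20), 20, 1000), "shorter than delay")
})

test_that("a sine embedded at quarter period lies on a circle", {
  fs <- 1000; f <- 5
  tt <- (0:999) / fs
  x <- 0.5 + 0.4 * sin(2 * pi * f * tt)
  quarter_ms <- 1000 / f / 4
  pairs <- embed_delay(x, quarter_ms, fs)
  r2 <- (pairs[, 1] - 0.5)^2 + (pairs[, 2] - 0.5)^2
  expect_lt(max(abs(r2 - 0.4^2)), 1e-3)
})

test_that("rasterization handles degenerate inputs per contract", {
  empty <- rasterize(matrix(numeric(0), ncol = 2), grid_n = 10)
  expect_identical(empty$n_black, 0L)
  single <- rasterize(rbind(c(0.5, 0.5), c(0.5, 0.5)), grid_n = 10)
  expect_identical(single$n_black, 1L)
  diag <- rasterize(rbind(c(0, 0), c(1, 1)), grid_n = 10, mode = "line")
  expect_identical(diag$n_black, 10L)
  expect_error(rasterize(rbind(c(0, 1.2)), grid_n = 10), "within \\[0, 1\\]")
  expect_error(rasterize(rbind(c(0.5, 0.5)), grid_n = 1), "grid_n")
})

test_that("conservation and mode monotonicity hold for random trajectories", {
  set.seed(7)
  for (i in 1:10) {
    pairs <- cbind(runif(40), runif(40))
    n <- sample(5:30, 1)
    line <- rasterize(pairs, n, "line")
    point <- rasterize(pairs, n, "point")
    expect_identical(line$n_black + line$n_white, as.integer(n^2))
    expect_identical(point$n_black + point$n_white, as.integer(n^2))
    expect_gte(line$n_black, point$n_black)
    # every sample point's pixel is black in both modes
    expect_true(all(line$grid[point$grid]))
  }
})

test_that("line rasterization equals the brute-force intersection oracle", {
  set.seed(11)
  for (i in 1:12) {
    n <- sample(4:16, 1)
    np <- sample(2:50, 1)
    pairs <- cbind(runif(np), runif(np))
    expect_identical(rasterize(pairs, n, "line")$grid,
                     raster_oracle(pairs, n))
  }
  # axis-aligned and gridline-coincident segments
  expect_identical(rasterize(rbind(c(0.5, 0), c(0.5, 1)), 10)$grid,
                   raster_oracle(rbind(c(0.5, 0), c(0.5, 1)), 10))
})

test_that("box-count series preserves order, count and determinism", {
  set.seed(2)
  fa <- make_fa(24)
  windows <- make_interval_windows(fa)
  bc <- box_count_series(windows, delay_ms = 20, fs = 1000, grid_n = 50)
  expect_identical(bc$k, 5L)
  expect_identical(bc$window_index, as.numeric(1:5))
  dup <- rep(windows[1], 5)
  bc2 <- box_count_series(dup, 20, 1000, 50)
  expect_true(all(bc2$counts == bc2$counts[1]))
  short <- windows
  short[[2]]$series <- short[[2]]$series[1:10]
  expect_warning(bc3 <- box_count_series(short, 20, 1000, 50), "dropped")
  expect_identical(bc3$k, 4L)
  short1 <- list(short[[2]])
  expect_error(box_count_series(short1, 20, 1000, 50), "shorter than")
})

test_that("diseased windows produce larger box counts than healthy ones", {
  for (seed in 1:4) {
    tr <- transition_run(seed)
    ab <- truth_ab_indices(tr$rec$labels, clamp = TRUE)
    counts <- tr$run$QT$counts$counts
    healthy_idx <- seq_len(sum(tr$rec$labels == "healthy") - 19)
    unhealthy_idx <- (sum(tr$rec$labels == "healthy") + 1):length(counts)
    expect_gt(mean(counts[unhealthy_idx]), mean(counts[healthy_idx]))
  }
})

test_that("short delays concentrate the portrait near the diagonal", {
  cf <- clean_features(2, n = 25)
  w <- make_interval_windows(cf$features$QT)[[1]]
  frac_diag <- function(p) {
    idx <- which(p$grid, arr.ind = TRUE)
    mean(abs(idx[, 1] - idx[, 2]) <= 1)
  }
  p5 <- rasterize(embed_delay(w, 5, 1000), 100)
  p20 <- rasterize(embed_delay(w, 20, 1000), 100)
  expect_gt(frac_diag(p5), frac_diag(p20))
})

test_that("portrait export writes parseable images", {
  p <- rasterize(rbind(c(0, 0), c(1, 1)), 16)
  pgm <- withr::local_tempfile(fileext = ".pgm")
  write_portrait(p, pgm)
  con <- file(pgm, "rb")
  hdr <- readLines(con, n = 3, warn = FALSE)
  pix <- readBin(con, "raw", 16 * 16)
  close(con)
  expect_identical(hdr[1], "P5")
  expect_identical(sum(pix == 0), 16L)            # the diagonal is black
})
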
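test_that("CSV writer and reader are inverse", {
  rec <- clean_record(1, n = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ecg_csv(rec$signal, path)
  back <- read_ecg(path, format = "csv")
  expect_identical(back$samples, rec$signal$samples)
  expect_equal(back$fs, rec$signal$fs)
})

test_that("irregular time axis is rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  tt <- (0:99) / 1000
  tt[50] <- tt[50] + 2e-4                        # 20% local jitter
  writeLines(c("t,voltage", sprintf("%.17g,%g", tt, sin(1:100))), path)
  expect_error(read_ecg(path), "non-uniform sampling")
})

test_that("a record written as WFDB round-trips, including channel selection", {
  rec <- clean_record(2, n = 3)
  dir <- withr::local_tempdir()
  base <- file.path(dir, "rec1")
  write_ecg_wfdb(rec$signal, base)
  back <- read_ecg(base, format = "wfdb")
  expect_equal(back$fs, 1000)
  # 16-bit storage at gain 200 quantizes to 1/400 units
  expect_lt(max(abs(back$samples - rec$signal$samples)), 1 / 300)

  # two-channel fixture constructed independently of the package writer
  ch1 <- as.integer(round(200 * sin(2 * pi * (0:499) / 100)))
  ch2 <- as.integer(round(200 * cos(2 * pi * (0:499) / 50)))
  writeLines(c("twoch 2 500 500",
               "twoch.dat 16 200(0)/mV 16 0 0 0 0 I",
               "twoch.dat 16 200(0)/mV 16 0 0 0 0 II"),
             file.path(dir, "twoch.hea"))
  inter <- as.integer(rbind(ch1, ch2))               # interleaved frames
  writeBin(inter, file.path(dir, "twoch.dat"), size = 2, endian = "little")
  second <- read_ecg(file.path(dir, "twoch"), format = "wfdb", channel = 2)
  expect_equal(second$samples, ch2 / 200)
  expect_equal(second$fs, 500)
  expect_error(read_ecg(file.path(dir, "twoch"), channel = 3),
               "channel 3 not present")
})

test_that("band-limiting attenuates stopband and preserves passband", {
  fs <- 1000
  tt <- seq(0, 30, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  slow <- ecg_signal(sin(2 * pi * 0.2 * tt), fs)
  out <- bandlimit(slow)
  expect_lt(rms(out$samples) / rms(slow$samples), 0.1)
  mid <- ecg_signal(sin(2 * pi * 10 * tt), fs)
  out <- bandlimit(mid)
  expect_equal(rms(out$samples) / rms(mid$samples), 1, tolerance = 0.1)
  zero <- ecg_signal(rep(0, 1000), fs)
  expect_equal(bandlimit(zero)$samples, rep(0, 1000))
})

test_that("band-limiting preserves length and fs and rejects bad cutoffs", {
  sig <- ecg_signal(rnorm(2048), 500)
  out <- bandlimit(sig)
  expect_length(out$samples, 2048)
  expect_identical(out$fs, 500)
  expect_error(bandlimit(sig, lp_hz = 300), "Nyquist")
  expect_error(bandlimit(sig, hp_hz = 50, lp_hz = 40), "Nyquist|cutoffs")
})

test_that("normalization maps forced examples and rejects degenerate input", {
  expect_equal(normalize_ecg(ecg_signal(c(-2, 0, 2), 1))$samples,
               c(0, 0.5, 1))
  already <- ecg_signal(c(0, 0.25, 1), 1)
  expect_equal(normalize_ecg(already)$samples, already$samples)
  expect_error(normalize_ecg(ecg_signal(c(5, 5, 5), 1)),
               "degenerate normalization")
})

test_that("normalization is idempotent and affine-invariant", {
  set.seed(5)
  for (i in 1:5) {
    x <- ecg_signal(rnorm(200), 100)
    n1 <- normalize_ecg(x)
    expect_equal(normalize_ecg(n1)$samples, n1$samples)
    a <- runif(1, 0.1, 7); b <- runif(1, -5, 5)
    scaled <- ecg_signal(a * x$samples + b, 100)
    expect_equal(normalize_ecg(scaled)$samples, n1$samples)
  }
})
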
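# Shared fixtures, memoised so expensive pipeline runs happen once per
# test session.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

clean_record <- function(seed = 1, n = 10) {
  cached(paste0("clean_", seed, "_", n),
         generate_record(n, 0, jitter_healthy = 0, seed = seed))
}

preprocessed <- function(rec) normalize_ecg(bandlimit(rec$signal))

# preprocessed signal + detected beats + features for a clean record
clean_features <- function(seed = 1, n = 10) {
  cached(paste0("cleanfeat_", seed, "_", n), {
    rec <- clean_record(seed, n)
    pre <- preprocessed(rec)
    beats <- detect_beats(pre)
    list(rec = rec, pre = pre, beats = beats,
         features = extract_features(pre, beats))
  })
}

# full pipeline run on a healthy-only jittered record
healthy_run <- function(seed) {
  cached(paste0("healthyrun_", seed), {
    rec <- generate_record(45, 0, seed = seed)
    list(rec = rec, run = suppressWarnings(run_pipeline(rec)))
  })
}

# full pipeline run on a healthy -> unhealthy transition record
transition_run <- function(seed) {
  cached(paste0("transrun_", seed), {
    rec <- generate_record(45, 39, seed = seed)
    list(rec = rec, run = suppressWarnings(run_pipeline(rec)))
  })
}

# brute-force rasterization oracle: pixel (i, j) is black iff some segment
# of the polyline has a parameter value whose point maps to that pixel
# under the half-open floor-clamp convention. Computed per pixel from the
# closed-form t-intervals of each axis.
raster_oracle <- function(pairs, n) {
  g <- matrix(FALSE, n, n)
  cell_of <- function(v) pmin(floor(v * n), n - 1)
  if (nrow(pairs) >= 1) {
    g[cell_of(pairs[1, 2]) + 1, cell_of(pairs[1, 1]) + 1] <- TRUE
  }
  seg_axis_interval <- function(v0, v1, i) {
    # t range where coordinate lies in [i/n, (i+1)/n)
    if (v0 == v1) {
      if (cell_of(v0) == i) c(0, 1) else NULL
    } else {
      tt <- sort(c((i / n - v0) / (v1 - v0), ((i + 1) / n - v0) / (v1 - v0)))
      out <- c(max(0, tt[1]), min(1, tt[2]))
      if (out[1] > out[2]) NULL else out
    }
  }
  for (s in seq_len(max(nrow(pairs) - 1, 0))) {
    v <- pairs[s, ]; w <- pairs[s + 1, ]
    for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
      if (g[j + 1, i + 1]) next
      tx <- seg_axis_interval(v[1], w[1], i)
      ty <- seg_axis_interval(v[2], w[2], j)
      if (is.null(tx) || is.null(ty)) next
      lo <- max(tx[1], ty[1]); hi <- min(tx[2], ty[2])
      if (lo > hi) next
      tm <- (lo + hi) / 2
      px <- v[1] + tm * (w[1] - v[1]); py <- v[2] + tm * (w[2] - v[2])
      if (cell_of(px) == i && cell_of(py) == j) g[j + 1, i + 1] <- TRUE
    }
  }
  g
}
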
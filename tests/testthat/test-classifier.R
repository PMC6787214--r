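trace_from <- function(cvs, w = 20) {
  cv_trace <- getFromNamespace("cv_trace", "psrcvd")
  cv_trace(means = rep(1, length(cvs)), sds = cvs, cvs = cvs, w = w,
           kind = "QT")
}

test_that("patient extrema read the healthy prefix and unhealthy suffix", {
  lab <- labeled_cv_trace(trace_from(c(0.03, 0.05, 0.04, 0.12, 0.11, 0.15)),
                          a_index = 3, b_index = 4)
  expect_equal(patient_extrema(lab), c(th_max = 0.05, th_min = 0.11))
  mono <- labeled_cv_trace(trace_from(seq(0.01, 0.1, by = 0.01)),
                           a_index = 4, b_index = 7)
  expect_equal(patient_extrema(mono),
               c(th_max = 0.04, th_min = 0.07))
  expect_error(labeled_cv_trace(trace_from(rep(0.1, 5)), 4, 4), "a_index")
  expect_error(labeled_cv_trace(trace_from(rep(0.1, 5)), 2, 6), "a_index")
})

test_that("threshold learning is max-of-maxima / min-of-minima", {
  mk <- function(th_max, th_min) {
    labeled_cv_trace(trace_from(c(th_max / 2, th_max, th_min, th_min * 2)),
                     a_index = 2, b_index = 3)
  }
  set <- list(mk(0.05, 0.11), mk(0.06, 0.10), mk(0.04, 0.13))
  th <- learn_thresholds(set, "PR")
  expect_equal(th$th_final_max, 0.06)
  expect_equal(th$th_final_min, 0.10)
  expect_false(th$degenerate)
  expect_identical(th$n_patients, 3L)
  one <- learn_thresholds(set[1], "PR")
  expect_equal(unname(unlist(one[c("th_final_max", "th_final_min")])),
               unname(patient_extrema(set[[1]])))
  same <- learn_thresholds(rep(set[2], 4), "PR")
  expect_equal(same$th_final_max, 0.06)
  expect_equal(same$th_final_min, 0.10)
  expect_error(learn_thresholds(list()), "empty")
})

test_that("learned pairs stay in the convex hull and grow monotonically", {
  set.seed(6)
  mk_rand <- function() {
    cvs <- c(sort(runif(3, 0.01, 0.08)), sort(runif(3, 0.05, 0.2)))
    labeled_cv_trace(trace_from(cvs), a_index = 3, b_index = 4)
  }
  set <- replicate(8, mk_rand(), simplify = FALSE)
  ex <- vapply(set, patient_extrema, numeric(2))
  th <- learn_thresholds(set, "QT")
  expect_true(all(th$th_final_max >= ex["th_max", ]))
  expect_true(all(th$th_final_min <= ex["th_min", ]))
  th_small <- learn_thresholds(set[1:4], "QT")
  expect_gte(th$th_final_max, th_small$th_final_max)
  expect_lte(th$th_final_min, th_small$th_final_min)
})

test_that("the published threshold pairs drive the three-band rule", {
  pr <- published_thresholds("PR")
  expect_identical(as.character(classify_cv(0.05, pr)), "healthy")
  expect_identical(as.character(classify_cv(0.15, pr)), "unhealthy")
  expect_identical(as.character(classify_cv(0.08, pr)),
                   "tending_to_unhealthy")
  # boundary semantics: both bounds inclusive
  expect_identical(as.character(classify_cv(pr$th_final_max, pr)), "healthy")
  expect_identical(as.character(classify_cv(pr$th_final_min, pr)),
                   "unhealthy")
  qt <- published_thresholds("QT")
  expect_identical(as.character(classify_cv(0.0805, qt)),
                   "tending_to_unhealthy")
})

test_that("classification is monotone in CV", {
  th <- threshold_pair("QT", 0.07, 0.1)
  labels <- classify_cv(seq(0, 0.2, by = 0.005), th)
  expect_false(is.unsorted(labels))
})

test_that("degenerate pairs are flagged, rejected, and degraded gracefully", {
  dg <- threshold_pair("QT", 0.12, 0.08)
  expect_true(dg$degenerate)
  expect_error(classify_cv(0.05, dg), "degenerate")
  expect_warning(res <- classify_trace(trace_from(c(0.05, 0.15)), dg),
                 "midpoint")
  expect_identical(as.character(res$windows), c("healthy", "unhealthy"))
  expect_error(threshold_pair("QT", -0.1, 0.2), "> 0")
})

test_that("trace classification aggregates with the any-window rule", {
  th <- threshold_pair("QT", 0.07, 0.1)
  all_low <- classify_trace(trace_from(c(0.02, 0.05, 0.06)), th)
  expect_identical(as.character(all_low$subject), "healthy")
  tending <- classify_trace(trace_from(c(0.02, 0.08, 0.05)), th)
  expect_identical(as.character(tending$subject), "tending_to_unhealthy")
  one_hit <- classify_trace(trace_from(c(0.02, 0.1, 0.05)), th)
  expect_identical(as.character(one_hit$subject), "unhealthy")
  expect_error(classify_trace(trace_from(numeric(0)), th), "empty")
})

test_that("train/validation splits are stratified, sized and reproducible", {
  labels <- rep(c("healthy", "unhealthy"), c(33, 32))
  sp <- split_train_validate(labels, 0.8, seed = 1)
  expect_length(sp$train, 52)
  expect_length(sp$validate, 13)
  expect_identical(sort(c(sp$train, sp$validate)), 1:65)
  # both strata represented on both sides
  for (side in sp) expect_identical(sort(unique(labels[side])),
                                    c("healthy", "unhealthy"))
  sp2 <- split_train_validate(labels, 0.8, seed = 1)
  expect_identical(sp, sp2)
  sp3 <- split_train_validate(labels, 0.8, seed = 2)
  expect_false(identical(sp, sp3))
  tiny <- split_train_validate(c("a", "b"), 0.5, seed = 1)
  expect_length(tiny$train, 1)
  expect_length(tiny$validate, 1)
  expect_error(split_train_validate(labels, 1.2), "train_fraction")
})

test_that("threshold pairs persist through JSON round-trip", {
  th <- published_thresholds("QRS")
  path <- withr::local_tempfile(fileext = ".json")
  write_thresholds_json(th, path)
  back <- read_thresholds_json(path)
  expect_equal(back$th_final_max, th$th_final_max)
  expect_equal(back$th_final_min, th$th_final_min)
  expect_identical(back$kind, "QRS")
})
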
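test_that("diagnosis measures reproduce the worked confusion arithmetic", {
  # 62 of 65 diseased detected, zero false positives among 65 healthy
  m <- diagnosis_measures(confusion_counts(tp = 62, fn = 3, tn = 65, fp = 0))
  expect_equal(m$acc, 100 * 127 / 130, tolerance = 1e-10)   # 97.69%
  expect_equal(m$se, 100 * 62 / 65, tolerance = 1e-10)      # 95.38%
  expect_equal(m$sp, 100)
  expect_equal(m$ppv, 100)
  expect_equal(m$npv, 100 * 65 / 68, tolerance = 1e-10)     # 95.58%
})

test_that("perfect and coin-flip classifiers give the canonical measures", {
  perfect <- diagnosis_measures(confusion_counts(10, 0, 10, 0))
  for (k in c("se", "sp", "acc", "ppv", "npv", "f1")) {
    expect_equal(perfect[[k]], 100)
  }
  for (k in c("fpr", "fdr", "fnr")) expect_equal(perfect[[k]], 0)
  half <- diagnosis_measures(confusion_counts(1, 1, 1, 1))
  for (k in names(half)) expect_equal(half[[k]], 50)
})

test_that("zero denominators yield NA, and complementarity holds", {
  no_pos <- diagnosis_measures(confusion_counts(0, 0, 5, 0))
  expect_true(is.na(no_pos$se))
  expect_true(is.na(no_pos$ppv))
  expect_equal(no_pos$sp, 100)
  expect_error(confusion_counts(0, 0, 0, 0), "all-zero")
  set.seed(8)
  for (i in 1:10) {
    cc <- confusion_counts(sample(0:20, 1) + 1, sample(0:20, 1),
                           sample(0:20, 1) + 1, sample(0:20, 1))
    m <- diagnosis_measures(cc)
    expect_equal(m$fpr + m$sp, 100)
    expect_equal(m$fnr + m$se, 100)
    if (!is.na(m$ppv)) expect_equal(m$fdr + m$ppv, 100)
  }
})

test_that("confidence intervals follow the t closed form", {
  expect_equal(mean_ci(5, 0, 10), c(lcl = 5, ucl = 5))
  ci <- mean_ci(0.037, 0.0135, 65, 0.95)
  expect_equal(unname(ci), c(0.03366, 0.04034), tolerance = 1e-3)
  wide <- mean_ci(0.037, 0.0135, 65, 0.99)
  expect_lt(wide["lcl"], ci["lcl"])
  expect_gt(wide["ucl"], ci["ucl"])
  half_n <- mean_ci(0.037, 0.0135, 16, 0.95)
  expect_gt(half_n["ucl"] - half_n["lcl"], 1.9 * (ci["ucl"] - ci["lcl"]))
  expect_error(mean_ci(1, -1, 10), "sd")
})

test_that("the one-tailed paired t test matches its closed form", {
  x <- c(1, 2, 3)
  res <- paired_t_one_tailed(rep(0, 3), x)
  t_hand <- mean(x) / (sd(x) / sqrt(3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pt(t_hand, 2, lower.tail = FALSE))
  null <- paired_t_one_tailed(c(1, 2, 4), c(1, 2, 4))
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 0.5)
  expect_false(null$reject)
  expect_error(paired_t_one_tailed(c(0, 0), c(1, 1)), "zero-variance")
  expect_error(paired_t_one_tailed(1:3, 1:4), "equal length")
})

test_that("repeated-measures ANOVA equals the squared paired t", {
  set.seed(12)
  for (i in 1:8) {
    n <- sample(5:30, 1)
    h <- rnorm(n, 0.05, 0.02)
    u <- rnorm(n, 0.15, 0.05)
    tt <- paired_t_one_tailed(h, u)
    ff <- rm_anova_two_conditions(h, u)
    expect_equal(ff$statistic, tt$statistic^2, tolerance = 1e-9)
    expect_identical(ff$df, c(1, n - 1))
  }
  same <- rm_anova_two_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
})

test_that("critical values match the printed t and F table entries", {
  expect_equal(critical_value("t", 0.05, 64), 1.669, tolerance = 5e-4)
  expect_equal(critical_value("f", 0.05, c(1, 64)), 3.991, tolerance = 5e-4)
  expect_equal(critical_value("t", 0.05, 1e7), 1.645, tolerance = 5e-4)
  expect_error(critical_value("t", 0.05, c(1, 2)), "one df")
  expect_error(critical_value("f", 0.05, 64), "two df")
  expect_error(critical_value("t", 1.5, 64), "alpha")
})

test_that("the paired t p-value is uniform under the null", {
  set.seed(21)
  pvals <- replicate(2000, {
    h <- rnorm(10)
    paired_t_one_tailed(h, h + rnorm(10))$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
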
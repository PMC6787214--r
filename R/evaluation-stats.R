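#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts; `p = tp + fn` positives,
#'   `n = fp + tn` negatives, with `p + n > 0`.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(v) == 0) stop("all-zero confusion counts", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

#' Diagnostic-accuracy measures from confusion counts
#'
#' The nine standard measures, as percentages: sensitivity
#' `Se = TP/(TP+FN)`, specificity `Sp = TN/(FP+TN)`, accuracy
#' `Acc = (TP+TN)/(P+N)`, precision `PPV = TP/(TP+FP)`,
#' `NPV = TN/(TN+FN)`, fall-out `FPR = FP/(FP+TN)`, false discovery rate
#' `FDR = FP/(FP+TP)`, miss rate `FNR = FN/(FN+TP)` and
#' `F1 = 2TP/(2TP+FP+FN)`. A measure whose denominator is zero is reported
#' as `NA` (not available), never as 0. The complementarity identities
#' `FPR = 100 - Sp`, `FNR = 100 - Se` and `FDR = 100 - PPV` hold wherever
#' both sides are defined.
#'
#' @param c a [confusion_counts()].
#' @return named list of class `diagnosis_measures` with elements `se`,
#'   `sp`, `acc`, `ppv`, `npv`, `fpr`, `fdr`, `fnr`, `f1` in `[0, 100]`.
#' @export
diagnosis_measures <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  with(c, structure(list(
    se = ratio(tp, tp + fn),
    sp = ratio(tn, fp + tn),
    acc = ratio(tp + tn, tp + fp + tn + fn),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    fpr = ratio(fp, fp + tn),
    fdr = ratio(fp, fp + tp),
    fnr = ratio(fn, fn + tp),
    f1 = ratio(2 * tp, 2 * tp + fp + fn)),
    class = "diagnosis_measures"))
}

#' @export
print.diagnosis_measures <- function(x, ...) {
  for (k in names(x)) {
    cat(sprintf("%-4s %s\n", toupper(k),
                if (is.na(x[[k]])) "n/a" else sprintf("%.2f%%", x[[k]])))
  }
  invisible(x)
}

#' Confidence interval for a mean from summary statistics
#'
#' `mean +- t_{(1+level)/2, n-1} * sd / sqrt(n)`.
#'
#' @param mean sample mean.
#' @param sd sample standard deviation (n-1 denominator, >= 0).
#' @param n sample size (>= 2).
#' @param level confidence level in (0, 1), default 0.95.
#' @return named numeric vector `c(lcl, ucl)`.
#' @export
mean_ci <- function(mean, sd, n, level = 0.95) {
  if (!(n >= 2) || !(sd >= 0) || !(level > 0 && level < 1)) {
    stop("need n >= 2, sd >= 0, 0 < level < 1", call. = FALSE)
  }
  half <- qt((1 + level) / 2, df = n - 1) * sd / sqrt(n)
  c(lcl = mean - half, ucl = mean + half)
}

#' One-tailed paired t test (unhealthy greater than healthy)
#'
#' Right-tailed paired t test on the per-patient differences
#' `unhealthy - healthy` with `df = n - 1`. The null hypothesis (no CV
#' increase under disease) is rejected when the statistic exceeds the
#' upper-tail critical value at `alpha`.
#'
#' @param healthy,unhealthy equal-length per-patient values, paired by
#'   patient.
#' @param alpha significance level (default 0.05).
#' @return object of class `hypothesis_result`: list with `statistic`,
#'   `df`, `p_value`, `critical`, `alpha`, `reject`, `method`.
#' @export
paired_t_one_tailed <- function(healthy, unhealthy, alpha = 0.05) {
  if (length(healthy) != length(unhealthy)) {
    stop("healthy and unhealthy must have equal length", call. = FALSE)
  }
  n <- length(healthy)
  if (n < 2) stop("need n >= 2 pairs", call. = FALSE)
  d <- unhealthy - healthy
  crit <- qt(1 - alpha, df = n - 1)
  if (sd(d) == 0) {
    # elementwise-equal samples give the exact null value t = 0, p = 0.5;
    # a constant nonzero difference has no finite t statistic
    if (all(d == 0)) {
      return(hypothesis_result(statistic = 0, df = n - 1, p_value = 0.5,
                               critical = crit, alpha = alpha,
                               method = "paired t (one-tailed)"))
    }
    stop("zero-variance differences", call. = FALSE)
  }
  tt <- t.test(unhealthy, healthy, paired = TRUE, alternative = "greater")
  hypothesis_result(statistic = unname(tt$statistic), df = n - 1,
                    p_value = tt$p.value, critical = crit, alpha = alpha,
                    method = "paired t (one-tailed)")
}

#' Repeated-measures ANOVA for two within-subject conditions
#'
#' F = MS_between / MS_error with degrees of freedom (1, n - 1), fitted via
#' `aov(value ~ condition + Error(subject))`. For two conditions this F
#' equals the square of the paired t statistic.
#'
#' @inheritParams paired_t_one_tailed
#' @return a `hypothesis_result` with `df = c(1, n - 1)`.
#' @export
rm_anova_two_conditions <- function(healthy, unhealthy, alpha = 0.05) {
  if (length(healthy) != length(unhealthy)) {
    stop("healthy and unhealthy must have equal length", call. = FALSE)
  }
  n <- length(healthy)
  if (n < 2) stop("need n >= 2 subjects", call. = FALSE)
  crit <- qf(1 - alpha, 1, n - 1)
  d <- unhealthy - healthy
  if (sd(d) == 0) {
    # identical conditions: the between-condition contrast is exactly null
    if (all(d == 0)) {
      return(hypothesis_result(statistic = 0, df = c(1, n - 1), p_value = 1,
                               critical = crit, alpha = alpha,
                               method = "repeated-measures ANOVA (2 conditions)"))
    }
    stop("zero-variance differences", call. = FALSE)
  }
  df_long <- data.frame(
    value = c(healthy, unhealthy),
    condition = factor(rep(c("healthy", "unhealthy"), each = n)),
    subject = factor(rep(seq_len(n), times = 2)))
  fit <- aov(value ~ condition + Error(subject), data = df_long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  fstat <- tab["condition", "F value"]
  pval <- tab["condition", "Pr(>F)"]
  if (is.nan(fstat) || is.na(fstat)) {
    stop("degenerate ANOVA: zero error variance", call. = FALSE)
  }
  hypothesis_result(statistic = unname(fstat), df = c(1, n - 1),
                    p_value = unname(pval), critical = crit, alpha = alpha,
                    method = "repeated-measures ANOVA (2 conditions)")
}

hypothesis_result <- function(statistic, df, p_value, critical, alpha,
                              method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 critical = critical, alpha = alpha,
                 reject = statistic > critical, method = method),
            class = "hypothesis_result")
}

#' @export
print.hypothesis_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g (df = %s), p = %.3g, critical = %.4g, %s\n",
              x$method, x$statistic, paste(x$df, collapse = ", "),
              x$p_value, x$critical,
              if (x$reject) "reject H0" else "do not reject H0"))
  invisible(x)
}

#' Upper-tail critical value of the t or F distribution
#'
#' The quantile at probability `1 - alpha`: e.g. t at `alpha = 0.05`,
#' `df = 64` is 1.669 and F at `df = (1, 64)` is 3.991.
#'
#' @param dist `"t"` or `"f"`.
#' @param alpha upper-tail probability in (0, 1).
#' @param df degrees of freedom: one value for t, two for F.
#' @return the critical value.
#' @export
critical_value <- function(dist = c("t", "f"), alpha, df) {
  dist <- match.arg(dist)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)",
                                      call. = FALSE)
  if (any(df <= 0)) stop("invalid degrees of freedom", call. = FALSE)
  if (dist == "t") {
    if (length(df) != 1) stop("t requires one df", call. = FALSE)
    qt(1 - alpha, df)
  } else {
    if (length(df) != 2) stop("F requires two df", call. = FALSE)
    qf(1 - alpha, df[1], df[2])
  }
}
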
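#' Label a CV trace with its healthy/unhealthy window boundaries
#'
#' For threshold learning each training trace is annotated with `a_index`,
#' the ordinal of the last window whose contributing beats are all healthy,
#' and `b_index`, the ordinal of the first window whose beats are all
#' unhealthy. Windows between the two straddle the transition. Indices are
#' 1-based window ordinals.
#'
#' @param trace a `cv_trace`.
#' @param a_index,b_index window ordinals with
#'   `1 <= a_index < b_index <= length(trace)`.
#' @param patient_id optional identifier.
#' @return object of class `labeled_cv_trace`.
#' @export
labeled_cv_trace <- function(trace, a_index, b_index, patient_id = NA) {
  stopifnot(inherits(trace, "cv_trace"))
  len <- length(trace)
  if (!(a_index >= 1 && a_index < b_index && b_index <= len)) {
    stop("need 1 <= a_index < b_index <= length(trace) (= ", len, ")",
         call. = FALSE)
  }
  structure(list(trace = trace, a_index = as.integer(a_index),
                 b_index = as.integer(b_index), patient_id = patient_id),
            class = "labeled_cv_trace")
}

#' Per-patient CV extrema for threshold learning
#'
#' `th_max_i` is the maximum CV over the all-healthy prefix (windows
#' `1 ... a_index`); `th_min_i` is the minimum CV over the all-unhealthy
#' suffix (windows `b_index ... end`).
#'
#' @param labeled a [labeled_cv_trace()].
#' @return named numeric vector `c(th_max, th_min)`.
#' @export
patient_extrema <- function(labeled) {
  stopifnot(inherits(labeled, "labeled_cv_trace"))
  cvs <- labeled$trace$cvs
  c(th_max = max(cvs[1:labeled$a_index]),
    th_min = min(cvs[labeled$b_index:length(cvs)]))
}

#' Learn the two CV thresholds from a labeled training cohort
#'
#' The final thresholds aggregate the per-patient extrema:
#' `th_final_max = max_i th_max_i` (upper edge of the healthy band) and
#' `th_final_min = min_i th_min_i` (lower edge of the unhealthy band). A
#' usable three-band rule needs `th_final_max < th_final_min`; overlapping
#' cohorts can violate this, in which case the pair is flagged degenerate.
#'
#' @param labeled_set list of [labeled_cv_trace()] objects (>= 1).
#' @param kind feature kind the thresholds apply to (`"PR"`, `"QRS"`,
#'   `"QT"`).
#' @return a [threshold_pair()].
#' @export
learn_thresholds <- function(labeled_set, kind = NA_character_) {
  if (!length(labeled_set)) stop("empty training set", call. = FALSE)
  ex <- vapply(labeled_set, patient_extrema, numeric(2))
  threshold_pair(kind = kind,
                 th_final_max = max(ex["th_max", ]),
                 th_final_min = min(ex["th_min", ]),
                 n_patients = length(labeled_set))
}

#' Construct a threshold pair
#'
#' @param kind feature kind.
#' @param th_final_max,th_final_min the two CV thresholds (> 0); CV at or
#'   below `th_final_max` is healthy, at or above `th_final_min` unhealthy.
#' @param n_patients training cohort size (metadata).
#' @return object of class `threshold_pair` with a `degenerate` flag set
#'   when `th_final_max >= th_final_min`.
#' @export
threshold_pair <- function(kind, th_final_max, th_final_min,
                           n_patients = NA_integer_) {
  if (!(th_final_max > 0 && th_final_min > 0)) {
    stop("thresholds must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, th_final_max = th_final_max,
                 th_final_min = th_final_min, n_patients = n_patients,
                 degenerate = th_final_max >= th_final_min),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("Thresholds (%s): healthy <= %.4g, unhealthy >= %.4g%s\n",
              x$kind, x$th_final_max, x$th_final_min,
              if (x$degenerate) "  [DEGENERATE]" else ""))
  invisible(x)
}

#' Published per-feature CV thresholds
#'
#' The threshold pairs learned on the original 65-patient cohort:
#' PR (0.068, 0.1012), QRS (0.069, 0.083), QT (0.079, 0.082). These ship as
#' usable defaults for classification without retraining.
#'
#' @param kind `"PR"`, `"QRS"` or `"QT"`; omit for the full named list.
#' @return a [threshold_pair()], or a named list of all three.
#' @export
published_thresholds <- function(kind = NULL) {
  all <- list(
    PR = threshold_pair("PR", 0.068, 0.1012, 65L),
    QRS = threshold_pair("QRS", 0.069, 0.083, 65L),
    QT = threshold_pair("QT", 0.079, 0.082, 65L))
  if (is.null(kind)) all else all[[match.arg(kind, names(all))]]
}

#' Three-class decision for a single CV value
#'
#' `cv <= th_final_max` is healthy; `cv >= th_final_min` is unhealthy
#' (both bounds inclusive); CV strictly inside the band is
#' `tending_to_unhealthy`.
#'
#' @param cv coefficient-of-variation value.
#' @param thresholds a non-degenerate [threshold_pair()].
#' @return factor level among `healthy < tending_to_unhealthy < unhealthy`.
#' @export
classify_cv <- function(cv, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  if (thresholds$degenerate) {
    stop("degenerate thresholds: th_final_max >= th_final_min",
         call. = FALSE)
  }
  lab <- ifelse(cv <= thresholds$th_final_max, "healthy",
                ifelse(cv >= thresholds$th_final_min, "unhealthy",
                       "tending_to_unhealthy"))
  factor(lab, levels = c("healthy", "tending_to_unhealthy", "unhealthy"),
         ordered = TRUE)
}

#' Classify every window of a CV trace and aggregate to subject level
#'
#' Applies [classify_cv()] per window. The subject is unhealthy if any
#' window is unhealthy, tending if any window is tending, else healthy.
#' With a degenerate threshold pair classification degrades, with a
#' warning, to a two-class rule at the midpoint of the two thresholds.
#'
#' @param trace a non-empty `cv_trace`.
#' @param thresholds a [threshold_pair()].
#' @return list with `windows` (ordered factor of per-window labels) and
#'   `subject` (single label).
#' @export
classify_trace <- function(trace, thresholds) {
  stopifnot(inherits(trace, "cv_trace"))
  if (!length(trace)) stop("empty trace", call. = FALSE)
  if (thresholds$degenerate) {
    warning("degenerate thresholds; falling back to a two-class rule at ",
            "the threshold midpoint", call. = FALSE)
    mid <- (thresholds$th_final_max + thresholds$th_final_min) / 2
    lab <- ifelse(trace$cvs <= mid, "healthy", "unhealthy")
    win <- factor(lab, levels = c("healthy", "tending_to_unhealthy",
                                  "unhealthy"), ordered = TRUE)
  } else {
    win <- classify_cv(trace$cvs, thresholds)
  }
  subject <- if (any(win == "unhealthy")) "unhealthy"
             else if (any(win == "tending_to_unhealthy")) "tending_to_unhealthy"
             else "healthy"
  list(windows = win,
       subject = factor(subject, levels = levels(win), ordered = TRUE))
}

#' Seeded stratified train/validation split
#'
#' Splits subjects into a training and a validation set, stratified by
#' label so both sets preserve class composition. Allocation uses
#' largest-remainder rounding so the total training size is
#' `round(n * train_fraction)`.
#'
#' @param labels character/factor vector of subject labels.
#' @param train_fraction fraction assigned to training (0 < f < 1).
#' @param seed integer seed; the same seed reproduces the same split.
#' @return list with integer index vectors `train` and `validate`.
#' @export
split_train_validate <- function(labels, train_fraction = 0.8, seed = 0) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  labels <- as.character(labels)
  strata <- split(seq_along(labels), labels)
  if (any(vapply(strata, length, integer(1)) == 0)) {
    stop("empty stratum", call. = FALSE)
  }
  n_train_total <- round(length(labels) * train_fraction)
  raw <- vapply(strata, length, integer(1)) * train_fraction
  base <- floor(raw)
  rem <- n_train_total - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  with_seed(seed, {
    train <- unlist(lapply(seq_along(strata), function(i) {
      sample(strata[[i]], base[i])
    }), use.names = FALSE)
    list(train = sort(train),
         validate = sort(setdiff(seq_along(labels), train)))
  })
}

#' Persist a threshold pair as JSON
#'
#' @param thresholds a [threshold_pair()].
#' @param path output path.
#' @export
write_thresholds_json <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a threshold pair from JSON
#'
#' @param path path written by [write_thresholds_json()].
#' @return a [threshold_pair()].
#' @export
read_thresholds_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_pair(x$kind, x$th_final_max, x$th_final_min, x$n_patients)
}
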
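#' Cross-tabulate manual and automated binary scores
#'
#' @param manual,predicted Equal-length 0/1 vectors (manual annotation and
#'   automated prediction).
#' @return Object of class `confusion_counts` with fields
#'   `a` (manual 0, predicted 0), `b` (manual 1, predicted 0),
#'   `c` (manual 0, predicted 1), `d` (manual 1, predicted 1).
#' @export
confusion_counts <- function(manual, predicted) {
  manual <- as.integer(manual); predicted <- as.integer(predicted)
  if (length(manual) != length(predicted))
    stop(sprintf("length mismatch: manual %d vs predicted %d",
                 length(manual), length(predicted)))
  if (!all(manual %in% c(0L, 1L)) || !all(predicted %in% c(0L, 1L)))
    stop("inputs must be binary 0/1")
  new_confusion(a = sum(manual == 0L & predicted == 0L),
                b = sum(manual == 1L & predicted == 0L),
                c = sum(manual == 0L & predicted == 1L),
                d = sum(manual == 1L & predicted == 1L))
}

#' @rdname confusion_counts
#' @param a,b,c,d Cell counts for building a `confusion_counts` directly
#'   (e.g. from a published matrix).
#' @export
new_confusion <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || sum(counts) < 1)
    stop("counts must be non-negative with total >= 1")
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("predicted 0", "predicted 1"),
                              c("manual 0", "manual 1")))
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial tail probabilities via beta quantiles:
#' `lo = qbeta(alpha/2, s, n - s + 1)` and
#' `hi = qbeta(1 - alpha/2, s + 1, n - s)`, with `lo = 0` when `s = 0`
#' and `hi = 1` when `s = n`.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
#' @examples
#' round(clopper_pearson(52, 60), 3)  # 0.754 0.941
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n)
    stop("invalid counts: need 0 <= successes <= n, n >= 1")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  alpha <- 1 - level
  lo <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lo = lo, hi = hi)
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' Computes accuracy `(a + d) / N` with its exact binomial confidence
#' interval, and sensitivity/specificity under an explicit positive-class
#' convention. With `positive_label = 0` (the default, matching the
#' evaluation convention of the original protocol, where the first factor
#' level — behavior absent / not retrieved — is the positive class):
#' sensitivity `= a / (a + c)` and specificity `= d / (b + d)`. With
#' `positive_label = 1` the two definitions swap exactly. A rate whose
#' denominator class is empty is reported as `NA`.
#'
#' Rates are stored at full precision; round only for presentation.
#'
#' @param cm A `confusion_counts`.
#' @param positive_label 0 or 1.
#' @param level Confidence level for the accuracy CI.
#' @return Object of class `metric_report` with `accuracy`, `accuracy_ci`
#'   (`level`, `lo`, `hi`), `sensitivity`, `specificity`,
#'   `positive_label` and `n`.
#' @export
classification_report <- function(cm, positive_label = 0, level = 0.95) {
  stopifnot(inherits(cm, "confusion_counts"))
  if (!positive_label %in% c(0, 1)) stop("positive_label must be 0 or 1")
  n <- cm$a + cm$b + cm$c + cm$d
  correct <- cm$a + cm$d
  ci <- clopper_pearson(correct, n, level)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  if (positive_label == 0) {
    sens <- rate(cm$a, cm$a + cm$c)
    spec <- rate(cm$d, cm$b + cm$d)
  } else {
    sens <- rate(cm$d, cm$b + cm$d)
    spec <- rate(cm$a, cm$a + cm$c)
  }
  structure(list(accuracy = correct / n,
                 accuracy_ci = list(level = level, lo = unname(ci[1]),
                                    hi = unname(ci[2])),
                 sensitivity = sens, specificity = spec,
                 positive_label = positive_label, n = n),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.1f%% (%g%% CI %.1f, %.1f); sensitivity %.1f%%; ",
    100 * x$accuracy, 100 * x$accuracy_ci$level, 100 * x$accuracy_ci$lo,
    100 * x$accuracy_ci$hi, 100 * x$sensitivity))
  cat(sprintf("specificity %.1f%% [positive label: %d; n = %d]\n",
              100 * x$specificity, x$positive_label, x$n))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin validation wrapper used to compare automated against manual
#' per-trial scores (times, durations, counts).
#'
#' @param x,y Equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return The correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y, method = "pearson")
}
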
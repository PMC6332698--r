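# Predictor evaluation utilities: the confusion-matrix panel, correlation
# statistics and normalised percentage errors used to benchmark aggregation
# predictors against labelled variant data.

check_preds <- function(preds, cols) {
  if (!is.data.frame(preds) || !all(cols %in% names(preds))) {
    abort(sprintf("`preds` must contain columns: %s", paste(cols, collapse = ", ")))
  }
  as_tibble(preds)
}

as_binary <- function(x, what) {
  if (is.logical(x)) return(x)
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x) && all(x %in% c(0, 1))) return(x == 1)
  if (is.character(x)) {
    u <- sort(unique(x))
    if (all(u %in% c("FALSE", "TRUE"))) return(x == "TRUE")
    if (length(u) <= 2L && length(u) >= 1L) {
      # alphabetically-last level is the positive class unless obvious
      pos <- if (any(c("positive", "aggregating", "yes", "1") %in% u)) {
        intersect(c("positive", "aggregating", "yes", "1"), u)[1]
      } else tail(u, 1)
      return(x == pos)
    }
  }
  abort(sprintf("`%s` must be binary (logical, 0/1 or two-level)", what))
}

#' Confusion-matrix metrics for binary aggregation calls
#'
#' Standard confusion-matrix panel: sensitivity, specificity, precision,
#' accuracy and Matthews correlation coefficient (four-cell formula).
#' Ratios with a zero denominator are undefined and reported as `NA` --
#' e.g. precision of a predictor that never calls a positive.
#'
#' @param preds Tibble with binary columns `observed_class` and
#'   `predicted_class` (logical, 0/1, or two-level; the
#'   aggregating/positive level is `TRUE`, `1`, `"aggregating"`,
#'   `"positive"`, `"yes"` or the alphabetically-last level).
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `precision`, `accuracy`, `mcc`.
#' @export
#' @examples
#' confusion_metrics(tibble::tibble(observed_class = c(TRUE, TRUE, FALSE),
#'                                  predicted_class = c(TRUE, FALSE, FALSE)))
confusion_metrics <- function(preds) {
  preds <- check_preds(preds, c("observed_class", "predicted_class"))
  obs <- as_binary(preds$observed_class, "observed_class")
  est <- as_binary(preds$predicted_class, "predicted_class")
  tp <- sum(obs & est); fp <- sum(!obs & est)
  tn <- sum(!obs & !est); fn <- sum(obs & !est)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp),
         precision = ratio(tp, tp + fp),
         accuracy = ratio(tp + tn, tp + fp + tn + fn),
         mcc = if (mcc_den == 0) NA_real_ else
           (tp * tn - fp * fn) / sqrt(mcc_den))
}

#' Correlation statistics between predicted and observed values
#'
#' Coefficient of determination (squared Pearson r), its two-tailed
#' t-distribution p-value, and Spearman's rho (rank correlation with
#' average ranks on ties). Undefined when either variable has zero
#' variance; reported as `NA`.
#'
#' @param preds Tibble with numeric columns `predicted` and `observed`.
#' @return One-row tibble: `n`, `r_squared`, `p_value`, `rho`.
#' @export
correlation_stats <- function(preds) {
  preds <- check_preds(preds, c("predicted", "observed"))
  x <- preds$predicted; y <- preds$observed
  if (length(x) < 3L) abort("need at least 3 prediction pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("values must be finite")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(n = length(x), r_squared = NA_real_,
                  p_value = NA_real_, rho = NA_real_))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  rho <- cor(x, y, method = "spearman")
  tibble(n = length(x),
         r_squared = unname(ct$estimate)^2,
         p_value = ct$p.value,
         rho = rho)
}

# min-max rescale to [0, 1]; a constant series maps to 0
rescale01 <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Normalised percentage-error statistics
#'
#' Predicted and observed values are each min-max rescaled to a common
#' `[0, 1]` span, the per-variant error is `100 * (predicted - observed)`
#' on that scale, and the mean, sample SD and SEM (`SD / sqrt(n)`) are
#' reported. The common-span rescaling makes predictors with different
#' native scales comparable; it is recorded in the output so alternative
#' error definitions can be compared.
#'
#' @param preds Tibble with numeric columns `predicted` and `observed`.
#' @return One-row tibble: `n`, `mean_pct_error`, `sd_pct_error`,
#'   `sem_pct_error`, `scaling`. SD and SEM are `NA` for fewer than two
#'   pairs.
#' @export
error_stats <- function(preds) {
  preds <- check_preds(preds, c("predicted", "observed"))
  err <- 100 * (rescale01(preds$predicted) - rescale01(preds$observed))
  n <- length(err)
  s <- if (n >= 2L) sd(err) else NA_real_
  tibble(n = n, mean_pct_error = mean(err), sd_pct_error = s,
         sem_pct_error = s / sqrt(n), scaling = "minmax01")
}

#' Full evaluation panel for a continuous aggregation predictor
#'
#' Combines [confusion_metrics()], [error_stats()] and
#' [correlation_stats()] into one long table of metric/value rows. When
#' `predicted_class` is absent it is derived by thresholding the
#' continuous prediction at `threshold` (default 0.45, the low-score
#' classification boundary: scores at or above it count as aggregating).
#'
#' @param preds Tibble with columns `predicted`, `observed`,
#'   `observed_class` and optionally `predicted_class`.
#' @param threshold Binarisation threshold for `predicted` when
#'   `predicted_class` is absent.
#' @return Tibble with columns `metric` and `value`, rows: sensitivity,
#'   specificity, precision, accuracy, mcc, mean_pct_error, sd_pct_error,
#'   sem_pct_error, r_squared, p_value, rho. Undefined entries are `NA`.
#' @export
metrics_report <- function(preds, threshold = 0.45) {
  preds <- check_preds(preds, c("predicted", "observed", "observed_class"))
  if (!"predicted_class" %in% names(preds)) {
    preds$predicted_class <- preds$predicted >= threshold
  }
  cm <- confusion_metrics(preds)
  es <- error_stats(preds)
  cs <- correlation_stats(preds)
  out <- tibble(
    metric = c("sensitivity", "specificity", "precision", "accuracy", "mcc",
               "mean_pct_error", "sd_pct_error", "sem_pct_error",
               "r_squared", "p_value", "rho"),
    value = c(cm$sensitivity, cm$specificity, cm$precision, cm$accuracy,
              cm$mcc, es$mean_pct_error, es$sd_pct_error, es$sem_pct_error,
              cs$r_squared, cs$p_value, cs$rho))
  attr(out, "threshold") <- threshold
  attr(out, "error_scaling") <- es$scaling
  out
}
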
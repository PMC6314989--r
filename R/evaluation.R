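#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#' Scale-invariant, location-sensitive.
#'
#' @param values numeric vector, length >= 2, nonzero mean, no NA.
#' @return the CV as a ratio.
#' @export
#' @examples
#' cvValue(c(1, 3))  # sqrt(2) / 2
cvValue <- function(values) {
  if (anyNA(values)) stop("value error: NA in values", call. = FALSE)
  if (length(values) < 2L) stop("value error: need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("value error: zero mean", call. = FALSE)
  sd(values) / m
}

#' Two-sided variance-ratio (F) test
#'
#' Compares the variances of two samples with the standard F test
#' (`stats::var.test`, two-sided). The statistic is `var(a) / var(b)`;
#' swapping the arguments inverts F and leaves p unchanged.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with elements `F`, `p`, `df`.
#' @export
varianceRatioTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("value error: need at least 2 values per sample", call. = FALSE)
  if (var(b) == 0 || var(a) == 0)
    stop("value error: zero variance sample", call. = FALSE)
  ft <- var.test(a, b, alternative = "two.sided")
  list(F = unname(ft$statistic), p = ft$p.value,
       df = unname(ft$parameter))
}

#' Empirical ROC analysis with Youden-optimal cutoff
#'
#' Builds the empirical ROC over all distinct thresholds (via pROC),
#' computes the trapezoidal AUC — equal to the Mann-Whitney rank statistic
#' — and selects the Youden-optimal cutoff; accuracy is the fraction of
#' subjects correctly classified at that cutoff. The default direction
#' encodes "low SBR = abnormal".
#'
#' @param values numeric SBR values.
#' @param labels class labels, same length.
#' @param positive the label of the positive (abnormal) class.
#' @param direction `"lower_is_positive"` (default) or
#'   `"higher_is_positive"`.
#' @return a [RocSummary-class].
#' @export
rocAnalysis <- function(values, labels, positive,
                        direction = c("lower_is_positive", "higher_is_positive")) {
  direction <- match.arg(direction)
  if (anyNA(values)) stop("value error: NA in values", call. = FALSE)
  isPos <- labels == positive
  if (!any(isPos) || all(isPos))
    stop("value error: both classes must be present", call. = FALSE)
  dir <- if (direction == "lower_is_positive") ">" else "<"
  r <- pROC::roc(response = isPos, predictor = values,
                 levels = c(FALSE, TRUE), direction = dir, quiet = TRUE)
  co <- pROC::coords(r, "all", ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = "threshold", transpose = FALSE)
  cutoff <- best$threshold[1L]   # first optimum if tied
  pred <- if (direction == "lower_is_positive") values <= cutoff else values >= cutoff
  acc <- mean(pred == isPos)
  new("RocSummary", thresholds = co$threshold, sensitivity = co$sensitivity,
      specificity = co$specificity, auc = as.numeric(pROC::auc(r)),
      cutoff = cutoff, accuracy = acc, direction = direction)
}

#' Classification accuracy at a fixed cutoff
#'
#' @inheritParams rocAnalysis
#' @param cutoff decision threshold.
#' @return fraction correctly classified.
#' @export
accuracyAtCutoff <- function(values, labels, positive, cutoff,
                             direction = c("lower_is_positive", "higher_is_positive")) {
  direction <- match.arg(direction)
  isPos <- labels == positive
  pred <- if (direction == "lower_is_positive") values <= cutoff else values >= cutoff
  mean(pred == isPos)
}

#' Paired bootstrap test for an AUC difference
#'
#' Resamples subjects with replacement and compares the AUCs of two
#' paired markers on the same labels; the p-value is the two-sided
#' bootstrap probability that the AUC difference crosses zero.
#'
#' @param x,y paired marker values (e.g. two SBR methods on one cohort).
#' @param labels class labels.
#' @param positive positive-class label.
#' @param direction as in [rocAnalysis()].
#' @param nBoot bootstrap replicates.
#' @param seed RNG seed.
#' @return list with `aucX`, `aucY`, `delta`, `p`.
#' @export
aucDiffTest <- function(x, y, labels, positive,
                        direction = "lower_is_positive", nBoot = 500L,
                        seed = 1L) {
  aucOf <- function(v, lab) rocAnalysis(v, lab, positive, direction)@auc
  a1 <- aucOf(x, labels); a2 <- aucOf(y, labels)
  n <- length(labels)
  deltas <- withPhantomSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        lab <- labels[idx]
        if (any(lab == positive) && !all(lab == positive)) break
      }
      aucOf(x[idx], lab) - aucOf(y[idx], lab)
    }, numeric(1))
  })
  p <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  list(aucX = a1, aucY = a2, delta = a1 - a2, p = min(1, p))
}

#' Agreement between two SBR methods
#'
#' Ordinary least squares of the Tossici-Bolt values on the count-based
#' values, plus the Pearson correlation.
#'
#' @param newValues count-based SBR values (regressor).
#' @param boltValues Tossici-Bolt SBR values (response), paired.
#' @return list with `r`, `slope`, `intercept`, `n`.
#' @export
methodAgreement <- function(newValues, boltValues) {
  if (length(newValues) != length(boltValues))
    stop("value error: unpaired inputs", call. = FALSE)
  if (length(newValues) < 3L)
    stop("value error: need at least 3 pairs", call. = FALSE)
  if (var(newValues) == 0 || var(boltValues) == 0)
    stop("value error: zero variance input", call. = FALSE)
  fit <- lm(boltValues ~ newValues)
  list(r = cor(newValues, boltValues),
       slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       n = length(newValues))
}

#' Validate a cohort SBR table
#'
#' The long-format cohort table has one SBR per row with columns
#' `subject_id`, `group`, `method`, `side`, `sbr`.
#'
#' @param df a data.frame.
#' @return invisibly `df`; errors when malformed.
#' @export
validateCohort <- function(df) {
  need <- c("subject_id", "group", "method", "side", "sbr")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("cohort table missing columns: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (anyNA(df$sbr)) stop("cohort table contains NA sbr values", call. = FALSE)
  counts <- table(df$group)
  if (any(counts < 2L))
    stop("each group needs at least 2 subjects for dispersion statistics",
         call. = FALSE)
  invisible(df)
}
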
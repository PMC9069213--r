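#' Classify one sample from its arm Z profile
#'
#' The diagnostic score combines all chromosome arms as the maximum absolute
#' arm Z-score; a sample is called positive when the score reaches the
#' cutoff (boundary inclusive, `|Z| >= cutoff`), so a deep loss counts the
#' same as a strong gain.
#'
#' @param profile An [arm_zscores()] object.
#' @param cutoff Positive threshold on `max |Z|` (default 2.5).
#' @return Object of class `diagnosis_call`: list with `sample_id`, `score`,
#'   `positive`, `cutoff`, `arms` (the argmax arm set).
#' @export
classify_sample <- function(profile, cutoff = 2.5) {
  stopifnot(inherits(profile, "arm_z"), cutoff > 0)
  if (length(profile$z) == 0) stop("empty Z profile for ", profile$sample_id)
  score <- max(abs(profile$z))
  structure(list(sample_id = profile$sample_id, score = score,
                 positive = score >= cutoff, cutoff = cutoff,
                 arms = names(profile$z)[abs(profile$z) == score]),
            class = "diagnosis_call")
}

#' @export
print.diagnosis_call <- function(x, ...) {
  cat(x$sample_id, ": score ", round(x$score, 3), " (",
      paste(x$arms, collapse = ","), ") -> ",
      if (x$positive) "POSITIVE" else "negative",
      " at cutoff ", x$cutoff, "\n", sep = "")
  invisible(x)
}

#' Confusion-matrix counts
#' @param tn,tp,fn,fp Non-negative integer cell counts; total must be > 0.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tn, tp, fn, fp) {
  v <- c(tn = tn, tp = tp, fn = fn, fp = fp)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (sum(v) == 0) stop("empty confusion matrix")
  structure(as.list(v), class = "confusion_counts")
}

# round half-up to `digits` decimals (so 81.25 -> 81.3 in percent display)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

#' Wilson score interval with continuity correction
#'
#' The continuity-corrected Wilson interval for a binomial proportion
#' `k / n` (Newcombe's formulation). The lower bound is 0 when `k = 0` and
#' the upper bound 1 when `k = n`.
#'
#' @param k Number of successes.
#' @param n Number of trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lo, hi)` on the proportion scale.
#' @examples
#' round(100 * wilson_ci(13, 16), 1)  # 53.7 95.0
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  lo <- (2 * n * p + z^2 - 1 -
           z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) / (2 * (n + z^2))
  hi <- (2 * n * p + z^2 + 1 +
           z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) / (2 * (n + z^2))
  if (k == 0) lo <- 0
  if (k == n) hi <- 1
  c(lo = max(0, lo), hi = min(1, hi))
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity, specificity, PPV, NPV and accuracy as fractions, each with a
#' 95% Wilson continuity-corrected interval, plus Youden's
#' `J = sensitivity + specificity - 1`. A metric whose denominator is zero
#' is reported as NA. The `percent` element carries the display values,
#' rounded half-up to one decimal.
#'
#' @param counts A [confusion_counts()] object.
#' @param conf Confidence level for the intervals (default 0.95).
#' @return Object of class `diag_metrics`.
#' @examples
#' m <- confusion_metrics(confusion_counts(tn = 9, tp = 13, fn = 3, fp = 0))
#' m$percent["sensitivity"]  # 81.3
#' @export
confusion_metrics <- function(counts, conf = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  frac <- function(k, n) if (n > 0) k / n else NA_real_
  ci <- function(k, n) if (n > 0) wilson_ci(k, n, conf) else c(lo = NA_real_, hi = NA_real_)
  with(counts, {
    est <- c(sensitivity = frac(tp, tp + fn), specificity = frac(tn, tn + fp),
             ppv = frac(tp, tp + fp), npv = frac(tn, tn + fn),
             accuracy = frac(tp + tn, tn + tp + fn + fp))
    cis <- rbind(sensitivity = ci(tp, tp + fn), specificity = ci(tn, tn + fp),
                 ppv = ci(tp, tp + fp), npv = ci(tn, tn + fn),
                 accuracy = ci(tp + tn, tn + tp + fn + fp))
    structure(list(counts = counts, estimate = est, ci = cis,
                   percent = round_half_up(100 * est, 1),
                   youden_j = est[["sensitivity"]] + est[["specificity"]] - 1,
                   conf = conf),
              class = "diag_metrics")
  })
}

#' @export
print.diag_metrics <- function(x, ...) {
  cat("Diagnostic metrics (TN=", x$counts$tn, " TP=", x$counts$tp,
      " FN=", x$counts$fn, " FP=", x$counts$fp, "):\n", sep = "")
  for (m in names(x$estimate)) {
    cat(sprintf("  %-12s %5.1f%%  (%d%% CI %.1f-%.1f)\n", m,
                x$percent[[m]], round(100 * x$conf),
                round_half_up(100 * x$ci[m, "lo"], 1),
                round_half_up(100 * x$ci[m, "hi"], 1)))
  }
  cat(sprintf("  Youden J     %.3f\n", x$youden_j))
  invisible(x)
}

# DeLong placement values: psi(case, control) with ties scoring 1/2
delong_placements <- function(cases, controls) {
  v10 <- vapply(cases, function(x)
    mean((x > controls) + 0.5 * (x == controls)), numeric(1))
  v01 <- vapply(controls, function(y)
    mean((cases > y) + 0.5 * (cases == y)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' ROC curve, AUC and DeLong confidence interval
#'
#' The ROC is traced over every distinct observed score used as a threshold
#' (decision `score >= t` when high scores mark cases, `score <= t` when low
#' scores do, as for the free/total PSA ratio). The AUC is computed by pair
#' counting with ties scoring 1/2 (the Mann-Whitney identity) and its CI by
#' the DeLong variance estimator.
#'
#' @param scores Numeric scores, one per sample.
#' @param labels Logical or 0/1 vector; TRUE/1 marks a case.
#' @param direction `"high"` (default) when larger scores indicate disease,
#'   `"low"` when smaller scores do.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `roc_result`: list with `points` (data.frame
#'   cutoff/sensitivity/fpr), `auc`, `auc_ci`, `n_pos`, `n_neg`,
#'   `direction`.
#' @export
roc_auc <- function(scores, labels, direction = c("high", "low"), conf = 0.95) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("missing scores or labels")
  if (!any(labels) || all(labels)) stop("need at least one case and one control")
  s <- if (direction == "low") -scores else scores
  cases <- s[labels]; controls <- s[!labels]
  pl <- delong_placements(cases, controls)
  m <- length(cases); n <- length(controls)
  var_auc <- stats::var(pl$v10) / m + stats::var(pl$v01) / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- c(lo = max(0, pl$auc - z * sqrt(var_auc)),
          hi = min(1, pl$auc + z * sqrt(var_auc)))
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  pts <- data.frame(
    cutoff = if (direction == "low") -thr else thr,
    sensitivity = vapply(thr, function(t) mean(cases >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(controls >= t), numeric(1)))
  structure(list(points = pts, auc = pl$auc, auc_ci = ci,
                 n_pos = m, n_neg = n, direction = direction, conf = conf),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d%% CI %.3f-%.3f), %d cases vs %d controls\n",
              x$auc, round(100 * x$conf), x$auc_ci["lo"], x$auc_ci["hi"],
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two markers measured on the same samples, using the
#' DeLong covariance of the paired placement values and a two-sided normal
#' approximation.
#'
#' @param scores_a,scores_b Scores of the two markers on the same samples.
#' @param labels Logical or 0/1 case indicator.
#' @param direction_a,direction_b Orientation of each marker (see
#'   [roc_auc()]).
#' @return List with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        direction_a = "high", direction_b = "high") {
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("both markers must score the same samples")
  if (!any(labels) || all(labels)) stop("need both classes")
  sa <- if (direction_a == "low") -scores_a else scores_a
  sb <- if (direction_b == "low") -scores_b else scores_b
  pa <- delong_placements(sa[labels], sa[!labels])
  pb <- delong_placements(sb[labels], sb[!labels])
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  if (var_diff <= 0) {
    z <- 0; p <- if (abs(diff) < 1e-12) 1 else 0
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p_value = p)
}

#' Youden-optimal cutoff among candidate operating points
#'
#' Returns the candidate cutoff maximizing `J = sensitivity + specificity -
#' 1`; ties break toward the larger cutoff (the more specific test).
#'
#' @param candidates data.frame with columns `cutoff`, `tn`, `tp`, `fn`,
#'   `fp` (at least 2 rows).
#' @return The selected cutoff (single number).
#' @export
youden_cutoff <- function(candidates) {
  need <- c("cutoff", "tn", "tp", "fn", "fp")
  if (!is.data.frame(candidates) || !all(need %in% names(candidates)))
    stop("candidates must be a data.frame with columns ", paste(need, collapse = ", "))
  if (nrow(candidates) < 2) stop("need >= 2 candidate cutoffs")
  j <- with(candidates, tp / (tp + fn) + tn / (tn + fp) - 1)
  best <- which(j == max(j))
  candidates$cutoff[best[which.max(candidates$cutoff[best])]]
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional hypergeometric two-sided p-value: the sum of probabilities of
#' all tables with the observed margins whose point probability does not
#' exceed the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2) || any(tab < 0)) stop("need a non-negative 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  stats::fisher.test(tab)$p.value
}

#' Mann-Whitney U test
#'
#' Rank-sum U with midranks for ties; the p-value is exact (full
#' enumeration) when both groups are small and tie-free, otherwise a normal
#' approximation with tie correction.
#'
#' @param x,y Numeric samples for the two groups (non-empty).
#' @param exact_max Use the exact distribution when `length(x) + length(y)`
#'   is at most this and there are no ties (default 12).
#' @return List with `u` (number of (x, y) pairs with x > y, ties 1/2) and
#'   `p_value` (two-sided).
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  list(u = unname(ht$statistic), p_value = ht$p.value)
}

#' Combined aneuploidy + f/t PSA call
#'
#' A sample is positive for the combined test when the CNV model calls it
#' positive or its free/total PSA ratio is present and below the threshold
#' (low f/t PSA is the cancer-suspicious direction). Missing f/t PSA leaves
#' the PSA arm uninformative.
#'
#' @param cnv_positive Logical vector of CNV-model calls.
#' @param ft_psa_percent Numeric f/t PSA (percent), NA allowed.
#' @param ft_threshold Positivity threshold in percent (default 16).
#' @return Logical vector of combined calls.
#' @export
combined_test <- function(cnv_positive, ft_psa_percent, ft_threshold = 16) {
  if (length(cnv_positive) != length(ft_psa_percent))
    stop("inputs must be aligned per sample")
  cnv_positive | (!is.na(ft_psa_percent) & ft_psa_percent < ft_threshold)
}
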
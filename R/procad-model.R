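#' Fit the arm-level aneuploidy diagnostic model to a cohort
#'
#' The full pipeline behind the urine-cell copy-number test, as one model
#' fit. Benign controls define a panel of normals (per-bin and per-arm
#' coverage mean and SD); every sample is depth-normalized, quality
#' controlled by the adjacent-bin MAD rule, and scored with one Z per
#' retained chromosome arm, `Z_a = (V_a - mean(V_control)) /
#' stdev(V_control)`. The diagnostic score is `max_a |Z_a|`; a sample is
#' called positive when the score reaches `cutoff`. When case/control
#' labels are present the fit also evaluates the classifier: ROC and
#' pair-counting AUC with a DeLong interval, confusion metrics with Wilson
#' continuity-corrected CIs at each candidate cutoff, and the
#' Youden-optimal cutoff among them.
#'
#' @param x List of [bin_counts()] objects on a common grid (e.g. from
#'   [simulate_cohort()] or [count_bam_reads()]).
#' @param sample_sheet data.frame with columns `sample_id` and `group`
#'   (groups `PCa`, `BPH`, `PIN`; anything non-`PCa` is treated as benign
#'   for evaluation). Optional `ft_percent` enables the combined test.
#' @param control_groups Groups forming the panel of normals (default
#'   `"BPH"`, the benign-hypertrophy panel; add `"PIN"` to pool all
#'   non-cancer samples).
#' @param cutoff Positivity threshold on `max |Z|` (default 2.5).
#' @param candidate_cutoffs Cutoffs tabulated for Youden selection
#'   (default `c(2, 2.5, 3)`).
#' @param mode Arm aggregation, `"arm-mean"` (default) or `"stouffer"`
#'   (see [arm_zscores()]).
#' @param loo_controls Score panel members against a panel excluding
#'   themselves (default FALSE: a control's own coverage is part of the
#'   reference it is compared against, which bounds member scores at
#'   `(n-1)/sqrt(n)` and matches the all-negative behavior of a benign
#'   panel; set TRUE for leave-one-out calibration studies).
#' @param min_bins_per_arm,min_median_count,max_zero_fraction Panel and
#'   bin-mask tuning (see [build_panel()] and [filter_bins()]).
#' @param qc A [qc_config()]; QC-failed samples are excluded from scoring
#'   and listed in the fit.
#' @return Object of class `procad`: list with `z` (samples x arms
#'   matrix), `scores`, `calls` (data.frame), `panel`, `mask`, `qc`
#'   (data.frame), `excluded`, `roc`, `metrics_by_cutoff`, `youden`,
#'   `cutoff`, `sample_sheet`, `config`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_controls = 6, n_cases = 4,
#'                                   mean_read_pairs = 2e5, rng_seed = 3))
#' fit <- procad(sim$counts, sim$sample_sheet)
#' fit
#' @export
procad <- function(x, sample_sheet, control_groups = "BPH", cutoff = 2.5,
                   candidate_cutoffs = c(2, 2.5, 3),
                   mode = c("arm-mean", "stouffer"), loo_controls = FALSE,
                   min_bins_per_arm = 10, min_median_count = 10,
                   max_zero_fraction = 0.2, qc = qc_config()) {
  mode <- match.arg(mode)
  stopifnot(cutoff > 0)
  ids <- vapply(x, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  if (!all(c("sample_id", "group") %in% names(sample_sheet)))
    stop("sample_sheet needs sample_id and group columns")
  row <- match(ids, sample_sheet$sample_id)
  if (anyNA(row)) stop("samples missing from sheet: ",
                       paste(ids[is.na(row)], collapse = ", "))
  sheet <- sample_sheet[row, , drop = FALSE]
  is_control <- sheet$group %in% control_groups
  if (sum(is_control) < 2)
    stop("need >= 2 control samples in groups {",
         paste(control_groups, collapse = ","), "}")

  mask <- filter_bins(x[is_control], min_median_count, max_zero_fraction)
  norm <- lapply(x, normalize_coverage, mask = mask)
  panel <- build_panel(norm[is_control], min_bins_per_arm)

  qc_reports <- lapply(seq_along(x), function(i)
    qc_sample(norm[[i]], panel$bin_mean, x[[i]], qc))
  qc_df <- data.frame(
    sample_id = ids,
    mad = vapply(qc_reports, `[[`, numeric(1), "mad_value"),
    read_pairs = vapply(qc_reports, `[[`, numeric(1), "read_pairs"),
    pass = vapply(qc_reports, `[[`, logical(1), "pass"),
    flags = vapply(qc_reports, function(r) paste(r$flags, collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE)
  # exclusion follows the MAD rule; a short library is warning-grade only
  keep <- !grepl("high_mad", qc_df$flags)
  excluded <- ids[!keep]
  if (length(excluded))
    warning("QC-failed sample(s) excluded: ", paste(excluded, collapse = ", "))
  if (any(qc_df$pass != keep))
    warning("low-depth sample(s) retained with a warning: ",
            paste(ids[!qc_df$pass & keep], collapse = ", "))
  if (!any(keep)) stop("every sample failed QC")

  profiles <- lapply(norm[keep], arm_zscores, panel = panel, mode = mode,
                     leave_one_out = loo_controls)
  z <- do.call(rbind, lapply(profiles, `[[`, "z"))
  rownames(z) <- ids[keep]
  calls <- lapply(profiles, classify_sample, cutoff = cutoff)
  calls_df <- data.frame(
    sample_id = ids[keep], group = sheet$group[keep],
    score = vapply(calls, `[[`, numeric(1), "score"),
    positive = vapply(calls, `[[`, logical(1), "positive"),
    top_arm = vapply(calls, function(cl) cl$arms[1], character(1)),
    stringsAsFactors = FALSE)

  label <- sheet$group[keep] == "PCa"
  roc <- NULL; metrics <- NULL; youden <- NA_real_
  if (any(label) && !all(label)) {
    roc <- roc_auc(calls_df$score, label)
    tab <- do.call(rbind, lapply(candidate_cutoffs, function(ct) {
      pos <- calls_df$score >= ct
      data.frame(cutoff = ct,
                 tn = sum(!pos & !label), tp = sum(pos & label),
                 fn = sum(!pos & label), fp = sum(pos & !label))
    }))
    metrics <- lapply(seq_len(nrow(tab)), function(i)
      confusion_metrics(confusion_counts(tab$tn[i], tab$tp[i],
                                         tab$fn[i], tab$fp[i])))
    names(metrics) <- as.character(tab$cutoff)
    youden <- youden_cutoff(tab)
  }
  structure(list(z = z, scores = stats::setNames(calls_df$score, calls_df$sample_id),
                 calls = calls_df, panel = panel, mask = mask, qc = qc_df,
                 excluded = excluded, roc = roc,
                 metrics_by_cutoff = metrics, youden = youden,
                 cutoff = cutoff, sample_sheet = sheet,
                 config = list(control_groups = control_groups, mode = mode,
                               loo_controls = loo_controls,
                               candidate_cutoffs = candidate_cutoffs,
                               min_bins_per_arm = min_bins_per_arm,
                               min_median_count = min_median_count,
                               max_zero_fraction = max_zero_fraction,
                               qc = qc)),
            class = "procad")
}

#' @export
print.procad <- function(x, ...) {
  cat("procad fit: ", nrow(x$z), " samples x ", ncol(x$z), " arms",
      " (panel of ", length(x$panel$control_ids), " controls)\n", sep = "")
  cat("  positive at |Z| >= ", x$cutoff, ": ", sum(x$calls$positive),
      "/", nrow(x$calls), "\n", sep = "")
  if (!is.null(x$roc))
    cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f); Youden cutoff %.2f\n",
                x$roc$auc, x$roc$auc_ci["lo"], x$roc$auc_ci["hi"], x$youden))
  if (length(x$excluded))
    cat("  QC-excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.procad <- function(object, ...) {
  x <- object
  cat("Arm-level aneuploidy model\n")
  cat("==========================\n")
  print(x)
  pos <- x$calls[x$calls$positive, , drop = FALSE]
  if (nrow(pos)) {
    cat("\nPositive samples (top arm):\n")
    for (i in seq_len(nrow(pos)))
      cat(sprintf("  %-10s %-6s score %5.2f  %s\n", pos$sample_id[i],
                  pos$group[i], pos$score[i], pos$top_arm[i]))
  }
  if (!is.null(x$metrics_by_cutoff)) {
    cat("\nOperating points:\n")
    for (ct in names(x$metrics_by_cutoff)) {
      m <- x$metrics_by_cutoff[[ct]]
      cat(sprintf("  cutoff %-4s sens %5.1f%%  spec %5.1f%%  acc %5.1f%%  J %.3f\n",
                  ct, m$percent[["sensitivity"]], m$percent[["specificity"]],
                  m$percent[["accuracy"]], m$youden_j))
    }
  }
  invisible(x)
}

#' Score new samples against a fitted panel
#'
#' @param object A [procad()] fit.
#' @param newdata A [bin_counts()] object or list of them, on the fit's
#'   grid.
#' @param cutoff Positivity threshold (defaults to the fit's).
#' @param ... Unused.
#' @return data.frame with sample_id, score, positive, top_arm.
#' @export
predict.procad <- function(object, newdata, cutoff = object$cutoff, ...) {
  if (inherits(newdata, "bin_counts")) newdata <- list(newdata)
  rows <- lapply(newdata, function(raw) {
    nv <- normalize_coverage(raw, object$mask)
    prof <- arm_zscores(nv, object$panel, mode = object$config$mode,
                        leave_one_out = FALSE)
    cl <- classify_sample(prof, cutoff)
    data.frame(sample_id = cl$sample_id, score = cl$score,
               positive = cl$positive, top_arm = cl$arms[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot the fitted classifier's ROC curve or a sample's Z profile
#'
#' @param x A [procad()] fit.
#' @param type `"roc"` (default; requires labels) or `"z"` (arm Z profile
#'   of one sample).
#' @param sample_id Sample to show when `type = "z"`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.procad <- function(x, type = c("roc", "z"), sample_id = NULL, ...) {
  type <- match.arg(type)
  if (type == "roc") {
    if (is.null(x$roc)) stop("no labelled evaluation in this fit")
    p <- x$roc$points
    plot(p$fpr, p$sensitivity, type = "s", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "1 - specificity", ylab = "sensitivity",
         main = sprintf("AUC = %.2f", x$roc$auc), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  } else {
    if (is.null(sample_id)) sample_id <- rownames(x$z)[1]
    z <- x$z[sample_id, ]
    graphics::barplot(z, las = 2, cex.names = 0.6, ylab = "arm Z",
                      main = sample_id, ...)
    graphics::abline(h = c(-x$cutoff, x$cutoff), lty = 2, col = "red")
  }
  invisible(x)
}
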
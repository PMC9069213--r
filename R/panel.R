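#' Build control-panel coverage statistics
#'
#' The panel of normals is the reference every sample is scored against:
#' per-bin mean and standard deviation of depth-normalized coverage across
#' the benign controls, and the same pair at arm resolution (each control's
#' arm value is the mean of its usable-bin coverage on that arm). Arms with
#' fewer than `min_bins_per_arm` usable bins are dropped from the retained
#' set; bins or arms with zero spread across controls are dropped with a
#' warning, since a Z-score denominator must be positive.
#'
#' @param controls List of [normalize_coverage()] objects on identical
#'   usable bins; at least 2 (the sample SD uses the n-1 denominator, chosen
#'   for small panels).
#' @param min_bins_per_arm Minimum usable bins for an arm to be retained
#'   (default 10).
#' @return Object of class `control_panel` with fields `control_ids`,
#'   `bins`, `grid`, `bin_mean`, `bin_sd`, `bin_ok`, `arm_ids`, `arm_mean`,
#'   `arm_sd`, and the per-control value matrices `V` (bins x controls) and
#'   `A` (arms x controls) used for leave-one-out rescoring.
#' @export
build_panel <- function(controls, min_bins_per_arm = 10) {
  if (length(controls) < 2) stop("need >= 2 controls to build a panel")
  bins <- controls[[1]]$bins
  for (ctl in controls)
    if (!identical(ctl$bins, bins)) stop("controls are not on identical usable bins")
  grid <- controls[[1]]$grid
  ids <- vapply(controls, `[[`, character(1), "sample_id")
  V <- vapply(controls, `[[`, numeric(length(bins)), "values")
  bin_mean <- rowMeans(V)
  bin_sd <- apply(V, 1, stats::sd)
  bin_ok <- bin_sd > 0
  if (!all(bin_ok))
    warning(sum(!bin_ok), " bin(s) with zero spread across controls dropped")
  if (!any(bin_ok)) stop("every bin has zero spread across controls")

  arm_of_bin <- grid$arm_id[bins]
  tab <- table(arm_of_bin)[unique(arm_of_bin)]
  arm_ids <- names(tab)[as.integer(tab) >= min_bins_per_arm]
  if (!length(arm_ids)) stop("no arm has >= ", min_bins_per_arm, " usable bins")
  A <- do.call(rbind, lapply(arm_ids, function(a) colMeans(V[arm_of_bin == a, , drop = FALSE])))
  rownames(A) <- arm_ids
  arm_mean <- rowMeans(A)
  arm_sd <- apply(A, 1, stats::sd)
  keep <- arm_sd > 0
  if (!all(keep)) {
    warning(sum(!keep), " arm(s) with zero spread across controls dropped")
    arm_ids <- arm_ids[keep]; A <- A[keep, , drop = FALSE]
    arm_mean <- arm_mean[keep]; arm_sd <- arm_sd[keep]
  }
  structure(list(control_ids = ids, bins = bins, grid = grid,
                 bin_mean = bin_mean, bin_sd = bin_sd, bin_ok = bin_ok,
                 arm_ids = arm_ids, arm_mean = stats::setNames(arm_mean, arm_ids),
                 arm_sd = stats::setNames(arm_sd, arm_ids),
                 min_bins_per_arm = min_bins_per_arm, V = V, A = A),
            class = "control_panel")
}

#' @export
print.control_panel <- function(x, ...) {
  cat("control_panel: ", length(x$control_ids), " controls, ",
      length(x$bins), " usable bins, ", length(x$arm_ids),
      " retained arms (min ", x$min_bins_per_arm, " bins/arm)\n", sep = "")
  invisible(x)
}

# panel column index of a sample when scored leave-one-out, or 0
loo_index <- function(sample, panel, leave_one_out) {
  if (!leave_one_out) return(0L)
  ix <- match(sample$sample_id, panel$control_ids)
  if (is.na(ix)) return(0L)
  if (length(panel$control_ids) < 3)
    stop("leave-one-out scoring of a panel member needs >= 3 controls")
  ix
}

#' Bin-level Z-scores against the control panel
#'
#' `Z_b = (V_b - mean_b) / sd_b` per usable bin. When the scored sample is
#' itself a panel member and `leave_one_out` is TRUE (the default), the
#' panel mean and SD are recomputed without it, preventing the control's own
#' coverage from deflating its score.
#'
#' @param sample A [normalize_coverage()] object on the panel's usable bins.
#' @param panel A [build_panel()] object.
#' @param leave_one_out Recompute panel statistics without the scored sample
#'   when it is a panel member (default TRUE).
#' @return Numeric vector of Z-scores over usable bins; NA where the bin was
#'   dropped for zero spread.
#' @export
bin_zscores <- function(sample, panel, leave_one_out = TRUE) {
  stopifnot(inherits(sample, "norm_cov"), inherits(panel, "control_panel"))
  if (!identical(sample$bins, panel$bins))
    stop("sample '", sample$sample_id, "' is not on the panel's usable bins")
  ix <- loo_index(sample, panel, leave_one_out)
  if (ix > 0) {
    V <- panel$V[, -ix, drop = FALSE]
    m <- rowMeans(V); s <- apply(V, 1, stats::sd)
  } else {
    m <- panel$bin_mean; s <- panel$bin_sd
  }
  z <- (sample$values - m) / s
  z[s == 0] <- NA_real_
  z
}

#' Arm-level Z-scores against the control panel
#'
#' The diagnostic statistic of the pipeline: one Z per retained chromosome
#' arm. The default `"arm-mean"` mode applies the Z formula to the
#' arm-averaged coverage, `Z_a = (V_a - mean_a) / sd_a`, where `V_a` is the
#' sample's mean usable-bin coverage on the arm; `"stouffer"` instead
#' combines the bin Z-scores as `sum(Z_b)/sqrt(n_bins)`. Both respond to a
#' uniform arm-wide shift with the same sign; arm-mean is the default
#' because the Z formula is stated for a generic coverage value and one
#' score per arm is reported.
#'
#' @inheritParams bin_zscores
#' @param mode `"arm-mean"` (default) or `"stouffer"`.
#' @return Object of class `arm_z`: list with `sample_id`, `z` (named by
#'   arm), `n_arms`, `mode`.
#' @export
arm_zscores <- function(sample, panel, mode = c("arm-mean", "stouffer"),
                        leave_one_out = TRUE) {
  stopifnot(inherits(sample, "norm_cov"), inherits(panel, "control_panel"))
  mode <- match.arg(mode)
  if (!identical(sample$bins, panel$bins))
    stop("sample '", sample$sample_id, "' is not on the panel's usable bins")
  arm_of_bin <- panel$grid$arm_id[panel$bins]
  if (mode == "arm-mean") {
    ix <- loo_index(sample, panel, leave_one_out)
    if (ix > 0) {
      A <- panel$A[, -ix, drop = FALSE]
      m <- rowMeans(A); s <- apply(A, 1, stats::sd)
    } else {
      m <- panel$arm_mean; s <- panel$arm_sd
    }
    if (any(s == 0)) stop("zero arm spread in leave-one-out panel")
    va <- vapply(panel$arm_ids,
                 function(a) mean(sample$values[arm_of_bin == a]), numeric(1))
    z <- (va - m) / s
  } else {
    zb <- bin_zscores(sample, panel, leave_one_out)
    z <- vapply(panel$arm_ids, function(a) {
      v <- zb[arm_of_bin == a]
      v <- v[!is.na(v)]
      sum(v) / sqrt(length(v))
    }, numeric(1))
  }
  structure(list(sample_id = sample$sample_id,
                 z = stats::setNames(as.numeric(z), panel$arm_ids),
                 n_arms = length(panel$arm_ids), mode = mode),
            class = "arm_z")
}

#' @export
print.arm_z <- function(x, ...) {
  top <- sort(abs(x$z), decreasing = TRUE)[seq_len(min(3, x$n_arms))]
  cat("arm_z '", x$sample_id, "': ", x$n_arms, " arms (", x$mode,
      "); top |Z|: ",
      paste(names(top), round(x$z[names(top)], 2), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Call arm-level copy-number events from a Z profile
#'
#' An arm is called when `|Z| >= cutoff` (boundary inclusive); the direction
#' is a gain for positive Z and a loss for negative Z. A sample is
#' CNV-positive when it carries at least one event.
#'
#' @param profile An [arm_zscores()] object.
#' @param cutoff Positive Z magnitude threshold (default 2.5).
#' @return Object of class `cnv_calls`: list with `sample_id`, `calls`
#'   (data.frame arm/z/direction), `n_events`, `positive`, `cutoff`.
#' @export
cnv_events <- function(profile, cutoff = 2.5) {
  stopifnot(inherits(profile, "arm_z"), cutoff > 0)
  hit <- which(abs(profile$z) >= cutoff)
  calls <- data.frame(arm = names(profile$z)[hit],
                      z = as.numeric(profile$z[hit]),
                      direction = ifelse(profile$z[hit] > 0, "gain", "loss"),
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(list(sample_id = profile$sample_id, calls = calls,
                 n_events = nrow(calls), positive = nrow(calls) >= 1,
                 cutoff = cutoff),
            class = "cnv_calls")
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat("cnv_calls '", x$sample_id, "': ", x$n_events, " event(s) at |Z| >= ",
      x$cutoff, if (x$n_events) ": " else "", sep = "")
  if (x$n_events)
    cat(paste0(x$calls$arm, " ", x$calls$direction,
               " (Z=", round(x$calls$z, 2), ")", collapse = ", "))
  cat("\n")
  invisible(x)
}
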
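#' Quality-control configuration
#'
#' @param mad_threshold Flag a sample when the genome-wide adjacent-bin MAD
#'   of its log2 copy ratios exceeds this value (default 0.38).
#' @param min_read_pairs Minimum library size in read pairs (default 1.5e7).
#' @param epsilon Guard added inside the log2 ratio (default 1e-6).
#' @param mad_constant Consistency constant for the MAD (default 1.4826,
#'   the scaling that makes the MAD estimate a normal SD; set to 1 for the
#'   unscaled estimator).
#' @return Object of class `qc_config`.
#' @export
qc_config <- function(mad_threshold = 0.38, min_read_pairs = 15e6,
                      epsilon = 1e-6, mad_constant = 1.4826) {
  stopifnot(mad_threshold > 0, min_read_pairs >= 0, epsilon > 0)
  structure(list(mad_threshold = mad_threshold, min_read_pairs = min_read_pairs,
                 epsilon = epsilon, mad_constant = mad_constant),
            class = "qc_config")
}

#' Log2 copy ratios of a sample against the panel mean
#'
#' `r_b = log2((V_b + eps) / (m_b + eps))` per usable bin, where `V_b` is the
#' sample's depth-normalized coverage and `m_b` the control-panel mean.
#'
#' @param sample A [normalize_coverage()] object.
#' @param panel_mean Numeric vector of panel bin means on the same usable
#'   bins (e.g. `panel$bin_mean`).
#' @param epsilon Additive guard (default 1e-6).
#' @return Numeric vector of log2 ratios, one per usable bin.
#' @export
log2_ratios <- function(sample, panel_mean, epsilon = 1e-6) {
  stopifnot(inherits(sample, "norm_cov"))
  if (length(sample$values) != length(panel_mean))
    stop("sample has ", length(sample$values), " usable bins but panel mean has ",
         length(panel_mean))
  if (any(panel_mean <= 0)) stop("panel mean must be positive in every bin")
  log2((sample$values + epsilon) / (panel_mean + epsilon))
}

#' Genome-wide MAD of adjacent-bin log2-ratio differences
#'
#' First differences are taken only between bins that are adjacent within
#' the same chromosome arm (jumps across centromeres and chromosome ends are
#' structural, not noise), pooled genome-wide, and summarized as
#' `constant * median(|d - median(d)|)`. This is the standard noise metric
#' for low-pass copy-number profiles.
#'
#' @param ratios Log2 ratios over usable bins ([log2_ratios()]).
#' @param sample A `norm_cov` (provides the usable-bin -> arm mapping), or a
#'   character vector of arm ids aligned to `ratios`.
#' @param constant MAD consistency constant (default 1.4826).
#' @return The pooled MAD, a single number.
#' @export
adjacent_mad <- function(ratios, sample, constant = 1.4826) {
  arm_id <- if (inherits(sample, "norm_cov")) sample$grid$arm_id[sample$bins]
            else as.character(sample)
  if (length(arm_id) != length(ratios)) stop("arm ids not aligned to ratios")
  same_arm <- arm_id[-1] == arm_id[-length(arm_id)]
  d <- diff(ratios)[same_arm]
  if (length(d) < 2) stop("fewer than 2 adjacent-bin differences; grid too small")
  constant * stats::median(abs(d - stats::median(d)))
}

#' Quality-control verdict for one sample
#'
#' Flags `"high_mad"` when the adjacent-bin MAD exceeds the configured
#' threshold and `"low_depth"` when the library holds fewer read pairs than
#' required; a sample passes iff it collects no flags.
#'
#' @param sample A [normalize_coverage()] object.
#' @param panel_mean Panel bin means on the sample's usable bins.
#' @param raw The sample's [bin_counts()] (supplies the read-pair total).
#' @param cfg A [qc_config()].
#' @return Object of class `qc_report`: list with `sample_id`, `mad_value`,
#'   `read_pairs`, `flags`, `pass`.
#' @export
qc_sample <- function(sample, panel_mean, raw, cfg = qc_config()) {
  r <- log2_ratios(sample, panel_mean, cfg$epsilon)
  madv <- adjacent_mad(r, sample, cfg$mad_constant)
  flags <- character(0)
  if (madv > cfg$mad_threshold) flags <- c(flags, "high_mad")
  if (raw$total_read_pairs < cfg$min_read_pairs) flags <- c(flags, "low_depth")
  structure(list(sample_id = sample$sample_id, mad_value = madv,
                 read_pairs = raw$total_read_pairs, flags = flags,
                 pass = length(flags) == 0),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC ", x$sample_id, ": MAD = ", format(round(x$mad_value, 4)),
      ", read pairs = ", format(x$read_pairs, big.mark = ","), " -> ",
      if (x$pass) "PASS" else paste("FAIL:", paste(x$flags, collapse = ",")),
      "\n", sep = "")
  invisible(x)
}
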
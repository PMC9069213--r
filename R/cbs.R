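#' Circular binary segmentation parameters
#'
#' @param alpha Permutation significance level required to accept a split
#'   (default 0.01).
#' @param n_permutations Permutations per split test (default 1000; must be
#'   >= 100).
#' @param min_width Minimum arc width in bins (default 2).
#' @param rng_seed Optional integer seed; when set, segmentation is
#'   bit-reproducible regardless of the caller's RNG state.
#' @param max_depth Recursion depth guard (default 30).
#' @return Object of class `seg_params`.
#' @export
seg_params <- function(alpha = 0.01, n_permutations = 1000, min_width = 2,
                       rng_seed = NULL, max_depth = 30) {
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 100, min_width >= 2)
  structure(list(alpha = alpha, n_permutations = n_permutations,
                 min_width = min_width, rng_seed = rng_seed,
                 max_depth = max_depth),
            class = "seg_params")
}

#' Maximizing arc of the circular binary segmentation statistic
#'
#' Scans every arc `(i, j]` of the sequence with width `k = j - i` between
#' `min_width` and `n - min_width` and returns the arc maximizing `|T|`,
#' where `T = (mean_in - mean_out) / (s * sqrt(1/k + 1/(n-k)))` compares the
#' arc mean with the mean of its complement, standardized by the overall
#' standard deviation `s`. Because an arc and its complement give the same
#' `|T|`, scanning ordered pairs `0 <= i < j <= n` covers all circular
#' splits. Ties break toward the smallest `i`, then the smallest `j`.
#'
#' @param x Numeric sequence (length >= 4).
#' @param min_width Minimum arc width (default 2).
#' @return List with `i`, `j` (0-based boundaries: arc is positions
#'   `(i+1):j`), and the signed statistic `t`.
#' @export
max_arc_statistic <- function(x, min_width = 2) {
  n <- length(x)
  if (n < 4) stop("need at least 4 points, got ", n)
  if (n < 2 * min_width) stop("sequence shorter than twice min_width")
  s <- stats::sd(x)
  if (s == 0 || !is.finite(s))
    return(list(i = 0L, j = as.integer(min_width), t = 0))
  S0 <- c(0, cumsum(x))
  total <- S0[n + 1]
  best <- list(i = 0L, j = as.integer(min_width), t = 0)
  best_abs <- -1
  tol <- 1e-9  # an arc and its complement tie up to floating error
  for (k in min_width:(n - min_width)) {
    i <- 0:(n - k)                       # arc (i, i+k]
    d <- S0[i + k + 1] - S0[i + 1]
    tt <- (d / k - (total - d) / (n - k)) / (s * sqrt(1 / k + 1 / (n - k)))
    a <- abs(tt)
    m <- max(a)
    w <- which(a >= m - tol)[1]          # smallest i for this k
    if (m > best_abs + tol) {
      best <- list(i = i[w], j = i[w] + k, t = tt[w]); best_abs <- m
    } else if (m >= best_abs - tol &&
               (i[w] < best$i || (i[w] == best$i && i[w] + k < best$j))) {
      # near-equal |t|: keep the lexicographically smaller (i, j)
      best <- list(i = i[w], j = i[w] + k, t = tt[w])
      best_abs <- max(best_abs, m)
    }
  }
  best$i <- as.integer(best$i); best$j <- as.integer(best$j)
  best
}

# max |T| only, for permutation replicates
max_arc_abs <- function(x, min_width) {
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0 || !is.finite(s)) return(0)
  S0 <- c(0, cumsum(x))
  total <- S0[n + 1]
  m <- 0
  for (k in min_width:(n - min_width)) {
    d <- S0[(k + 1):(n + 1)] - S0[1:(n + 1 - k)]
    tt <- abs((d / k - (total - d) / (n - k)) / (s * sqrt(1 / k + 1 / (n - k))))
    mk <- max(tt)
    if (mk > m) m <- mk
  }
  m
}

# permutation p-value for the observed max |T|; add-one estimator with
# early exit once significance at `alpha` is no longer reachable
perm_pvalue <- function(x, observed, params) {
  B <- params$n_permutations
  limit <- params$alpha * (1 + B) - 1   # max exceedances still significant
  count <- 0
  for (b in seq_len(B)) {
    if (max_arc_abs(sample(x), params$min_width) >= observed) {
      count <- count + 1
      if (count > limit) return((1 + count) / (1 + b))  # already > alpha
    }
  }
  (1 + count) / (1 + B)
}

#' Segment one sequence by circular binary segmentation
#'
#' Recursive change-point search: find the maximizing arc, assess it by a
#' permutation test (add-one p-value estimator, so p is never exactly 0),
#' and if `p <= alpha` split the sequence at the arc boundaries — a ternary
#' split in general, binary when the arc touches either end — then recurse
#' into each piece. Pieces too short to test are left whole.
#'
#' @param x Numeric sequence.
#' @param params A [seg_params()] object.
#' @return Sorted integer vector of breakpoints: a value `b` means a
#'   boundary between positions `b` and `b + 1`; empty when the sequence is
#'   a single segment.
#' @export
cbs_segment <- function(x, params = seg_params()) {
  if (!is.null(params$rng_seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(params$rng_seed)
  }
  n <- length(x)
  if (n < 4) stop("need at least 4 points to segment")
  bp <- cbs_recurse(x, 0L, params, depth = 0L)
  sort(bp)
}

cbs_recurse <- function(x, offset, params, depth) {
  n <- length(x)
  if (n < max(4, 2 * params$min_width) || depth >= params$max_depth)
    return(integer(0))
  arc <- max_arc_statistic(x, params$min_width)
  if (abs(arc$t) == 0) return(integer(0))
  p <- perm_pvalue(x, abs(arc$t), params)
  if (p > params$alpha) return(integer(0))
  cuts <- setdiff(c(arc$i, arc$j), c(0L, n))  # boundary arcs give binary splits
  pieces <- c(0L, cuts, n)
  out <- offset + cuts
  for (q in seq_len(length(pieces) - 1)) {
    lo <- pieces[q] + 1L; hi <- pieces[q + 1]
    out <- c(out, cbs_recurse(x[lo:hi], offset + pieces[q], params, depth + 1L))
  }
  out
}

#' Segment a sample's genome-wide log2 ratios
#'
#' Applies [cbs_segment()] independently to each chromosome arm's usable
#' bins (per-arm segmentation keeps centromere jumps out of the change-point
#' search), and reports one row per segment with its bin span and mean log2
#' ratio. Arms too short to test are emitted as a single segment. Per-arm
#' RNG streams are derived from `params$rng_seed` so results do not depend
#' on arm order.
#'
#' @param ratios Log2 ratios over usable bins ([log2_ratios()]).
#' @param sample The `norm_cov` the ratios belong to (provides bin
#'   coordinates), or any list with `bins` and `grid`.
#' @param params A [seg_params()] object.
#' @return Object of class `seg_set`: data.frame with columns `sample_id`,
#'   `chrom`, `arm_id`, `start`, `end` (0-based half-open), `n_bins`,
#'   `seg_mean`.
#' @export
segment_genome <- function(ratios, sample, params = seg_params()) {
  bins <- sample$bins; grid <- sample$grid
  if (length(ratios) != length(bins)) stop("ratios not aligned to usable bins")
  arm_of_bin <- grid$arm_id[bins]
  segs <- list()
  arms <- unique(arm_of_bin)
  for (ai in seq_along(arms)) {
    a <- arms[ai]
    sel <- which(arm_of_bin == a)
    r <- ratios[sel]
    rows <- bins[sel]
    p <- params
    if (!is.null(p$rng_seed)) p$rng_seed <- p$rng_seed + ai
    bp <- if (length(r) >= max(4, 2 * params$min_width))
      cbs_segment(r, p) else integer(0)
    edges <- c(0L, bp, length(r))
    for (q in seq_len(length(edges) - 1)) {
      lo <- edges[q] + 1L; hi <- edges[q + 1]
      segs[[length(segs) + 1]] <- data.frame(
        sample_id = sample$sample_id %||% "sample",
        chrom = grid$chrom[rows[lo]], arm_id = a,
        start = grid$start[rows[lo]], end = grid$end[rows[hi]],
        n_bins = hi - lo + 1L, seg_mean = mean(r[lo:hi]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  structure(out, class = c("seg_set", "data.frame"))
}

#' Write / read segments in SEG format
#'
#' Tab-delimited SEG with header
#' `ID chrom loc.start loc.end num.mark seg.mean`; coordinates are written
#' 1-based inclusive per community convention and converted back on read.
#'
#' @param segs A `seg_set` (or compatible data.frame).
#' @param path File path.
#' @return `write_seg` the path, invisibly; `read_seg` a `seg_set`.
#' @export
write_seg <- function(segs, path) {
  df <- data.frame(ID = segs$sample_id, chrom = segs$chrom,
                   loc.start = segs$start + 1, loc.end = segs$end,
                   num.mark = segs$n_bins,
                   seg.mean = round(segs$seg_mean, 6))
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  out <- data.frame(sample_id = as.character(df$ID), chrom = as.character(df$chrom),
                    start = df$loc.start - 1, end = df$loc.end,
                    n_bins = df$num.mark, seg_mean = df$seg.mean,
                    stringsAsFactors = FALSE)
  structure(out, class = c("seg_set", "data.frame"))
}
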
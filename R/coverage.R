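#' Per-bin read counts for one sample
#'
#' Container for the raw binned coverage of a single library, aligned to a
#' [make_bins()] grid.
#'
#' @param sample_id Sample label.
#' @param counts Integer vector, one entry per grid bin, in grid order.
#' @param grid The `bin_grid` the counts live on.
#' @param total_read_pairs Total read pairs in the library (defaults to the
#'   count sum).
#' @param source `"bam"` or `"table"`.
#' @return Object of class `bin_counts`.
#' @export
bin_counts <- function(sample_id, counts, grid, total_read_pairs = sum(counts),
                       source = "table") {
  stopifnot(inherits(grid, "bin_grid"))
  if (length(counts) != nrow(grid))
    stop("counts length ", length(counts), " != number of bins ", nrow(grid))
  if (any(counts < 0)) stop("negative counts")
  structure(list(sample_id = as.character(sample_id),
                 counts = as.numeric(counts),
                 total_read_pairs = as.numeric(total_read_pairs),
                 source = source, grid = grid),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat("bin_counts '", x$sample_id, "': ", length(x$counts), " bins, ",
      format(sum(x$counts), big.mark = ","), " assigned reads\n", sep = "")
  invisible(x)
}

# reconcile "chr1" vs "1" style naming between a BAM and the grid
reconcile_chroms <- function(bam_names, grid_chroms) {
  strip <- function(x) sub("^chr", "", x)
  map <- stats::setNames(rep(NA_character_, length(bam_names)), bam_names)
  for (i in seq_along(bam_names)) {
    hit <- grid_chroms[strip(grid_chroms) == strip(bam_names[i])]
    if (length(hit)) map[i] <- hit[1]
  }
  if (all(is.na(map)))
    stop("no chromosome names in common; alignment has {",
         paste(utils::head(bam_names, 5), collapse = ", "),
         "} vs grid {", paste(utils::head(unique(grid_chroms), 5), collapse = ", "), "}")
  map
}

# assign midpoints (0-based) on one chromosome to that chromosome's bins
assign_midpoints <- function(mid, starts, ends) {
  idx <- findInterval(mid, starts)
  ok <- idx >= 1 & idx <= length(starts)
  ok[ok] <- mid[ok] < ends[idx[ok]]
  idx[!ok] <- NA_integer_
  idx
}

#' Count alignments into grid bins by fragment midpoint
#'
#' Each primary, mapped, (optionally) non-duplicate alignment with mapping
#' quality at or above `mapq_min` is assigned to the bin containing its
#' fragment midpoint (template midpoint from TLEN for paired reads, read
#' midpoint otherwise). Midpoint binning approximates per-base pileup
#' averaging at 200-kb resolution while touching each record once.
#'
#' @param bam_path Coordinate-sorted, indexed BAM file.
#' @param grid A [make_bins()] grid.
#' @param mapq_min Minimum mapping quality (default 30).
#' @param dedup Exclude duplicate-flagged reads (default TRUE).
#' @param sample_id Label for the output (defaults to the file name).
#' @return A [bin_counts()] object.
#' @export
count_bam_reads <- function(bam_path, grid, mapq_min = 30, dedup = TRUE,
                            sample_id = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM index (.bai) missing for ", bam_path)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = if (dedup) FALSE else NA)
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = mapq_min,
                                   what = c("rname", "pos", "qwidth", "isize"))
  rec <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  counts <- numeric(nrow(grid))
  n_assigned <- 0
  if (length(rec$pos)) {
    rname <- as.character(rec$rname)
    map <- reconcile_chroms(unique(rname), unique(grid$chrom))
    chrom <- unname(map[rname])
    pos0 <- rec$pos - 1  # BAM pos is 1-based
    isize <- rec$isize; isize[is.na(isize)] <- 0
    qw <- rec$qwidth; qw[is.na(qw)] <- 0
    mid <- ifelse(isize > 0, pos0 + isize / 2,
           ifelse(isize < 0, pos0 + qw + isize / 2, pos0 + qw / 2))
    keep <- !is.na(chrom)
    for (cn in unique(chrom[keep])) {
      sel <- which(chrom == cn)
      rows <- which(grid$chrom == cn)
      idx <- assign_midpoints(mid[sel], grid$start[rows], grid$end[rows])
      tab <- tabulate(idx[!is.na(idx)], nbins = length(rows))
      counts[rows] <- counts[rows] + tab
      n_assigned <- n_assigned + sum(!is.na(idx))
    }
  }
  bin_counts(sample_id %||% basename(bam_path), counts, grid,
             total_read_pairs = length(rec$pos), source = "bam")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write per-bin counts as 4-column bedGraph-style TSV
#'
#' Files carry (chrom, start, end, count) rows; on read they must be
#' congruent with the grid (same bins, any order; `chr` prefix reconciled).
#'
#' @param x,path A `bin_counts` object and a file path.
#' @param grid Grid the file must match.
#' @param sample_id Label for the loaded sample (defaults to file name).
#' @return `write_bin_counts` returns the path invisibly; `read_bin_counts`
#'   a [bin_counts()] object in grid order.
#' @export
write_bin_counts <- function(x, path) {
  stopifnot(inherits(x, "bin_counts"))
  df <- data.frame(chrom = x$grid$chrom, start = x$grid$start,
                   end = x$grid$end, count = x$counts)
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_counts
#' @export
read_bin_counts <- function(path, grid, sample_id = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("chrom", "start", "end", "count"))
  map <- reconcile_chroms(unique(df$chrom), unique(grid$chrom))
  df$chrom <- unname(map[as.character(df$chrom)])
  key_file <- sprintf("%s:%.0f-%.0f", df$chrom, df$start, df$end)
  key_grid <- sprintf("%s:%.0f-%.0f", grid$chrom, grid$start, grid$end)
  if (anyDuplicated(key_file))
    stop("duplicate bin in ", path, ": ", key_file[duplicated(key_file)][1])
  pos <- match(key_grid, key_file)
  if (anyNA(pos))
    stop("bin missing from ", path, ": ", key_grid[which(is.na(pos))[1]])
  extra <- setdiff(key_file, key_grid)
  if (length(extra)) stop("bin not in grid: ", extra[1])
  bin_counts(sample_id %||% sub("\\.[^.]*$", "", basename(path)),
             df$count[pos], grid, source = "table")
}

#' Mask unstable bins from a panel of samples
#'
#' A bin is excluded if its median count across the panel falls below
#' `min_median_count` or if it is zero in more than `max_zero_fraction` of
#' panel samples. Masking is shared by every downstream statistic so all
#' samples live on the same usable-bin set.
#'
#' @param panel List of [bin_counts()] on a common grid (at least 2).
#' @param min_median_count Minimum panel median count (default 10).
#' @param max_zero_fraction Maximum tolerated fraction of zero counts
#'   (default 0.2).
#' @return Object of class `bin_mask`: list with logical `usable` and
#'   character `reason` vectors over grid bins, plus the grid.
#' @export
filter_bins <- function(panel, min_median_count = 10, max_zero_fraction = 0.2) {
  if (length(panel) < 2) stop("need >= 2 panel samples to filter bins")
  grid <- panel[[1]]$grid
  mat <- vapply(panel, function(p) p$counts, numeric(nrow(grid)))
  med <- apply(mat, 1, stats::median)
  zfrac <- rowMeans(mat == 0)
  reason <- rep(NA_character_, nrow(grid))
  reason[zfrac > max_zero_fraction] <- "zero"
  reason[med < min_median_count & is.na(reason)] <- "low_median"
  usable <- is.na(reason)
  if (!any(usable)) stop("all bins masked; panel too shallow for this grid")
  structure(list(usable = usable, reason = reason, grid = grid),
            class = "bin_mask")
}

#' Depth-normalize a sample's binned counts
#'
#' Divides each usable bin's count by the mean count over usable autosomal
#' bins, yielding the coverage value V with mean exactly 1: the quantity the
#' control-panel Z-score compares across samples. Masked bins are dropped.
#'
#' @param raw A [bin_counts()] object.
#' @param mask A [filter_bins()] mask (or NULL to use all bins).
#' @return Object of class `norm_cov`: list with `sample_id`, `values`
#'   (over usable bins), `bins` (grid row indices), and the grid.
#' @export
normalize_coverage <- function(raw, mask = NULL) {
  stopifnot(inherits(raw, "bin_counts"))
  usable <- if (is.null(mask)) rep(TRUE, length(raw$counts)) else mask$usable
  v <- raw$counts[usable]
  m <- mean(v)
  if (m == 0) stop("no reads in usable bins for sample ", raw$sample_id)
  structure(list(sample_id = raw$sample_id, values = v / m,
                 bins = which(usable), grid = raw$grid),
            class = "norm_cov")
}

#' @export
print.norm_cov <- function(x, ...) {
  cat("norm_cov '", x$sample_id, "': ", length(x$values),
      " usable bins, mean ", format(mean(x$values)), "\n", sep = "")
  invisible(x)
}
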
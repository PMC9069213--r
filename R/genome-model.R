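#' Chromosome-arm coordinate tables
#'
#' An arm table is the coordinate scaffold every coverage statistic in this
#' package lives on: one row per chromosome arm, with 0-based half-open
#' coordinates. The packaged `"hg19"` table holds the 44 autosomal arms
#' (chr1--chr22, p and q) with boundaries taken from the UCSC cytoband
#' centromere (acen) annotation.
#'
#' @param source Either the builtin identifier `"hg19"`, a path to a
#'   tab-delimited table with columns (chrom, start, end, arm) and optional
#'   `#` comment lines, or a data.frame with those columns.
#' @param assembly Label recorded on the returned table (defaults to the
#'   builtin name or `"custom"`).
#'
#' @return An object of class `arm_table`: a data.frame with columns
#'   `chrom`, `start`, `end`, `arm` and attribute `assembly`.
#' @examples
#' arms <- arm_table("hg19")
#' nrow(arms)  # 44
#' @export
arm_table <- function(source = "hg19", assembly = NULL) {
  if (is.data.frame(source)) {
    df <- source
    if (is.null(assembly)) assembly <- "custom"
  } else if (identical(source, "hg19")) {
    path <- system.file("extdata", "hg19_arms.tsv", package = "procad")
    df <- utils::read.table(path, sep = "\t", comment.char = "#",
                            col.names = c("chrom", "start", "end", "arm"),
                            colClasses = c("character", "numeric", "numeric", "character"))
    if (is.null(assembly)) assembly <- "hg19"
  } else {
    if (!file.exists(source)) stop("arm table not found: ", source)
    df <- utils::read.table(source, sep = "\t", comment.char = "#",
                            col.names = c("chrom", "start", "end", "arm"),
                            colClasses = c("character", "numeric", "numeric", "character"))
    if (is.null(assembly)) assembly <- "custom"
  }
  validate_arm_table(df)
  df <- df[order(chrom_rank(df$chrom), df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, assembly = assembly, class = c("arm_table", "data.frame"))
}

# numeric ordering for chr1..chr22 style names, others after
chrom_rank <- function(chrom) {
  base <- sub("^chr", "", chrom)
  n <- suppressWarnings(as.numeric(base))
  n[is.na(n)] <- 1000 + as.numeric(factor(base[is.na(n)]))
  n
}

validate_arm_table <- function(df) {
  need <- c("chrom", "start", "end", "arm")
  if (!all(need %in% names(df))) stop("arm table needs columns: ", paste(need, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    if (df$end[i] <= df$start[i])
      stop("arm table row ", i, " (", df$chrom[i], df$arm[i], "): end <= start")
    if (!df$arm[i] %in% c("p", "q"))
      stop("arm table row ", i, ": arm must be 'p' or 'q', got '", df$arm[i], "'")
  }
  for (cn in unique(df$chrom)) {
    sub <- df[df$chrom == cn, , drop = FALSE]
    if (any(duplicated(sub$arm))) stop("duplicate arm entries for ", cn)
    if (all(c("p", "q") %in% sub$arm)) {
      p <- sub[sub$arm == "p", ]; q <- sub[sub$arm == "q", ]
      if (p$end > q$start)
        stop("arms overlap on ", cn, ": p ends at ", p$end, ", q starts at ", q$start)
      if (p$start > q$start) stop("p-arm must precede q-arm on ", cn)
    }
  }
  invisible(df)
}

#' @export
print.arm_table <- function(x, ...) {
  cat("Chromosome arm table (", attr(x, "assembly"), "): ",
      nrow(x), " arms on ", length(unique(x$chrom)), " chromosomes\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Tile chromosome arms with fixed-width bins
#'
#' Each arm is tiled from its start with half-open bins of exactly
#' `bin_size` bases; a trailing remainder shorter than `bin_size` is
#' dropped so that all bins have identical width. Tiling is per-arm, so no
#' bin ever straddles a centromere and every bin belongs to exactly one arm.
#'
#' @param arms An [arm_table()].
#' @param bin_size Bin width in bases (default 200 kb, minimum 1 kb).
#'
#' @return An object of class `bin_grid`: a data.frame with columns `chrom`,
#'   `start`, `end`, `arm_id` (e.g. `"chr8q"`) and `bin_index`, plus
#'   attributes `bin_size` and `arms`.
#' @examples
#' toy <- arm_table(data.frame(chrom = "chr1", start = c(0, 5e5),
#'                             end = c(4e5, 1.5e6), arm = c("p", "q")))
#' grid <- make_bins(toy, 2e5)
#' table(grid$arm_id)
#' @export
make_bins <- function(arms, bin_size = 200000) {
  if (!inherits(arms, "arm_table")) arms <- arm_table(arms)
  if (nrow(arms) == 0) stop("empty arm table")
  if (bin_size < 1000) stop("bin_size must be >= 1000 bases")
  pieces <- lapply(seq_len(nrow(arms)), function(i) {
    n <- floor((arms$end[i] - arms$start[i]) / bin_size)
    if (n == 0) return(NULL)
    s <- arms$start[i] + bin_size * (seq_len(n) - 1)
    data.frame(chrom = arms$chrom[i], start = s, end = s + bin_size,
               arm_id = paste0(arms$chrom[i], arms$arm[i]))
  })
  grid <- do.call(rbind, pieces)
  if (is.null(grid)) stop("no arm is long enough to hold a single bin")
  grid <- grid[order(chrom_rank(grid$chrom), grid$start), , drop = FALSE]
  grid$bin_index <- seq_len(nrow(grid))
  rownames(grid) <- NULL
  structure(grid, bin_size = bin_size, arms = arms,
            class = c("bin_grid", "data.frame"))
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("Bin grid: ", nrow(x), " bins of ", attr(x, "bin_size"), " bp over ",
      length(unique(x$arm_id)), " arms\n", sep = "")
  invisible(x)
}

#' Number of bins per arm
#' @param grid A [make_bins()] grid.
#' @return Named integer vector, one entry per arm present in the grid.
#' @export
arm_bin_counts <- function(grid) {
  stopifnot(inherits(grid, "bin_grid"))
  tab <- table(grid$arm_id)
  out <- as.integer(tab)
  names(out) <- names(tab)
  # keep genome order rather than alphabetical
  out[unique(grid$arm_id)]
}

#' Write an arm table or bin grid as BED-like TSV
#' @param x An `arm_table` or `bin_grid`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- as.data.frame(x)
  cols <- intersect(c("chrom", "start", "end", "arm", "arm_id"), names(df))
  utils::write.table(format(df[cols], scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
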
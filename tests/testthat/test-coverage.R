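test_that("bin-count tables round-trip and reject incongruent files", {
  g <- tiny_grid()
  bc <- tiny_counts(g, "s1", base = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bin_counts(bc, path)
  back <- read_bin_counts(path, g, sample_id = "s1")
  expect_equal(back$counts, bc$counts)

  # drop one bin -> error naming the coordinate
  lines <- readLines(path)
  writeLines(lines[-3], path)
  expect_error(read_bin_counts(path, g), "missing")

  # shuffled rows are re-ordered to grid order
  writeLines(sample(lines), path)
  expect_equal(read_bin_counts(path, g)$counts, bc$counts)
})

test_that("chr-prefix differences are reconciled on read", {
  g <- tiny_grid()
  bc <- tiny_counts(g, "s1")
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(chrom = sub("^chr", "", g$chrom), start = g$start,
                   end = g$end, count = bc$counts)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_equal(read_bin_counts(path, g)$counts, bc$counts)
})

test_that("bin mask equals direct evaluation of its two predicates", {
  g <- tiny_grid()
  set.seed(41)
  panel <- lapply(1:6, function(i)
    bin_counts(paste0("c", i), rpois(nrow(g), 40) *
                 rbinom(nrow(g), 1, 0.93), g))
  mask <- filter_bins(panel, min_median_count = 30, max_zero_fraction = 0.2)
  mat <- sapply(panel, `[[`, "counts")
  expect_equal(mask$usable,
               apply(mat, 1, median) >= 30 & rowMeans(mat == 0) <= 0.2)
  # reasons recorded for masked bins only
  expect_true(all(is.na(mask$reason[mask$usable])))
  expect_true(all(mask$reason[!mask$usable] %in% c("zero", "low_median")))
  expect_error(filter_bins(panel[1]), ">= 2")
})

test_that("an all-zero bin across the panel is masked as 'zero'", {
  g <- tiny_grid()
  panel <- lapply(1:4, function(i) {
    cnt <- rep(100, nrow(g)); cnt[5] <- 0
    bin_counts(paste0("c", i), cnt, g)
  })
  mask <- filter_bins(panel)
  expect_false(mask$usable[5])
  expect_equal(mask$reason[5], "zero")
  expect_true(all(mask$usable[-5]))
})

test_that("normalization has unit mean, scale invariance and depth invariance", {
  g <- tiny_grid()
  set.seed(42)
  raw <- bin_counts("s", rpois(nrow(g), 200) + 1, g)
  nv <- normalize_coverage(raw)
  expect_equal(mean(nv$values), 1, tolerance = 1e-9)
  # doubling every count changes nothing
  doubled <- bin_counts("s", 2 * raw$counts, g)
  expect_equal(normalize_coverage(doubled)$values, nv$values)
  # uniform counts -> V == 1 everywhere; one doubled bin sits at ~2x the rest
  unif <- normalize_coverage(tiny_counts(g, base = 50))
  expect_true(all(abs(unif$values - 1) < 1e-12))
  spike <- tiny_counts(g, base = 50); spike$counts[1] <- 100
  vs <- normalize_coverage(spike)$values
  expect_equal(vs[1] / vs[2], 2, tolerance = 1e-12)
})

test_that("BAM midpoint counting matches a brute-force tally and round-trips", {
  g <- tiny_grid(5e5)
  set.seed(43)
  cnt <- rpois(nrow(g), 30)
  bc <- bin_counts("toy", cnt, g)
  bam <- withr::local_tempfile(fileext = ".bam")
  simulate_alignments(bc, bam)
  rec <- count_bam_reads(bam, g, mapq_min = 0, sample_id = "toy")
  expect_equal(rec$counts, bc$counts)
  expect_equal(sum(rec$counts), sum(cnt))

  # independent oracle: re-scan the BAM and bin midpoints by interval overlap
  raw <- Rsamtools::scanBam(bam)[[1]]
  mids <- (raw$pos - 1) + raw$qwidth / 2
  tally <- numeric(nrow(g))
  for (r in seq_along(mids)) {
    hit <- which(g$chrom == as.character(raw$rname[r]) &
                   g$start <= mids[r] & mids[r] < g$end)
    tally[hit] <- tally[hit] + 1
  }
  expect_equal(rec$counts, tally)
})

test_that("empty alignments yield all-zero counts and missing index errors", {
  g <- tiny_grid(5e5)
  bc <- bin_counts("empty", rep(0, nrow(g)), g)
  bam <- withr::local_tempfile(fileext = ".bam")
  simulate_alignments(bc, bam)
  rec <- count_bam_reads(bam, g, mapq_min = 0)
  expect_true(all(rec$counts == 0))
  expect_error(count_bam_reads(withr::local_tempfile(fileext = ".bam"), g),
               "not found")
})
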
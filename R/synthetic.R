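#' Toy genome arm table for fast simulations
#'
#' Four 20-Mb chromosomes with a 9-Mb p arm, a 1-Mb centromere gap and a
#' 10-Mb q arm: large enough for arm statistics, small enough that a full
#' cohort simulates in seconds.
#'
#' @param n_chrom Number of chromosomes (default 4).
#' @param chrom_len Chromosome length in bases (default 2e7).
#' @return An [arm_table()].
#' @export
toy_genome <- function(n_chrom = 4, chrom_len = 2e7) {
  p_end <- round(0.45 * chrom_len)
  q_start <- round(0.50 * chrom_len)
  df <- do.call(rbind, lapply(seq_len(n_chrom), function(i) data.frame(
    chrom = paste0("chr", i), start = c(0, q_start),
    end = c(p_end, chrom_len), arm = c("p", "q"))))
  arm_table(df, assembly = "toy")
}

#' One simulated arm-level copy-number event
#'
#' @param arm Arm id, e.g. `"chr2q"`.
#' @param copy_state Integer copy number in {0, 1, 3, 4} (2 is diploid and
#'   not an event).
#' @param tumor_fraction Fraction of tumor-derived DNA in (0, 1].
#' @return List with the fields above plus `expected_ratio`, the bulk
#'   coverage ratio `r = (1 - f) + f * copy_state / 2`.
#' @export
cnv_event <- function(arm, copy_state, tumor_fraction) {
  if (!copy_state %in% c(0L, 1L, 3L, 4L)) stop("copy_state must be 0, 1, 3 or 4")
  if (tumor_fraction <= 0 || tumor_fraction > 1) stop("tumor_fraction in (0, 1]")
  list(arm = arm, copy_state = as.integer(copy_state),
       tumor_fraction = tumor_fraction,
       expected_ratio = (1 - tumor_fraction) + tumor_fraction * copy_state / 2)
}

#' Simulation configuration for a binned low-pass WGS cohort
#'
#' Defaults emulate the study design the package targets: a 9-sample benign
#' control panel, 16 cases, 200-kb bins, and libraries of 15 million read
#' pairs. Counts are negative-binomial around a shared lognormal per-bin
#' bias (real low-pass panels are overdispersed relative to Poisson, and
#' the panel SD that forms the Z denominator must reflect inter-sample
#' structure).
#'
#' @param arms An [arm_table()] (default [toy_genome()]; pass
#'   `arm_table("hg19")` for a genome-scale cohort).
#' @param bin_size Bin width (default 2e5).
#' @param n_controls,n_cases Cohort sizes (defaults 9 and 16).
#' @param mean_read_pairs Mean library size (default 1.5e7).
#' @param bin_bias_sd SD of the shared per-bin lognormal bias (default 0.1).
#' @param sample_dispersion Negative-binomial overdispersion: extra
#'   per-bin coefficient of variation squared beyond Poisson (default 0.01,
#'   i.e. 10% extra CV per bin).
#' @param gc_bias_amplitude Amplitude of an optional smooth positional bias
#'   standing in for GC content (default 0, off).
#' @param events List over cases; each element a list of [cnv_event()]s
#'   (may be empty). Default: one single-copy gain or loss per case at
#'   tumor fraction 0.4 on arms cycling through the genome, with every
#'   6th case event-free, loosely matching observed cohorts where a
#'   minority of cases carry no detectable arm event.
#' @param rng_seed Integer seed; the whole cohort is reproducible from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(arms = toy_genome(), bin_size = 2e5,
                       n_controls = 9, n_cases = 16,
                       mean_read_pairs = 1.5e7,
                       bin_bias_sd = 0.1, sample_dispersion = 0.01,
                       gc_bias_amplitude = 0, events = NULL,
                       rng_seed = 1) {
  stopifnot(n_controls >= 2, n_cases >= 0, mean_read_pairs > 0,
            bin_bias_sd >= 0, sample_dispersion >= 0)
  grid <- make_bins(arms, bin_size)
  arm_ids <- unique(grid$arm_id)
  if (is.null(events)) {
    events <- lapply(seq_len(n_cases), function(i) {
      if (i %% 6 == 0) return(list())  # some cases carry no arm event
      arm <- arm_ids[(i - 1) %% length(arm_ids) + 1]
      cs <- if (i %% 2 == 0) 1L else 3L
      list(cnv_event(arm, cs, 0.4))
    })
  }
  if (length(events) != n_cases) stop("events must have one entry per case")
  for (evs in events) for (e in evs)
    if (!e$arm %in% arm_ids) stop("event arm not in grid: ", e$arm)
  structure(list(arms = arms, bin_size = bin_size, grid = grid,
                 n_controls = n_controls, n_cases = n_cases,
                 mean_read_pairs = mean_read_pairs,
                 bin_bias_sd = bin_bias_sd,
                 sample_dispersion = sample_dispersion,
                 gc_bias_amplitude = gc_bias_amplitude,
                 events = events, rng_seed = rng_seed),
            class = "sim_config")
}

# one sample's counts: multinomial over bins with gamma-perturbed weights,
# so counts sum exactly to the drawn read total while being marginally
# negative-binomial with the configured overdispersion
sim_sample_counts <- function(base_weight, ratio, total, dispersion) {
  w <- base_weight * ratio
  if (dispersion > 0)
    w <- w * stats::rgamma(length(w), shape = 1 / dispersion, scale = dispersion)
  as.numeric(stats::rmultinom(1, total, w))
}

#' Simulate a cohort of binned read counts with known truth
#'
#' Controls are diploid everywhere; each case carries its configured
#' arm-level events, which scale that arm's expected coverage by
#' `r = (1 - f) + f * copy_state / 2`. A free/total PSA percentage is drawn
#' per sample from group-specific distributions (benign higher than
#' cancer, a minority of case values missing) as demo covariate data.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (list of [bin_counts()], controls first),
#'   `truth` (data.frame: sample_id, group, arms, expected ratios, ft
#'   percent), `sample_sheet` (data.frame: sample_id, group, ft_percent),
#'   and `grid`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)
  grid <- cfg$grid
  nb <- nrow(grid)
  bias <- exp(stats::rnorm(nb, 0, cfg$bin_bias_sd))
  if (cfg$gc_bias_amplitude > 0)
    bias <- bias * (1 + cfg$gc_bias_amplitude * sin(2 * pi * seq_len(nb) / 60))
  ids <- c(sprintf("ctrl%02d", seq_len(cfg$n_controls)),
           sprintf("case%02d", seq_len(cfg$n_cases)))
  group <- c(rep("BPH", cfg$n_controls), rep("PCa", cfg$n_cases))
  counts <- vector("list", length(ids))
  truth <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    ratio <- rep(1, nb)
    evs <- if (group[s] == "PCa") cfg$events[[s - cfg$n_controls]] else list()
    for (e in evs) ratio[grid$arm_id == e$arm] <- e$expected_ratio
    total <- stats::rpois(1, cfg$mean_read_pairs)
    counts[[s]] <- bin_counts(ids[s],
                              sim_sample_counts(bias, ratio, total,
                                                cfg$sample_dispersion),
                              grid, total_read_pairs = total)
    ft <- if (group[s] == "PCa") {
      if (stats::runif(1) < 0.3) NA_real_
      else max(3, stats::rnorm(1, 13, 6))
    } else max(3, stats::rnorm(1, 18, 5))
    truth[[s]] <- data.frame(
      sample_id = ids[s], group = group[s],
      arms = paste(vapply(evs, `[[`, character(1), "arm"), collapse = ";"),
      copy_states = paste(vapply(evs, `[[`, integer(1), "copy_state"), collapse = ";"),
      tumor_fractions = paste(vapply(evs, `[[`, numeric(1), "tumor_fraction"), collapse = ";"),
      expected_ratios = paste(vapply(evs, `[[`, numeric(1), "expected_ratio"), collapse = ";"),
      ft_percent = round(ft, 2), stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  sheet <- data.frame(sample_id = truth$sample_id, group = truth$group,
                      gleason = NA_character_, psa_total = NA_real_,
                      psa_free = NA_real_, ft_percent = truth$ft_percent,
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth, sample_sheet = sheet, grid = grid)
}

#' Emit a toy BAM whose midpoint binning reproduces given counts
#'
#' Writes, sorts and indexes a small single-end BAM in which each bin
#' receives exactly its requested number of 100-bp reads, each read's
#' midpoint placed uniformly inside the bin. Intended to exercise
#' [count_bam_reads()] end to end; guarded to small inputs.
#'
#' @param counts A [bin_counts()] object with at most 1e5 reads total.
#' @param path Output BAM path (a `.sam` sibling is created and removed).
#' @return The BAM path, invisibly.
#' @export
simulate_alignments <- function(counts, path) {
  stopifnot(inherits(counts, "bin_counts"))
  if (sum(counts$counts) > 1e5)
    stop("simulate_alignments is for toy data (<= 1e5 reads)")
  grid <- counts$grid
  chroms <- unique(grid$chrom)
  chrom_len <- vapply(chroms, function(cn) max(grid$end[grid$chrom == cn]),
                      numeric(1))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(chrom_len)))
  recs <- list()
  rid <- 0
  for (b in seq_len(nrow(grid))) {
    k <- counts$counts[b]
    if (k == 0) next
    # midpoint strictly inside the bin, away from edges so pos stays valid
    mid <- floor(stats::runif(k, grid$start[b] + 50, grid$end[b] - 50))
    pos1 <- mid - 50 + 1  # 1-based leftmost; 100M => midpoint pos0 + 50
    recs[[length(recs) + 1]] <- data.frame(
      qname = sprintf("r%06d", rid + seq_len(k)), chrom = grid$chrom[b],
      pos = as.integer(pos1), stringsAsFactors = FALSE)
    rid <- rid + k
  }
  sam_path <- sub("\\.bam$", ".sam", path)
  lines <- hdr
  if (length(recs)) {
    df <- do.call(rbind, recs)
    df <- df[order(match(df$chrom, chroms), df$pos), ]
    lines <- c(lines, sprintf("%s\t0\t%s\t%d\t60\t100M\t*\t0\t0\t*\t*",
                              df$qname, df$chrom, df$pos))
  }
  writeLines(lines, sam_path)
  Rsamtools::asBam(sam_path, sub("\\.bam$", "", path), overwrite = TRUE,
                   indexDestination = TRUE)
  unlink(sam_path)
  invisible(path)
}

#' Published-table fixtures
#'
#' The printed study tables packaged as plain data: the per-patient
#' baseline sheet (28 patients: 16 adenocarcinoma, 9 BPH, 3 PIN; `NA`
#' where the table prints a dash) and the five diagnostic confusion
#' matrices (CNV model at cutoffs 2, 2.5 and 3; f/t PSA at thresholds 10%
#' and 16%).
#'
#' @return List with `table1` (data.frame: sample_id, age, group, gleason,
#'   psa_total, psa_free, ft_percent) and `table3` (data.frame: test,
#'   cutoff, tn, tp, fn, fp).
#' @export
study_fixtures <- function() {
  p1 <- system.file("extdata", "table1_patients.csv", package = "procad")
  p3 <- system.file("extdata", "table3_confusions.csv", package = "procad")
  t1 <- utils::read.csv(p1, stringsAsFactors = FALSE,
                        na.strings = c("NA", "-", "–"))
  t3 <- utils::read.csv(p3, stringsAsFactors = FALSE)
  list(table1 = t1, table3 = t3)
}
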
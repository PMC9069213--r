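make_cohort <- function(n_controls = 9, n_cases = 0, seed = 61, events = NULL,
                        dispersion = 0.01) {
  cfg <- sim_config(n_controls = n_controls, n_cases = n_cases,
                    mean_read_pairs = 2e5, sample_dispersion = dispersion,
                    events = events, rng_seed = seed)
  sim <- simulate_cohort(cfg)
  mask <- filter_bins(sim$counts[seq_len(n_controls)])
  norm <- lapply(sim$counts, normalize_coverage, mask = mask)
  list(sim = sim, mask = mask, norm = norm,
       controls = norm[seq_len(n_controls)])
}

test_that("panel statistics match direct mean/SD recomputation", {
  ch <- make_cohort(n_controls = 9)
  panel <- build_panel(ch$controls, min_bins_per_arm = 10)
  V <- sapply(ch$controls, `[[`, "values")
  expect_equal(panel$bin_mean, rowMeans(V))
  expect_equal(panel$bin_sd, apply(V, 1, sd))
  arm_of_bin <- panel$grid$arm_id[panel$bins]
  for (a in panel$arm_ids) {
    va <- colMeans(V[arm_of_bin == a, , drop = FALSE])
    expect_equal(unname(panel$arm_mean[a]), mean(va))
    expect_equal(unname(panel$arm_sd[a]), sd(va))
  }
  expect_equal(length(panel$control_ids), 9)
})

test_that("degenerate panels are rejected", {
  ch <- make_cohort(n_controls = 2, seed = 62)
  # two identical controls -> zero SD everywhere -> error surface
  twin <- list(ch$controls[[1]], ch$controls[[1]])
  twin[[2]]$sample_id <- "twin"
  expect_error(suppressWarnings(build_panel(twin)), "zero spread")
  expect_error(build_panel(ch$controls[1]), ">= 2 controls")
})

test_that("two-point SD example: controls at 0.9 and 1.1 give mean 1, sd ~0.1414", {
  g <- tiny_grid()
  mk <- function(id, lo, hi) {
    cnt <- rep(c(lo, hi), length.out = nrow(g))
    normalize_coverage(bin_counts(id, cnt, g))
  }
  # construct two controls whose values at each bin are 0.9 and 1.1
  c1 <- mk("a", 90, 110); c2 <- mk("b", 110, 90)
  # arm-level spread is zero by construction here (each control's arm mean
  # is exactly 1), so the arm warning is expected; bin stats are the point
  panel <- suppressWarnings(build_panel(list(c1, c2), min_bins_per_arm = 2))
  expect_equal(unname(panel$bin_mean), rep(1, nrow(g)), tolerance = 1e-12)
  expect_equal(unname(panel$bin_sd), rep(sd(c(0.9, 1.1)), nrow(g)),
               tolerance = 1e-9)
  expect_equal(sd(c(0.9, 1.1)), 0.1414, tolerance = 1e-3)
})

test_that("bin and arm Z obey the formula identities", {
  ch <- make_cohort(n_controls = 6, seed = 63)
  panel <- build_panel(ch$controls, min_bins_per_arm = 10)
  # synthetic sample exactly at the panel mean -> all Z zero
  smp <- ch$controls[[1]]
  smp$sample_id <- "probe"; smp$values <- panel$bin_mean
  expect_true(all(abs(bin_zscores(smp, panel)) < 1e-12, na.rm = TRUE))
  az <- arm_zscores(smp, panel)
  expect_true(all(abs(az$z) < 1e-9))
  # mean + 2 SD at every bin -> bin Z == 2
  smp$values <- panel$bin_mean + 2 * panel$bin_sd
  expect_equal(unname(bin_zscores(smp, panel)),
               rep(2, length(panel$bin_mean)))
})

test_that("arm-mean and stouffer modes agree in sign on uniform shifts", {
  ch <- make_cohort(n_controls = 9, n_cases = 1, seed = 64,
                    events = list(list(cnv_event("chr2q", 3, 0.5))))
  panel <- build_panel(ch$controls, min_bins_per_arm = 10)
  case <- ch$norm[[10]]
  z1 <- arm_zscores(case, panel, mode = "arm-mean")
  z2 <- arm_zscores(case, panel, mode = "stouffer")
  expect_gt(z1$z[["chr2q"]], 2.5)
  expect_gt(z2$z[["chr2q"]], 2.5)
  strong <- abs(z1$z) > 1 & abs(z2$z) > 1
  expect_true(all(sign(z1$z[strong]) == sign(z2$z[strong])))
  expect_error(arm_zscores(case, panel, mode = "nope"))
})

test_that("a 1-copy 8q-style gain at tumor fraction 0.4 scores Z >= 2.5", {
  ch <- make_cohort(n_controls = 9, n_cases = 2, seed = 65,
                    events = list(list(cnv_event("chr3q", 3, 0.4)),
                                  list(cnv_event("chr1p", 1, 0.4))))
  panel <- build_panel(ch$controls, min_bins_per_arm = 10)
  gain <- arm_zscores(ch$norm[[10]], panel)
  loss <- arm_zscores(ch$norm[[11]], panel)
  expect_gt(gain$z[["chr3q"]], 2.5)
  expect_lt(loss$z[["chr1p"]], -2.5)
})

test_that("leave-one-out control Z-scores are calibrated near N(0, 1)", {
  ch <- make_cohort(n_controls = 18, seed = 66)
  panel <- build_panel(ch$controls, min_bins_per_arm = 10)
  z <- unlist(lapply(ch$controls, function(ctl)
    arm_zscores(ctl, panel, leave_one_out = TRUE)$z))
  expect_lt(abs(mean(z)), 0.15)
  expect_gt(sd(z), 0.8)
  expect_lt(sd(z), 1.3)
  # leave-one-out needs a big enough panel when scoring members
  small <- build_panel(ch$controls[1:2], min_bins_per_arm = 10)
  expect_error(arm_zscores(ch$controls[[1]], small, leave_one_out = TRUE),
               ">= 3 controls")
})

test_that("scoring is invariant to common depth rescaling", {
  ch <- make_cohort(n_controls = 5, n_cases = 1, seed = 67,
                    events = list(list(cnv_event("chr4q", 3, 0.4))))
  panel <- build_panel(ch$controls, min_bins_per_arm = 10)
  z1 <- arm_zscores(ch$norm[[6]], panel)
  scaled <- lapply(seq_len(6), function(i) {
    bc <- ch$sim$counts[[i]]; bc$counts <- bc$counts * 3
    normalize_coverage(bc, ch$mask)
  })
  panel2 <- build_panel(scaled[1:5], min_bins_per_arm = 10)
  z2 <- arm_zscores(scaled[[6]], panel2)
  expect_equal(z1$z, z2$z, tolerance = 1e-9)
})

test_that("event summarization applies the |Z| >= cutoff rule exactly", {
  prof <- structure(list(sample_id = "s",
                         z = c(chr8q = 3.0, chr18q = -2.6, chr1p = 2.49,
                               chr2q = 0), n_arms = 4L, mode = "arm-mean"),
                    class = "arm_z")
  ev <- cnv_events(prof, cutoff = 2.5)
  expect_equal(ev$n_events, 2)
  expect_true(ev$positive)
  expect_equal(ev$calls$direction[ev$calls$arm == "chr8q"], "gain")
  expect_equal(ev$calls$direction[ev$calls$arm == "chr18q"], "loss")
  expect_false("chr1p" %in% ev$calls$arm)   # 2.49 < 2.5, threshold is >=
  null_prof <- prof; null_prof$z[] <- 0
  expect_false(cnv_events(null_prof, 2.5)$positive)
})
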
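test_that("classification uses max |Z| with an inclusive boundary", {
  prof <- structure(list(sample_id = "s", z = c(chr1p = 0, chr8q = 0),
                         n_arms = 2L, mode = "arm-mean"), class = "arm_z")
  expect_false(classify_sample(prof, 2.5)$positive)
  prof$z <- c(chr1p = -3, chr8q = 1)
  cl <- classify_sample(prof, 2.5)
  expect_true(cl$positive)          # losses count through the absolute value
  expect_equal(cl$arms, "chr1p")
  prof$z <- c(chr1p = 2.5, chr8q = 1)
  expect_true(classify_sample(prof, 2.5)$positive)  # score == cutoff
  empty <- prof; empty$z <- numeric(0)
  expect_error(classify_sample(empty, 2.5), "empty")
})

test_that("confusion metrics reproduce the published operating points", {
  rows <- list(
    list(cc = c(9, 13, 3, 0),
         pct = c(sensitivity = 81.3, specificity = 100.0, ppv = 100.0,
                 npv = 75.0, accuracy = 88.0)),
    list(cc = c(3, 15, 1, 6),
         pct = c(sensitivity = 93.8, specificity = 33.3, ppv = 71.4,
                 npv = 75.0, accuracy = 72.0)),
    list(cc = c(9, 8, 8, 0),
         pct = c(sensitivity = 50.0, specificity = 100.0, ppv = 100.0,
                 npv = 52.9, accuracy = 68.0)))
  for (r in rows) {
    m <- confusion_metrics(confusion_counts(tn = r$cc[1], tp = r$cc[2],
                                            fn = r$cc[3], fp = r$cc[4]))
    expect_equal(m$percent[names(r$pct)], r$pct)
    expect_equal(m$youden_j,
                 m$estimate[["sensitivity"]] + m$estimate[["specificity"]] - 1)
    expect_equal(m$estimate[["accuracy"]] *
                   with(m$counts, tn + tp + fn + fp),
                 m$counts$tp + m$counts$tn)
  }
  # degenerate denominators are NA, not errors
  m0 <- confusion_metrics(confusion_counts(tn = 0, tp = 5, fn = 0, fp = 0))
  expect_equal(m0$estimate[["sensitivity"]], 1)
  expect_true(is.na(m0$estimate[["specificity"]]))
})

test_that("Wilson continuity-corrected intervals hit the printed CIs", {
  expect_equal(unname(round(100 * wilson_ci(13, 16), 1)), c(53.7, 95.0))
  expect_equal(unname(round(100 * wilson_ci(10, 11), 1)), c(57.1, 99.5))
  expect_equal(unname(round(100 * wilson_ci(3, 5), 1)), c(17.0, 92.7))
  expect_equal(unname(wilson_ci(0, 9)[1]), 0)
  expect_equal(unname(wilson_ci(9, 9)[2]), 1)
  ci <- wilson_ci(7, 10)
  expect_true(ci[1] < 0.7 && 0.7 < ci[2])
  expect_error(wilson_ci(5, 4), "k <= n")
})

test_that("AUC by pair counting equals trapezoidal ROC integration", {
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_equal(roc_auc(c(3.1, 0.5, 1.0), c(1, 1, 0))$auc, 0.5)
  set.seed(81)
  for (r in 1:200) {
    n1 <- sample(2:15, 1); n0 <- sample(2:15, 1)
    sc <- c(rnorm(n1, 0.5), rnorm(n0))
    if (runif(1) < 0.3) sc <- round(sc)   # force ties sometimes
    lab <- rep(c(1, 0), c(n1, n0))
    roc <- roc_auc(sc, lab)
    expect_equal(roc$auc, oracle_trapezoid_auc(roc$points), tolerance = 1e-10)
  }
})

test_that("AUC and DeLong CI agree with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(82)
  sc <- c(rnorm(16, 0.8), rnorm(9))
  lab <- rep(c(1, 0), c(16, 9))
  mine <- roc_auc(sc, lab)
  ref <- pROC::roc(lab, sc, direction = "<", quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
  expect_equal(unname(mine$auc_ci),
               as.numeric(pROC::ci.auc(ref, method = "delong"))[c(1, 3)],
               tolerance = 1e-9)
})

test_that("low-is-positive orientation mirrors the score scale", {
  sc <- c(5, 8, 20, 30)          # low values mark cases
  lab <- c(1, 1, 0, 0)
  expect_equal(roc_auc(sc, lab, direction = "low")$auc, 1)
  expect_equal(roc_auc(sc, lab, direction = "high")$auc, 0)
})

test_that("paired DeLong test behaves at its fixed points and has power", {
  set.seed(83)
  sc <- c(rnorm(20, 1), rnorm(20))
  lab <- rep(c(1, 0), each = 20)
  same <- delong_test(sc, sc, lab)
  expect_equal(same$p_value, 1)
  expect_equal(same$auc_a, same$auc_b)
  perfect <- c(rnorm(50, 10), rnorm(50))    # separable marker
  noise <- rnorm(100)
  lab100 <- rep(c(1, 0), each = 50)
  dt <- delong_test(perfect, noise, lab100)
  expect_lt(dt$p_value, 0.01)
  expect_equal(dt$auc_a, roc_auc(perfect, lab100)$auc)
  expect_equal(dt$auc_b, roc_auc(noise, lab100)$auc)
  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(lab100, perfect, direction = "<", quiet = TRUE),
                        pROC::roc(lab100, noise, direction = "<", quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(dt$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("Youden selection picks 2.50 from the published table and breaks ties up", {
  t3 <- study_fixtures()$table3
  cand <- t3[t3$test == "cnv_z", c("cutoff", "tn", "tp", "fn", "fp")]
  expect_equal(youden_cutoff(cand), 2.5)
  tie <- data.frame(cutoff = c(1, 2), tn = c(5, 5), tp = c(5, 5),
                    fn = c(0, 0), fp = c(0, 0))
  expect_equal(youden_cutoff(tie), 2)
  expect_error(youden_cutoff(tie[1, ]), ">= 2")
})

test_that("Fisher p-values equal exhaustive enumeration over fixed margins", {
  expect_equal(fisher_exact_2x2(matrix(c(10, 1, 3, 2), 2, byrow = TRUE)),
               0.2143, tolerance = 1e-4)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)),
               2 / choose(10, 5), tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(c(4, 4, 6, 6), 2)), 1)
  set.seed(84)
  for (r in 1:50) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab), tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 2), 2, byrow = TRUE)),
               "margin")
})

test_that("Mann-Whitney exact p equals permutation enumeration at small n", {
  set.seed(85)
  for (r in 1:20) {
    x <- rnorm(4); y <- rnorm(4)
    mw <- mann_whitney_u(x, y)
    expect_equal(mw$p_value, oracle_mw_exact_p(x, y), tolerance = 1e-9)
    expect_equal(mw$u, sum(outer(x, y, ">")))
  }
  # complete separation attains the smallest possible p for the sizes
  mw <- mann_whitney_u(11:14, 1:4)
  expect_equal(mw$u, 16)
  expect_equal(mw$p_value, 2 / choose(8, 4), tolerance = 1e-9)
  # identical multisets -> p ~ 1 (tie-corrected normal approximation)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.99)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("the combined CNV + f/t PSA rule is an OR with missing PSA ignored", {
  cnv <- c(FALSE, TRUE, FALSE, TRUE)
  ft <- c(8, NA, 20, 12)
  expect_equal(combined_test(cnv, ft, ft_threshold = 16),
               c(TRUE, TRUE, FALSE, TRUE))
  expect_error(combined_test(c(TRUE, FALSE), 1), "aligned")
})
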
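# shared fixtures and independent oracles for the test suite

# two-chromosome toy arm table (fast, 4 arms)
tiny_arms <- function() {
  arm_table(data.frame(
    chrom = rep(c("chr1", "chr2"), each = 2),
    start = rep(c(0, 5e6), 2),
    end = rep(c(4e6, 1e7), 2),
    arm = rep(c("p", "q"), 2)))
}

tiny_grid <- function(bin_size = 2e5) make_bins(tiny_arms(), bin_size)

# deterministic pseudo-counts on a grid, optionally scaled per arm
tiny_counts <- function(grid, id = "s1", base = 100, arm_scale = NULL) {
  cnt <- rep(base, nrow(grid))
  if (!is.null(arm_scale))
    for (a in names(arm_scale)) cnt[grid$arm_id == a] <- base * arm_scale[[a]]
  bin_counts(id, cnt, grid)
}

# brute-force arc search: direct double loop over all (i, j)
oracle_max_arc <- function(x, min_width = 2) {
  n <- length(x); s <- sd(x)
  best <- list(i = 0L, j = as.integer(min_width), t = 0); best_abs <- -1
  for (i in 0:(n - min_width)) {
    for (j in (i + min_width):n) {
      k <- j - i
      if (k > n - min_width) next
      arc <- x[(i + 1):j]; rest <- x[setdiff(seq_len(n), (i + 1):j)]
      tt <- (mean(arc) - mean(rest)) / (s * sqrt(1 / k + 1 / (n - k)))
      if (abs(tt) > best_abs + 1e-12) {
        best <- list(i = i, j = j, t = tt); best_abs <- abs(tt)
      }
    }
  }
  best
}

# exhaustive two-sided Fisher p for a 2x2 table with fixed margins
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(a_range, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y); nx <- length(x)
  u_of <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_of(x, y)
  combs <- utils::combn(length(pooled), nx)
  u_all <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mu <- nx * (length(y)) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# trapezoidal AUC from ROC points (fpr ascending)
oracle_trapezoid_auc <- function(points) {
  o <- order(points$fpr, points$sensitivity)
  fpr <- points$fpr[o]; sens <- points$sensitivity[o]
  sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
}
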
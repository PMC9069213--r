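---
title: "Arm-level aneuploidy detection from low-pass WGS: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arm-level aneuploidy detection from low-pass WGS: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procad)
```

## The problem and the model

Solid tumors, prostate adenocarcinoma prominently among them, are rich in
chromosomal instability: whole chromosome arms gained or lost. Cells shed
into urine carry that signal, and low-pass whole-genome sequencing (well
below 1x) is enough to read it out as coverage imbalance, even though it is
far too shallow for variant calling. The package implements the complete
analysis chain for this design:

1. **Coordinate scaffold.** Autosomal chromosome arms (44 for the packaged
   hg19 table) are tiled per-arm with fixed-width bins (200 kb by default;
   trailing remainders are dropped so every bin has identical width).
   Tiling per arm, not per chromosome, means no bin straddles a
   centromere, which matters because every downstream statistic is
   arm-resolved.
2. **Depth normalization.** Each sample's bin counts are divided by their
   mean over usable bins, giving a coverage value $V_b$ with mean exactly
   1. Any common depth factor cancels, so libraries of different size are
   comparable.
3. **Panel of normals.** Benign controls define per-bin and per-arm
   reference statistics. A sample's score on arm $a$ is
   $$Z_a = \frac{V_a - \overline{V}_{\mathrm{control},a}}
                {\mathrm{sd}(V_{\mathrm{control},a})},$$
   with $V_a$ the mean usable-bin coverage on the arm. The SD uses the
   $n-1$ denominator because panels are small (nine controls in the
   motivating design).
4. **Classifier.** The diagnostic score is $\max_a |Z_a|$; a sample is
   positive when the score reaches the cutoff (2.5 by default, selected by
   Youden's index among tabulated operating points). Losses count through
   the absolute value.

A heterozygous arm gain at tumor fraction $f$ multiplies expected coverage
by $r = 1 + f/2$; a loss by $1 - f/2$. At $f = 0.3$ a gain is a 15% shift,
which at 200-kb bins and a quiet panel corresponds to arm $|Z|$ far above
the cutoff — the test's power is limited mainly by panel spread, not
sequencing noise.

## Quality control

Noisy libraries are flagged by the adjacent-bin MAD rule: first
differences of log2 copy ratios between bins adjacent *within the same
arm* (jumps across centromeres are structure, not noise), pooled
genome-wide, summarized as $1.4826 \cdot \mathrm{median}|d -
\mathrm{median}(d)|$, and compared against a threshold of 0.38. The
threshold is interpreted as *flag when exceeded* — a point-equality
trigger is meaningless for a continuous statistic — and the 1.4826
consistency constant is configurable since conventions differ on whether
the scaled or raw MAD is quoted. A minimum library size (15 million read
pairs by default) is checked as well, but it is warning-grade: the
exclusion rule proper is the MAD rule, and short toy libraries remain
usable for simulation work.

## Scoring protocols: members vs held-out samples

Whether a panel member should be scored against a panel containing itself
is a genuinely open design point, and the two protocols differ sharply at
$n = 9$:

- **Self-included** (the `procad()` default, `loo_controls = FALSE`): a
  member's score is bounded by $(n-1)/\sqrt{n} \approx 2.67$, and in
  practice sits far below 2.5. This reproduces the characteristic
  all-negative behavior of a benign reference panel: a control's own
  coverage is part of the reference it is compared against.
- **Leave-one-out** (`leave_one_out = TRUE` in the scoring functions):
  unbiased but heavy-tailed — the score is approximately
  $\sqrt{1 + 1/(n-1)}\, t_{n-2}$, which exceeds 2.5 on roughly 5% of
  null arms at $n = 9$. This protocol is the right one for calibration
  studies (the null-calibration tests use it with larger panels, where
  the pooled SD lands near 1 as it should).

Held-out samples (cases, or anything scored through `predict()`) always
use the full panel. Their null arms inherit $t_{n-1}$ tails, so with small
panels occasional spurious arm calls at $|Z| \ge 2.5$ are expected — about
5% per arm at $n = 9$. This is a property of the method, not of the
implementation; it is why the classifier reports the *top* arm (argmax of
$|Z|$), which is essentially always the true event arm when an event is
present, while event-level call sets should be read with the per-arm false
rate in mind.

## Segmentation

Circular binary segmentation is implemented from scratch. The arc
statistic compares the mean inside an arc $(i, j]$ against the mean
outside, standardized by the overall SD; the maximizing arc is found by an
exact scan over all arcs (vectorized per arc width via cumulative sums,
equivalent to brute-force enumeration, which the tests verify). Split
significance uses a permutation test with the add-one estimator
$p = (1 + \#\{T^{*} \ge T\})/(1 + B)$, $B = 1000$ by default — never
exactly zero, and the permutation loop exits early once significance at
$\alpha$ is out of reach. Accepted splits are ternary in general, binary
when the arc touches an end, and recursion continues into each piece.
Segmentation is per-arm for consistency with arm-level diagnosis. There is
no "undo splits" pruning stage; at arm-scale signal it has nothing to do.
Per-arm RNG streams are derived from the configured seed so results do not
depend on arm order, and identical seeds give identical breakpoints.

## Statistical evaluation battery

- **Confusion metrics** report sensitivity, specificity, PPV, NPV and
  accuracy with 95% **Wilson continuity-corrected** intervals. This
  interval family was chosen because it exactly reproduces the printed
  intervals of the motivating study at one decimal in percent (13/16
  giving 53.7–95.0, 10/11 giving 57.1–99.5, 3/5 giving 17.0–92.7);
  Clopper–Pearson and the plain Wilson score do not. Display percentages
  round half-up to one decimal (so 13/16 shows as 81.3%).
- **ROC/AUC** by pair counting with ties scoring 1/2 (the Mann–Whitney
  identity; equal to trapezoidal integration of the ROC, a tested
  invariant), with DeLong variance for the CI and the paired DeLong test
  for comparing correlated markers such as the CNV score against the
  free/total PSA ratio (which is oriented low-is-positive).
- **Youden selection** maximizes $J$ over tabulated operating points,
  breaking ties toward the larger (more specific) cutoff.
- Group comparisons go through Fisher's exact test and the Mann–Whitney
  U test; the tests verify both against exhaustive enumeration oracles.

## The cohort simulator

`simulate_cohort()` generates binned counts with known arm-level truth.
Each bin carries a shared lognormal bias (SD 0.1 by default) standing in
for mappability/GC structure; each sample draws a read total around the
configured mean and distributes it multinomially with gamma-perturbed
weights, which makes counts marginally negative-binomial (default
overdispersion 0.01, i.e. 10% extra CV per bin beyond Poisson) while
conserving the read total exactly. Case samples scale their event arms by
$r = (1-f) + f \cdot \mathrm{copies}/2$. Defaults mirror the motivating
study: 9 controls, 16 cases, 200-kb bins, 15 million read pairs.

What the simulator does *not* emulate: GC dependence of individual
fragments, mappability dropout, subclonal mixtures, and correlated
wave artifacts of real low-pass data. Passing recovery tests therefore
demonstrate the pipeline's correctness and calibration under its stated
noise model, not clinical performance.

`simulate_alignments()` additionally renders small count vectors as
sorted, indexed BAM files (each read's midpoint placed inside its bin) so
the BAM counting path is exercised end to end without any external data.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open internally; SEG output converts to
  1-based inclusive per community convention.
- Arms with fewer than 10 usable bins are dropped (`min_bins_per_arm`).
  On real 200-kb data this removes the acrocentric short arms, which
  reconciles "44 arms computed" with the ~39 arms usable in practice; on
  clean synthetic panels all toy arms pass.
- Zero-SD bins or arms in the panel are dropped with a warning: a Z-score
  needs a positive denominator.
- Bins with low panel median or frequent zeros are masked before anything
  else, with per-bin reason codes.
- Log2 ratios use an additive epsilon guard (1e-6) against empty bins.
- The arc search breaks ties (including arc/complement ties, which are
  equal up to floating error) toward the lexicographically smallest
  boundary pair.
- `max |Z|` comparisons are boundary-inclusive everywhere (score 2.50 at
  cutoff 2.50 is positive), matching the stated decision rule.

## Problem sizes used by the test suite

The suite favors toy genomes (4 chromosomes of 20 Mb, 200-kb bins, about
380 bins) with 2e5-read libraries: at ~500 reads per bin these leave the
arm-level signal-to-noise of the full-scale design intact while a full
cohort simulates in under a second. Oracle-equivalence checks run the
exact arc scan against brute-force enumeration on 100 random sequences up
to length 50; the permutation null is profiled over 200 seeded runs at
sequence length 60 and 500 permutations; null calibration uses a
16-control panel. A genome-scale smoke test runs the hg19 arm table at
2-Mb bins.

## Limitations

- The arm-level Z has $t$-tails at small panel sizes; per-arm event calls
  at $|Z| \ge 2.5$ carry a ~5% false rate per arm with a 9-sample panel.
  Larger panels tighten this roughly as $t_{n-1}$.
- GC correction is available in spirit (the simulator can generate GC-like
  bias) but the default pipeline applies none, since the motivating
  workflow does not.
- The packaged hg19 arm table is cytoband-derived; users with other
  assemblies supply their own 4-column table.
- Tumor fraction is not estimated; the score is a detection statistic,
  not a quantification.
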
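---
title: "Scale-space CNV calling from exome read depth: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-space CNV calling from exome read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excnvss)
```

## The problem

Whole-exome sequencing captures a sparse set of short target intervals
(typically ~200,000 genome-wide, a few hundred base pairs each), so copy
number variants (CNVs) leave their footprint only as depth changes over
scattered, small, non-contiguous windows. Two obstacles dominate: capture
and sequencing introduce strong per-target coverage biases, and a CNV may
span anything from part of one exon to dozens of consecutive exons, so no
single smoothing window is right.

`excnvss` addresses both with a two-part design:

1. **Normalization.** Per-base depth over all targets is concatenated into
   one axis. With a matched control, the signal is the per-base ratio of
   test to control depth times a library-size factor
   $\omega = m_C / m_T$ (total control mass over total test mass), which
   cancels shared capture bias. Without a control (noRatio mode), the raw
   test depth is used. The signal is then partitioned into fixed
   `bin_size` segments, segment means are converted to t-scores against
   the grand mean and standard deviation of all segment means, shifted so
   the minimum is zero, and finally redistributed to base level while
   preserving within-segment deviations.
2. **Scale-space detection.** The normalized signal is smoothed with a
   geometric family of Gaussians $\sigma_k = \sigma_0 g^{k-1}$
   (defaults $\sigma_0 = 100$ bases, $g = 1.1$, 50 layers). Inflection
   points of each smoothed layer — zero crossings of the second-order
   difference — form the fingerprint map. At every layer, intervals
   bounded by two opposite-sign crossings with no crossing between them
   are candidate CNVs if their mean smoothed signal lies beyond empirical
   rank baselines: the upper baseline is the smallest of the top
   $\lceil (1-p_{\max}) n \rceil$ values of that layer, the lower the
   largest of the bottom $\lceil p_{\min} n \rceil$ values. Accepted
   intervals are traced down the fingerprint map to base resolution,
   typed as gains (above the upper baseline) or losses (below the lower),
   and declared top-down with already-declared regions excluded, so the
   coarsest explanation of a region wins and finer structure is only
   reported where nothing coarser claimed it.

Large CNVs are therefore found at coarse layers and single-exon CNVs at
fine layers with one pass of the same machinery.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `bin_size` | 30 bases | segment size of the normalization; remnants of a target shorter than one segment are trimmed symmetrically (`floor(rem/2)` in front). 30 keeps at least three segments for a median ~240 bp target while leaving enough bases per segment for a stable within-segment standard deviation. |
| `epsilon` | 1e-3 | near-zero guard of the depth ratio. Depths below it are treated as zero evidence: both below → ratio 1; test below → 0. |
| `base_sigma`, `growth`, `n_layers` | 100, 1.1, 50 | the scale schedule; $\sigma$ spans 100 to ~10,700 bases, covering single-segment events up to multi-exon spans. Layers whose $6\sigma$ exceeds the signal are dropped. |
| `p_max`, `p_min` | 0.9875, 0.0125 (ratio); `p_min` 0.04 (noRatio) | rank levels of the per-layer baselines; the defaults are the best-performing thresholds of the reference study. `auto_pmin` raises `p_min` to the fraction of zero-depth test bases, the situation the lower threshold exists for. |
| `min_mapq` | 0 | BAM filter; unmapped, secondary, supplementary and duplicate reads are always excluded. |

## Interpretive choices in the piecewise ratio

The published piecewise rule leaves two points open, and one ordering is
ambiguous:

* **Branch order.** Read literally, the "test below epsilon gives 0"
  branch shadows the "both below epsilon give 1" branch. We evaluate the
  joint branch first, since the second branch is dead code otherwise;
  `strict_literal = TRUE` restores the literal order.
* **Control below epsilon, test not.** The rule does not define this
  case. We return `t / max(1, epsilon)` — the denominator floored at one
  read. Flooring at `epsilon` itself (1e-3) would put such bases three
  orders of magnitude above a single-copy gain; because the t-score step
  divides by the global standard deviation of segment means, one such
  base is enough to compress the entire dynamic range of the signal and
  plant a spurious spike. One read is the natural lower bound on what a
  covered control base could have shown.
* **Redistribution.** "Normally distributed within the segment" is
  implemented as the deterministic mean shift
  $nR_j = tR_s + (r_j - m_s)$, which preserves within-segment deviations
  (hence the segment's standard deviation) exactly; a stochastic
  resampling alternative was rejected for reproducibility.

## Numerical choices

* **Circular boundaries.** Smoothing is executed in the frequency domain
  (layer $k$ is the inverse DFT of $C(w)\,e^{-w^2\sigma_k^2/2}$), which
  makes the convolution circular. The two ends of the concatenated axis
  are biologically arbitrary, so wrap-around calls are split at the
  signal ends when reported. The second difference and the crossing rule
  use circular neighbours for consistency.
* **Arbitrary-length FFTs.** Signal length is data-driven
  (`bin_size` × segment count). R's mixed-radix FFT degrades to
  near-quadratic cost when the length has a large prime factor, so
  lengths whose largest prime factor exceeds 127 go through a Bluestein
  chirp-z reformulation over power-of-two FFTs. Both routes are exact
  (tested against each other and against direct spatial convolution).
* **Real-transform packing.** Layers come in pairs: the signal is real
  and the Gaussian transfer function symmetric, so the spectra of two
  layers are packed as real and imaginary parts of one inverse transform.
* **Curvature floor.** Curvature magnitudes at or below $10^{-12}$ of the
  layer's largest absolute value are treated as exact zeros. Without
  this, floating-point jitter left by the FFT in genuinely flat stretches
  mints spurious inflections; $10^{-12}$ sits orders of magnitude above
  round-off and below any curvature a detectable feature produces.
* **Doubled crossing marks.** The strict crossing rule marks both samples
  flanking a sign change that falls between samples. This is faithful to
  the rule's inequalities; interval search is unaffected because the
  inner marks of two adjacent events still bound the interval.
* **Tracing.** The published description traces crossings to the base
  layer without defining the rule. We follow, per layer downward, the
  nearest crossing of the same sign within $\pm\lceil 3\sigma \rceil$ of
  the next-finer layer, carrying the position down unchanged when none
  exists; ties break toward the smaller position. Calls whose traced
  extent collapses are dropped, and traced extents are trimmed against
  already-declared regions so declared calls stay pairwise disjoint.
* **Degenerate inputs.** Equal segment means give all-zero t-scores; a
  featureless (constant) track yields zero calls; an all-zero test track
  caps `auto_pmin` at 0.5 with a warning.

## What the simulator emulates — and what it does not

`simulate_exome()` works at coverage level: no reads, no alignment.
It draws a panel of ~21,881 targets with lengths from a truncated
log-normal (`meanlog` 5.255, `sdlog` 0.5, truncated to [115, 8551] bp,
giving a truncated mean of 240 bp — the summary statistics of the
reference capture panel), plants 20–30 CNV events per sample on
non-overlapping runs of 1–5 consecutive targets with heterozygous
single-copy multipliers (loss 0.5, gain 1.5), and draws per-base depth as
negative binomial with mean $40 \times b_i \times m$: $b_i$ is a
per-target log-normal capture bias (log-sd 0.3, hence per-target depth
CV ≈ 0.3) shared between test and its CNV-free matched control, and $m$
is the event multiplier (test only). The negative-binomial size (10) adds
moderate per-base overdispersion.

What this does not emulate: read-level artifacts (alignment errors,
mappability, GC-tracking bias curves), autocorrelation of coverage on the
read-length scale, and any spatial correlation of capture bias between
neighbouring targets (our $b_i$ are independent). Passing tests therefore
demonstrate the machinery under a clean but realistically dispersed noise
model, not performance on real exomes. The independence and amplitude of
the per-target bias matter most in noRatio mode, where bias is not
cancelled: under CV-0.3 independent bias a +50% single-exon gain sits
near the 80th percentile of per-target means and is often undetectable
without a control, which is why the test-only mode's false negative rate
in this emulation is markedly worse than with a matched control.

## Evaluation conventions

Scoring is at the level of target regions: every capture target covered
by a planted event is one truth region, validated when calls of the same
kind cover more than 30% of its length. FNR is the percentage of truth
target regions not validated; FPR is the percentage of non-truth targets
that calls cover by more than the same 30% rule (so a traced boundary
grazing a neighbour does not count it as detected). Size classes
(small 100–159, medium 160–299, large 300–8260 bp) classify each target
region by its own length. `validate_regions(unit = "event")` switches to
whole-event counting, and `fpr_mode = "precision"` reports the share of
called targets lying outside truth instead.

## Problem sizes used in the packaged studies

The packaged acceptance study runs 11 replicates of a 3,000-target panel
(events scaled proportionally, ~3–4 per replicate, so the truth fraction
of the panel matches the reference design of ~25 events in 21,881
targets); the test suite uses 2,500-target replicates and smaller panels
for the unit fixtures. The rank baselines interact with the fraction of
the panel occupied by truth, so scaled emulations keep that fraction
fixed rather than the absolute event count; a dense panel (e.g. planting
hundreds of events in a few thousand targets) would push several percent
of all bases past the 1.25% rank thresholds and measure a different
regime. Coarse-layer false calls cover a larger *fraction* of a small
panel than of the full-size one, which biases the scaled FPR estimates
slightly upward; we accept this rather than trimming scales.

## Known limitations

* Absolute copy-number genotyping (integer copy states, homozygous vs
  heterozygous) is out of scope; calls are typed only as gain or loss.
* The rank baselines assume CNVs are rare on the concatenated axis; on
  panels where variants occupy more than ~1% of the target space the
  upper/lower thresholds land inside the variant population and
  sensitivity drops (visible in the dense-panel regime discussed above).
* Events wider than the largest scale cannot be captured by a single
  layer and may be reported fragmented.
* noRatio mode inherits all per-target capture bias; with strong
  independent bias its sensitivity for gains is limited (see above).

## A worked call

```{r example}
cfg <- sim_config(n_targets = 600, n_events = 5, seed = 11)
sim <- simulate_exome(cfg)
fit <- excnvss(sim$test, sim$control)
fit
head(as.data.frame(fit))
validate_regions(fit$calls, sim$truth, sim$targets)
```
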
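# excnvss

Copy-number variant (CNV) detection from whole-exome sequencing read
depth, for analysts who have per-base coverage over a capture panel (from
a BAM or a depth track) and want gain/loss calls of *any* size — from a
single exon to spans of many exons — with or without a matched control
sample.

## The method

Exome capture leaves depth only over sparse, short target intervals, with
strong per-target bias. `excnvss` concatenates the per-base depth of all
targets into one axis and runs two stages:

**Normalization.** With a matched control the signal is the per-base
ratio `r_j = t_j / c_j`, guarded near zero by a small `ε` (both depths
below `ε` → 1; test below → 0) and scaled by the library-size factor
`ω = m_C / m_T` (total control over total test mass), which cancels
capture bias shared by the pair. Without a control (*noRatio* mode) the
raw test depth is used. Each target is cut into fixed 30-base segments
(remnants trimmed symmetrically); segment means `m_s` become t-scores

```
tR_s = (m_s − mean(m)) / ( sd(m) / √N ),   N = total segments,
```

are shifted so `min(tR) = 0`, and are redistributed to base level
preserving within-segment deviations.

**Scale-space detection.** The normalized signal `c[i]` is smoothed with
a geometric family of Gaussians, `σ_k = 100 · 1.1^(k−1)` over 50 layers,
computed in the frequency domain as `c[·,k] = F⁻¹{ C(w) e^(−w²σ_k²/2) }`.
Zero crossings of the second-order difference of each layer form the
fingerprint map. At each layer, an interval bounded by two opposite-sign
crossings with none between is declared a CNV when the mean smoothed
signal over it exceeds the layer's upper rank baseline (smallest of the
top `⌈(1−p_max)·n⌉` values; gain) or falls below the lower baseline
(largest of the bottom `⌈p_min·n⌉` values; loss). Declared intervals are
traced down the map to base resolution; search proceeds from the coarsest
layer down with declared regions excluded, so each region gets its
coarsest sufficient explanation. Defaults `p_max = 0.9875`,
`p_min = 0.0125` (ratio) or `0.04` (noRatio).

The package also ships a coverage-level exome simulator with CNV
spike-ins and matched CNV-free controls, and a target-level FNR/FPR
evaluator with threshold sweeps, so the whole calling-and-scoring study
is reproducible offline.

## A worked example

```r
library(excnvss)

cfg <- sim_config(n_targets = 600, n_events = 5, seed = 11)
sim <- simulate_exome(cfg)                    # panel + truth + test/control
fit <- excnvss(sim$test, sim$control)         # ratio mode, default thresholds
fit
#> Scale-space CNV calls (ratio mode)
#>   signal: 136410 normalized bases over 600 targets; 50 layers (sigma 100..10671.9)
#>   thresholds: p_max 0.9875, p_min 0.0125
#>   calls: 5 (2 gain, 3 loss) covering 25 target(s)

head(as.data.frame(fit))
#>   chrom  start    end kind    score origin_layer target_ids
#> 1  chrS 182895 182973 loss 255.8500            2         80
#> 2  chrS 183066 183306 loss 255.8500            2         81
#> 3  chrS 183871 183887 loss 255.8500            2         82
#> ...

validate_regions(fit$calls, sim$truth, sim$targets)
#> Target-level evaluation (30% overlap rule)
#>   truth regions: 17  validated: 13
#>   FNR: 23.53%   FPR: 1.37% (target mode)
#>   FNR by size class: small 20  medium 37.5  large 0
```

Each call row is one contiguous genomic span (BED coordinates) with its
type, the mean smoothed signal of the originating interval (`score`), the
layer it was declared at, and the capture targets it covers. The
evaluation counts *target regions*: every target covered by a planted
event, validated when same-kind calls cover more than 30% of it; FNR is
the share of truth targets missed and FPR the share of non-truth targets
falsely covered. `write_calls()` / `read_calls()` round-trip the call set
as BED6+; `plot(fit)` draws the fingerprint map with calls overlaid.

For real data, build the tracks instead of simulating:

```r
targets <- read_targets("capture.bed")
test <- extract_coverage("test.bam", targets)        # or read_depth_track()
ctrl <- extract_coverage("control.bam", targets)
fit <- excnvss(test, ctrl)                            # or excnvss(test) for noRatio
```

A thin command-line wrapper with `call` / `simulate` / `evaluate`
subcommands is installed at `inst/cli/excnvss.R`.

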
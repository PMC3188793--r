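---
title: "Integrative meta-analysis of ChIP-chip and ChIP-seq data: methods and design"
author: "chipmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative meta-analysis of ChIP-chip and ChIP-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it computes and why: the two
statistical procedures, the assumptions they make, the tunable parameters,
the synthetic designs the benchmarks run on, and the numerical choices that
are easy to get silently wrong.

## The tiling-array branch

### Model

Tiling-array pipelines summarize probe intensities into a sliding-window
statistic per probe (a standardized t-like score for one-color arrays, a
GC-corrected analogue for two-color arrays; when an input sample exists, the
ChIP-minus-input score difference). `chipmeta` deliberately consumes these
*already standardized* score tracks rather than raw intensities: probe
sequence effects, copy-number correction and dye bias are platform-specific
problems with established platform-specific solutions, and re-fitting them
here would add nothing. The package's job starts where those pipelines end:
scores from different platforms live on different genomic grids and
different scales.

Three steps align them:

1. **Interpolation.** Scores are linearly interpolated onto a grid anchored
   at coordinate 0 in multiples of `target_step`, so grids from any two
   tracks coincide without designating a reference track. Interpolation is
   only allowed between adjacent probes at most `max_interp_dist` apart (a
   per-platform cap, e.g. 10 bp for a 7 bp design and 100 bp for sparse
   designs); beyond that gap the grid stays missing, and no value is ever
   extrapolated past the first or last probe. Grid points that coincide
   with a probe copy the probe score bit-exactly.

2. **Z-normalization.** Window-score distributions are approximately normal
   with a heavy *right* tail — the tail is the signal. A plain mean/SD
   would therefore be inflated by exactly the regions we want to detect.
   The null is estimated from the left half only: `mu0` is the sample
   median and `sigma0` is 1.4826 times the median absolute deviation of the
   values at or below the median (the factor makes the estimator consistent
   for a normal SD). Adding a constant to a track shifts `mu0` and leaves
   the Z-grid unchanged.

3. **Stouffer combination.** At each grid point covered by a set M of
   datasets (|M| at least `min_datasets`),

   S = Σ_{i∈M} wᵢ Zᵢ / sqrt(Σ_{i∈M} wᵢ²),

   which is standard normal under the null for *any* covering subset — the
   property that makes partial platform coverage unproblematic. With unit
   weights and full coverage this is the classic sum over √k. Weights
   default to 1 (sources weighed equally); the weighted form is provided
   for designs with known quality differences (e.g. weights proportional
   to replicate numbers). Whether to combine over the union of platform
   coverage or the intersection is genuinely open; the union with
   `min_datasets = 1` is the default, and `min_datasets = k` recovers the
   intersection.

Peaks are maximal runs of grid points with S above the one-sided normal
quantile Z₀ of `pvalue_cutoff`; runs separated by at most `merge_gap` bp
are merged and runs shorter than `min_peak_len` bp are dropped. Defaults
tie to the grid: `merge_gap = 2 * target_step` (about one missing probe)
and `min_peak_len = 4 * target_step`. The summit is the leftmost maximal
grid point (a deterministic tie-break), the peak P-value the one-sided
normal tail at the maximum.

### Empirical FDR by sign flipping

Under the null the composite is symmetric around zero, so peaks called on
−S with identical rules estimate the number of false positives among the
peaks called on S: eFDR = min(1, N/P). Two conventions matter: the
estimate is capped at 1 (a ratio above 1 carries no extra information), and
P = 0 yields `NA` rather than 0 — an empty peak list has an *undefined*
FDR, and reporting 0 would claim the opposite of what is known.

## The sequencing branch

### Fragment-size model and tag shifting

A sequenced tag is the end of a ChIP-DNA fragment, so around a true binding
site Watson-strand 5′ ends accumulate about d/2 upstream and Crick-strand
5′ ends d/2 downstream, where d is the library's characteristic fragment
size. d varies between laboratories (roughly 100-400 bp), which is exactly
why libraries cannot simply be concatenated.

Per library, after duplicate removal (default: one tag per position and
strand, removing PCR artifacts):

1. Windows of `2 * bandwidth` (default 600 bp) are scanned; windows whose
   tag count is between `mfold[1]` and `mfold[2]` times (default 10-30x)
   the genome-background expectation become model candidates, greedily
   non-overlapping, capped at the `max_model_peaks` most enriched. The
   upper m-fold bound excludes towers and amplified repeats; fewer than
   `min_model_peaks` usable candidates aborts with advice to set
   `default_d` explicitly.
2. In each candidate, the Watson and Crick modes are located on lightly
   smoothed per-bp pileups (21 bp moving sum; leftmost maximum on ties);
   candidates without a Watson-before-Crick pair are dropped.
3. **d is the median of the per-candidate mode-to-mode distances.** The
   obvious alternative — average the aligned strand profiles over all
   candidates and take the distance between the two global modes — is
   unstable in precisely the situation this package exists for: when the
   input mixes sub-libraries with different fragment sizes, the averaged
   Watson profile is multimodal with near-equal peaks, and the global
   argmax degenerates to a coin flip between them. The per-candidate
   median aggregates hundreds of independent (if individually noisy)
   distance estimates instead, and its consensus value is stable and
   well-defined for both homogeneous and mixed inputs. The averaged
   profiles (aligned on per-candidate mode midpoints) are still computed
   and stored in the `shift_model` for visual inspection.

Tags then shift 3′ by floor(d/2) — Watson right, Crick left, floored at
coordinate 0. The floor costs under 1 bp of bias for odd d and keeps
coordinates integral.

### Pooling and peak detection

Shifted ChIP libraries are pooled; controls are pooled independently,
shifted with their paired ChIP library's d (a uniform control is
insensitive to the shift, so pairing conventions are immaterial in
practice). The scan window defaults to the *largest* per-source d, so one
window accommodates every source's pileup; windows slide at half-window
steps, which bounds the worst-case miss of a summit at a quarter window
while keeping the scan deterministic.

Scoring is two-stage. Windows loosely enriched against the genome
background rate (Poisson P below `seed_cutoff`, default 1e-3 — the exact
value only needs to be permissive; it is exposed as a parameter) become
candidates; overlapping candidate windows merge into regions; each region
is rescored with its count scaled to one scan window against the dynamic
rate

λ_local = max(λ_bg, λ_1k, λ_5k, λ_10k),

with the local rates measured on the control in centered windows of 1, 5
and 10 kb and converted to expected counts per scan window. Control counts
are scaled linearly by the depth ratio (ChIP total over control total)
before comparison — a generalization of subsampling both libraries to
equal depth that wastes no tags. Without a control, the 1 kb window is
dropped (it would sit inside the peak itself) and the remaining local rates
come from the ChIP library. λ_local can never drop below λ_bg, which also
serves as the floor that prevents zero-rate singularities. P-values are
computed in log space (`ppois(..., log.p = TRUE)`), so scores of
−10·log10 P survive far beyond double underflow.

The summit is the leftmost maximum of the region's per-bp pileup of
shifted 5′ ends smoothed with a *triangular* kernel (half-width one eighth
of the scan window). The kernel choice is deliberate: a flat moving
average turns an isolated spike into a plateau whose leftmost point is
systematically offset, while a strictly peaked kernel preserves the
location of symmetric pileups exactly.

### Empirical FDR by sample swap

Peaks are called twice with identical parameters (including the already
resolved scan window): ChIP versus control (P peaks) and control versus
ChIP (N peaks); eFDR = min(1, N/P), with the same `NA`-for-0/0 convention
as the array branch. Swapping identical libraries yields eFDR = 1 by
construction, which the test suite asserts.

### The merge-then-model baseline

`merged_baseline()` implements the common alternative: concatenate raw
tags, fit one model, shift everything by the single d/2. With one library
or identical fragment sizes it coincides with the per-library pipeline (a
tested identity). With heterogeneous libraries the single d mis-shifts
every source — the benchmark below quantifies by how much.

## Synthetic designs

The generators produce data with the statistical structure the methods
assume, under known truth — they are first-class, tested code, not ad hoc
fixtures.

* **Spike-in tracks** (`make_spikein_tracks`): 100 truth regions of mean
  length 497 bp (SD one fifth, floored at 100 bp) placed without overlap
  in a 2 Mb genome; per platform, probes at 7/35/100 bp resolution with
  interpolation caps 10/50/100 bp, 10% probe dropout, Student-t(5) null
  noise — heavy-tailed on purpose, so the robust null estimator is
  exercised against the tail behavior real window scores show — scaled by
  1/1.3/1.6 across platforms so sources genuinely differ in
  signal-to-noise, and a per-region enrichment shift drawn uniformly from
  [2, 6] score units.
* **Tag libraries** (`make_seq_library`): sites spaced regularly with
  uniform jitter (non-overlapping by construction); per site,
  Poisson-distributed tag counts split between strands, Watson 5′ ends at
  s − d/2 + N(0, d/4) and Crick at s + d/2 + N(0, d/4). The d/4 spread
  keeps the two strand modes separable down to d = 50 bp, which the
  shift-ablation benchmark depends on: with a much wider spread the two
  modes fuse and the shift step would have nothing to correct. Background
  is uniform on both strands; the control is background-only at matched
  depth.
* **Split-and-shift pairs** (`make_delta_d_pair`): a base library is halved
  at random; the second half's tags move 5′ by Δd (Watson left, Crick
  right), inflating that half's effective fragment size by 2Δd while
  keeping both halves' binding sites, depths and noise identical. This
  construction — rather than simulating a second library de novo —
  isolates the fragment-size difference as the only varying factor.

What the generators do *not* emulate: probe-sequence and copy-number
effects (assumed removed upstream), mappability structure, correlated
noise between platforms sharing probe designs (residual probe effects can
correlate Z-scores across datasets and inflate the composite; with input
controls this largely cancels), read sequences, and paired-end structure.
Passing benchmarks therefore demonstrate that the algorithms do what they
claim under their own assumptions — not that those assumptions hold on any
particular real dataset.

## Evaluation machinery

Truth-based evaluation uses a fixed-width window universe (250 bp tiles of
the simulated genome): a window is positive if it overlaps a truth region
by at least 1 bp. For ranked outputs (composite score, per-platform
Z-scores) the ROC is the standard sweep over window scores. Voting and
intersection produce only a region set per threshold, so their curves are
traced by sweeping a ladder of p-value cutoffs (10^-0.5 to 10^-10 in
half-decade steps) through identical single-platform peak calls, anchoring
at (0,0) and (1,1), and integrating. For the head-to-head comparison the
composite is swept through the *same* peak-calling rules and ladder — a
continuous ranking and a thresholded staircase are otherwise not
commensurable. The window-level false-positive denominator is a choice
(region-level and probe-level alternatives exist and are not equivalent);
it is stated here once and used consistently.

Summit accuracy is the fraction of the top-N peaks (ranked by ascending
P-value, ties broken by score) whose summit lies within 50 bp of a truth
site.

Benchmark problem sizes, chosen to make each check sharp at desk scale:
null calibration on 3 x 1e5 grid points; spike-in ROC on 3 platforms x
2 Mb; fragment-size recovery with 2000 sites x 40 tags at d = 100, 200,
300 (estimates within ±10%); Δd robustness with a 500-site, 80-tags-per-
site base library split at Δd = 0/100/200 (per-library top-200 summit
accuracy varies by under 5 points; the merged baseline loses over 5 points
— in practice all of its accuracy — at Δd = 200); shift ablation at
d = 100 (disabling the shift costs over 10 points; about half the summits
land a mode-width away).

## Motif evaluation

Where truth is unknown, rankings are compared by motif enrichment: the
fraction of top-N peaks whose summit-centered window (±50 bp for
sequencing, ±250 bp for arrays) contains a position-weight-matrix hit.
Windows are scored as log2 PWM likelihood minus log2 background likelihood
under a third-order Markov model; both strands are scanned and windows
containing ambiguous bases are skipped rather than imputed. The background
is trained on user-supplied sequence — peak flanks by default, since a
matched local background is the conservative choice and the training
corpus is otherwise unspecified in common practice. The hit threshold
defaults to the score whose null exceedance probability is 1e-4, estimated
by sampling windows from the background model itself; the sampled-null
route works for any PWM/background pair without distributional
assumptions.

## Known limitations

* No cross-modality integration: array and sequencing branches are
  separate by design, and combining a Z-score grid with a Poisson count
  scan would need a model this package does not claim to have.
* The sequencing branch assumes point-source binding; broad histone-mark
  domains violate the bimodal model that fragment-size estimation relies
  on.
* Libraries from different sequencing platforms may differ in more than
  fragment size; only fragment size is modeled.
* The sign-flip eFDR assumes null symmetry of the composite; strongly
  skewed residual artifacts (e.g. shared probe effects without input
  correction) bias it optimistically.
* eFDR estimates are slightly conservative relative to the positive FDR;
  they are reported as-is, uncorrected.
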
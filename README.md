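# chipmeta

Model-based meta-analysis of ChIP-chip and ChIP-seq experiments in R.

## The problem

ChIP experiments that map protein-DNA binding genome-wide are routinely
repeated on different tiling-array platforms (Affymetrix, NimbleGen,
Agilent) and sequenced in different laboratories. Platform-specific probe
behavior, tiling resolution, dye bias, and laboratory-specific ChIP-DNA
fragment sizes make the resulting datasets hard to compare, and the common
practice of intersecting independently called peak lists is both
conservative and ad hoc. `chipmeta` is for analysts who have several such
datasets for the same factor and want one principled, jointly called set of
enriched regions — with an empirical estimate of its false discovery rate —
instead of a Venn diagram.

## The method

**Tiling arrays** (`chipchip_meta()`). Each platform's standardized window
scores (MAT/MA2C-style statistics, or a ChIP-minus-input score difference)
are linearly interpolated onto a common grid anchored at coordinate zero,
with interpolation allowed only across probe gaps below a per-platform cap.
Because window scores are approximately normal with a heavy right tail of
genuine enrichment, each dataset's null is estimated robustly from the left
side of its score distribution (median, and 1.4826 times the median
absolute deviation of the values at or below the median), and scores are
standardized to Z-scores. Grids are combined by Stouffer's method,

  S = Σᵢ wᵢ Zᵢ / √(Σᵢ wᵢ²),

which is standard normal under the null for any subset of covering
datasets, so a one-sided P-value follows directly. Peaks are maximal runs
of grid points with S above the quantile Z₀ of the chosen cutoff (merged
across small gaps, short runs dropped), and the empirical FDR of the peak
list is the count of peaks called on the sign-flipped composite divided by
the count of positive peaks.

**Sequencing libraries** (`chipseq_meta()`). Tag 5′ ends around a binding
site are bimodal — Watson-strand tags pile up upstream, Crick-strand tags
downstream, one fragment length *d* apart. For *each* library the package
scans for moderately enriched candidate regions, locates the Watson and
Crick modes in each, and takes *d* as the median mode-to-mode distance;
tags are then shifted 3′ by *d*/2 so they pile up on the binding point.
Shifted libraries are pooled (ChIP and control independently) and scanned
with sliding windows scored by a Poisson test against a dynamic rate
λ_local = max(λ_bg, λ_1k, λ_5k, λ_10k) estimated from the depth-scaled
control, which absorbs local chromatin and copy-number biases. The
empirical FDR comes from swapping ChIP and control and re-running with
identical parameters. A merge-then-model comparator (`merged_baseline()`),
majority voting, region intersection, ROC/summit-accuracy/motif-fraction
evaluators, and synthetic-data generators for all benchmark designs are
included.

## Worked example

```r
library(chipmeta)

## three simulated spike-in tracks at 7/35/100 bp tiling resolution
des <- spikein_design(seed = 7)
si  <- make_spikein_tracks(des)
fit <- chipchip_meta(si$tracks, chipchip_config(target_step = 7,
                                                pvalue_cutoff = 1e-4))
fit
#> Integrative tiling-array analysis of 3 dataset(s): platform1_res7, platform2_res35, platform3_res100
#>   grid step 7 bp, P-value cutoff 0.0001 (Z0 = 3.719)
#>   197 peaks; empirical FDR 0.1066 (21 negative / 197 positive)
roc_curve(fit$peaks, si$truth, tile_windows(des$genome_len, 250))$auc
#> [1] 0.9323
```

197 regions exceed Z₀ = 3.72 on the composite; sign flipping finds 21
regions below −Z₀, so about 11% of the list is expected to be noise, and
the called peaks rank the known spiked-in regions with a window-level ROC
AUC of 0.93.

```r
## two sequencing libraries whose fragment sizes differ by 400 bp
libdes <- seq_library_design(n_sites = 500, tags_per_site = 80, d = 100,
                             genome_len = 1e7, bg_rate = 5e-4, seed = 7)
lib  <- make_seq_library(libdes)
pair <- make_delta_d_pair(lib$chip, delta = 200, seed = 7)  # 5' shift
ctl  <- make_delta_d_pair(lib$control, 0, seed = 8)
sfit <- chipseq_meta(list(pair$common, pair$variant),
                     list(ctl$common, ctl$variant),
                     chipseq_config(genome_size = 1e7))
sfit
#> Integrative sequencing analysis (per-library model, 2 libraries)
#>   fragment size d: 98, 483 bp; scan window 483 bp
#>   500 peaks at P < 1e-05; empirical FDR 0 (0 control / 500 ChIP peaks)
summit_accuracy(sfit$peaks, lib$truth_sites, 50)[200]
#> [1] 1
```

The per-library models recover both fragment sizes (true values 100 and
500 bp), so after shifting, every one of the top 200 peak summits lands
within 50 bp of a true site; pooling the raw tags and fitting one model
instead (`merged_baseline()`) mis-shifts both libraries and its summit
accuracy collapses.

A command-line wrapper for the same functionality is installed at
`system.file("cli", "chipmeta.R", package = "chipmeta")`, with subcommands
`chip`, `seq`, `simulate`, `combine-naive`, `eval` and `motif`.

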
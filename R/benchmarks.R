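# Evaluation harnesses reproducing the package's benchmark designs end to
# end. They are ordinary exported functions so the same computation backs the
# unit tests, the acceptance script and the worked examples.

#' Tile a chromosome into fixed-width evaluation windows
#'
#' @param genome_len chromosome length in bp.
#' @param window window width in bp.
#' @param chrom chromosome name.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
tile_windows <- function(genome_len, window = 250, chrom = "chr1") {
  starts <- seq(0, genome_len - 1, by = window)
  data.frame(chrom = chrom, start = starts,
             end = pmin(starts + window, genome_len),
             stringsAsFactors = FALSE)
}

# max grid value per tiled window (single chromosome named in `windows`)
window_max_grid <- function(values, grid_start, step, windows) {
  scores <- rep(-Inf, nrow(windows))
  if (!length(values)) return(scores)
  pos <- grid_start + (seq_along(values) - 1) * step
  w <- windows$end[1] - windows$start[1]
  wi <- floor(pos / w) + 1
  ok <- !is.na(values) & wi >= 1 & wi <= nrow(windows)
  if (!any(ok)) return(scores)
  mx <- tapply(values[ok], wi[ok], max)
  scores[as.integer(names(mx))] <- as.numeric(mx)
  scores
}

#' Spike-in benchmark: composite ranking vs single platforms and naive rules
#'
#' Runs the full array branch on spike-in tracks and compares, on a
#' fixed-width window universe, the ROC AUC of (a) the composite score,
#' (b) each single platform's Z-score, and (c) majority voting and region
#' intersection of the per-platform peak calls swept over a ladder of
#' matched p-value cutoffs.
#'
#' @param tracks list of [score_track()]s (e.g. from
#'   [make_spikein_tracks()]).
#' @param truth truth-region data.frame.
#' @param config a [chipchip_config()].
#' @param genome_len evaluation extent in bp.
#' @param window evaluation window width in bp.
#' @param cutoffs p-value ladder for the voting/intersection sweeps.
#' @return list with `auc_composite` (continuous window ranking by composite
#'   score), `auc_single` (same ranking per platform, named vector),
#'   `auc_composite_swept` (composite peak calls swept over the cutoff
#'   ladder, so it is directly comparable with the voting/intersection
#'   staircases), `auc_vote`, `auc_intersect`, the fitted `chipchip_fit` and
#'   the sweep operating points.
#' @export
spikein_benchmark <- function(tracks, truth, config = chipchip_config(7),
                              genome_len, window = 250,
                              cutoffs = 10^seq(-0.5, -10, by = -0.5)) {
  fit <- chipchip_meta(tracks, config)
  windows <- tile_windows(genome_len, window)
  labels <- overlaps_any(windows, truth)
  score_of <- function(grid_or_comp, field) {
    ch <- grid_or_comp$chroms[["chr1"]]
    window_max_grid(ch[[field]], ch$grid_start, grid_or_comp$step, windows)
  }
  auc_composite <- roc_from_scores(score_of(fit$composite, "composite"),
                                   labels)$auc
  auc_single <- vapply(fit$z_grids, function(g)
    roc_from_scores(score_of(g, "values"), labels)$auc, 0)
  names(auc_single) <- vapply(tracks, `[[`, "", "dataset_id")
  # one composite_track per single platform so identical peak-calling rules
  # apply at every cutoff of the sweep
  single_comps <- lapply(fit$z_grids, function(g)
    combine_stouffer(list(g), config))
  op_point <- function(reg) {
    hit <- if (nrow(reg)) overlaps_any(windows, reg)
           else rep(FALSE, nrow(windows))
    c(tpr = sum(hit & labels) / sum(labels),
      fpr = sum(hit & !labels) / sum(!labels))
  }
  sweep <- lapply(cutoffs, function(cut) {
    cfg <- config; cfg$pvalue_cutoff <- cut
    calls <- lapply(single_comps, call_peaks_composite, config = cfg)
    list(vote = op_point(majority_vote(calls)),
         intersect = op_point(intersect_regions(calls)),
         composite = op_point(call_peaks_composite(fit$composite, cfg)))
  })
  pts <- function(field) t(vapply(sweep, `[[`, c(tpr = 0, fpr = 0), field))
  vote_pts <- pts("vote"); int_pts <- pts("intersect")
  comp_pts <- pts("composite")
  list(auc_composite = auc_composite, auc_single = auc_single,
       auc_composite_swept = roc_points_auc(comp_pts[, "fpr"],
                                            comp_pts[, "tpr"]),
       auc_vote = roc_points_auc(vote_pts[, "fpr"], vote_pts[, "tpr"]),
       auc_intersect = roc_points_auc(int_pts[, "fpr"], int_pts[, "tpr"]),
       fit = fit, n_windows = nrow(windows),
       vote_points = vote_pts, intersect_points = int_pts,
       composite_points = comp_pts)
}

#' Two-library benchmark with varied inter-library fragment-size differences
#'
#' Reproduces the split-and-shift construction: one synthetic base library is
#' halved, the second half is 5'-shifted by each `delta`, and the pair is
#' analyzed both with per-library fragment-size models ([chipseq_meta()]) and
#' with the merge-then-model baseline ([merged_baseline()]). Performance is
#' the top-N summit accuracy against the known sites.
#'
#' @param design a [seq_library_design()] for the base library.
#' @param deltas 5' shift distances in bp.
#' @param config a [chipseq_config()]; `genome_size` is overridden by the
#'   design's genome length.
#' @param top_n ranked-prefix size for the accuracy readout.
#' @param tol summit tolerance in bp.
#' @param seed RNG seed for the random splits.
#' @return data.frame with one row per (delta, method): the top-N accuracy,
#'   the estimated fragment sizes and the peak count.
#' @export
deltad_benchmark <- function(design, deltas = c(0, 100, 200),
                             config = chipseq_config(), top_n = 200,
                             tol = 50, seed = 1L) {
  config$genome_size <- design$genome_len
  lib <- make_seq_library(design)
  ctl <- make_delta_d_pair(lib$control, 0, seed = seed + 1L)
  rows <- list()
  for (delta in deltas) {
    pair <- make_delta_d_pair(lib$chip, delta, seed = seed)
    chip_libs <- list(pair$common, pair$variant)
    ctl_libs <- list(ctl$common, ctl$variant)
    fits <- list(per_library = chipseq_meta(chip_libs, ctl_libs, config),
                 merged = merged_baseline(chip_libs, ctl_libs, config))
    for (method in names(fits)) {
      f <- fits[[method]]
      acc <- summit_accuracy(f$peaks, lib$truth_sites, tol)
      rows[[length(rows) + 1]] <- data.frame(
        delta = delta, method = method,
        accuracy = acc[min(top_n, length(acc))],
        n_peaks = nrow(f$peaks),
        d = paste(vapply(f$models, `[[`, 0, "d"), collapse = "/"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Ablation of the tag-shift step
#'
#' Runs the sequencing pipeline on one synthetic library twice -- with the
#' estimated `d/2` shift and with the shift disabled (same scan window) --
#' and reports the top-N summit accuracy of both.
#'
#' @inheritParams deltad_benchmark
#' @return list with `accuracy_shifted`, `accuracy_unshifted`, `d`,
#'   `n_peaks`.
#' @export
shift_ablation <- function(design, config = chipseq_config(), top_n = 200,
                           tol = 50) {
  config$genome_size <- design$genome_len
  lib <- make_seq_library(design)
  fit_on <- chipseq_meta(lib$chip, lib$control, config, shift = TRUE)
  config$scan_window <- fit_on$config$scan_window
  fit_off <- chipseq_meta(lib$chip, lib$control, config, shift = FALSE)
  acc <- function(f) {
    a <- summit_accuracy(f$peaks, lib$truth_sites, tol)
    if (length(a)) a[min(top_n, length(a))] else 0
  }
  list(accuracy_shifted = acc(fit_on), accuracy_unshifted = acc(fit_off),
       d = fit_on$models[[1]]$d,
       n_peaks = c(shifted = nrow(fit_on$peaks),
                   unshifted = nrow(fit_off$peaks)))
}
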
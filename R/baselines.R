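# peaks/regions data.frame -> per-chrom IRanges (0-based half-open -> 1-based)
regions_to_iranges <- function(df) {
  lapply(split(df, df$chrom), function(d)
    IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end)))
}

coverage_regions <- function(peak_lists, min_lists) {
  irl <- lapply(peak_lists, regions_to_iranges)
  chroms <- unique(unlist(lapply(irl, names)))
  out <- lapply(chroms, function(chrom) {
    per <- lapply(irl, function(x) x[[chrom]])
    per <- per[!vapply(per, is.null, TRUE)]
    if (length(per) < min_lists) return(NULL)
    width <- max(vapply(per, function(ir)
      if (length(ir)) max(IRanges::end(ir)) else 0L, 0L), 1L)
    cov <- Reduce(`+`, lapply(per, IRanges::coverage, width = width))
    hit <- IRanges::slice(cov, lower = min_lists, rangesOnly = TRUE)
    if (!length(hit)) return(NULL)
    data.frame(chrom = chrom, start = IRanges::start(hit) - 1L,
               end = IRanges::end(hit), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Majority-voting combination of peak lists
#'
#' Base pairs covered by peaks in strictly more than half of the lists,
#' merged into maximal regions. Voting operates on base-pair coverage, which
#' avoids arbitrary whole-peak overlap thresholds.
#'
#' @param peak_lists list (length >= 2) of peak data.frames.
#' @return data.frame of merged regions (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @export
majority_vote <- function(peak_lists) {
  if (length(peak_lists) < 2)
    stop("majority voting needs at least two peak lists")
  coverage_regions(peak_lists, floor(length(peak_lists) / 2) + 1L)
}

#' Region-intersection combination of peak lists
#'
#' Base pairs covered by peaks in every list, merged into maximal regions --
#' the common but conservative way of combining independent analyses.
#'
#' @inheritParams majority_vote
#' @return data.frame of merged regions.
#' @export
intersect_regions <- function(peak_lists) {
  if (length(peak_lists) < 2)
    stop("region intersection needs at least two peak lists")
  coverage_regions(peak_lists, length(peak_lists))
}

overlaps_any <- function(df, truth) {
  hit <- rep(FALSE, nrow(df))
  for (chrom in unique(df$chrom)) {
    tt <- truth[truth$chrom == chrom, ]
    sel <- df$chrom == chrom
    if (!nrow(tt)) next
    q <- IRanges::IRanges(df$start[sel] + 1L, df$end[sel])
    s <- IRanges::IRanges(tt$start + 1L, tt$end)
    hit[sel] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' ROC curve from scores and binary labels
#'
#' Standard empirical ROC: candidates are swept in decreasing score order
#' (ties handled as blocks), `tpr` is the fraction of positives recovered and
#' `fpr` the fraction of negatives admitted; the AUC is the trapezoidal area.
#' Invariant to strictly monotone transformations of the score.
#'
#' @param scores numeric ranking scores (`-Inf` allowed for "never called").
#' @param labels logical (or 0/1) truth labels, same length.
#' @return list with `fpr`, `tpr`, `auc`.
#' @export
roc_from_scores <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels); N <- sum(!labels)
  if (P == 0) stop("no positive candidates in the truth universe")
  if (N == 0) stop("no negative candidates in the universe")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp_last <- cumsum(rle(s)$lengths)
  tpr <- cumsum(l)[grp_last] / P
  fpr <- cumsum(!l)[grp_last] / N
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  list(fpr = fpr, tpr = tpr,
       auc = sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2))
}

#' Trapezoidal AUC through a set of operating points
#'
#' For methods that only produce a region set per threshold (voting,
#' intersection), the ROC is traced by sweeping thresholds; this anchors the
#' resulting points at (0,0) and (1,1), sorts by false positive rate and
#' integrates.
#'
#' @param fpr,tpr operating points in `[0, 1]`.
#' @return AUC in `[0, 1]`.
#' @export
roc_points_auc <- function(fpr, tpr) {
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' ROC of a ranked peak list against known truth regions
#'
#' The candidate universe is a set of evaluable intervals (e.g. tiled
#' windows); a universe interval counts as positive when it overlaps a truth
#' region by at least 1 bp. Each universe interval is scored by the best
#' (maximum-score) ranked peak overlapping it (`-Inf` when none does) and the
#' standard ROC is computed over the universe.
#'
#' @param ranked peak data.frame sorted or sortable by significance (its
#'   `score` column is used as the ranking score).
#' @param truth data.frame of truth regions (`chrom`, `start`, `end`).
#' @param universe data.frame of candidate intervals (`chrom`, `start`,
#'   `end`).
#' @return list with `fpr`, `tpr`, `auc`.
#' @export
roc_curve <- function(ranked, truth, universe) {
  if (!nrow(truth)) stop("truth set is empty")
  labels <- overlaps_any(universe, truth)
  scores <- rep(-Inf, nrow(universe))
  for (chrom in unique(universe$chrom)) {
    sel <- universe$chrom == chrom
    pk <- ranked[ranked$chrom == chrom, ]
    if (!nrow(pk)) next
    q <- IRanges::IRanges(universe$start[sel] + 1L, universe$end[sel])
    s <- IRanges::IRanges(pk$start + 1L, pk$end)
    ov <- IRanges::findOverlaps(q, s)
    if (!length(ov)) next
    best <- tapply(pk$score[S4Vectors::subjectHits(ov)],
                   S4Vectors::queryHits(ov), max)
    idx <- which(sel)[as.integer(names(best))]
    scores[idx] <- as.numeric(best)
  }
  roc_from_scores(scores, labels)
}

#' Summit accuracy over nested top-N prefixes
#'
#' Peaks are ranked by ascending p-value (ties by descending score); for each
#' prefix length N the value is the fraction of the top N peaks whose summit
#' lies within `tol` bp of some truth site.
#'
#' @param peaks peak data.frame.
#' @param truth_sites data.frame (`chrom`, `pos`) or, for a single
#'   chromosome, a numeric vector of site positions.
#' @param tol tolerance in bp (> 0).
#' @return numeric vector of length `nrow(peaks)`; element N is the top-N
#'   accuracy.
#' @export
summit_accuracy <- function(peaks, truth_sites, tol = 50) {
  stopifnot(tol > 0)
  if (!nrow(peaks)) return(numeric(0))
  if (!is.data.frame(truth_sites)) {
    stopifnot(length(unique(peaks$chrom)) <= 1)
    truth_sites <- data.frame(chrom = peaks$chrom[1], pos = truth_sites)
  }
  peaks <- peaks[order(peaks$pvalue, -peaks$score), , drop = FALSE]
  hit <- vapply(seq_len(nrow(peaks)), function(i) {
    s <- truth_sites$pos[truth_sites$chrom == peaks$chrom[i]]
    length(s) > 0 && min(abs(s - peaks$summit[i])) <= tol
  }, TRUE)
  cumsum(hit) / seq_along(hit)
}
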
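#' Configuration for the tiling-array meta-analysis branch
#'
#' @param target_step common grid step in bp all tracks are interpolated to.
#'   7 bp suits dense spike-in style designs; 35 bp suits standard promoter /
#'   whole-genome tiling.
#' @param pvalue_cutoff one-sided peak-calling cutoff on the composite score;
#'   converted internally to the standard-normal quantile `Z0 > 0`.
#' @param merge_gap peaks separated by at most this many bp of sub-threshold
#'   grid are merged. Default twice the grid step (about one probe gap).
#' @param min_peak_len minimum peak length in bp; shorter runs are dropped.
#'   Default four grid steps.
#' @param min_datasets a grid point enters the composite only if at least
#'   this many datasets cover it. `1` uses the union of platform coverage;
#'   setting it to the number of datasets gives the intersection.
#' @param weights optional positive per-dataset weights for the combination;
#'   `NULL` weighs all sources equally.
#' @return A list of class `chipchip_config`.
#' @export
chipchip_config <- function(target_step = 35, pvalue_cutoff = 1e-4,
                            merge_gap = 2 * target_step,
                            min_peak_len = 4 * target_step,
                            min_datasets = 1L, weights = NULL) {
  stopifnot(target_step > 0, pvalue_cutoff > 0, pvalue_cutoff < 1,
            merge_gap >= 0, min_peak_len >= 0, min_datasets >= 1)
  if (!is.null(weights) && any(weights <= 0)) stop("weights must be > 0")
  structure(list(target_step = target_step, pvalue_cutoff = pvalue_cutoff,
                 merge_gap = merge_gap, min_peak_len = min_peak_len,
                 min_datasets = as.integer(min_datasets), weights = weights),
            class = "chipchip_config")
}

#' Interpolate a score track onto a common grid
#'
#' The grid is anchored at coordinate 0 in multiples of `target_step`, so
#' grids from different platforms are directly comparable. A grid point
#' between two adjacent probes is filled by linear interpolation only when
#' the probe gap is at most the track's `max_interp_dist`; grid points that
#' coincide with a probe take the probe score exactly; everything else is
#' missing (`NA`). No extrapolation beyond the first/last probe ever occurs.
#'
#' @param track a [score_track()].
#' @param target_step grid step in bp (> 0).
#' @return An object of class `grid_track`: per chromosome `grid_start`
#'   (first grid coordinate) and `values` (with `NA` for missing), plus the
#'   shared `step`.
#' @export
interpolate_to_grid <- function(track, target_step) {
  if (target_step <= 0) stop("target_step must be > 0")
  chroms <- lapply(track$chroms, function(ch) {
    p <- ch$positions; s <- ch$scores
    if (length(p) == 0)
      return(list(grid_start = NA_real_, values = numeric(0)))
    i0 <- ceiling(p[1] / target_step)
    i1 <- floor(p[length(p)] / target_step)
    if (i1 < i0) return(list(grid_start = NA_real_, values = numeric(0)))
    g <- seq(i0, i1) * target_step
    j <- findInterval(g, p)              # p[j] <= g < p[j+1]
    v <- rep(NA_real_, length(g))
    exact <- g == p[j]
    v[exact] <- s[j[exact]]
    mid <- !exact & j >= 1 & j < length(p)
    if (any(mid)) {
      jm <- j[mid]
      ok <- (p[jm + 1] - p[jm]) <= track$max_interp_dist
      idx <- which(mid)[ok]
      jm <- jm[ok]
      v[idx] <- s[jm] + (g[idx] - p[jm]) / (p[jm + 1] - p[jm]) *
        (s[jm + 1] - s[jm])
    }
    list(grid_start = g[1], values = v)
  })
  structure(list(dataset_id = track$dataset_id, step = target_step,
                 chroms = chroms),
            class = "grid_track")
}

#' Estimate the null distribution of window scores
#'
#' Window-score distributions from tiling arrays are approximately normal
#' with a heavy right tail produced by genuine enrichment, so location and
#' scale are estimated from the left (non-enriched) side only: the null mean
#' is the sample median and the null standard deviation is the median
#' absolute deviation of the values at or below the median, scaled by 1.4826
#' for consistency with a normal distribution.
#'
#' @param x numeric vector of scores, a [score_track()] or a `grid_track`
#'   (all finite values are used).
#' @param min_n minimum number of finite values required (default 100).
#' @return list of class `null_model` with elements `mu0` and `sigma0`.
#' @export
estimate_null <- function(x, min_n = 100L) {
  if (inherits(x, "score_track"))
    x <- unlist(lapply(x$chroms, `[[`, "scores"), use.names = FALSE)
  if (inherits(x, "grid_track"))
    x <- unlist(lapply(x$chroms, `[[`, "values"), use.names = FALSE)
  x <- x[is.finite(x)]
  if (length(x) < min_n)
    stop("insufficient data to estimate the null (", length(x), " < ",
         min_n, " values)")
  mu0 <- stats::median(x)
  left <- x[x <= mu0]
  sigma0 <- 1.4826 * stats::median(mu0 - left)
  if (!is.finite(sigma0) || sigma0 <= 0)
    stop("degenerate score distribution: no spread below the median")
  structure(list(mu0 = mu0, sigma0 = sigma0), class = "null_model")
}

#' Convert a grid track to Z-scores
#'
#' @param grid a `grid_track` from [interpolate_to_grid()].
#' @param null a `null_model` from [estimate_null()].
#' @return A `grid_track` of Z values; missing points stay missing.
#' @export
to_zscores <- function(grid, null) {
  stopifnot(inherits(grid, "grid_track"), null$sigma0 > 0)
  grid$chroms <- lapply(grid$chroms, function(ch) {
    ch$values <- (ch$values - null$mu0) / null$sigma0
    ch
  })
  grid
}

#' Combine Z-score grids by Stouffer's method
#'
#' At each grid point covered by `m >= min_datasets` sources the composite is
#' `S = sum(w_i * Z_i) / sqrt(sum(w_i^2))` over the covering subset, which is
#' standard normal under the null for any subset size and reduces to
#' `sum(Z_i)/sqrt(k)` with unit weights and full coverage.
#'
#' @param z_grids list of `grid_track`s sharing the same step (anchored grids
#'   are automatically comparable).
#' @param config a [chipchip_config()]; its `weights` (named by dataset or in
#'   list order) and `min_datasets` are used.
#' @return An object of class `composite_track`: per chromosome `grid_start`,
#'   `composite` (S, `NA` where uncovered) and `k_used`.
#' @export
combine_stouffer <- function(z_grids, config = chipchip_config()) {
  stopifnot(length(z_grids) >= 1)
  steps <- vapply(z_grids, `[[`, 0, "step")
  if (length(unique(steps)) != 1)
    stop("all grids must share the same step (got ",
         paste(unique(steps), collapse = ", "), ")")
  step <- steps[1]
  k <- length(z_grids)
  w <- config$weights
  if (is.null(w)) w <- rep(1, k)
  if (length(w) != k) stop("need one weight per dataset")
  all_chroms <- unique(unlist(lapply(z_grids, function(g) names(g$chroms))))
  chroms <- lapply(all_chroms, function(chrom) {
    idx0 <- idx1 <- integer(0)
    for (g in z_grids) {
      ch <- g$chroms[[chrom]]
      if (!is.null(ch) && length(ch$values)) {
        i0 <- round(ch$grid_start / step)
        idx0 <- c(idx0, i0)
        idx1 <- c(idx1, i0 + length(ch$values) - 1L)
      }
    }
    if (!length(idx0))
      return(list(grid_start = NA_real_, composite = numeric(0),
                  k_used = integer(0)))
    lo <- min(idx0); hi <- max(idx1); n <- hi - lo + 1L
    num <- den <- numeric(n)
    kuse <- integer(n)
    for (i in seq_len(k)) {
      ch <- z_grids[[i]]$chroms[[chrom]]
      if (is.null(ch) || !length(ch$values)) next
      at <- round(ch$grid_start / step) - lo + seq_along(ch$values)
      ok <- !is.na(ch$values)
      num[at[ok]] <- num[at[ok]] + w[i] * ch$values[ok]
      den[at[ok]] <- den[at[ok]] + w[i]^2
      kuse[at[ok]] <- kuse[at[ok]] + 1L
    }
    S <- ifelse(kuse >= config$min_datasets & den > 0, num / sqrt(den),
                NA_real_)
    list(grid_start = lo * step, composite = S, k_used = kuse)
  })
  names(chroms) <- all_chroms
  structure(list(step = step, chroms = chroms, weights = w,
                 n_datasets = k),
            class = "composite_track")
}

# Maximal runs of `sel` grid points, runs closer than merge_gap bp merged,
# runs shorter than min_peak_len bp dropped. Returns a peak data.frame built
# from `values` (used for summit/score).
call_runs <- function(pos, values, sel, step, merge_gap, min_peak_len) {
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) return(empty_peaks())
  r <- rle(sel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ri <- which(r$values)
  run_s <- starts[ri]; run_e <- ends[ri]
  # merge runs separated by <= merge_gap bp of missing/sub-threshold grid
  if (length(ri) > 1) {
    gap_bp <- pos[run_s[-1]] - (pos[run_e[-length(run_e)]] + step)
    new_grp <- cumsum(c(TRUE, gap_bp > merge_gap))
    run_s <- as.integer(tapply(run_s, new_grp, min))
    run_e <- as.integer(tapply(run_e, new_grp, max))
  }
  out <- lapply(seq_along(run_s), function(i) {
    a <- run_s[i]; b <- run_e[i]
    if ((pos[b] + step) - pos[a] < min_peak_len) return(NULL)
    v <- values[a:b]
    v[is.na(v)] <- -Inf
    m <- a + which.max(v) - 1L          # leftmost maximum
    list(start = pos[a], end = pos[b] + step, summit = pos[m],
         score = values[m])
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty_peaks())
  data.frame(chrom = NA_character_,
             start = as.integer(vapply(out, `[[`, 0, "start")),
             end = as.integer(vapply(out, `[[`, 0, "end")),
             name = NA_character_,
             score = vapply(out, `[[`, 0, "score"),
             summit = as.integer(vapply(out, `[[`, 0, "summit")),
             pvalue = NA_real_, efdr = NA_real_, n_datasets = NA_integer_,
             stringsAsFactors = FALSE)
}

rank_and_name <- function(peaks) {
  if (!nrow(peaks)) return(peaks)
  rk <- order(peaks$pvalue, -peaks$score, peaks$chrom, peaks$start)
  peaks$name[rk] <- paste0("peak_", seq_len(nrow(peaks)))
  peaks
}

#' Call peaks on a composite track
#'
#' Maximal runs of grid points with composite score above the one-sided
#' standard-normal quantile `Z0` of `pvalue_cutoff` become peaks; runs closer
#' than `merge_gap` bp are merged and runs shorter than `min_peak_len` bp are
#' dropped. The summit is the leftmost grid point of maximal composite score;
#' the peak p-value is the one-sided normal tail at that maximum.
#'
#' @param comp a `composite_track` from [combine_stouffer()].
#' @param config a [chipchip_config()].
#' @param sign `+1` (default) finds enriched peaks above `Z0`; `-1` applies
#'   the identical rules to the sign-flipped track (used by the empirical
#'   FDR machinery).
#' @return Peak data.frame (0-based half-open), named in rank order of
#'   significance.
#' @export
call_peaks_composite <- function(comp, config = chipchip_config(), sign = 1) {
  z0 <- stats::qnorm(config$pvalue_cutoff, lower.tail = FALSE)
  stopifnot(z0 > 0, sign %in% c(1, -1))
  res <- lapply(names(comp$chroms), function(chrom) {
    ch <- comp$chroms[[chrom]]
    if (!length(ch$composite)) return(empty_peaks())
    pos <- ch$grid_start + (seq_along(ch$composite) - 1L) * comp$step
    v <- sign * ch$composite
    pk <- call_runs(pos, v, v > z0, comp$step, config$merge_gap,
                    config$min_peak_len)
    if (nrow(pk)) {
      pk$chrom <- chrom
      pk$pvalue <- stats::pnorm(pk$score, lower.tail = FALSE)
      kch <- ch$k_used
      pk$n_datasets <- kch[(pk$summit - ch$grid_start) / comp$step + 1L]
    }
    pk
  })
  peaks <- do.call(rbind, res)
  if (is.null(peaks)) peaks <- empty_peaks()
  rank_and_name(peaks)
}

#' Empirical FDR of composite peaks by sign flipping
#'
#' Since the composite score is standard normal and symmetric under the null,
#' peaks called on the sign-flipped track with identical rules estimate the
#' false-positive count: `eFDR = min(1, N_negative / N_positive)`. With no
#' positive peaks the estimate is undefined (`NA`), which is distinct from 0.
#'
#' @inheritParams call_peaks_composite
#' @return list with `efdr`, `n_positive`, `n_negative`.
#' @export
efdr_signflip <- function(comp, config = chipchip_config()) {
  p <- nrow(call_peaks_composite(comp, config, sign = 1))
  n <- nrow(call_peaks_composite(comp, config, sign = -1))
  list(efdr = if (p == 0) NA_real_ else min(1, n / p),
       n_positive = p, n_negative = n)
}

#' Integrative tiling-array analysis
#'
#' Runs the full array branch: per-track null estimation on the original
#' probe scores, interpolation to the common grid, Z-normalization, Stouffer
#' combination, composite peak calling and sign-flip empirical FDR. The
#' list-level eFDR is annotated on every peak.
#'
#' @param tracks list of [score_track()]s (one per platform/laboratory).
#' @param config a [chipchip_config()].
#' @return Object of class `chipchip_fit` with elements `peaks`, `efdr`,
#'   `composite`, `nulls`, `z_grids`, `config`.
#' @export
chipchip_meta <- function(tracks, config = chipchip_config()) {
  if (inherits(tracks, "score_track")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1,
            all(vapply(tracks, inherits, TRUE, "score_track")))
  nulls <- lapply(tracks, estimate_null)
  z_grids <- Map(function(tr, nu)
    to_zscores(interpolate_to_grid(tr, config$target_step), nu),
    tracks, nulls)
  comp <- combine_stouffer(z_grids, config)
  peaks <- call_peaks_composite(comp, config)
  fdr <- efdr_signflip(comp, config)
  if (nrow(peaks)) peaks$efdr <- fdr$efdr
  structure(list(peaks = peaks, efdr = fdr, composite = comp,
                 nulls = nulls, z_grids = z_grids, config = config,
                 dataset_ids = vapply(tracks, `[[`, "", "dataset_id")),
            class = "chipchip_fit")
}

#' @export
print.chipchip_fit <- function(x, ...) {
  cat(sprintf("Integrative tiling-array analysis of %d dataset(s): %s\n",
              length(x$dataset_ids), paste(x$dataset_ids, collapse = ", ")))
  cat(sprintf("  grid step %g bp, P-value cutoff %g (Z0 = %.3f)\n",
              x$config$target_step, x$config$pvalue_cutoff,
              stats::qnorm(x$config$pvalue_cutoff, lower.tail = FALSE)))
  cat(sprintf("  %d peaks; empirical FDR %s (%d negative / %d positive)\n",
              nrow(x$peaks),
              if (is.na(x$efdr$efdr)) "undefined" else
                sprintf("%.4g", x$efdr$efdr),
              x$efdr$n_negative, x$efdr$n_positive))
  invisible(x)
}

#' @export
summary.chipchip_fit <- function(object, ...) {
  print(object)
  for (i in seq_along(object$nulls))
    cat(sprintf("  null[%s]: mu0 = %.4g, sigma0 = %.4g\n",
                object$dataset_ids[i], object$nulls[[i]]$mu0,
                object$nulls[[i]]$sigma0))
  if (nrow(object$peaks)) {
    cat("  top peaks:\n")
    top <- object$peaks[order(object$peaks$pvalue), ][
      seq_len(min(5, nrow(object$peaks))), ]
    print(top, row.names = FALSE)
  }
  invisible(object)
}
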
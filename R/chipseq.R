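#' Configuration for the sequencing meta-analysis branch
#'
#' Defaults follow the conventional settings of model-based sliding-window
#' peak callers of the short-read era; all are exposed so they can be tuned
#' per experiment.
#'
#' @param genome_size effective (mappable) genome size in bp.
#' @param bandwidth half-window in bp used when scanning for model-building
#'   candidate regions (the scan uses windows of `2 * bandwidth`).
#' @param mfold numeric length-2: candidate regions must be enriched between
#'   `mfold[1]`- and `mfold[2]`-fold over the genome background; the upper
#'   bound excludes towers and amplified repeats.
#' @param max_model_peaks cap on the number of candidate regions used to
#'   build the fragment-size model (the most enriched are kept).
#' @param min_model_peaks minimum number of usable candidate regions; below
#'   this the model build aborts with an error suggesting `default_d`.
#' @param min_d smallest credible fragment size in bp; estimates below it are
#'   rejected and `default_d` is used with a warning.
#' @param default_d fallback fragment size in bp.
#' @param scan_window peak-scan window in bp; `NULL` (default) means "use the
#'   largest estimated fragment size of the pooled libraries".
#' @param pvalue_cutoff Poisson p-value below which a region is a peak.
#' @param seed_cutoff loose p-value (against the genome background rate) that
#'   admits a window into the candidate set before local-rate rescoring.
#' @param max_dup_per_pos tags retained per (chrom, position, strand);
#'   1 keeps unique genomic locations only.
#' @param lambda_windows widths in bp of the centered windows used for the
#'   local Poisson rate (the smallest is skipped when there is no control).
#' @return A list of class `chipseq_config`.
#' @export
chipseq_config <- function(genome_size = 2.7e9, bandwidth = 300,
                           mfold = c(10, 30), max_model_peaks = 1000L,
                           min_model_peaks = 100L, min_d = 50,
                           default_d = 200, scan_window = NULL,
                           pvalue_cutoff = 1e-5, seed_cutoff = 1e-3,
                           max_dup_per_pos = 1L,
                           lambda_windows = c(1000, 5000, 10000)) {
  stopifnot(genome_size > 0, bandwidth > 0, length(mfold) == 2,
            mfold[1] > 0, mfold[1] < mfold[2], min_d > 0, default_d > 0,
            pvalue_cutoff > 0, pvalue_cutoff < 1, max_dup_per_pos >= 1)
  structure(list(genome_size = genome_size, bandwidth = bandwidth,
                 mfold = mfold, max_model_peaks = as.integer(max_model_peaks),
                 min_model_peaks = as.integer(min_model_peaks),
                 min_d = min_d, default_d = default_d,
                 scan_window = scan_window, pvalue_cutoff = pvalue_cutoff,
                 seed_cutoff = seed_cutoff,
                 max_dup_per_pos = as.integer(max_dup_per_pos),
                 lambda_windows = sort(lambda_windows)),
            class = "chipseq_config")
}

#' Collapse duplicate tags
#'
#' Retains at most `max_dup_per_pos` tags per (chrom, 5' position, strand).
#' The default of 1 keeps tags with unique genomic locations only, removing
#' PCR amplification artifacts.
#'
#' @param tags a [tag_set()].
#' @param max_dup_per_pos maximum retained multiplicity (>= 1).
#' @return A [tag_set()].
#' @export
dedup_tags <- function(tags, max_dup_per_pos = 1L) {
  stopifnot(max_dup_per_pos >= 1)
  t <- tags$tags
  if (!nrow(t)) return(tags)
  key <- paste(t$chrom, t$pos5, t$strand)
  keep <- if (max_dup_per_pos == 1L) !duplicated(key)
          else stats::ave(seq_len(nrow(t)), key, FUN = seq_along) <=
            max_dup_per_pos
  tag_set(t[keep, , drop = FALSE], dataset_id = tags$dataset_id)
}

#' Shift tags 3' by half the fragment size
#'
#' Watson-strand 5' ends move right and Crick-strand 5' ends move left by
#' `floor(d/2)` bp (floored at coordinate 0), so that shifted tags pile up on
#' the protein-DNA contact point.
#'
#' @param tags a [tag_set()].
#' @param d fragment size in bp (>= 0).
#' @return A [tag_set()].
#' @export
shift_tags <- function(tags, d) {
  stopifnot(d >= 0)
  s <- floor(d / 2)
  t <- tags$tags
  t$pos5 <- ifelse(t$strand == "+", t$pos5 + s, pmax(0, t$pos5 - s))
  tag_set(t, dataset_id = tags$dataset_id)
}

# zero-padded running sum over window [i - h, i + h]
run_sum <- function(x, h) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs[pmin(n, seq_len(n) + h) + 1] - cs[pmax(0, seq_len(n) - h - 1) + 1]
}

# zero-padded triangular-kernel smoothing (peak-preserving, no plateaus
# introduced around an isolated spike)
tri_smooth <- function(x, h) {
  if (h < 1) return(x)
  kern <- (h + 1) - abs(seq(-h, h))
  n <- length(x)
  xp <- c(numeric(h), x, numeric(h))
  as.numeric(stats::filter(xp, kern, sides = 2))[(h + 1):(h + n)]
}

# count of sorted integer positions falling in [starts, starts + width)
count_in <- function(sorted_pos, starts, width) {
  findInterval(starts + width - 1, sorted_pos) -
    findInterval(starts - 1, sorted_pos)
}

#' Estimate the characteristic fragment size of a library
#'
#' Tag 5' ends around a binding site are bimodal: Watson tags pile up
#' upstream and Crick tags downstream, one fragment length apart. The model
#' build (i) scans `2*bandwidth` windows and keeps non-overlapping windows
#' whose tag count is between `mfold[1]` and `mfold[2]` times the genome
#' background expectation, capped at `max_model_peaks` most enriched;
#' (ii) locates the Watson and Crick tag modes inside each candidate
#' (lightly smoothed per-bp pileups, leftmost maximum, candidates lacking a
#' proper Watson-before-Crick pair are dropped); (iii) takes the fragment
#' size `d` as the median Watson-to-Crick mode distance over candidates, a
#' consensus that stays stable when the pooled input mixes heterogeneous
#' sub-libraries. Strand-specific profiles averaged after aligning
#' candidates on their mode midpoints are returned for inspection.
#'
#' @param chip a deduplicated [tag_set()].
#' @param config a [chipseq_config()].
#' @return Object of class `shift_model`: `d`, `n_model_peaks`,
#'   `watson_profile`, `crick_profile`, `offsets`, `d_spread` (IQR of the
#'   per-candidate distances).
#' @export
estimate_fragment_size <- function(chip, config = chipseq_config()) {
  t <- chip$tags
  if (!any(t$strand == "+") || !any(t$strand == "-"))
    stop("model building requires tags on both strands")
  bw <- config$bandwidth
  W <- 2 * bw
  lambda2 <- chip$n_tags * W / config$genome_size
  lo <- config$mfold[1] * lambda2
  hi <- config$mfold[2] * lambda2
  cand <- list()
  for (chrom in unique(t$chrom)) {
    pos <- t$pos5[t$chrom == chrom]         # sorted by tag_set invariant
    if (length(pos) < 2) next
    starts <- seq(max(0, pos[1] - W), pos[length(pos)], by = bw)
    counts <- count_in(pos, starts, W)
    ok <- which(counts >= lo & counts <= hi)
    if (!length(ok)) next
    # greedy non-overlapping selection by descending count; windows at step
    # bandwidth and width 2*bandwidth overlap iff their indices differ by <= 1
    blocked <- rep(FALSE, length(starts))
    sel <- integer(0)
    for (i in ok[order(-counts[ok])]) {
      if (blocked[i]) next
      sel <- c(sel, i)
      blocked[max(1, i - 1):min(length(starts), i + 1)] <- TRUE
    }
    cand[[chrom]] <- data.frame(chrom = chrom, start = starts[sel],
                                count = counts[sel])
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand))
    stop("no model-building candidates found; set config$default_d and ",
         "config$scan_window explicitly")
  cand <- cand[order(-cand$count), , drop = FALSE]
  cand <- cand[seq_len(min(nrow(cand), config$max_model_peaks)), ,
               drop = FALSE]
  wprof <- cprof <- numeric(W + 1)
  d_all <- numeric(0)
  used <- 0L
  for (chrom in unique(cand$chrom)) {
    tc <- t[t$chrom == chrom, ]
    wpos <- tc$pos5[tc$strand == "+"]
    cpos <- tc$pos5[tc$strand == "-"]
    for (s in cand$start[cand$chrom == chrom]) {
      win_w <- wpos[wpos >= s & wpos < s + W]
      win_c <- cpos[cpos >= s & cpos < s + W]
      if (!length(win_w) || !length(win_c)) next
      pw <- run_sum(tabulate(win_w - s + 1, W), 10)
      pc <- run_sum(tabulate(win_c - s + 1, W), 10)
      wmode <- s + which.max(pw) - 1
      cmode <- s + which.max(pc) - 1
      if (cmode <= wmode) next
      d_all <- c(d_all, cmode - wmode)
      mid <- round((wmode + cmode) / 2)
      ow <- win_w - mid; oc <- win_c - mid
      ow <- ow[abs(ow) <= bw]; oc <- oc[abs(oc) <= bw]
      wprof <- wprof + tabulate(ow + bw + 1, W + 1)
      cprof <- cprof + tabulate(oc + bw + 1, W + 1)
      used <- used + 1L
    }
  }
  if (used < config$min_model_peaks)
    stop("only ", used, " usable model-building candidates (need ",
         config$min_model_peaks, "); supply a fragment size via ",
         "config$default_d and config$scan_window")
  d <- round(stats::median(d_all))
  if (d < config$min_d) {
    warning("estimated fragment size ", d, " bp is below min_d = ",
            config$min_d, "; falling back to default_d = ", config$default_d)
    d <- config$default_d
  }
  structure(list(d = d, n_model_peaks = used,
                 watson_profile = wprof / used, crick_profile = cprof / used,
                 offsets = seq(-bw, bw),
                 d_spread = unname(stats::IQR(d_all))),
            class = "shift_model")
}

#' @export
print.shift_model <- function(x, ...) {
  cat(sprintf("shift_model: fragment size d = %d bp (from %d candidate regions, IQR %.0f bp); tags will be shifted 3' by %d bp\n",
              x$d, x$n_model_peaks, x$d_spread, floor(x$d / 2)))
  invisible(x)
}

#' Pool shifted tag libraries
#'
#' Concatenates libraries (each already shifted with its own fragment size)
#' and re-sorts; the result is invariant to pooling order and conserves tag
#' counts.
#'
#' @param shifted list of [tag_set()]s with distinct `dataset_id`s.
#' @param per_source_d optional numeric of the per-library fragment sizes,
#'   recorded for downstream window sizing.
#' @return Object of class `pooled_library` with elements `tags` (a
#'   [tag_set()]), `source_ids`, `per_source_d`.
#' @export
pool_libraries <- function(shifted, per_source_d = NULL) {
  if (inherits(shifted, "tag_set")) shifted <- list(shifted)
  ids <- vapply(shifted, `[[`, "", "dataset_id")
  if (anyDuplicated(ids)) stop("duplicate dataset_id in pooled libraries")
  tags <- tag_set(do.call(rbind, lapply(shifted, `[[`, "tags")),
                  dataset_id = paste(ids, collapse = "+"))
  if (!is.null(per_source_d)) names(per_source_d) <- ids
  structure(list(tags = tags, source_ids = ids,
                 per_source_d = per_source_d),
            class = "pooled_library")
}

as_pooled <- function(x) {
  if (inherits(x, "pooled_library")) return(x)
  if (inherits(x, "tag_set"))
    return(structure(list(tags = x, source_ids = x$dataset_id,
                          per_source_d = NULL), class = "pooled_library"))
  stop("expected a tag_set or pooled_library")
}

#' Poisson upper-tail probability
#'
#' `P(X >= count)` for `X ~ Poisson(lam)`, evaluated in log space so that
#' extreme enrichment does not underflow before the caller can log it.
#'
#' @param count non-negative integer (vectorized).
#' @param lam Poisson rate >= 0 (vectorized).
#' @param log.p return the natural log of the tail probability.
#' @return numeric; `P(X >= 0)` is 1.
#' @export
poisson_sf <- function(count, lam, log.p = FALSE) {
  if (any(count < 0)) stop("count must be non-negative")
  if (any(lam < 0)) stop("lam must be non-negative")
  stats::ppois(count - 1, lam, lower.tail = FALSE, log.p = log.p)
}

#' Local Poisson rates around candidate regions
#'
#' For each region center the expected tag count per scan window is estimated
#' from centered windows of the configured widths (1 kb/5 kb/10 kb by
#' default) and from the genome-wide background; the dynamic rate
#' `lambda_local` is the maximum of the available estimates, which absorbs
#' local chromatin, copy-number and sequencing biases. Local windows are
#' measured on the control when present (scaled to the ChIP sequencing
#' depth); without a control the smallest window is skipped and the remaining
#' local windows are measured on the ChIP library itself.
#'
#' @param centers region center positions (bp) on `chrom`.
#' @param chrom chromosome name.
#' @param chip ChIP [tag_set()] or `pooled_library`.
#' @param control control [tag_set()]/`pooled_library`, or `NULL`.
#' @param config a [chipseq_config()]; `scan_window` must be set.
#' @return data.frame with one row per center: `lambda_bg`, one `lambda_<w>`
#'   column per window width (NA when unavailable) and `lambda_local`.
#' @export
local_lambda <- function(centers, chrom, chip, control = NULL,
                         config = chipseq_config()) {
  chip <- as_pooled(chip)
  sw <- config$scan_window
  if (is.null(sw)) stop("config$scan_window must be set")
  n_chip <- chip$tags$n_tags
  lambda_bg <- n_chip * sw / config$genome_size
  out <- data.frame(lambda_bg = rep(lambda_bg, length(centers)))
  has_ctrl <- !is.null(control)
  if (has_ctrl) {
    control <- as_pooled(control)
    src <- control$tags$tags
    ratio <- n_chip / control$tags$n_tags
  } else {
    src <- chip$tags$tags
    ratio <- 1
  }
  pos <- src$pos5[src$chrom == chrom]
  widths <- config$lambda_windows
  if (!has_ctrl) widths <- widths[-1]     # drop the smallest window
  lam_mat <- matrix(NA_real_, length(centers), length(config$lambda_windows),
                    dimnames = list(NULL, paste0("lambda_",
                                                 config$lambda_windows)))
  for (w in widths) {
    cnt <- count_in(pos, pmax(0, centers - w / 2), w)
    lam_mat[, paste0("lambda_", w)] <- cnt * ratio * sw / w
  }
  out <- cbind(out, lam_mat)
  out$lambda_local <- pmax(lambda_bg,
                           apply(lam_mat, 1, max, na.rm = TRUE))
  out
}

#' Call peaks on pooled, shifted tag libraries
#'
#' Windows of `scan_window` bp slide at half-window steps; windows loosely
#' enriched over the genome background (`seed_cutoff`) become candidates,
#' overlapping candidates merge into regions, and each region is rescored
#' with a Poisson test of its tag count (scaled to one scan window) against
#' the dynamic local rate at its center. Control counts are scaled to the
#' ChIP sequencing depth. The summit is the leftmost maximum of the
#' triangular-smoothed per-bp pileup of shifted tag 5' ends in the region;
#' the peak score is `-10*log10(pvalue)`.
#'
#' @param chip pooled ChIP library ([pool_libraries()] output or a
#'   [tag_set()]).
#' @param control pooled control library or `NULL`.
#' @param config a [chipseq_config()]; if `scan_window` is `NULL` the largest
#'   per-source fragment size recorded in `chip` is used (failing that,
#'   `default_d`).
#' @return Peak data.frame (0-based half-open), named in rank order.
#' @export
call_peaks_seq <- function(chip, control = NULL, config = chipseq_config()) {
  chip <- as_pooled(chip)
  if (!is.null(control)) control <- as_pooled(control)
  sw <- config$scan_window
  if (is.null(sw))
    sw <- if (length(chip$per_source_d)) max(chip$per_source_d)
          else config$default_d
  sw <- max(10, round(sw))
  config$scan_window <- sw
  step <- max(1, floor(sw / 2))
  n_chip <- chip$tags$n_tags
  if (n_chip == 0) return(empty_peaks())
  if (!is.null(control) && control$tags$n_tags < n_chip)
    message("control library is shallower than ChIP (",
            control$tags$n_tags, " < ", n_chip,
            "); control counts are scaled up accordingly")
  lambda_bg <- n_chip * sw / config$genome_size
  log_seed <- log(config$seed_cutoff)
  log_cut <- log(config$pvalue_cutoff)
  smooth_h <- max(2, floor(sw / 8))
  t <- chip$tags$tags
  res <- list()
  for (chrom in unique(t$chrom)) {
    pos <- t$pos5[t$chrom == chrom]
    starts <- seq(max(0, pos[1] - sw), pos[length(pos)], by = step)
    counts <- count_in(pos, starts, sw)
    cand <- which(poisson_sf(counts, lambda_bg, log.p = TRUE) < log_seed)
    if (!length(cand)) next
    cs <- starts[cand]
    grp <- cumsum(c(TRUE, cs[-1] > cs[-length(cs)] + sw))
    rs <- as.numeric(tapply(cs, grp, min))
    re <- as.numeric(tapply(cs, grp, max)) + sw
    centers <- floor((rs + re) / 2)
    rcount <- count_in(pos, rs, re - rs)
    lam <- local_lambda(centers, chrom, chip, control, config)
    scaled <- round(rcount * sw / (re - rs))
    logp <- poisson_sf(scaled, lam$lambda_local, log.p = TRUE)
    keep <- which(logp <= log_cut)
    if (!length(keep)) next
    pk <- lapply(keep, function(i) {
      i0 <- findInterval(rs[i] - 1, pos) + 1
      i1 <- findInterval(re[i] - 1, pos)
      pile <- tabulate(pos[i0:i1] - rs[i] + 1, re[i] - rs[i])
      summit <- rs[i] + which.max(tri_smooth(pile, smooth_h)) - 1
      list(start = rs[i], end = re[i], summit = summit, logp = logp[i])
    })
    res[[chrom]] <- data.frame(
      chrom = chrom,
      start = as.integer(vapply(pk, `[[`, 0, "start")),
      end = as.integer(vapply(pk, `[[`, 0, "end")),
      name = NA_character_,
      score = -10 * vapply(pk, `[[`, 0, "logp") / log(10),
      summit = as.integer(vapply(pk, `[[`, 0, "summit")),
      pvalue = pmax(exp(vapply(pk, `[[`, 0, "logp")), .Machine$double.xmin),
      efdr = NA_real_, n_datasets = length(chip$source_ids),
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, res)
  if (is.null(peaks)) return(empty_peaks())
  rownames(peaks) <- NULL
  rank_and_name(peaks)
}

#' Empirical FDR by swapping ChIP and control
#'
#' Peaks are called twice with identical parameters (including the scan
#' window resolved from the ChIP pool): ChIP vs control gives `P` peaks,
#' control vs ChIP gives `N` peaks, and `eFDR = min(1, N/P)`. With `P = 0`
#' the estimate is undefined (`NA`), distinct from 0.
#'
#' @inheritParams call_peaks_seq
#' @param control pooled control library (required).
#' @return list with `efdr`, `n_chip_peaks`, `n_control_peaks`.
#' @export
efdr_swap <- function(chip, control, config = chipseq_config()) {
  stopifnot(!is.null(control))
  chip <- as_pooled(chip); control <- as_pooled(control)
  if (is.null(config$scan_window))
    config$scan_window <- if (length(chip$per_source_d))
      max(chip$per_source_d) else config$default_d
  p <- nrow(call_peaks_seq(chip, control, config))
  n <- nrow(call_peaks_seq(control, chip, config))
  list(efdr = if (p == 0) NA_real_ else min(1, n / p),
       n_chip_peaks = p, n_control_peaks = n)
}

#' Integrative sequencing analysis with per-library fragment-size models
#'
#' For each ChIP library: deduplicate, estimate the fragment size `d`, shift
#' tags 3' by `d/2`. Shifted ChIP libraries are pooled, controls (shifted
#' with their paired ChIP library's `d`) are pooled independently, peaks are
#' called with the dynamic-lambda Poisson scan, and the empirical FDR is
#' estimated by swapping ChIP and control.
#'
#' @param chip_libs a [tag_set()] or list of them, one per data source.
#' @param control_libs optional control [tag_set()]s; either one per ChIP
#'   library (paired by position) or any other number (pooled as-is, shifted
#'   by the mean `d`).
#' @param config a [chipseq_config()].
#' @param shift set `FALSE` to skip the tag shift while keeping the estimated
#'   fragment sizes for window sizing (ablation of the shift step).
#' @return Object of class `chipseq_fit` with `peaks`, `models`, `efdr`,
#'   `chip_pool`, `control_pool`, `config`.
#' @export
chipseq_meta <- function(chip_libs, control_libs = NULL,
                         config = chipseq_config(), shift = TRUE) {
  if (inherits(chip_libs, "tag_set")) chip_libs <- list(chip_libs)
  if (inherits(control_libs, "tag_set")) control_libs <- list(control_libs)
  chip_libs <- lapply(chip_libs, dedup_tags, config$max_dup_per_pos)
  models <- lapply(chip_libs, estimate_fragment_size, config)
  ds <- vapply(models, `[[`, 0, "d")
  shifted <- if (shift) Map(shift_tags, chip_libs, ds) else chip_libs
  chip_pool <- pool_libraries(shifted, per_source_d = ds)
  control_pool <- NULL
  if (!is.null(control_libs)) {
    control_libs <- lapply(control_libs, dedup_tags, config$max_dup_per_pos)
    cds <- if (length(control_libs) == length(chip_libs)) ds
           else rep(round(mean(ds)), length(control_libs))
    cshift <- if (shift) Map(shift_tags, control_libs, cds) else control_libs
    control_pool <- pool_libraries(cshift, per_source_d = cds)
  }
  if (is.null(config$scan_window)) config$scan_window <- max(ds)
  peaks <- call_peaks_seq(chip_pool, control_pool, config)
  fdr <- NULL
  if (!is.null(control_pool)) {
    fdr <- efdr_swap(chip_pool, control_pool, config)
    if (nrow(peaks)) peaks$efdr <- fdr$efdr
  }
  structure(list(peaks = peaks, models = models, efdr = fdr,
                 chip_pool = chip_pool, control_pool = control_pool,
                 config = config, shift = shift, method = "per-library"),
            class = "chipseq_fit")
}

#' Merge-then-model baseline
#'
#' The common alternative to per-library modeling: raw (unshifted) tags from
#' all sources are pooled first, a single fragment-size model is built on the
#' merged pool, every tag is shifted by the one `d/2`, and peaks are called
#' as in [chipseq_meta()]. With a single library (or identical fragment
#' sizes) this coincides with the per-library pipeline; with heterogeneous
#' libraries the single model mis-shifts every source.
#'
#' @inheritParams chipseq_meta
#' @return Object of class `chipseq_fit` (with `method = "merged"`).
#' @export
merged_baseline <- function(chip_libs, control_libs = NULL,
                            config = chipseq_config()) {
  if (inherits(chip_libs, "tag_set")) chip_libs <- list(chip_libs)
  if (inherits(control_libs, "tag_set")) control_libs <- list(control_libs)
  chip_libs <- lapply(chip_libs, dedup_tags, config$max_dup_per_pos)
  merged <- pool_libraries(chip_libs)
  model <- estimate_fragment_size(merged$tags, config)
  d <- model$d
  chip_pool <- pool_libraries(shift_tags(merged$tags, d))
  chip_pool$per_source_d <- stats::setNames(rep(d, length(merged$source_ids)),
                                            merged$source_ids)
  chip_pool$source_ids <- merged$source_ids
  control_pool <- NULL
  if (!is.null(control_libs)) {
    control_libs <- lapply(control_libs, dedup_tags, config$max_dup_per_pos)
    cm <- pool_libraries(control_libs)
    control_pool <- pool_libraries(shift_tags(cm$tags, d))
  }
  if (is.null(config$scan_window)) config$scan_window <- d
  peaks <- call_peaks_seq(chip_pool, control_pool, config)
  fdr <- NULL
  if (!is.null(control_pool)) {
    fdr <- efdr_swap(chip_pool, control_pool, config)
    if (nrow(peaks)) peaks$efdr <- fdr$efdr
  }
  structure(list(peaks = peaks, models = list(model), efdr = fdr,
                 chip_pool = chip_pool, control_pool = control_pool,
                 config = config, shift = TRUE, method = "merged"),
            class = "chipseq_fit")
}

#' @export
print.chipseq_fit <- function(x, ...) {
  ds <- vapply(x$models, `[[`, 0, "d")
  cat(sprintf("Integrative sequencing analysis (%s model%s)\n",
              x$method, if (x$method == "merged") "" else
                paste0(", ", length(ds), " librar",
                       if (length(ds) == 1) "y" else "ies")))
  cat(sprintf("  fragment size d: %s bp%s; scan window %d bp\n",
              paste(ds, collapse = ", "),
              if (x$shift) "" else " (tag shift disabled)",
              x$config$scan_window))
  cat(sprintf("  %d peaks at P < %g", nrow(x$peaks),
              x$config$pvalue_cutoff))
  if (!is.null(x$efdr))
    cat(sprintf("; empirical FDR %s (%d control / %d ChIP peaks)",
                if (is.na(x$efdr$efdr)) "undefined" else
                  sprintf("%.4g", x$efdr$efdr),
                x$efdr$n_control_peaks, x$efdr$n_chip_peaks))
  cat("\n")
  invisible(x)
}

#' @export
summary.chipseq_fit <- function(object, ...) {
  print(object)
  for (m in object$models) print(m)
  if (nrow(object$peaks)) {
    cat("  top peaks:\n")
    top <- object$peaks[order(object$peaks$pvalue), ][
      seq_len(min(5, nrow(object$peaks))), ]
    print(top, row.names = FALSE)
  }
  invisible(object)
}
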
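#' Design of a multi-platform spike-in benchmark
#'
#' Emulates a spike-in experiment in which a known set of cloned genomic
#' fragments (the truth regions) is mixed into genomic background and
#' hybridized to tiling arrays of different resolutions and noise
#' characteristics. Null probe noise is Student-t (heavy right and left
#' tails) so that the robust null estimator is exercised against the heavy
#' tails real window scores show; probes inside a truth region are shifted up
#' by a per-region enrichment effect.
#'
#' @param n_regions number of truth regions (default 100).
#' @param mean_len mean truth-region length in bp (default 497); individual
#'   lengths are Normal(mean_len, mean_len/5) floored at 100 bp.
#' @param genome_len simulated genome length in bp (single chromosome).
#' @param platforms list of per-platform parameter lists with fields
#'   `resolution`, `max_interp_dist`, `noise_df` (Student-t degrees of
#'   freedom), `noise_scale` (multiplier on the null noise, so platforms
#'   differ in signal-to-noise ratio) and `probe_dropout` (fraction of probes
#'   removed at random). Defaults emulate a dense, a medium and a sparse
#'   tiling design (7/35/100 bp with interpolation caps 10/50/100 bp) of
#'   increasing noise.
#' @param fold_range range of the per-region score shift (uniform draw).
#' @param seed RNG seed; the generator is a pure function of seed and design.
#' @return list of class `spikein_design`.
#' @export
spikein_design <- function(n_regions = 100L, mean_len = 497, genome_len = 2e6,
                           platforms = list(
                             list(resolution = 7, max_interp_dist = 10,
                                  noise_df = 5, noise_scale = 1,
                                  probe_dropout = 0.1),
                             list(resolution = 35, max_interp_dist = 50,
                                  noise_df = 5, noise_scale = 1.3,
                                  probe_dropout = 0.1),
                             list(resolution = 100, max_interp_dist = 100,
                                  noise_df = 5, noise_scale = 1.6,
                                  probe_dropout = 0.1)),
                           fold_range = c(2, 6), seed = 1L) {
  stopifnot(n_regions >= 1, mean_len > 0, genome_len > n_regions * mean_len,
            length(platforms) >= 1)
  structure(list(n_regions = as.integer(n_regions), mean_len = mean_len,
                 genome_len = genome_len, platforms = platforms,
                 fold_range = fold_range, seed = seed),
            class = "spikein_design")
}

place_regions <- function(n, lens, genome_len, gap = 100) {
  for (try in 1:200) {
    starts <- sort(sample.int(genome_len - max(lens) - gap, n))
    ends <- starts + lens
    if (n == 1 || all(starts[-1] - ends[-n] > gap))
      return(data.frame(start = starts, end = ends))
  }
  stop("could not place ", n, " non-overlapping regions; increase genome_len")
}

#' Generate spike-in tracks and their truth set
#'
#' @param design a [spikein_design()].
#' @return list with `tracks` (list of [score_track()]s, one per platform)
#'   and `truth` (data.frame `chrom`, `start`, `end`, `fold`; 0-based
#'   half-open).
#' @export
make_spikein_tracks <- function(design) {
  stopifnot(inherits(design, "spikein_design"))
  with_seed(design$seed, {
    n <- design$n_regions
    lens <- pmax(100, round(stats::rnorm(n, design$mean_len,
                                         design$mean_len / 5)))
    reg <- place_regions(n, lens, design$genome_len)
    folds <- stats::runif(n, design$fold_range[1], design$fold_range[2])
    tracks <- lapply(seq_along(design$platforms), function(pi) {
      p <- design$platforms[[pi]]
      pos <- seq(p$resolution, design$genome_len - 1, by = p$resolution)
      if (p$probe_dropout > 0)
        pos <- pos[stats::runif(length(pos)) >= p$probe_dropout]
      ns <- if (is.null(p$noise_scale)) 1 else p$noise_scale
      sc <- ns * stats::rt(length(pos), df = p$noise_df)
      ri <- findInterval(pos, reg$start)
      inside <- ri >= 1 & pos < reg$end[pmax(ri, 1)]
      sc[inside] <- sc[inside] + folds[ri[inside]]
      score_track(list(chr1 = list(positions = pos, scores = sc)),
                  dataset_id = sprintf("platform%d_res%g", pi, p$resolution),
                  platform = sprintf("res%g", p$resolution),
                  resolution = p$resolution,
                  max_interp_dist = p$max_interp_dist)
    })
    list(tracks = tracks,
         truth = data.frame(chrom = "chr1", start = reg$start,
                            end = reg$end, fold = folds,
                            stringsAsFactors = FALSE))
  })
}

#' Design of a synthetic ChIP-seq library
#'
#' Tag libraries with the bimodal strand structure around binding sites:
#' Watson 5' ends pile up `d/2` upstream and Crick 5' ends `d/2` downstream
#' of each site, each with positional spread Normal(0, d/4) -- narrow enough
#' to keep the two modes separable for fragment sizes of 50 bp and up.
#' Background tags are uniform on both strands; the control library is
#' background-only at the depth of the ChIP library.
#'
#' @param n_sites number of binding sites (0 allowed for background-only).
#' @param tags_per_site mean ChIP tag count per site (Poisson, split evenly
#'   between strands).
#' @param d true fragment size in bp.
#' @param genome_len simulated genome length in bp (single chromosome).
#' @param bg_rate background tag rate per bp per strand.
#' @param seed RNG seed.
#' @return list of class `seq_library_design`.
#' @export
seq_library_design <- function(n_sites = 2000L, tags_per_site = 40,
                               d = 100, genome_len = 2e7, bg_rate = 5e-4,
                               seed = 1L) {
  stopifnot(n_sites >= 0, tags_per_site >= 0, d > 0, genome_len > 0,
            bg_rate >= 0)
  if (d / 4 < 1) stop("degenerate positional spread: d/4 must be >= 1 bp")
  structure(list(n_sites = as.integer(n_sites),
                 tags_per_site = tags_per_site, d = d,
                 genome_len = genome_len, bg_rate = bg_rate, seed = seed),
            class = "seq_library_design")
}

#' Generate a synthetic ChIP-seq library with known binding sites
#'
#' @param design a [seq_library_design()].
#' @return list with `chip` and `control` ([tag_set()]s) and `truth_sites`
#'   (numeric site positions on `chr1`).
#' @export
make_seq_library <- function(design) {
  stopifnot(inherits(design, "seq_library_design"))
  with_seed(design$seed, {
    G <- design$genome_len; d <- design$d
    n <- design$n_sites
    sites <- numeric(0)
    tags <- list()
    if (n > 0) {
      # one site per genome cell, jittered: non-overlapping by construction
      cell <- G / n
      sites <- round((seq_len(n) - 1) * cell + cell * (0.2 + 0.6 *
                                                         stats::runif(n)))
      nw <- stats::rpois(n, design$tags_per_site / 2)
      nc <- stats::rpois(n, design$tags_per_site / 2)
      wpos <- round(rep(sites, nw) - d / 2 +
                      stats::rnorm(sum(nw), 0, d / 4))
      cpos <- round(rep(sites, nc) + d / 2 +
                      stats::rnorm(sum(nc), 0, d / 4))
      pos_site <- pmax(0, c(wpos, cpos))
      tags$site <- data.frame(
        chrom = rep("chr1", length(pos_site)), pos5 = pos_site,
        strand = rep(c("+", "-"), c(length(wpos), length(cpos))))
    }
    nbg <- stats::rpois(2, design$bg_rate * G)
    if (sum(nbg) > 0)
      tags$bg <- data.frame(
        chrom = rep("chr1", sum(nbg)),
        pos5 = c(sample.int(G, nbg[1], replace = TRUE),
                 sample.int(G, nbg[2], replace = TRUE)) - 1L,
        strand = rep(c("+", "-"), nbg))
    if (!length(tags)) stop("design produces an empty library")
    chip <- tag_set(do.call(rbind, tags), dataset_id = "chip")
    nctl <- chip$n_tags
    half <- nctl %/% 2
    control <- tag_set(data.frame(
      chrom = "chr1",
      pos5 = sample.int(G, nctl, replace = TRUE) - 1L,
      strand = rep(c("+", "-"), c(half, nctl - half))),
      dataset_id = "control")
    list(chip = chip, control = control, truth_sites = sites)
  })
}

#' Split a library into a common half and a 5'-shifted variant half
#'
#' The library is divided into two equal groups by random tag selection; one
#' group is kept as-is (the common library) and the other group's tags are
#' moved toward the 5' direction by `delta` bp (Watson left, Crick right,
#' floored at 0), which inflates the variant library's effective fragment
#' size by `2 * delta`. Tag counts are conserved: the two halves partition
#' the input.
#'
#' @param base a [tag_set()].
#' @param delta 5' shift in bp (>= 0); `delta = 0` gives a plain random
#'   half-split.
#' @param seed RNG seed for the split.
#' @return list with `common` and `variant` [tag_set()]s.
#' @export
make_delta_d_pair <- function(base, delta, seed = 1L) {
  stopifnot(delta >= 0)
  t <- base$tags
  with_seed(seed, {
    idx <- sample.int(nrow(t), nrow(t) %/% 2)
    common <- t[idx, , drop = FALSE]
    variant <- t[-idx, , drop = FALSE]
    variant$pos5 <- ifelse(variant$strand == "+",
                           pmax(0, variant$pos5 - delta),
                           variant$pos5 + delta)
    list(common = tag_set(common,
                          dataset_id = paste0(base$dataset_id, "_common")),
         variant = tag_set(variant,
                           dataset_id = paste0(base$dataset_id, "_variant")))
  })
}
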
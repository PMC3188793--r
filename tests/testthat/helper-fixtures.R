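# Small in-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_track <- function(positions, scores, chrom = "chr1", resolution = 35,
                      max_interp_dist = 50, id = "toy") {
  score_track(stats::setNames(list(list(positions = positions,
                                        scores = scores)), chrom),
              dataset_id = id, resolution = resolution,
              max_interp_dist = max_interp_dist)
}

toy_tags <- function(pos5, strand, chrom = "chr1", id = "toy") {
  tag_set(data.frame(chrom = rep_len(chrom, length(pos5)), pos5 = pos5,
                     strand = strand),
          dataset_id = id)
}

# a full-coverage Gaussian-null track on a regular grid
null_track <- function(n, step = 7, seed = 1, id = paste0("null", seed),
                       mu = 0, sd = 1) {
  set.seed(seed)
  toy_track(seq_len(n) * step, stats::rnorm(n, mu, sd), resolution = step,
            max_interp_dist = step, id = id)
}

toy_peaks <- function(starts, ends, chrom = "chr1",
                      scores = seq_along(starts), summits = NULL,
                      pvalues = NULL) {
  n <- length(starts)
  if (is.null(summits)) summits <- floor((starts + ends) / 2)
  if (is.null(pvalues)) pvalues <- (seq_len(n)) / (n + 1)
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(ends), name = paste0("peak_", seq_len(n)),
             score = scores, summit = as.integer(summits), pvalue = pvalues,
             efdr = NA_real_, n_datasets = 1L, stringsAsFactors = FALSE)
}

# deterministic one-site ChIP library: all Watson tags at s - d/2, all Crick
# tags at s + d/2, plus sparse background
one_site_library <- function(s = 5000, d = 100, n_per_strand = 30,
                             genome = 2e4) {
  toy_tags(c(rep(s - d / 2, n_per_strand), rep(s + d / 2, n_per_strand)),
           rep(c("+", "-"), each = n_per_strand))
}
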
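test_that("grid interpolation matches hand-computed values and the gap rule", {
  # two probes 35 bp apart, within the interpolation cap
  tr <- toy_track(c(100, 135), c(2, 4), resolution = 35, max_interp_dist = 50)
  g <- interpolate_to_grid(tr, 35)
  expect_equal(g$chroms$chr1$grid_start, 105)
  expect_equal(g$chroms$chr1$values, 2 + (105 - 100) / 35 * 2)  # 2.2857...
  # probes 200 bp apart exceed the cap: everything between stays missing
  tr2 <- toy_track(c(100, 300), c(2, 4), resolution = 35, max_interp_dist = 50)
  g2 <- interpolate_to_grid(tr2, 35)
  expect_true(all(is.na(g2$chroms$chr1$values)))
  # a single probe on the grid keeps its exact score, nothing else fills
  tr3 <- toy_track(70, 1.234, resolution = 7, max_interp_dist = 7)
  g3 <- interpolate_to_grid(tr3, 7)
  expect_identical(g3$chroms$chr1$values, 1.234)
})

test_that("interpolation never extrapolates and is exact on probes", {
  set.seed(5)
  for (rep in 1:10) {
    pos <- sort(sample(1:5000, 80))
    sc <- rnorm(80)
    tr <- toy_track(pos, sc, resolution = 10, max_interp_dist = 60)
    g <- interpolate_to_grid(tr, 10)
    ch <- g$chroms$chr1
    gp <- ch$grid_start + (seq_along(ch$values) - 1) * 10
    on_probe <- gp %in% pos
    expect_identical(ch$values[on_probe], sc[match(gp[on_probe], pos)])
    filled <- which(!is.na(ch$values) & !on_probe)
    for (i in filled) {
      j <- findInterval(gp[i], pos)
      expect_lte(pos[j + 1] - pos[j], 60)
      expect_gte(ch$values[i], min(sc[j], sc[j + 1]) - 1e-12)
      expect_lte(ch$values[i], max(sc[j], sc[j + 1]) + 1e-12)
    }
  }
})

test_that("robust null estimation recovers Gaussian parameters and resists a heavy right tail", {
  set.seed(11)
  nm <- estimate_null(rnorm(1e5, 2, 3))
  expect_gt(nm$mu0, 1.9); expect_lt(nm$mu0, 2.1)
  expect_gt(nm$sigma0, 2.85); expect_lt(nm$sigma0, 3.15)
  contaminated <- c(rnorm(95000), rnorm(5000, 6, 1))
  nm2 <- estimate_null(contaminated)
  expect_gt(nm2$mu0, -0.1); expect_lt(nm2$mu0, 0.1)
  expect_gt(nm2$sigma0, 0.9); expect_lt(nm2$sigma0, 1.1)
  expect_error(estimate_null(rep(1, 500)), "degenerate")
  expect_error(estimate_null(rnorm(50)), "insufficient")
})

test_that("Z-scoring is exact at the null mean and scale and keeps missingness", {
  g <- interpolate_to_grid(toy_track(c(35, 70, 300), c(3, 5, 1),
                                     resolution = 35, max_interp_dist = 35),
                           35)
  z <- to_zscores(g, structure(list(mu0 = 3, sigma0 = 2),
                               class = "null_model"))
  v <- z$chroms$chr1$values
  expect_equal(v[1], 0)      # score == mu0
  expect_equal(v[2], 1)      # score == mu0 + sigma0
  expect_true(anyNA(v))      # gap beyond cap stays missing
})

test_that("Z-grids are invariant to adding a constant once the null is re-estimated", {
  set.seed(3)
  pos <- seq(10, 1e4, by = 10)
  sc <- rt(length(pos), 5)
  tr <- toy_track(pos, sc, resolution = 10, max_interp_dist = 20)
  tr_c <- toy_track(pos, sc + 7.5, resolution = 10, max_interp_dist = 20)
  z1 <- to_zscores(interpolate_to_grid(tr, 10), estimate_null(tr))
  z2 <- to_zscores(interpolate_to_grid(tr_c, 10), estimate_null(tr_c))
  expect_equal(z1$chroms$chr1$values, z2$chroms$chr1$values)
})

test_that("Stouffer combination reduces to known closed forms", {
  mk <- function(v, id) {
    g <- interpolate_to_grid(toy_track(seq_along(v) * 10, v, resolution = 10,
                                       max_interp_dist = 10, id = id), 10)
    g
  }
  # four unit Z-scores -> 4 / sqrt(4) = 2
  comp <- combine_stouffer(lapply(1:4, function(i) mk(rep(1, 5), i)),
                           chipchip_config(10))
  expect_equal(comp$chroms$chr1$composite, rep(2, 5))
  expect_equal(comp$chroms$chr1$k_used, rep(4L, 5))
  # a single dataset passes through unchanged
  z <- c(-1, 0.5, 2)
  comp1 <- combine_stouffer(list(mk(z, "a")), chipchip_config(10))
  expect_equal(comp1$chroms$chr1$composite, z)
  # k identical copies scale pointwise by sqrt(k)
  comp3 <- combine_stouffer(lapply(1:3, function(i) mk(z, i)),
                            chipchip_config(10))
  expect_equal(comp3$chroms$chr1$composite, sqrt(3) * z)
})

test_that("partial coverage combines over the covering subset with a standard-normal null", {
  set.seed(21)
  n <- 20000
  tracks <- lapply(1:3, function(i) {
    keep <- sort(sample(n, n * 0.7))
    toy_track(keep * 7, rnorm(length(keep)), resolution = 7,
              max_interp_dist = 7, id = paste0("t", i))
  })
  zg <- lapply(tracks, function(tr)
    to_zscores(interpolate_to_grid(tr, 7), estimate_null(tr)))
  comp <- combine_stouffer(zg, chipchip_config(7))
  S <- comp$chroms$chr1$composite
  k <- comp$chroms$chr1$k_used
  expect_true(all(is.na(S[k == 0])))
  expect_true(all(!is.na(S[k > 0])))
  # tail calibration irrespective of how many datasets cover a point
  expect_lt(abs(mean(S[k > 0] > qnorm(0.95), na.rm = TRUE) - 0.05), 0.01)
  # intersection behaviour via min_datasets = k
  comp_int <- combine_stouffer(zg, chipchip_config(7, min_datasets = 3))
  expect_true(all(is.na(comp_int$chroms$chr1$composite[k < 3])))
})

test_that("composite peak calling respects threshold, merge and length rules", {
  vals <- rep(0, 200)
  vals[50:61] <- 5                       # 12 points * 7 bp = 84 bp run
  vals[70:75] <- 5                       # second run, gap of 8 points
  vals[150] <- 5                         # isolated single point
  g <- structure(list(dataset_id = "x", step = 7,
                      chroms = list(chr1 = list(grid_start = 7,
                                                values = vals))),
                 class = "grid_track")
  comp <- combine_stouffer(list(g), chipchip_config(7))
  # gap between runs is (70-61-1)*7 = 56 bp: merged when merge_gap >= 56
  cfg <- chipchip_config(7, pvalue_cutoff = 0.05, merge_gap = 56,
                         min_peak_len = 28)
  pk <- call_peaks_composite(comp, cfg)
  expect_equal(nrow(pk), 1L)             # merged; isolated point too short
  expect_equal(pk$score, 5)
  expect_equal(pk$pvalue, pnorm(5, lower.tail = FALSE))
  expect_equal(pk$summit, 50 * 7)        # leftmost maximum
  cfg2 <- chipchip_config(7, pvalue_cutoff = 0.05, merge_gap = 49,
                          min_peak_len = 28)
  expect_equal(nrow(call_peaks_composite(comp, cfg2)), 2L)
  # nothing above threshold -> empty
  cfg3 <- chipchip_config(7, pvalue_cutoff = 1e-12)
  expect_equal(nrow(call_peaks_composite(comp, cfg3)), 0L)
})

test_that("sign-flip eFDR reproduces N/P arithmetic and edge cases", {
  vals <- rep(0, 5000)
  starts <- seq(10, 4000, by = 40)       # 100 positive runs of 5 points
  for (s in starts[1:100]) vals[s:(s + 4)] <- 6
  for (s in starts[1:5] + 4200) vals[s:(s + 4)] <- -6   # 5 negative runs
  g <- structure(list(dataset_id = "x", step = 7,
                      chroms = list(chr1 = list(grid_start = 7,
                                                values = vals))),
                 class = "grid_track")
  comp <- combine_stouffer(list(g), chipchip_config(7))
  cfg <- chipchip_config(7, pvalue_cutoff = 0.01, merge_gap = 0,
                         min_peak_len = 0)
  fdr <- efdr_signflip(comp, cfg)
  expect_equal(fdr$n_positive, 100L)
  expect_equal(fdr$n_negative, 5L)
  expect_equal(fdr$efdr, 0.05)
  # no negative peaks -> 0; no positive peaks -> undefined, not zero
  vals2 <- vals; vals2[vals2 < 0] <- 0
  comp2 <- combine_stouffer(list(structure(list(
    dataset_id = "x", step = 7,
    chroms = list(chr1 = list(grid_start = 7, values = vals2))),
    class = "grid_track")), chipchip_config(7))
  expect_equal(efdr_signflip(comp2, cfg)$efdr, 0)
  vals3 <- -abs(vals)
  comp3 <- combine_stouffer(list(structure(list(
    dataset_id = "x", step = 7,
    chroms = list(chr1 = list(grid_start = 7, values = vals3))),
    class = "grid_track")), chipchip_config(7))
  expect_true(is.na(efdr_signflip(comp3, cfg)$efdr))
})

test_that("the array-branch driver annotates the list-level eFDR on peaks", {
  set.seed(8)
  pos <- seq(7, 7e4, by = 7)
  sc <- rt(length(pos), 5)
  sc[3000:3100] <- sc[3000:3100] + 6
  tracks <- lapply(1:2, function(i)
    toy_track(pos, sc + rnorm(length(pos), 0, 0.2), resolution = 7,
              max_interp_dist = 10, id = paste0("t", i)))
  fit <- chipchip_meta(tracks, chipchip_config(7))
  expect_s3_class(fit, "chipchip_fit")
  expect_gt(nrow(fit$peaks), 0)
  expect_true(all(fit$peaks$efdr == fit$efdr$efdr))
  expect_output(print(fit), "peaks")
})
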
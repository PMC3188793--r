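test_that("duplicate tags collapse per (chrom, position, strand)", {
  ts <- toy_tags(c(500, 500, 500, 500, 800), c("+", "+", "+", "-", "+"))
  d1 <- dedup_tags(ts, 1)
  expect_equal(d1$n_tags, 3L)                       # 500+, 500-, 800+
  expect_equal(dedup_tags(ts, 2)$n_tags, 4L)
  empty <- toy_tags(integer(0), character(0))
  expect_equal(dedup_tags(empty)$n_tags, 0L)
})

test_that("tag shifting follows the strand-aware d/2 rule", {
  ts <- toy_tags(c(1000, 1000, 10), c("+", "-", "-"))
  sh <- shift_tags(ts, 100)
  expect_equal(sh$tags$pos5[sh$tags$strand == "+"], 1050)
  expect_equal(sort(sh$tags$pos5[sh$tags$strand == "-"]), c(0, 950))
  expect_equal(shift_tags(ts, 0)$tags, ts$tags)
  # odd d floors
  expect_equal(shift_tags(toy_tags(100, "+"), 101)$tags$pos5, 150)
  # invertibility for Watson tags away from the origin
  w <- toy_tags(c(100, 5000), c("+", "+"))
  expect_equal(shift_tags(shift_tags(w, 100), 0)$tags$pos5,
               w$tags$pos5 + 50)
})

test_that("pooling conserves tags and is order-invariant", {
  a <- toy_tags(sample(1:1000, 10), rep(c("+", "-"), 5), id = "a")
  b <- toy_tags(sample(1:1000, 15), rep(c("+", "-"), c(8, 7)), id = "b")
  p1 <- pool_libraries(list(a, b), per_source_d = c(100, 120))
  p2 <- pool_libraries(list(b, a), per_source_d = c(120, 100))
  expect_equal(p1$tags$n_tags, 25L)
  expect_equal(p1$tags$tags, p2$tags$tags)
  expect_equal(p1$per_source_d[["b"]], 120)
  empty <- toy_tags(integer(0), character(0), id = "e")
  expect_equal(pool_libraries(list(a, empty))$tags$tags, a$tags)
  expect_error(pool_libraries(list(a, a)), "duplicate")
})

test_that("Poisson tail probabilities match a direct-summation oracle", {
  psf_oracle <- function(count, lam) {
    j <- count:(count + 500)
    sum(exp(-lam + j * log(lam) - lgamma(j + 1)))
  }
  expect_equal(poisson_sf(0, 0.5), 1)
  expect_equal(poisson_sf(0, 17), 1)
  expect_equal(poisson_sf(1, 2), 1 - exp(-2))
  for (lam in c(0.1, 0.5, 1, 2, 5, 10, 20)) {
    for (count in c(0:10, 20, 35, 50)) {
      expect_lt(abs(poisson_sf(count, lam) / psf_oracle(count, lam) - 1),
                1e-12)
    }
  }
  expect_error(poisson_sf(-1, 2), "non-negative")
})

test_that("the local rate is the maximum of available window estimates", {
  cfg <- chipseq_config(genome_size = 1e6, scan_window = 100)
  # chip: 100 tags; control: uniform except a dense 1 kb patch at 50 kb
  set.seed(2)
  chip <- toy_tags(sort(sample(1e6, 200)) - 1, rep(c("+", "-"), 100),
                   id = "c")
  ctl_pos <- c(sort(sample(1e6, 200)) - 1, 49500 + sample(0:999, 300, TRUE))
  ctl <- toy_tags(ctl_pos, rep(c("+", "-"), length.out = length(ctl_pos)),
                  id = "k")
  lam <- local_lambda(c(50000, 900000), "chr1", chip, ctl, cfg)
  expect_true(all(lam$lambda_local >= lam$lambda_bg))
  expect_gt(lam$lambda_local[1], lam$lambda_local[2])   # dense patch caught
  expect_equal(lam$lambda_local[1], max(lam$lambda_bg[1],
                                        lam$lambda_1000[1],
                                        lam$lambda_5000[1],
                                        lam$lambda_10000[1]))
  # without a control the smallest window is excluded
  lam0 <- local_lambda(50000, "chr1", chip, NULL, cfg)
  expect_true(is.na(lam0$lambda_1000))
  expect_false(is.na(lam0$lambda_5000))
})

test_that("lambda_local stays near lambda_bg under a homogeneous control", {
  set.seed(7)
  G <- 1e7
  n <- 1e5
  ctl <- toy_tags(sort(sample.int(G, n, TRUE)) - 1,
                  sample(c("+", "-"), n, TRUE), id = "k")
  chip <- toy_tags(sort(sample.int(G, n, TRUE)) - 1,
                   sample(c("+", "-"), n, TRUE), id = "c")
  cfg <- chipseq_config(genome_size = G, scan_window = 100)
  centers <- seq(50000, G - 50000, length.out = 2000)
  lam <- local_lambda(centers, "chr1", chip, ctl, cfg)
  expect_true(all(lam$lambda_local >= lam$lambda_bg))
  # the max over window estimates inflates the mean a little; it must stay
  # close to (and never below) the true homogeneous rate
  ratio <- mean(lam$lambda_local) / lam$lambda_bg[1]
  expect_gte(ratio, 1)
  expect_lt(ratio, 1.3)
})

test_that("a symmetric single site yields its exact summit", {
  lib <- one_site_library(s = 5000, d = 100)
  cfg <- chipseq_config(genome_size = 2e4, scan_window = 100,
                        pvalue_cutoff = 1e-5)
  pk <- call_peaks_seq(pool_libraries(shift_tags(lib, 100)), NULL, cfg)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$summit, 5000L)
  expect_true(pk$start <= 5000 && pk$end > 5000)
})

test_that("model building requires both strands and enough candidates", {
  oneside <- toy_tags(seq(100, 5000, by = 10), rep("+", 491))
  expect_error(estimate_fragment_size(oneside, chipseq_config()),
               "both strands")
  tiny <- toy_tags(c(100, 150), c("+", "-"))
  expect_error(estimate_fragment_size(tiny, chipseq_config(genome_size = 1e4)),
               "candidates")
})

test_that("implausibly small fragment estimates fall back to the default", {
  des <- seq_library_design(n_sites = 300, tags_per_site = 40, d = 40,
                            genome_len = 3e6, bg_rate = 2e-4, seed = 5)
  lib <- make_seq_library(des)
  cfg <- chipseq_config(genome_size = des$genome_len, min_d = 50,
                        default_d = 200)
  expect_warning(m <- estimate_fragment_size(dedup_tags(lib$chip), cfg),
                 "falling back")
  expect_equal(m$d, 200)
})

test_that("background-only data yields essentially no peaks", {
  des <- seq_library_design(n_sites = 0, tags_per_site = 0, d = 100,
                            genome_len = 1e7, bg_rate = 1e-3, seed = 9)
  lib <- make_seq_library(des)
  cfg <- chipseq_config(genome_size = des$genome_len, scan_window = 100,
                        pvalue_cutoff = 1e-5)
  pk <- call_peaks_seq(pool_libraries(lib$chip), pool_libraries(lib$control),
                       cfg)
  expect_lte(nrow(pk), 2L)
})

test_that("a single library gives the same result through both pipelines", {
  des <- seq_library_design(n_sites = 400, tags_per_site = 40, d = 100,
                            genome_len = 4e6, bg_rate = 5e-4, seed = 13)
  lib <- make_seq_library(des)
  cfg <- chipseq_config(genome_size = des$genome_len)
  f1 <- suppressMessages(chipseq_meta(lib$chip, lib$control, cfg))
  f2 <- suppressMessages(merged_baseline(list(lib$chip), list(lib$control),
                                         cfg))
  expect_equal(f1$models[[1]]$d, f2$models[[1]]$d)
  expect_equal(f1$peaks$summit, f2$peaks$summit)
  expect_equal(f1$peaks$pvalue, f2$peaks$pvalue)
})
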
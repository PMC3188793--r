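# all 256 4-mers concatenated give a uniform third-order model with pc = 0
uniform_bg <- function() {
  kmers <- apply(expand.grid(BASES, BASES, BASES, BASES), 1, paste,
                 collapse = "")
  train_background(kmers, order = 3, pseudocount = 0)
}

consensus_pwm <- function(seq, pseudocount = 0) {
  m <- matrix(0, nchar(seq), 4, dimnames = list(NULL, BASES))
  m[cbind(seq_len(nchar(seq)), match(strsplit(seq, "")[[1]], BASES))] <- 1
  pwm(m, pseudocount = pseudocount)
}

test_that("background training recovers uniform and skewed compositions", {
  bg <- uniform_bg()
  expect_true(all(abs(2^bg$trans - 0.25) < 1e-12))
  expect_true(all(abs(rowSums(2^bg$trans) - 1) < 1e-9))
  skew <- train_background(strrep("A", 500), order = 3, pseudocount = 1)
  tA <- 2^skew$trans
  expect_gt(tA[1, "A"], max(tA[1, c("C", "G", "T")]))
  expect_equal(tA[1, "C"], tA[1, "G"])
  expect_error(train_background(character(0)), "empty")
})

test_that("window likelihoods under the background sum to one", {
  bg <- train_background(strrep("ACGTACGGTTACGATCGATCGGGCAT", 20),
                         order = 3, pseudocount = 1)
  w <- 5
  all_windows <- apply(expand.grid(rep(list(BASES), w)), 1, paste,
                       collapse = "")
  lik <- vapply(all_windows, function(s)
    2^bg_window_loglik(base_codes(s), w, bg), 0)
  expect_equal(sum(lik), 1, tolerance = 1e-9)
})

test_that("a perfect consensus match scores 2 bits per position on uniform background", {
  p <- consensus_pwm("ACGTAC")
  bg <- uniform_bg()
  hits <- scan_pwm("ACGTAC", p, bg, threshold = 0)
  expect_equal(hits$score[hits$strand == "+"], 2 * 6)
  # and its reverse complement scores identically on the minus strand
  hits_rc <- scan_pwm("GTACGT", p, bg, threshold = 0)
  expect_equal(hits_rc$score[hits_rc$strand == "-"], 2 * 6)
  expect_equal(hits_rc$offset[hits_rc$strand == "-"], 1L)
})

test_that("hit sets are invariant under reverse-complementing the input", {
  set.seed(12)
  seq <- paste(sample(BASES, 400, TRUE), collapse = "")
  # plant the consensus and its reverse complement so hits exist on both
  # strands
  substr(seq, 50, 57) <- "ACGTACGT"
  substr(seq, 201, 208) <- "ACGTACGT"   # palindromic: hits on both strands
  p <- consensus_pwm("ACGTACGT")
  bg <- train_background(seq, pseudocount = 1)
  thr <- 8
  fwd <- scan_pwm(seq, p, bg, thr)
  rc <- paste(rev(c(A = "T", C = "G", G = "C", T = "A")[
    strsplit(seq, "")[[1]]]), collapse = "")
  rev_hits <- scan_pwm(rc, p, bg, thr)
  # map reverse-scan coordinates back to the original sequence
  n <- nchar(seq); w <- 8
  mapped <- data.frame(offset = n - w + 2 - rev_hits$offset,
                       strand = ifelse(rev_hits$strand == "+", "-", "+"))
  mapped <- mapped[order(mapped$offset, mapped$strand), ]
  orig <- fwd[order(fwd$offset, fwd$strand), c("offset", "strand")]
  expect_equal(mapped$offset, orig$offset)
  expect_equal(mapped$strand, orig$strand)
})

test_that("windows containing ambiguous bases are skipped", {
  p <- consensus_pwm("ACGT")
  bg <- uniform_bg()
  hits <- scan_pwm("ACGNACGT", p, bg, threshold = -100)
  expect_false(any(hits$offset <= 4 & hits$strand == "+"))
  expect_true(any(hits$offset == 5 & hits$strand == "+"))
})

test_that("sampled score thresholds calibrate the null exceedance rate", {
  set.seed(33)
  corpus <- paste(sample(BASES, 5000, TRUE, prob = c(0.3, 0.2, 0.2, 0.3)),
                  collapse = "")
  bg <- train_background(corpus, pseudocount = 1)
  p <- consensus_pwm("ACGTACGTAC", pseudocount = 0.25)  # soft matrix
  thr <- motif_score_threshold(p, bg, p = 0.01, n = 2e4, seed = 10)
  # score random background windows; about 1% should exceed the threshold
  seqs <- vapply(1:3000, function(i)
    paste(sample(BASES, 10, TRUE, prob = c(0.3, 0.2, 0.2, 0.3)),
          collapse = ""), "")
  sc <- vapply(seqs, function(s) {
    h <- scan_pwm(s, p, bg, threshold = -1000)
    max(h$score[h$strand == "+"])
  }, 0)
  rate <- mean(sc >= thr)
  expect_lt(rate, 0.03)
})

test_that("motif-fraction curves hit closed-form values on planted designs", {
  p <- consensus_pwm("ACGTAC")
  bg <- uniform_bg()
  set.seed(3)
  rand_seq <- function() paste(sample(c("C", "A"), 40, TRUE), collapse = "")
  planted <- vapply(1:10, function(i)
    paste0(substr(rand_seq(), 1, 17), "ACGTAC", substr(rand_seq(), 24, 40)),
    "")
  barren <- vapply(1:10, function(i) rand_seq(), "")
  pk <- toy_peaks(seq(0, 1900, by = 100), seq(40, 1940, by = 100),
                  pvalues = seq(0.001, 0.02, length.out = 20))
  thr <- 11        # consensus scores 12 bits; random CA strings cannot
  curve_all <- motif_fraction_curve(pk, c(planted, planted), p, bg, thr)
  expect_equal(curve_all, rep(1, 20))
  curve_none <- motif_fraction_curve(pk, c(barren, barren), p, bg, thr)
  expect_equal(curve_none, rep(0, 20))
  curve_top <- motif_fraction_curve(pk, c(planted, barren), p, bg, thr)
  expect_equal(curve_top[10], 1)
  expect_equal(curve_top[20], 0.5)
  expect_warning(motif_fraction_curve(pk[1:2, ], c("ACG", planted[1]), p,
                                      bg, thr),
                 "shorter")
})

test_that("a better ranking dominates the motif-fraction curve", {
  # two rankings of the same 40 peaks: one concentrates the 20 motif-bearing
  # peaks on top (good), one alternates (poor)
  p <- consensus_pwm("ACGTAC")
  bg <- uniform_bg()
  set.seed(8)
  mk <- function(withm) {
    s <- paste(sample(c("C", "A"), 40, TRUE), collapse = "")
    if (withm) paste0(substr(s, 1, 17), "ACGTAC", substr(s, 24, 40)) else s
  }
  seqs <- c(vapply(1:20, function(i) mk(TRUE), ""),
            vapply(1:20, function(i) mk(FALSE), ""))
  good <- toy_peaks(seq(0, 3900, by = 100), seq(40, 3940, by = 100),
                    pvalues = seq(1e-6, 1e-3, length.out = 40))
  poor_order <- as.vector(rbind(1:20, 21:40))
  poor <- good; poor$pvalue <- seq(1e-6, 1e-3, length.out = 40)[
    order(poor_order)]
  c_good <- motif_fraction_curve(good, seqs, p, bg, 11)
  c_poor <- motif_fraction_curve(poor, seqs, p, bg, 11)
  expect_true(all(c_good - c_poor >= -1e-12))
  expect_gt(c_good[20], c_poor[20])
})
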
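BASES <- c("A", "C", "G", "T")

base_codes <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES)  # NA for N etc.
}

#' Construct a position weight matrix
#'
#' @param probs numeric matrix, width x 4 (columns A, C, G, T), each row a
#'   probability distribution.
#' @param pseudocount added to every cell before row renormalization when
#'   scoring (avoids -Inf on zero entries).
#' @return object of class `pwm`.
#' @export
pwm <- function(probs, pseudocount = 1e-3) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 4) stop("PWM width must be at least 4")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("PWM rows must sum to 1")
  colnames(probs) <- BASES
  structure(list(width = nrow(probs), probs = probs,
                 pseudocount = pseudocount), class = "pwm")
}

#' Read a 4-row position count/probability matrix
#'
#' Expects four whitespace-separated numeric rows in A, C, G, T order
#' (JASPAR-style; counts are normalized to probabilities per column). Lines
#' starting with `>` or `#` are ignored.
#'
#' @param path matrix file.
#' @param pseudocount see [pwm()].
#' @return a [pwm()].
#' @export
read_pwm <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*([>#]|$)", lines)]
  if (length(lines) != 4) stop("expected 4 matrix rows (A, C, G, T) in ", path)
  rows <- lapply(lines, function(l) {
    x <- suppressWarnings(
      as.numeric(strsplit(trimws(gsub("[][ACGTacgt:]", " ", l)),
                          "\\s+")[[1]]))
    x[!is.na(x)]
  })
  if (length(unique(lengths(rows))) != 1)
    stop("matrix rows have unequal lengths in ", path)
  m <- do.call(cbind, rows)          # width x 4
  m <- m / rowSums(m)
  pwm(m, pseudocount)
}

#' Train a k-th order Markov background model on sequences
#'
#' Conditional probabilities `P(base | previous k bases)` are estimated from
#' (k+1)-mer counts with a pseudocount, along with the marginal distribution
#' of initial k-mers. The default third order captures local composition
#' (CpG depletion, repeats) that a simple base-frequency background misses.
#'
#' @param seqs character vector of sequences (or a single sequence).
#' @param order Markov order (default 3).
#' @param pseudocount added to every (k+1)-mer count.
#' @return object of class `markov_background` with the `4^k x 4` conditional
#'   table `trans` (log2), the initial k-mer distribution `init` (log2) and
#'   the `order`.
#' @export
train_background <- function(seqs, order = 3L, pseudocount = 1) {
  if (!length(seqs) || all(nchar(seqs) == 0)) stop("empty training input")
  stopifnot(order >= 1, pseudocount >= 0)
  total <- sum(nchar(seqs))
  if (total <= 4^(order + 1))
    warning("training corpus shorter than 4^(order+1) bp; ",
            "estimates will lean on the pseudocount")
  ss <- Biostrings::DNAStringSet(gsub("[^ACGTacgt]", "N", seqs))
  kmer <- colSums(Biostrings::oligonucleotideFrequency(ss, order + 1))
  counts <- matrix(kmer + pseudocount, ncol = 4, byrow = TRUE,
                   dimnames = list(unique(substr(names(kmer), 1, order)),
                                   BASES))                      # ctx x base
  if (any(counts <= 0)) stop("zero counts with zero pseudocount; ",
                             "increase pseudocount")
  trans <- counts / rowSums(counts)
  init_counts <- colSums(Biostrings::oligonucleotideFrequency(ss, order)) +
    pseudocount
  structure(list(order = as.integer(order),
                 trans = log2(trans),
                 init = log2(init_counts / sum(init_counts))),
            class = "markov_background")
}

# log2 background likelihood of every window of width w in a coded sequence
# (codes 1..4, NA for ambiguous); windows containing NA come back NA. The
# window likelihood is P(first k bases) * prod P(base | previous k), so the
# likelihoods of all 4^w windows of width w sum to 1.
bg_window_loglik <- function(codes, w, bg) {
  k <- bg$order
  n <- length(codes)
  if (n < w) return(numeric(0))
  if (w <= k) stop("window width must exceed the background order")
  codes0 <- codes - 1
  # context index ending just before position t, for t in (k+1):n
  ctx <- rep(NA_real_, n)
  c0 <- rep(0, n - k)
  for (j in seq_len(k)) c0 <- c0 * 4 + codes0[seq(j, n - k + j - 1)]
  ctx[(k + 1):n] <- c0 + 1
  term <- rep(NA_real_, n)
  ok <- !is.na(ctx) & !is.na(codes)
  term[ok] <- bg$trans[cbind(ctx[ok], codes[ok])]
  cs <- cumsum(c(0, ifelse(is.na(term), 0, term)))
  # initial k-mer index at each possible window start
  i0 <- rep(0, n - k + 1)
  for (j in seq_len(k)) i0 <- i0 * 4 + codes0[seq(j, n - k + j)]
  starts <- seq_len(n - w + 1)
  out <- bg$init[i0[starts] + 1] + (cs[starts + w] - cs[starts + k])
  nacum <- cumsum(c(0, is.na(codes)))
  out[(nacum[starts + w] - nacum[starts]) > 0] <- NA_real_
  out
}

pwm_window_scores <- function(codes, lpwm) {
  w <- nrow(lpwm)
  n <- length(codes)
  if (n < w) return(numeric(0))
  starts <- seq_len(n - w + 1)
  sc <- numeric(length(starts))
  for (i in seq_len(w)) {
    b <- codes[starts + i - 1]
    sc <- sc + ifelse(is.na(b), NA_real_, lpwm[cbind(rep(i, length(b)), b)])
  }
  sc
}

log2_pwm <- function(p) {
  m <- (p$probs + p$pseudocount)
  log2(m / rowSums(m))
}

#' Scan a sequence with a PWM against a Markov background
#'
#' Every window of PWM width on both strands is scored as
#' `sum_i log2 PWM_i(base_i) - log2 P_bg(window)`, where the background
#' likelihood is the Markov-chain probability of the matched (possibly
#' reverse-complemented) window. Windows containing ambiguous bases are
#' skipped. Hit sets are invariant under reverse-complementing the input,
#' with strand labels swapped.
#'
#' @param seq a single sequence string.
#' @param pwm a [pwm()].
#' @param bg a [train_background()] model.
#' @param threshold minimum log2 odds score to report
#'   (see [motif_score_threshold()]).
#' @return data.frame `offset` (1-based start of the window on the input),
#'   `strand`, `score`, sorted by offset.
#' @export
scan_pwm <- function(seq, pwm, bg, threshold) {
  w <- pwm$width
  if (nchar(seq) < w)
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  lpwm <- log2_pwm(pwm)
  scan_one <- function(s) {
    codes <- base_codes(s)
    pwm_window_scores(codes, lpwm) - bg_window_loglik(codes, w, bg)
  }
  fwd <- scan_one(seq)
  rcseq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gsub("[^ACGTacgt]", "N", seq))))
  rev <- scan_one(rcseq)
  n <- nchar(seq)
  off_f <- which(!is.na(fwd) & fwd >= threshold)
  off_r <- n - w + 2 - which(!is.na(rev) & rev >= threshold)
  hits <- rbind(
    data.frame(offset = off_f, strand = rep("+", length(off_f)),
               stringsAsFactors = FALSE),
    data.frame(offset = off_r, strand = rep("-", length(off_r)),
               stringsAsFactors = FALSE))
  hits$score <- ifelse(hits$strand == "+", fwd[hits$offset],
                       rev[n - w + 2 - hits$offset])
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}

#' Score threshold with a given null exceedance probability
#'
#' Samples windows from the background model, scores them against the PWM and
#' returns the `(1 - p)` quantile, i.e. the score a background window exceeds
#' with probability about `p`.
#'
#' @param pwm a [pwm()].
#' @param bg a [train_background()] model.
#' @param p target null exceedance probability (default 1e-4).
#' @param n number of sampled windows.
#' @param seed RNG seed.
#' @return numeric threshold.
#' @export
motif_score_threshold <- function(pwm, bg, p = 1e-4, n = 1e5, seed = 1L) {
  stopifnot(p > 0, p < 1)
  with_seed(seed, {
    k <- bg$order
    w <- pwm$width
    init_p <- 2^bg$init
    trans_p <- 2^bg$trans
    ctx <- sample.int(4^k, n, replace = TRUE, prob = init_p)
    # decode contexts to k base columns
    mat <- matrix(0L, n, w)
    rem <- ctx - 1
    for (j in k:1) { mat[, j] <- rem %% 4 + 1; rem <- rem %/% 4 }
    for (j in (k + 1):w) {
      prev <- mat[, (j - k):(j - 1), drop = FALSE]
      ci <- rep(0, n)
      for (jj in seq_len(k)) ci <- ci * 4 + (prev[, jj] - 1)
      u <- stats::runif(n)
      cp <- trans_p[ci + 1, , drop = FALSE]
      cum <- t(apply(cp, 1, cumsum))
      mat[, j] <- max.col(cum >= u, ties.method = "first")
    }
    lpwm <- log2_pwm(pwm)
    sc <- numeric(n)
    lbg <- bg$init[ctx]
    for (j in seq_len(w)) sc <- sc + lpwm[j, ][mat[, j]]
    for (j in (k + 1):w) {
      prev <- mat[, (j - k):(j - 1), drop = FALSE]
      ci <- rep(0, n)
      for (jj in seq_len(k)) ci <- ci * 4 + (prev[, jj] - 1)
      lbg <- lbg + bg$trans[cbind(ci + 1, mat[, j])]
    }
    stats::quantile(sc - lbg, 1 - p, names = FALSE)
  })
}

#' Motif occurrence among top-ranked peaks
#'
#' For each prefix of the ranking, the fraction of peaks whose summit-centered
#' window contains at least one PWM hit. Used to compare rankings when truth
#' sites are unknown: a better ranking puts motif-bearing regions first.
#'
#' @param peaks ranked peak data.frame (sorted by ascending p-value
#'   internally).
#' @param seqs character vector of summit-centered sequences, one per peak in
#'   the same order as `peaks` rows (each should span summit +/- flank).
#' @param pwm a [pwm()].
#' @param bg a [train_background()] model.
#' @param threshold score cutoff (see [motif_score_threshold()]).
#' @return numeric vector; element N is the motif fraction among the top N
#'   peaks.
#' @export
motif_fraction_curve <- function(peaks, seqs, pwm, bg, threshold) {
  stopifnot(nrow(peaks) == length(seqs))
  o <- order(peaks$pvalue, -peaks$score)
  seqs <- seqs[o]
  short <- nchar(seqs) < pwm$width
  if (any(short))
    warning(sum(short), " sequence(s) shorter than the PWM width; ",
            "counted as motif-negative")
  has_hit <- vapply(seqs, function(s)
    !nchar(s) < pwm$width && nrow(scan_pwm(s, pwm, bg, threshold)) > 0,
    TRUE, USE.NAMES = FALSE)
  cumsum(has_hit) / seq_along(has_hit)
}
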
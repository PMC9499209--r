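# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: plain loops and stats::lm only.

# per-position least-squares slope via lm()
oracle_slope <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - h):min(n, i + h)
    unname(stats::coef(stats::lm(x[idx] ~ idx))[2])
  }, numeric(1))
}

# pairwise-comparison AUROC
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# cut-count histogram by explicit looping over fragments
oracle_cut_hist <- function(frags, chrom, start, end, nuc = 147L) {
  w <- end - start
  m <- matrix(0L, 4L, w,
              dimnames = list(c("fwd_short", "rev_short", "fwd_long",
                                "rev_long"), NULL))
  for (i in seq_len(nrow(frags))) {
    if (frags$chrom[i] != chrom) next
    cls <- if (frags$size[i] <= nuc) "short" else "long"
    left <- frags$start[i]
    right <- frags$end[i] - 1L
    if (left >= start && left < end)
      m[paste0("fwd_", cls), left - start + 1L] <-
        m[paste0("fwd_", cls), left - start + 1L] + 1L
    if (right >= start && right < end)
      m[paste0("rev_", cls), right - start + 1L] <-
        m[paste0("rev_", cls), right - start + 1L] + 1L
  }
  m
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

# score a single L-mer with the PWM score matrix, character by character
oracle_score_seq <- function(s, S) {
  chars <- strsplit(s, "")[[1]]
  if (any(!chars %in% names(REVCOMP))) return(NA_real_)
  tot <- 0
  for (j in seq_along(chars))
    tot <- tot + S[chars[j], j]
  tot
}

# exhaustive window scan on both strands
oracle_scan <- function(seqs, pwm, threshold) {
  S <- pwm$score
  rownames(S) <- c("A", "C", "G", "T")
  L <- ncol(S)
  out <- list()
  for (ch in names(seqs)) {
    s <- seqs[[ch]]
    n <- nchar(s)
    for (i in seq_len(n - L + 1L)) {
      win <- substr(s, i, i + L - 1L)
      fs <- oracle_score_seq(win, S)
      rc <- paste(rev(REVCOMP[strsplit(win, "")[[1]]]), collapse = "")
      rs <- oracle_score_seq(rc, S)
      if (!is.na(fs) && fs >= threshold)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = i - 1L, end = i - 1L + L, strand = "+",
          pwm_score = fs, stringsAsFactors = FALSE)
      if (!is.na(rs) && rs >= threshold)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = i - 1L, end = i - 1L + L, strand = "-",
          pwm_score = rs, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      pwm_score = numeric()))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

# enumerate all 4^L sequences and their PWM scores (uniform background)
oracle_enumerate_scores <- function(S) {
  L <- ncol(S)
  grid <- expand.grid(rep(list(1:4), L))
  apply(grid, 1L, function(b) sum(S[cbind(b, seq_len(L))]))
}

# Friedman chi-square by the textbook rank-sum formula (no ties expected)
oracle_friedman <- function(rank_mat) {
  n <- nrow(rank_mat)
  k <- ncol(rank_mat)
  Rj <- colSums(rank_mat)
  12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

toy_pwm <- function(L = 6L, seed = 42L) {
  counts <- footprintCNN:::with_seed(seed,
    matrix(sample(1:60, 4L * L, replace = TRUE), 4L, L))
  pwm_from_counts(counts, name = sprintf("toy%d", L))
}
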
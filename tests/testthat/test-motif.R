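test_that("PFM round-trips through the JASPAR text format", {
  counts <- matrix(c(10, 2, 3, 5,
                     1, 20, 1, 2,
                     4, 4, 4, 4,
                     0, 1, 30, 6), 4, 4)
  path <- withr::local_tempfile(fileext = ".pfm")
  write_pfm(counts, path, name = "MA0000.1 toy")
  pwm <- read_pfm(path)
  expect_equal(pwm$name, "MA0000.1 toy")
  expect_equal(pwm$length, 4L)
  expect_equal(unname(pwm$prob),
               unname(pwm_from_counts(counts)$prob), tolerance = 1e-6)
  expect_equal(colSums(pwm$prob), rep(1, 4), tolerance = 1e-12)
})

test_that("pvalue_threshold: single-column and p = 1 cases", {
  # L = 1, uniform background, p = 0.25: only the single best base passes
  pwm <- pwm_from_counts(matrix(c(40, 20, 10, 5), 4, 1), pseudocount = 1)
  thr <- pvalue_threshold(pwm, scan_config(pvalue = 0.25))
  expect_equal(thr, max(pwm$score))
  # p = 1: everything passes, threshold = minimum achievable score
  thr1 <- pvalue_threshold(pwm, scan_config(pvalue = 1))
  expect_equal(thr1, min(pwm$score))
})

test_that("pvalue_threshold matches full enumeration for a 4-mer PWM", {
  pwm <- toy_pwm(4L, seed = 5L)
  all_scores <- oracle_enumerate_scores(pwm$score)
  expect_length(all_scores, 256L)
  # p = 1/256 with a unique maximum: threshold = top-1 score
  expect_equal(sum(all_scores == max(all_scores)), 1L)
  thr <- pvalue_threshold(pwm, scan_config(pvalue = 1 / 256))
  expect_equal(thr, max(all_scores))
  # general p: smallest achievable score whose exceedance is <= p
  for (p in c(0.05, 0.01, 0.2)) {
    srt <- sort(unique(all_scores), decreasing = TRUE)
    tailp <- vapply(srt, function(t) mean(all_scores >= t), numeric(1))
    expected <- min(srt[tailp <= p + 1e-12])
    expect_equal(pvalue_threshold(pwm, scan_config(pvalue = p)), expected)
  }
})

test_that("empirical exceedance of the threshold respects the p-value", {
  pwm <- toy_pwm(8L, seed = 6L)
  p <- 0.01
  thr <- pvalue_threshold(pwm, scan_config(pvalue = p))
  set.seed(61)
  n <- 1e5
  bases <- matrix(sample.int(4L, n * 8L, replace = TRUE), n, 8L)
  sc <- numeric(n)
  for (j in 1:8) sc <- sc + pwm$score[, j][bases[, j]]
  # one-sided: frequency must not exceed p by more than binomial noise
  expect_lt(mean(sc >= thr), p + 4 * sqrt(p * (1 - p) / n))
})

test_that("binned DP threshold approximates the exact threshold", {
  pwm <- toy_pwm(8L, seed = 7L)
  cfg <- scan_config(pvalue = 1e-3, score_granularity = 0.01)
  exact <- pvalue_threshold(pwm, cfg, method = "exact")
  binned <- pvalue_threshold(pwm, cfg, method = "binned")
  expect_lt(abs(exact - binned), 0.01 * 8)
})

test_that("degenerate PWM without pseudocount is rejected", {
  counts <- matrix(c(10, 0, 0, 0), 4, 3)
  pwm <- pwm_from_counts(counts, pseudocount = 0)
  expect_error(pvalue_threshold(pwm), "degenerate")
})

test_that("scan_pwm finds planted consensus on both strands", {
  pwm <- toy_pwm(6L, seed = 8L)
  consensus <- c("A", "C", "G", "T")[apply(pwm$score, 2, which.max)]
  set.seed(81)
  bg <- strsplit(random_dna(400), "")[[1]]
  bg[101:106] <- consensus
  rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[consensus])
  bg[301:306] <- rc
  genome <- c(chrT = paste(bg, collapse = ""))
  thr <- sum(apply(pwm$score, 2, max)) - 1e-9
  hits <- scan_pwm(genome, pwm, thr)
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  expect_true(any(plus$start == 100 & plus$end == 106))
  expect_true(any(minus$start == 300 & minus$end == 306))
})

test_that("windows containing N are skipped", {
  pwm <- toy_pwm(6L, seed = 9L)
  genome <- c(chrT = "ACGTACGTNNACGTACGT")
  hits <- scan_pwm(genome, pwm, -1e6)
  # every reported window must avoid positions 8-9 (0-based N run)
  expect_true(all(hits$end <= 8 | hits$start >= 10))
  expect_gt(nrow(hits), 0)
})

test_that("scan_pwm equals the exhaustive scan oracle on 2 kb", {
  pwm <- toy_pwm(6L, seed = 10L)
  set.seed(101)
  genome <- c(chrA = random_dna(1200), chrB = random_dna(800))
  thr <- pvalue_threshold(pwm, scan_config(pvalue = 0.01))
  got <- scan_pwm(genome, pwm, thr)
  want <- oracle_scan(genome, pwm, thr)
  expect_gt(nrow(want), 10)
  expect_equal(got[c("chrom", "start", "end", "strand")],
               want[c("chrom", "start", "end", "strand")],
               ignore_attr = TRUE)
  expect_equal(got$pwm_score, want$pwm_score, tolerance = 1e-9)
})

test_that("restrict_to_open keeps only fully contained MPBSs", {
  mpbs <- data.frame(chrom = "chr1", start = c(100L, 195L, 500L),
                     end = c(110L, 205L, 510L), strand = "+",
                     pwm_score = 1, label = "unlabeled")
  peaks <- data.frame(chrom = "chr1", start = 90L, end = 200L)
  kept <- restrict_to_open(mpbs, peaks)
  expect_equal(kept$start, 100L) # straddling and outside sites dropped
  expect_equal(nrow(restrict_to_open(mpbs, peaks[0, ])), 0L)
})

np_row <- function(chrom, start, end, signal, peak, name = "p") {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = 0L, strand = ".", signalValue = signal, pValue = -1,
             qValue = -1, peak = peak, stringsAsFactors = FALSE)
}

test_that("label_mpbs implements the summit rule", {
  # one peak [1000,1300), summit at 1100; MPBS centers 10 and 40 bp away
  chip <- np_row("chr1", 1000L, 1300L, 50, 100L)
  mk <- function(centers) data.frame(
    chrom = "chr1", start = centers - 5L, end = centers + 5L, strand = "+",
    pwm_score = 1, label = "unlabeled", stringsAsFactors = FALSE)
  lab <- label_mpbs(mk(c(1110L, 1140L)), chip)
  expect_equal(lab$label, c("bound", "unlabeled"))
  # only MPBS is 60 bp from the summit (> 50): nothing bound
  lab2 <- label_mpbs(mk(1160L), chip)
  expect_equal(lab2$label, "unlabeled")
  # MPBS far from any peak: unbound
  lab3 <- label_mpbs(mk(6000L), chip)
  expect_equal(lab3$label, "unbound")
  # peak without summit raises
  expect_error(label_mpbs(mk(1110L), np_row("chr1", 1000L, 1300L, 50, -1L)),
               "summit")
})

test_that("label_mpbs multi-summit toy matches hand derivation", {
  # duplicate peak rows = two summits; the higher one (offset 100) wins
  chip <- rbind(np_row("chr1", 1000L, 1300L, 80, 100L),
                np_row("chr1", 1000L, 1300L, 60, 200L))
  centers <- c(1095L, 1110L, 1140L, 1260L, 5000L)
  mpbs <- data.frame(chrom = "chr1", start = centers - 5L,
                     end = centers + 5L, strand = "+", pwm_score = 1,
                     label = "unlabeled", stringsAsFactors = FALSE)
  lab <- label_mpbs(mpbs, chip)
  # hand derivation: distances to summit 1100 are 5, 10, 40, 160;
  # nearest (1095) bound, others inside the peak unlabeled, far unbound
  expect_equal(lab$label,
               c("bound", "unlabeled", "unlabeled", "unlabeled", "unbound"))
  # labeling is a partition
  expect_true(all(lab$label %in% c("bound", "unbound", "unlabeled")))
})

test_that("equidistant MPBSs break ties toward the smaller coordinate", {
  chip <- np_row("chr1", 1000L, 1300L, 50, 100L)
  mpbs <- data.frame(chrom = "chr1", start = c(1075L, 1115L),
                     end = c(1085L, 1125L), strand = "+", pwm_score = 1,
                     label = "unlabeled", stringsAsFactors = FALSE)
  lab <- label_mpbs(mpbs, chip) # centers 1080 and 1120, both 20 bp away
  expect_equal(lab$label, c("bound", "unlabeled"))
})

test_that("balance_and_split yields balanced deterministic 70/20/10 splits", {
  set.seed(31)
  mk <- function(n, label, off) data.frame(
    chrom = "chr1", start = off + (1:n) * 20L, end = off + (1:n) * 20L + 10L,
    strand = "+", pwm_score = rnorm(n), label = label,
    stringsAsFactors = FALSE)
  mpbs <- rbind(mk(100L, "bound", 0L), mk(300L, "unbound", 10000L))
  sp <- balance_and_split(mpbs, seed = 3L)
  counts <- vapply(sp, function(s) c(sum(s$label == "bound"),
                                     sum(s$label == "unbound")),
                   numeric(2))
  expect_equal(unname(counts), matrix(c(70, 70, 20, 20, 10, 10), 2))
  sp2 <- balance_and_split(mpbs, seed = 3L)
  expect_identical(sp, sp2)
  # tiny balanced input stays balanced in every split
  tiny <- rbind(mk(3L, "bound", 0L), mk(3L, "unbound", 10000L))
  spt <- balance_and_split(tiny, seed = 1L)
  for (s in spt)
    expect_equal(sum(s$label == "bound"), sum(s$label == "unbound"))
  # named errors on missing classes
  expect_error(balance_and_split(mk(5L, "bound", 0L)), "no unbound")
  expect_error(balance_and_split(mk(5L, "unbound", 0L)), "no bound")
})
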
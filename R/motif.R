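DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from a count (or probability) matrix
#'
#' Converts a 4 x L position frequency matrix into column probabilities
#' with a background-weighted pseudocount, and derives the log2-odds score
#' matrix against the background.
#'
#' @param counts 4 x L numeric matrix (rows A, C, G, T) of counts or
#'   probabilities.
#' @param name Motif name.
#' @param background Background base probabilities (length 4, sums to 1).
#' @param pseudocount Pseudocount added per column, spread by background
#'   (default 0.8). With `pseudocount = 0`, zero counts yield `-Inf`
#'   scores and the PWM is rejected by score-dependent operations.
#' @return An object of class `pwm` with elements `name`, `prob`,
#'   `score` (log2 odds), `background`, `pseudocount`, `length`.
#' @export
pwm_from_counts <- function(counts, name = "motif",
                            background = rep(0.25, 4), pseudocount = 0.8) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 1L, all(counts >= 0),
            length(background) == 4L, abs(sum(background) - 1) < 1e-6,
            pseudocount >= 0)
  rownames(counts) <- DNA_BASES
  tot <- colSums(counts)
  prob <- sweep(counts + pseudocount * background, 2L, tot + pseudocount, "/")
  score <- log2(prob / background)
  structure(list(name = name, prob = prob, score = score,
                 background = background, pseudocount = pseudocount,
                 length = ncol(counts)),
            class = "pwm")
}

#' Read a JASPAR-style PFM file
#'
#' Accepts the JASPAR text format (`>ID name` header, then four rows
#' `A [ 1 2 3 ]` ...) or a bare four-row numeric matrix.
#'
#' @param path PFM file.
#' @inheritParams pwm_from_counts
#' @return A `pwm` object.
#' @export
read_pfm <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- "motif"
  if (startsWith(lines[1], ">")) {
    name <- trimws(sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  if (length(lines) < 4L) stop("PFM needs 4 matrix rows", call. = FALSE)
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
    l <- gsub("\\[|\\]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  len <- unique(vapply(rows, length, 1L))
  if (length(len) != 1L) stop("ragged PFM rows", call. = FALSE)
  pwm_from_counts(do.call(rbind, rows), name = name,
                  background = background, pseudocount = pseudocount)
}

#' Write a PFM in JASPAR text format
#'
#' @param counts 4 x L count matrix or a `pwm` object (probabilities are
#'   written scaled by 100).
#' @param path Output file.
#' @param name Motif name for the header.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(counts, path, name = NULL) {
  if (inherits(counts, "pwm")) {
    name <- name %||% counts$name
    counts <- counts$prob * 100
  }
  name <- name %||% "motif"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", name), con)
  for (i in 1:4)
    writeLines(sprintf("%s  [ %s ]", DNA_BASES[i],
                       paste(format(counts[i, ], trim = TRUE),
                             collapse = " ")), con)
  invisible(path)
}

#' Motif-scan configuration
#'
#' @param pvalue Score-threshold p-value under the background model
#'   (default 1e-4).
#' @param score_granularity Bin width for the dynamic-programming score
#'   distribution used for long motifs (default 0.1 log2 units).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(pvalue = 1e-4, score_granularity = 0.1) {
  stopifnot(pvalue > 0, pvalue <= 1, score_granularity > 0)
  structure(list(pvalue = pvalue, score_granularity = score_granularity),
            class = "scan_config")
}

#' Score threshold for a PWM at a given p-value
#'
#' Computes the smallest achievable log2-odds score `t` such that the
#' probability that a random background L-mer scores at least `t` is at
#' most `config$pvalue`. For motifs up to 10 bp the full score
#' distribution is enumerated exactly by iterated convolution over
#' columns; longer motifs use a dynamic program over scores discretized at
#' `score_granularity` (threshold error bounded by the bin width).
#'
#' @param pwm A `pwm` object.
#' @param config A [scan_config()].
#' @param method `"auto"` (exact for motifs up to 10 bp, binned beyond),
#'   `"exact"`, or `"binned"`.
#' @return Numeric threshold. If even the best achievable score has tail
#'   probability above `pvalue`, a value just above the maximum achievable
#'   score is returned (no window can pass).
#' @export
pvalue_threshold <- function(pwm, config = scan_config(),
                             method = c("auto", "exact", "binned")) {
  method <- match.arg(method)
  S <- pwm$score
  if (any(!is.finite(S)))
    stop("degenerate PWM: non-finite log-odds scores (zero probability ",
         "with no pseudocount)", call. = FALSE)
  L <- ncol(S)
  bg <- pwm$background
  p <- config$pvalue
  if (method == "exact" || (method == "auto" && 4^L <= 2^20)) {
    v <- 0; pr <- 1
    for (j in seq_len(L)) {
      v <- as.vector(outer(v, S[, j], "+"))
      pr <- as.vector(outer(pr, bg, "*"))
    }
    o <- order(v, decreasing = TRUE)
    v <- v[o]; pr <- cumsum(pr[o])
    # tail probability of each distinct score = cumulative prob at its
    # last occurrence in the descending order
    grp_end <- which(c(v[-1] != v[-length(v)], TRUE))
    tailp <- pr[grp_end]
    scores <- v[grp_end]
    ok <- tailp <= p + 1e-12
    if (!any(ok)) return(scores[1] + 1e-9)
    return(min(scores[ok]))
  }
  # binned DP on integer-scaled scores
  g <- config$score_granularity
  q <- round(S / g)
  lo <- sum(apply(q, 2L, min)); hi <- sum(apply(q, 2L, max))
  dist <- c(1, numeric(hi - lo)) # index 1 <-> integer score `lo`
  cur_lo <- 0L
  for (j in seq_len(L)) {
    newlo <- cur_lo + min(q[, j])
    width <- length(dist) + (max(q[, j]) - min(q[, j]))
    nd <- numeric(width)
    for (b in 1:4) {
      sh <- q[b, j] - min(q[, j])
      nd[(1 + sh):(length(dist) + sh)] <-
        nd[(1 + sh):(length(dist) + sh)] + dist * bg[b]
    }
    dist <- nd
    cur_lo <- newlo
  }
  tailp <- rev(cumsum(rev(dist)))
  idx <- which(tailp <= p + 1e-12)
  if (!length(idx)) return((cur_lo + length(dist)) * g)
  (cur_lo + idx[1] - 1L) * g
}

seq_to_int <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA_BASES)
}

# score every window of an integer-coded sequence; NA where a window
# contains a non-ACGT base
score_windows <- function(ints, S) {
  L <- ncol(S)
  n <- length(ints)
  if (n < L) return(numeric(0))
  sc <- numeric(n - L + 1L)
  for (j in seq_len(L))
    sc <- sc + S[, j][ints[j:(n - L + j)]]
  sc
}

#' Scan sequences for motif-predicted binding sites
#'
#' Scores every window of every sequence on both strands with the PWM
#' log2-odds matrix and reports windows scoring at least `threshold`.
#' Windows containing non-ACGT characters are skipped. Minus-strand
#' matches are reported on forward-strand coordinates.
#'
#' @param genome Named character vector of sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param pwm A `pwm` object.
#' @param threshold Score threshold, typically from [pvalue_threshold()].
#' @return MPBS `data.frame`: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `pwm_score`, `label` (initialized to `"unlabeled"`).
#' @export
scan_pwm <- function(genome, pwm, threshold) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  S <- pwm$score
  L <- ncol(S)
  SR <- S[4:1, L:1, drop = FALSE] # reverse complement scoring matrix
  out <- list()
  for (ch in names(genome)) {
    ints <- seq_to_int(genome[[ch]])
    for (st in c("+", "-")) {
      sc <- score_windows(ints, if (st == "+") S else SR)
      hit <- which(!is.na(sc) & sc >= threshold)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = hit - 1L, end = hit - 1L + L, strand = st,
          pwm_score = sc[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      pwm_score = numeric(), label = character()))
  }
  mpbs <- do.call(rbind, out)
  mpbs <- mpbs[order(mpbs$chrom, mpbs$start, mpbs$strand), , drop = FALSE]
  rownames(mpbs) <- NULL
  mpbs$label <- "unlabeled"
  mpbs
}

#' Read / write narrowPeak files
#'
#' narrowPeak is BED6+4; the 10th column is the summit offset from
#' `start` (-1 when no summit was called). Coordinates 0-based half-open.
#'
#' @param path File path.
#' @return `data.frame` with the ten standard columns.
#' @export
read_narrowpeak <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "peak")
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 10L) stop("narrowPeak needs 10 columns", call. = FALSE)
  df <- as.data.frame(dt[, 1:10])
  names(df) <- cols
  df
}

#' @rdname read_narrowpeak
#' @param peaks `data.frame` with the ten narrowPeak columns.
#' @export
write_narrowpeak <- function(peaks, path) {
  data.table::fwrite(peaks, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Keep MPBSs inside open chromatin
#'
#' Retains MPBSs fully contained in an ATAC-seq peak interval.
#'
#' @param mpbs MPBS `data.frame` from [scan_pwm()].
#' @param peaks Peak `data.frame` with `chrom`, `start`, `end`.
#' @return Filtered MPBS `data.frame`.
#' @export
restrict_to_open <- function(mpbs, peaks) {
  if (!nrow(mpbs) || !nrow(peaks)) return(mpbs[integer(0), , drop = FALSE])
  keep <- logical(nrow(mpbs))
  for (ch in unique(mpbs$chrom)) {
    mi <- which(mpbs$chrom == ch)
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (!nrow(pk)) next
    q <- IRanges::IRanges(mpbs$start[mi] + 1L, mpbs$end[mi])
    s <- IRanges::IRanges(pk$start + 1L, pk$end)
    keep[mi] <- IRanges::overlapsAny(q, s, type = "within")
  }
  out <- mpbs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Labeling configuration
#'
#' @param summit_max_dist Maximum distance in bp between the highest
#'   ChIP-seq summit of a peak and the center of the MPBS labeled bound
#'   (default 50).
#' @return An object of class `label_config`.
#' @export
label_config <- function(summit_max_dist = 50L) {
  summit_max_dist <- as.integer(summit_max_dist)
  stopifnot(summit_max_dist >= 0L)
  structure(list(summit_max_dist = summit_max_dist), class = "label_config")
}

#' Label MPBSs as bound / unbound from ChIP-seq peaks and summits
#'
#' MPBSs whose centers fall outside every ChIP-seq peak are labeled
#' `unbound`. Within each peak, the single MPBS whose center is nearest
#' the peak's highest summit (ties broken toward the smaller coordinate)
#' and within `summit_max_dist` bp of it is labeled `bound`; all other
#' MPBSs inside the peak become `unlabeled` and are excluded from
#' datasets. MPBS centers are `floor((start + end) / 2)`. Peaks sharing
#' identical coordinates (multi-summit callers emit one row per summit)
#' are grouped, and the summit with the highest `signalValue` is used.
#'
#' @param mpbs MPBS `data.frame`.
#' @param chip_peaks narrowPeak `data.frame` ([read_narrowpeak()]); every
#'   peak must carry a summit offset (column `peak` >= 0).
#' @param config A [label_config()].
#' @return MPBS `data.frame` with `label` in
#'   `{"bound", "unbound", "unlabeled"}`.
#' @export
label_mpbs <- function(mpbs, chip_peaks, config = label_config()) {
  if (any(is.na(chip_peaks$peak)) || any(chip_peaks$peak < 0))
    stop("ChIP peak without summit", call. = FALSE)
  mpbs$label <- "unbound"
  if (!nrow(mpbs)) return(mpbs)
  center <- (mpbs$start + mpbs$end) %/% 2L
  # collapse duplicate peak intervals to their highest summit
  key <- paste(chip_peaks$chrom, chip_peaks$start, chip_peaks$end)
  ord <- order(key, -chip_peaks$signalValue, chip_peaks$start + chip_peaks$peak)
  pk <- chip_peaks[ord, , drop = FALSE]
  pk <- pk[!duplicated(paste(pk$chrom, pk$start, pk$end)), , drop = FALSE]
  pk$summit <- pk$start + pk$peak
  for (ch in unique(pk$chrom)) {
    pi <- which(pk$chrom == ch)
    mi <- which(mpbs$chrom == ch)
    if (!length(mi)) next
    q <- IRanges::IRanges(center[mi] + 1L, center[mi] + 1L)
    s <- IRanges::IRanges(pk$start[pi] + 1L, pk$end[pi])
    hits <- IRanges::findOverlaps(q, s, select = "first")
    inside <- which(!is.na(hits))
    if (!length(inside)) next
    mpbs$label[mi[inside]] <- "unlabeled"
    for (pj in unique(hits[inside])) {
      cand <- mi[inside[hits[inside] == pj]]
      d <- abs(center[cand] - pk$summit[pi[pj]])
      best <- cand[order(d, mpbs$start[cand])][1]
      if (min(d) <= config$summit_max_dist)
        mpbs$label[best] <- "bound"
    }
  }
  mpbs
}

#' Dataset split configuration
#'
#' @param train_frac,val_frac,test_frac Split fractions; must sum to 1
#'   (defaults 0.70 / 0.20 / 0.10).
#' @return An object of class `split_config`.
#' @export
split_config <- function(train_frac = 0.70, val_frac = 0.20,
                         test_frac = 0.10) {
  stopifnot(abs(train_frac + val_frac + test_frac - 1) < 1e-9,
            train_frac > 0, val_frac >= 0, test_frac >= 0)
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac), class = "split_config")
}

#' Balance bound/unbound MPBSs and split into train/val/test
#'
#' Randomly subsamples the majority class to the minority class size, then
#' assigns equal numbers of bound and unbound MPBSs to the train,
#' validation and test sets (fractions from `split`), so every emitted
#' split is exactly balanced. Deterministic for a fixed seed.
#'
#' @param mpbs Labeled MPBS `data.frame`; rows labeled `unlabeled` are
#'   dropped.
#' @param split A [split_config()].
#' @param seed Integer seed.
#' @return Named list of MPBS `data.frame`s: `train`, `val`, `test`.
#' @export
balance_and_split <- function(mpbs, split = split_config(), seed = 1L) {
  b <- mpbs[mpbs$label == "bound", , drop = FALSE]
  u <- mpbs[mpbs$label == "unbound", , drop = FALSE]
  if (!nrow(b)) stop("no bound MPBSs", call. = FALSE)
  if (!nrow(u)) stop("no unbound MPBSs", call. = FALSE)
  n <- min(nrow(b), nrow(u))
  with_seed(seed, {
    b <- b[sample.int(nrow(b), n), , drop = FALSE]
    u <- u[sample.int(nrow(u), n), , drop = FALSE]
  })
  n_tr <- floor(split$train_frac * n)
  n_va <- floor(split$val_frac * n)
  n_te <- n - n_tr - n_va
  cut3 <- function(df) {
    list(train = df[seq_len(n_tr), , drop = FALSE],
         val = df[seq_len(n_va) + n_tr, , drop = FALSE],
         test = df[seq_len(n_te) + n_tr + n_va, , drop = FALSE])
  }
  bs <- cut3(b); us <- cut3(u)
  out <- lapply(c(train = "train", val = "val", test = "test"), function(k) {
    x <- rbind(bs[[k]], us[[k]])
    rownames(x) <- NULL
    x
  })
  out
}
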
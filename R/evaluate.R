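#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly
#' chosen positive outscores a randomly chosen negative, ties counting
#' one half.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) class labels; both classes must be
#'   present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Footprint-score baseline
#'
#' Scores each MPBS by the mean footprint score over its own interval
#' `[start, end)` — the training-free baseline in which the footprint
#' statistic alone separates bound from unbound sites.
#'
#' @param mpbs MPBS `data.frame`.
#' @param fps_track Named list (by chromosome) of genome-wide per-base
#'   footprint-score vectors (position 1 = genomic position 0), e.g. from
#'   [footprint_scores()] on pooled [build_cut_tracks()] counts.
#' @return Numeric score per MPBS.
#' @export
fps_baseline_scores <- function(mpbs, fps_track) {
  vapply(seq_len(nrow(mpbs)), function(i) {
    tr <- fps_track[[mpbs$chrom[i]]]
    if (is.null(tr))
      stop("chromosome '", mpbs$chrom[i], "' absent from track",
           call. = FALSE)
    idx <- (mpbs$start[i] + 1L):mpbs$end[i]
    idx <- idx[idx >= 1L & idx <= length(tr)]
    if (!length(idx)) return(0)
    mean(tr[idx])
  }, numeric(1))
}

#' Genome-wide footprint-score track
#'
#' Pools the four cut channels per chromosome and computes
#' [footprint_scores()] over the full sequence.
#'
#' @param tracks A `cut_tracks` object.
#' @param config A [footprint_config()].
#' @return Named list of per-base footprint-score vectors.
#' @export
genome_fps_track <- function(tracks, config = footprint_config()) {
  lapply(tracks$tracks, function(tr)
    footprint_scores(colSums(tr$counts), config))
}

#' Footprint-overlap baseline scores
#'
#' Implements the rank construction used to score footprint-calling
#' methods that output footprint regions rather than per-site scores:
#' every MPBS keeps its PWM score, and MPBSs overlapping (>= 1 bp) any
#' footprint region have the maximum PWM score added, so every
#' overlapping MPBS outranks every non-overlapping one.
#'
#' @param mpbs MPBS `data.frame` carrying `pwm_score`.
#' @param footprint_regions `data.frame` with `chrom`, `start`, `end`
#'   (0-based half-open), possibly empty.
#' @return Numeric score per MPBS.
#' @export
footprint_overlap_scores <- function(mpbs, footprint_regions) {
  scores <- mpbs$pwm_score
  if (!nrow(footprint_regions) || !nrow(mpbs)) return(scores)
  mx <- max(scores)
  ov <- logical(nrow(mpbs))
  for (ch in unique(mpbs$chrom)) {
    mi <- which(mpbs$chrom == ch)
    fr <- footprint_regions[footprint_regions$chrom == ch, , drop = FALSE]
    if (!nrow(fr)) next
    q <- IRanges::IRanges(mpbs$start[mi] + 1L, mpbs$end[mi])
    s <- IRanges::IRanges(fr$start + 1L, fr$end)
    ov[mi] <- IRanges::overlapsAny(q, s)
  }
  scores + ifelse(ov, mx, 0)
}

#' Rank-based method comparison (Friedman-Nemenyi)
#'
#' For each transcription factor and replicate, methods are ranked by
#' AUROC (rank 1 = highest, ties get average ranks); ranks are averaged
#' over replicates per TF, and the per-TF mean ranks feed a Friedman test
#' across TFs with a Nemenyi post-hoc for pairwise method differences
#' (studentized-range reference distribution).
#'
#' @param results `data.frame` with columns `tf`, `method`, `replicate`,
#'   `auroc`; every (tf, method, replicate) cell must be present exactly
#'   once.
#' @return List: `mean_ranks` (`data.frame` of method, mean_rank, sem),
#'   `rank_matrix` (TF x method per-TF mean ranks), `friedman`
#'   (statistic, df, p_value), `nemenyi` (symmetric matrix of pairwise
#'   p-values).
#' @export
rank_compare <- function(results) {
  methods <- sort(unique(results$method))
  tfs <- sort(unique(results$tf))
  reps <- sort(unique(results$replicate))
  k <- length(methods)
  full <- expand.grid(tf = tfs, method = methods, replicate = reps,
                      stringsAsFactors = FALSE)
  got <- paste(results$tf, results$method, results$replicate)
  if (!all(paste(full$tf, full$method, full$replicate) %in% got) ||
      nrow(results) != nrow(full))
    stop("results must contain every (tf, method, replicate) cell exactly ",
         "once", call. = FALSE)
  # per (tf, replicate): rank methods, higher AUROC -> lower rank
  rank_mat <- matrix(0, length(tfs), k, dimnames = list(tfs, methods))
  for (tf in tfs) {
    acc <- numeric(k)
    for (rp in reps) {
      sub <- results[results$tf == tf & results$replicate == rp, ]
      sub <- sub[match(methods, sub$method), ]
      acc <- acc + rank(-sub$auroc, ties.method = "average")
    }
    rank_mat[tf, ] <- acc / length(reps)
  }
  mean_ranks <- data.frame(
    method = methods,
    mean_rank = colMeans(rank_mat),
    sem = apply(rank_mat, 2L, stats::sd) / sqrt(nrow(rank_mat)),
    row.names = NULL)
  fr <- stats::friedman.test(rank_mat)
  nb <- nrow(rank_mat)
  # Nemenyi: q = |Ri - Rj| / sqrt(k(k+1)/(6 n)) compared to the
  # studentized range with infinite df
  rr <- t(apply(rank_mat, 1L, rank, ties.method = "average"))
  rbar <- colMeans(rr)
  se <- sqrt(k * (k + 1) / (12 * nb))
  nem <- matrix(NA_real_, k, k, dimnames = list(methods, methods))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    nem[i, j] <- stats::ptukey(abs(rbar[i] - rbar[j]) / se,
                               nmeans = k, df = Inf, lower.tail = FALSE)
  list(mean_ranks = mean_ranks, rank_matrix = rank_mat,
       friedman = list(statistic = unname(fr$statistic),
                       df = unname(fr$parameter),
                       p_value = fr$p.value),
       nemenyi = nem)
}
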
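CHANNELS4 <- c("fwd_short", "rev_short", "fwd_long", "rev_long")

#' Cleavage signal processing configuration
#'
#' Knobs for the per-window normalization and slope computation applied to
#' raw cut counts before they enter the classifier: an optional `log1p`
#' transform, a centered boxcar smoother, min-max scaling within the
#' processing window, and the width of the centered least-squares window
#' used for slopes.
#'
#' @param smooth_window Odd boxcar width in bp (default 9).
#' @param slope_window Odd least-squares window in bp (default 9).
#' @param log_transform Apply `log1p` before smoothing (default TRUE).
#' @return An object of class `signal_config`.
#' @export
signal_config <- function(smooth_window = 9L, slope_window = 9L,
                          log_transform = TRUE) {
  smooth_window <- as.integer(smooth_window)
  slope_window <- as.integer(slope_window)
  stopifnot(smooth_window >= 3L, smooth_window %% 2L == 1L,
            slope_window >= 3L, slope_window %% 2L == 1L)
  structure(list(smooth_window = smooth_window, slope_window = slope_window,
                 log_transform = isTRUE(log_transform)),
            class = "signal_config")
}

#' Count Tn5 cuts in a region, by strand and fragment size
#'
#' Builds a 4 x width integer matrix of per-base cut counts over
#' `[start, end)` with channels `fwd_short`, `rev_short`, `fwd_long`,
#' `rev_long`. Each fragment contributes its left (forward-strand) cut at
#' `start` and its right (reverse-strand) cut at `end - 1`; cuts falling
#' outside the region are ignored.
#'
#' @param frags Fragment `data.frame` (see [read_fragments()]).
#' @param chrom Chromosome of the region.
#' @param start,end Region bounds, 0-based half-open.
#' @param config A [size_partition_config()].
#' @return An object of class `cut_matrix`: list with `chrom`, `start`,
#'   `end` and the `counts` matrix.
#' @export
count_cuts <- function(frags, chrom, start, end,
                       config = size_partition_config()) {
  stopifnot(end > start)
  w <- as.integer(end - start)
  counts <- matrix(0L, nrow = 4L, ncol = w, dimnames = list(CHANNELS4, NULL))
  f <- frags[frags$chrom == chrom, , drop = FALSE]
  if (nrow(f)) {
    cls <- size_class(f, config)
    left <- f$start
    right <- f$end - 1L
    for (k in c("short", "long")) {
      sel <- cls == k
      lf <- left[sel]; lf <- lf[lf >= start & lf < end]
      rt <- right[sel]; rt <- rt[rt >= start & rt < end]
      counts[paste0("fwd_", k), ] <- tabulate(lf - start + 1L, nbins = w)
      counts[paste0("rev_", k), ] <- tabulate(rt - start + 1L, nbins = w)
    }
  }
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), counts = counts),
            class = "cut_matrix")
}

#' Genome-wide cut-count tracks
#'
#' Convenience wrapper building one `cut_matrix` per chromosome covering
#' the whole sequence, used as the track store for window assembly.
#'
#' @param frags Fragment `data.frame`.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param config A [size_partition_config()].
#' @return An object of class `cut_tracks`: named list of `cut_matrix`
#'   objects plus the chromosome lengths.
#' @export
build_cut_tracks <- function(frags, chrom_lengths,
                             config = size_partition_config()) {
  tracks <- lapply(names(chrom_lengths), function(ch)
    count_cuts(frags, ch, 0L, chrom_lengths[[ch]], config))
  names(tracks) <- names(chrom_lengths)
  structure(list(tracks = tracks, chrom_lengths = chrom_lengths),
            class = "cut_tracks")
}

# centered boxcar mean with truncated windows at the track edges
boxcar_smooth <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Normalize a per-base count track
#'
#' `log1p` transform (optional), centered boxcar smoothing with truncated
#' edge windows, then min-max scaling within the track, mapping into
#' `[0, 1]`. A constant track (including all zeros) maps to all zeros.
#'
#' @param x Numeric per-base counts.
#' @param config A [signal_config()].
#' @return Numeric vector of the same length in `[0, 1]`.
#' @export
normalize_track <- function(x, config = signal_config()) {
  stopifnot(length(x) >= 1L)
  if (config$log_transform) x <- log1p(x)
  sm <- boxcar_smooth(x, config$smooth_window)
  r <- range(sm)
  # constant input (up to cumsum round-off) maps to all zeros
  if (r[2] - r[1] <= 1e-9 * max(1, abs(r[2]))) return(rep(0, length(x)))
  (sm - r[1]) / (r[2] - r[1])
}

#' Local slope of a signal track
#'
#' Centered least-squares linear slope over `slope_window` bases at each
#' position; edge positions (and degenerate tracks shorter than the
#' window) use the available truncated window. The operator is
#' antisymmetric under signal reversal.
#'
#' @param x Numeric per-base signal (typically [normalize_track()] output).
#' @param config A [signal_config()].
#' @return Numeric vector of per-base slopes.
#' @export
slope_track <- function(x, config = signal_config()) {
  n <- length(x)
  w <- config$slope_window
  if (n < 2L) stop("track shorter than 2 bases", call. = FALSE)
  h <- (w - 1L) %/% 2L
  out <- numeric(n)
  edge_idx <- if (n >= w) c(seq_len(h), seq.int(n - h + 1L, n))
              else seq_len(n) # degenerate short track: truncate everywhere
  if (n >= w) {
    # interior: symmetric window, slope = sum(d * x[i+d]) / sum(d^2)
    d <- seq.int(-h, h)
    denom <- sum(d^2)
    # embed(x, w)[i, j] = x[i + w - j]; offset from center = w - j - h
    wts <- (w - seq_len(w) - h) / denom
    out[(h + 1L):(n - h)] <- as.vector(stats::embed(x, w) %*% wts)
  }
  # edges: truncated asymmetric window, general least-squares slope
  for (i in edge_idx) {
    idx <- max(1L, i - h):min(n, i + h)
    xs <- idx - mean(idx)
    out[i] <- sum(xs * x[idx]) / sum(xs^2)
  }
  out
}

#' Write a bedGraph track
#'
#' Run-length collapses consecutive equal values; coordinates are 0-based
#' half-open as per the format.
#'
#' @param chrom Chromosome name.
#' @param start 0-based start of the first value.
#' @param values Numeric per-base values.
#' @param path Output file.
#' @param name Track name for the track line (omit line if `NULL`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(chrom, start, values, path, name = NULL) {
  r <- rle(values)
  ends <- start + cumsum(r$lengths)
  starts <- ends - r$lengths
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(name))
    writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  writeLines(sprintf("%s\t%d\t%d\t%g", chrom, starts, ends, r$values), con)
  invisible(path)
}
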
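#' Footprint-score configuration
#'
#' Parameters of the flank-minus-center footprint statistic: a small sweep
#' of odd center widths (candidate footprint sizes) and the width of the
#' two flanking windows immediately outside the center.
#'
#' @param center_widths Odd integer center widths in bp (default
#'   `c(5, 7, 9, 11)`).
#' @param flank_width Flank width in bp on each side (default 30); must be
#'   at least the largest center width.
#' @return An object of class `footprint_config`.
#' @export
footprint_config <- function(center_widths = c(5L, 7L, 9L, 11L),
                             flank_width = 30L) {
  center_widths <- sort(as.integer(center_widths))
  flank_width <- as.integer(flank_width)
  stopifnot(all(center_widths >= 3L), all(center_widths %% 2L == 1L),
            flank_width >= max(center_widths))
  structure(list(center_widths = center_widths, flank_width = flank_width),
            class = "footprint_config")
}

#' Single-base footprint scores
#'
#' For each base and each center width `c`, the score is the mean count in
#' the two flanks of `flank_width` bp immediately outside the centered
#' `c`-bp window minus the mean count inside that window. The final score
#' is the maximum over center widths, floored at zero, so protected
#' (depleted) positions score high and accessible or flat positions score
#' zero. Edge positions use the available truncated windows. Scores are
#' computed on raw strand- and size-pooled counts.
#'
#' @param x Numeric per-base aggregate cut counts.
#' @param config A [footprint_config()].
#' @return Numeric vector of non-negative per-base footprint scores.
#' @export
footprint_scores <- function(x, config = footprint_config()) {
  n <- length(x)
  fw <- config$flank_width
  if (n < 2L * fw + max(config$center_widths))
    stop("track shorter than 2*flank_width + max center width",
         call. = FALSE)
  cs <- c(0, cumsum(x))
  rngsum <- function(lo, hi) {
    lo2 <- pmax(lo, 1L)
    hi2 <- pmin(hi, n)
    len <- pmax(hi2 - lo2 + 1L, 0L)
    s <- numeric(length(lo))
    ok <- len > 0L
    s[ok] <- cs[hi2[ok] + 1L] - cs[lo2[ok]]
    list(sum = s, len = len)
  }
  i <- seq_len(n)
  best <- rep(-Inf, n)
  for (cw in config$center_widths) {
    hc <- (cw - 1L) %/% 2L
    ctr <- rngsum(i - hc, i + hc)
    fl <- rngsum(i - hc - fw, i - hc - 1L)
    fr <- rngsum(i + hc + 1L, i + hc + fw)
    flank_len <- fl$len + fr$len
    flank_mean <- ifelse(flank_len > 0L, (fl$sum + fr$sum) / flank_len, 0)
    score <- flank_mean - ctr$sum / ctr$len
    best <- pmax(best, score)
  }
  pmax(best, 0)
}
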
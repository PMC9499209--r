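LAYOUTS <- c("default", "variant1", "variant2", "variant3", "variant4")

#' Channel count of an input layout
#'
#' Input layouts: `default` = footprint scores + 4 cleavage signal + 4
#' slope channels (9); `variant1` drops the footprint row (8); `variant2`
#' keeps only the footprint row (1); `variant3` pools read strands before
#' normalization (footprint + 2 signal + 2 slope = 5); `variant4` pools
#' fragment sizes (5).
#'
#' @param layout One of `"default"`, `"variant1"` ... `"variant4"`.
#' @return Integer channel count.
#' @export
layout_channels <- function(layout) {
  layout <- match.arg(layout, LAYOUTS)
  c(default = 9L, variant1 = 8L, variant2 = 1L, variant3 = 5L,
    variant4 = 5L)[[layout]]
}

# raw 4-channel counts for [lo, hi) with zero padding outside the
# chromosome; returns list(counts, clipped)
extract_counts <- function(tracks, chrom, lo, hi) {
  tr <- tracks$tracks[[chrom]]
  if (is.null(tr))
    stop("chromosome '", chrom, "' absent from tracks", call. = FALSE)
  len <- ncol(tr$counts)
  w <- hi - lo
  out <- matrix(0, nrow = 4L, ncol = w, dimnames = list(CHANNELS4, NULL))
  a <- max(lo, 0L); b <- min(hi, len)
  if (b > a)
    out[, (a - lo + 1L):(b - lo)] <- tr$counts[, (a + 1L):b, drop = FALSE]
  list(counts = out, clipped = lo < 0L || hi > len)
}

#' Assemble the classifier input window for one MPBS
#'
#' Builds the `C x W` float matrix fed to the classifier for one site:
#' per-base footprint scores on pooled raw counts, plus normalized
#' cleavage signal and slope tracks per strand/size channel, all computed
#' on the window `[center - window_half, center + window_half)` with
#' `center = floor((start + end) / 2)`. Counts are extracted with a pad of
#' `flank_width + max(center_widths)` bp on each side so footprint-score
#' flanks near the window edges see real data; cleavage channels are
#' normalized within the window itself (the per-MPBS window is the
#' processing unit). Windows extending past a chromosome end are
#' zero-padded and flagged via attribute `"clipped"`.
#'
#' Strand-pooled (`variant3`) and size-pooled (`variant4`) layouts sum raw
#' counts across the pooled axis before normalization, and slopes are
#' recomputed from the pooled, normalized signal.
#'
#' @param mpbs Single-row MPBS `data.frame` (or list with `chrom`,
#'   `start`, `end`).
#' @param tracks A `cut_tracks` object from [build_cut_tracks()].
#' @param layout Input layout, see [layout_channels()].
#' @param window_half Half window width in bp (default 500, the 9x1000
#'   default input; smaller values give the shortened-window variants).
#' @param sig_config A [signal_config()].
#' @param fp_config A [footprint_config()].
#' @return `C x W` numeric matrix of class `signal_window` with
#'   attributes `layout`, `window_half`, `clipped`, `mpbs_id`.
#' @export
assemble_window <- function(mpbs, tracks, layout = "default",
                            window_half = 500L,
                            sig_config = signal_config(),
                            fp_config = footprint_config()) {
  layout <- match.arg(layout, LAYOUTS)
  window_half <- as.integer(window_half)
  stopifnot(window_half >= 1L)
  chrom <- as.character(mpbs$chrom[1])
  center <- (as.integer(mpbs$start[1]) + as.integer(mpbs$end[1])) %/% 2L
  w <- 2L * window_half
  pad <- fp_config$flank_width + max(fp_config$center_widths)
  ext <- extract_counts(tracks, chrom, center - window_half - pad,
                        center + window_half + pad)
  core <- (pad + 1L):(pad + w)
  fps <- footprint_scores(colSums(ext$counts), fp_config)[core]
  raw <- ext$counts[, core, drop = FALSE]
  sig_slope <- function(m) {
    sig <- t(apply(m, 1L, normalize_track, config = sig_config))
    slo <- t(apply(sig, 1L, slope_track, config = sig_config))
    rbind(sig, slo)
  }
  x <- switch(layout,
    default = rbind(fps = fps, sig_slope(raw)),
    variant1 = sig_slope(raw),
    variant2 = rbind(fps = fps),
    variant3 = rbind(fps = fps, sig_slope(rbind(
      short = raw["fwd_short", ] + raw["rev_short", ],
      long = raw["fwd_long", ] + raw["rev_long", ]))),
    variant4 = rbind(fps = fps, sig_slope(rbind(
      fwd = raw["fwd_short", ] + raw["fwd_long", ],
      rev = raw["rev_short", ] + raw["rev_long", ]))))
  structure(x, class = "signal_window", layout = layout,
            window_half = window_half, clipped = ext$clipped,
            mpbs_id = mpbs_id(mpbs))
}

mpbs_id <- function(mpbs) {
  paste0(mpbs$chrom, ":", mpbs$start, "-", mpbs$end, ":",
         mpbs$strand %||% "+")
}

#' Assemble input tensors for a set of MPBSs
#'
#' Applies [assemble_window()] to every MPBS row and stacks the results
#' into a `C x W x n` array, with a manifest describing each slice.
#'
#' @inheritParams assemble_window
#' @param mpbs MPBS `data.frame` with a `label` column.
#' @return Object of class `signal_dataset`: list with `x` (array
#'   `C x W x n`), `y` (0/1 numeric, 1 = bound, NA for unlabeled),
#'   `manifest` (`data.frame`), `layout`, `window_half`.
#' @export
assemble_dataset <- function(mpbs, tracks, layout = "default",
                             window_half = 500L,
                             sig_config = signal_config(),
                             fp_config = footprint_config()) {
  layout <- match.arg(layout, LAYOUTS)
  n <- nrow(mpbs)
  C <- layout_channels(layout)
  w <- 2L * as.integer(window_half)
  x <- array(0, dim = c(C, w, n))
  clipped <- logical(n)
  for (i in seq_len(n)) {
    win <- assemble_window(mpbs[i, ], tracks, layout, window_half,
                           sig_config, fp_config)
    x[, , i] <- win
    clipped[i] <- attr(win, "clipped")
  }
  lab <- mpbs$label %||% rep("unlabeled", n)
  manifest <- data.frame(mpbs_id = mpbs_id(mpbs), chrom = mpbs$chrom,
                         start = mpbs$start, end = mpbs$end,
                         strand = mpbs$strand %||% "+",
                         pwm_score = mpbs$pwm_score %||% NA_real_,
                         label = lab, clipped = clipped,
                         stringsAsFactors = FALSE)
  y <- ifelse(lab == "bound", 1, ifelse(lab == "unbound", 0, NA))
  structure(list(x = x, y = y, manifest = manifest, layout = layout,
                 window_half = as.integer(window_half)),
            class = "signal_dataset")
}
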
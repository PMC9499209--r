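#' Fragment size-partition configuration
#'
#' Parameters controlling how paired-end ATAC-seq fragments are shifted to
#' Tn5 insertion centers and partitioned into sub-nucleosomal ("short") and
#' nucleosome-spanning ("long") size classes. The canonical nucleosomal DNA
#' length of 147 bp is the default cutoff; fragments of exactly one
#' nucleosome length count as short (the cutoff is inclusive). The +4/-5
#' offsets are the standard ATAC-seq correction moving read 5' ends to the
#' transposase dyad.
#'
#' @param nucleosome_bp Size cutoff in bp; fragments with
#'   `size <= nucleosome_bp` are "short".
#' @param shift_forward Shift (bp) applied to the forward-strand cut when
#'   reading BAM input.
#' @param shift_reverse Shift (bp) applied to the reverse-strand cut
#'   (1-past coordinate) when reading BAM input.
#' @return An object of class `size_partition_config`.
#' @export
size_partition_config <- function(nucleosome_bp = 147L, shift_forward = 4L,
                                  shift_reverse = -5L) {
  nucleosome_bp <- as.integer(nucleosome_bp)
  stopifnot(nucleosome_bp > 0L)
  structure(list(nucleosome_bp = nucleosome_bp,
                 shift_forward = as.integer(shift_forward),
                 shift_reverse = as.integer(shift_reverse)),
            class = "size_partition_config")
}

#' Read paired-end ATAC-seq fragments
#'
#' Reads fragments either from a coordinate-sorted, indexed BAM of properly
#' paired reads or from a BED3+ file of fragment intervals. From BAM, one
#' fragment is emitted per proper pair (taken from the leftmost mate), with
#' the forward-strand cut shifted by `config$shift_forward` and the
#' reverse-strand cut (1-past coordinate) by `config$shift_reverse` before
#' the interval is constructed. BED intervals are taken verbatim and
#' assumed to be pre-shifted. All coordinates are 0-based half-open; a
#' fragment's two Tn5 cut sites are `start` (forward) and `end - 1`
#' (reverse).
#'
#' Unpaired, secondary, supplementary and duplicate-flagged BAM records and
#' records below `min_mapq` are skipped; the number of skipped records is
#' attached as attribute `"skipped"`.
#'
#' @param path BAM (`.bam`) or BED file of fragments.
#' @param config A [size_partition_config()].
#' @param min_mapq Minimum mapping quality for BAM records (default 30).
#' @param exclude_chroms Chromosome names to drop (default none).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `size`.
#' @export
read_fragments <- function(path, config = size_partition_config(),
                           min_mapq = 30, exclude_chroms = character()) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    frags <- read_fragments_bam(path, config, min_mapq)
  } else {
    frags <- read_fragments_bed(path)
  }
  if (length(exclude_chroms)) {
    keep <- !(frags$chrom %in% exclude_chroms)
    skipped <- attr(frags, "skipped")
    frags <- frags[keep, , drop = FALSE]
    rownames(frags) <- NULL
    attr(frags, "skipped") <- skipped
  }
  frags
}

read_fragments_bam <- function(path, config, min_mapq) {
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq,
                                   what = c("rname", "pos", "isize"))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  total <- Rsamtools::countBam(path)$records
  keep <- !is.na(res$isize) & res$isize > 0L & !is.na(res$pos)
  # 0-based fragment: forward cut = pos0 + shift_forward,
  # reverse cut = (pos0 + isize) + shift_reverse; interval spans both cuts.
  pos0 <- res$pos[keep] - 1L
  start <- pos0 + config$shift_forward
  end <- pos0 + res$isize[keep] + config$shift_reverse + 1L
  frags <- data.frame(chrom = as.character(res$rname[keep]),
                      start = start, end = end, size = end - start,
                      stringsAsFactors = FALSE)
  bad <- frags$size < 1L
  frags <- frags[!bad, , drop = FALSE]
  rownames(frags) <- NULL
  # every emitted fragment accounts for two records (the proper pair)
  attr(frags, "skipped") <- total - 2L * nrow(frags)
  frags
}

read_fragments_bed <- function(path) {
  if (file.size(path) == 0) {
    frags <- data.frame(chrom = character(), start = integer(),
                        end = integer(), size = integer())
    attr(frags, "skipped") <- 0L
    return(frags)
  }
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = 1)),
    error = function(e) stop("failed to parse BED file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0L) {
    frags <- data.frame(chrom = character(), start = integer(),
                        end = integer(), size = integer())
    attr(frags, "skipped") <- 0L
    return(frags)
  }
  if (ncol(dt) < 3L)
    stop("BED fragment file needs >= 3 columns", call. = FALSE)
  start <- suppressWarnings(as.integer(dt[[2]]))
  end <- suppressWarnings(as.integer(dt[[3]]))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad))
    stop("malformed BED line ", bad[1], " in '", path, "'", call. = FALSE)
  frags <- data.frame(chrom = as.character(dt[[1]]), start = start,
                      end = end, size = end - start,
                      stringsAsFactors = FALSE)
  attr(frags, "skipped") <- 0L
  frags
}

#' Classify fragments by size
#'
#' Partitions fragments into `"short"` (`size <= nucleosome_bp`, i.e. at
#' most one nucleosome length) and `"long"` classes.
#'
#' @param x A fragment `data.frame` from [read_fragments()] or a numeric
#'   vector of fragment sizes.
#' @param config A [size_partition_config()].
#' @return A factor with levels `c("short", "long")`.
#' @export
size_class <- function(x, config = size_partition_config()) {
  size <- if (is.data.frame(x)) x$size else x
  factor(ifelse(size <= config$nucleosome_bp, "short", "long"),
         levels = c("short", "long"))
}

#' Downsample fragments
#'
#' Uniform random subsample without replacement, deterministic for a fixed
#' seed. Emulates sequencing-depth reduction experiments. If `target_n` is
#' at least the number of fragments, all fragments are returned unchanged.
#'
#' @param frags Fragment `data.frame`.
#' @param target_n Number of fragments to keep.
#' @param seed Integer seed.
#' @return Fragment `data.frame` with `target_n` rows (or fewer if the
#'   input is smaller), in original coordinate order.
#' @export
downsample_fragments <- function(frags, target_n, seed = 1L) {
  stopifnot(target_n >= 0)
  n <- nrow(frags)
  if (target_n >= n) return(frags)
  idx <- with_seed(seed, sort(sample.int(n, target_n)))
  out <- frags[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- attr(frags, "skipped")
  out
}
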
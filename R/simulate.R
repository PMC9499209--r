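#' Simulation configuration
#'
#' Describes a fully synthetic ATAC-seq world on one chromosome: a random
#' background genome with one motif consensus planted per site, open
#' chromatin peaks around every site, paired-end fragments whose two Tn5
#' cuts follow a uniform rate inside peaks, a protection ("footprint")
#' that multiplies the cut rate by `footprint_depth` within
#' `footprint_halfwidth` bp of bound-site centers only, an optional
#' CTCF-like strand-asymmetric excess of forward-strand cuts 10-30 bp
#' upstream of bound centers, a bimodal fragment-size mixture straddling
#' one nucleosome length, and ChIP-seq peaks/summits centered (plus
#' jitter) on the bound sites.
#'
#' @param genome_len Chromosome length in bp (default 1.2e6, enough for
#'   600 sites spaced ~2 kb apart).
#' @param n_bound,n_unbound Planted bound / unbound site counts
#'   (defaults 300 / 300).
#' @param background_cut_rate Expected cuts per bp inside ATAC peaks
#'   (default 0.5).
#' @param footprint_depth Cut-rate multiplier inside bound motifs, in
#'   `[0, 1]`; 0 = full protection, 1 = no footprint (default 0.2).
#' @param footprint_halfwidth Protection half-width in bp (default 10).
#' @param strand_asymmetry Fraction of `background_cut_rate` added as
#'   extra forward-strand cuts in `[center - 30, center - 10]` of bound
#'   sites (default 0).
#' @param frac_short Fraction of fragments at most one nucleosome long
#'   (default 0.6).
#' @param size_params Named vector `short_mean`, `long_mean`, `sd` of the
#'   fragment-size mixture in bp (default 70 / 250 / 25).
#' @param chip_noise_bp Gaussian jitter sd of ChIP summits in bp
#'   (default 0).
#' @param peak_halfwidth ATAC peak half-width around each site
#'   (default 500).
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_len = 1200000L, n_bound = 300L,
                       n_unbound = 300L, background_cut_rate = 0.5,
                       footprint_depth = 0.2, footprint_halfwidth = 10L,
                       strand_asymmetry = 0, frac_short = 0.6,
                       size_params = c(short_mean = 70, long_mean = 250,
                                       sd = 25),
                       chip_noise_bp = 0, peak_halfwidth = 500L,
                       seed = 1L) {
  stopifnot(background_cut_rate >= 0, footprint_depth >= 0,
            footprint_depth <= 1, strand_asymmetry >= 0,
            strand_asymmetry <= 1, frac_short >= 0, frac_short <= 1,
            n_bound >= 0, n_unbound >= 0, chip_noise_bp >= 0)
  structure(list(genome_len = as.integer(genome_len),
                 n_bound = as.integer(n_bound),
                 n_unbound = as.integer(n_unbound),
                 background_cut_rate = background_cut_rate,
                 footprint_depth = footprint_depth,
                 footprint_halfwidth = as.integer(footprint_halfwidth),
                 strand_asymmetry = strand_asymmetry,
                 frac_short = frac_short, size_params = size_params,
                 chip_noise_bp = chip_noise_bp,
                 peak_halfwidth = as.integer(peak_halfwidth),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# built-in 12-bp synthetic motif (strong consensus, 85:5:5:5 counts)
sim_pfm_counts <- function() {
  consensus <- c("T", "G", "C", "C", "A", "C", "C", "T", "A", "G", "G", "T")
  counts <- matrix(5, 4, length(consensus), dimnames = list(DNA_BASES, NULL))
  counts[cbind(match(consensus, DNA_BASES), seq_along(consensus))] <- 85
  counts
}

rfrag_sizes <- function(m, cfg) {
  sp <- cfg$size_params
  short <- stats::runif(m) < cfg$frac_short
  sz <- integer(m)
  sz[short] <- pmin(pmax(round(stats::rnorm(sum(short), sp[["short_mean"]],
                                            sp[["sd"]])), 20L), 147L)
  sz[!short] <- pmax(round(stats::rnorm(sum(!short), sp[["long_mean"]],
                                        sp[["sd"]])), 148L)
  sz
}

#' Simulate a synthetic ATAC-seq experiment
#'
#' Generates and writes the complete set of files needed to exercise the
#' pipeline end-to-end: genome FASTA, pre-shifted fragment BED, ATAC and
#' ChIP narrowPeak files, a truth table of planted sites, and the planted
#' motif PFM. Byte-identical output for a fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created).
#' @return List with file paths (`genome`, `fragments`, `atac_peaks`,
#'   `chip_peaks`, `truth`, `pfm`), the `truth` `data.frame`, the `pwm`,
#'   the chromosome name and its length, invisibly usable in-memory.
#' @export
simulate_atac <- function(config = sim_config(), dir = tempfile("sim")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chrom <- "chrSim"
  counts <- sim_pfm_counts()
  pwm <- pwm_from_counts(counts, name = "SIM1 synthetic")
  L <- ncol(counts)
  out <- with_seed(config$seed, {
    glen <- config$genome_len
    n_tot <- config$n_bound + config$n_unbound
    margin <- 2500L
    spacing <- (glen - 2L * margin) %/% n_tot
    if (spacing < 1500L)
      stop("genome too short for the requested number of sites",
           call. = FALSE)
    centers <- margin + spacing * (seq_len(n_tot) - 1L) + spacing %/% 2L
    bound <- logical(n_tot)
    bound[sample.int(n_tot, config$n_bound)] <- TRUE

    genome_chars <- sample(DNA_BASES, glen, replace = TRUE)
    consensus <- DNA_BASES[apply(counts, 2L, which.max)]
    mstart <- centers - (L %/% 2L) # 0-based motif start
    for (i in seq_len(n_tot))
      genome_chars[(mstart[i] + 1L):(mstart[i] + L)] <- consensus

    ph <- config$peak_halfwidth
    # fragments: left cuts uniform over the widened peak, sizes from the
    # bimodal mixture, right cut = left + size - 1
    ext <- 700L
    lefts <- integer(0); sizes <- integer(0)
    rate <- config$background_cut_rate
    for (i in seq_len(n_tot)) {
      m <- stats::rpois(1L, rate * (2L * ext) / 2)
      lf <- centers[i] - ext + sample.int(2L * ext, m, replace = TRUE) - 1L
      sz <- rfrag_sizes(m, config)
      if (bound[i]) {
        # thin fragments with cuts inside the protected zone
        zlo <- centers[i] - config$footprint_halfwidth
        zhi <- centers[i] + config$footprint_halfwidth
        rt <- lf + sz - 1L
        nprot <- (lf >= zlo & lf <= zhi) + (rt >= zlo & rt <= zhi)
        keep <- stats::runif(m) < config$footprint_depth^nprot
        lf <- lf[keep]; sz <- sz[keep]
        if (config$strand_asymmetry > 0) {
          me <- stats::rpois(1L, config$strand_asymmetry * rate * 21)
          lfe <- centers[i] - 30L + sample.int(21L, me, replace = TRUE) - 1L
          sze <- rfrag_sizes(me, config)
          lf <- c(lf, lfe); sz <- c(sz, sze)
        }
      }
      lefts <- c(lefts, lf); sizes <- c(sizes, sz)
    }
    # sparse genome-wide background outside peaks (5% of the peak rate)
    mbg <- stats::rpois(1L, 0.05 * rate * glen / 2)
    lbg <- sample.int(glen, mbg, replace = TRUE) - 1L
    sbg <- rfrag_sizes(mbg, config)
    lefts <- c(lefts, lbg); sizes <- c(sizes, sbg)
    keep <- lefts >= 0L & (lefts + sizes) <= glen
    frags <- data.frame(chrom = chrom, start = lefts[keep],
                        end = lefts[keep] + sizes[keep],
                        stringsAsFactors = FALSE)
    frags <- frags[order(frags$start, frags$end), , drop = FALSE]
    rownames(frags) <- NULL

    atac <- data.frame(chrom = chrom, start = centers - ph,
                       end = centers + ph,
                       name = sprintf("atac_peak_%d", seq_len(n_tot)),
                       score = 1000L, strand = ".",
                       signalValue = 10, pValue = -1, qValue = -1,
                       peak = ph, stringsAsFactors = FALSE)
    bc <- centers[bound]
    jit <- round(stats::rnorm(length(bc), 0, config$chip_noise_bp))
    chip <- data.frame(chrom = chrom, start = bc - 150L, end = bc + 150L,
                       name = sprintf("chip_peak_%d", seq_along(bc)),
                       score = 1000L, strand = ".",
                       signalValue = round(stats::runif(length(bc), 50, 100),
                                           3),
                       pValue = -1, qValue = -1,
                       peak = pmin(pmax(150L + jit, 0L), 299L),
                       stringsAsFactors = FALSE)
    truth <- data.frame(chrom = chrom, start = mstart, end = mstart + L,
                        center = centers,
                        label = ifelse(bound, "bound", "unbound"),
                        stringsAsFactors = FALSE)
    list(genome = paste(genome_chars, collapse = ""), frags = frags,
         atac = atac, chip = chip, truth = truth)
  })
  paths <- list(genome = file.path(dir, "genome.fa"),
                fragments = file.path(dir, "fragments.bed"),
                atac_peaks = file.path(dir, "atac_peaks.narrowPeak"),
                chip_peaks = file.path(dir, "chip_peaks.narrowPeak"),
                truth_tsv = file.path(dir, "truth.tsv"),
                pfm = file.path(dir, "motif.pfm"))
  seqs <- Biostrings::DNAStringSet(stats::setNames(out$genome, chrom))
  Biostrings::writeXStringSet(seqs, paths$genome)
  data.table::fwrite(out$frags, paths$fragments, sep = "\t",
                     col.names = FALSE)
  write_narrowpeak(out$atac, paths$atac_peaks)
  write_narrowpeak(out$chip, paths$chip_peaks)
  data.table::fwrite(out$truth, paths$truth_tsv, sep = "\t")
  write_pfm(sim_pfm_counts(), paths$pfm, name = "SIM1 synthetic")
  c(paths, list(truth = out$truth, pwm = pwm, chrom = chrom,
                chrom_length = config$genome_len,
                fragments_df = out$frags, atac = out$atac,
                chip = out$chip, dir = dir))
}

#' Aggregate metaprofile of signal windows
#'
#' Position-wise mean of window values per channel, per group — the
#' metagene-style aggregate used to inspect footprint depletion and
#' strand asymmetry in simulated or labeled data.
#'
#' @param x `C x W x n` array of windows (e.g. raw counts or a
#'   `signal_dataset$x`).
#' @param groups Factor/character of length `n` grouping the windows.
#' @return Named list of `C x W` mean matrices, one per group level.
#' @export
metaprofile <- function(x, groups) {
  stopifnot(length(groups) == dim(x)[3], dim(x)[3] >= 1L)
  groups <- as.factor(groups)
  out <- lapply(levels(groups), function(g) {
    idx <- which(groups == g)
    if (!length(idx)) return(NULL)
    apply(x[, , idx, drop = FALSE], c(1L, 2L), mean)
  })
  names(out) <- levels(groups)
  out[!vapply(out, is.null, logical(1))]
}
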
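# scaled-down worlds keep the suite fast; rates and structure match the
# generator's defaults
small_sim <- function(...) {
  sim_config(genome_len = 200000L, n_bound = 40L, n_unbound = 40L, ...)
}

test_that("simulation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_atac(small_sim(seed = 9L), d1)
  s2 <- simulate_atac(small_sim(seed = 9L), d2)
  for (f in c("genome", "fragments", "atac_peaks", "chip_peaks",
              "truth_tsv", "pfm"))
    expect_identical(unname(tools::md5sum(s1[[f]])),
                     unname(tools::md5sum(s2[[f]])), label = f)
  s3 <- simulate_atac(small_sim(seed = 10L), withr::local_tempdir())
  expect_false(identical(unname(tools::md5sum(s1$fragments)),
                         unname(tools::md5sum(s3$fragments))))
})

test_that("truth, peaks and planted motifs are mutually consistent", {
  sim <- simulate_atac(small_sim(seed = 11L), withr::local_tempdir())
  truth <- sim$truth
  chip <- sim$chip
  bound <- truth[truth$label == "bound", ]
  unbound <- truth[truth$label == "unbound", ]
  expect_equal(nrow(bound), 40L)
  # every ChIP peak contains exactly one bound site and no unbound site
  expect_equal(nrow(chip), nrow(bound))
  for (i in seq_len(nrow(chip))) {
    inside_b <- bound$center >= chip$start[i] & bound$center < chip$end[i]
    inside_u <- unbound$center >= chip$start[i] &
      unbound$center < chip$end[i]
    expect_equal(sum(inside_b), 1L)
    expect_equal(sum(inside_u), 0L)
  }
  # the consensus is really planted at every truth site
  genome <- as.character(Biostrings::readDNAStringSet(sim$genome))[[1]]
  consensus <- paste(c("A", "C", "G", "T")[apply(
    footprintCNN:::sim_pfm_counts(), 2, which.max)], collapse = "")
  for (i in sample.int(nrow(truth), 10))
    expect_equal(substr(genome, truth$start[i] + 1L, truth$end[i]),
                 consensus)
})

test_that("fragment sizes follow the bimodal mixture", {
  sim <- simulate_atac(small_sim(seed = 12L), withr::local_tempdir())
  fr <- read_fragments(sim$fragments)
  short_frac <- mean(fr$size <= 147)
  n <- nrow(fr)
  expect_lt(abs(short_frac - 0.6), 3 * sqrt(0.6 * 0.4 / n) + 0.01)
  # the two modes straddle one nucleosome length
  expect_gt(mean(fr$size[fr$size > 147]), 200)
  expect_lt(mean(fr$size[fr$size <= 147]), 120)
})

test_that("full protection empties bound motifs of cuts", {
  sim <- simulate_atac(small_sim(seed = 13L, footprint_depth = 0),
                       withr::local_tempdir())
  fr <- read_fragments(sim$fragments)
  tracks <- build_cut_tracks(fr, setNames(200000L, sim$chrom))
  pooled <- colSums(tracks$tracks[[sim$chrom]]$counts)
  bound <- sim$truth[sim$truth$label == "bound", ]
  core <- unlist(lapply(bound$center, function(ct) (ct - 8L):(ct + 8L)))
  flank <- unlist(lapply(bound$center, function(ct)
    c((ct - 200L):(ct - 100L), (ct + 100L):(ct + 200L))))
  expect_lt(mean(pooled[core + 1L]), 0.05 * mean(pooled[flank + 1L]))
})

test_that("no footprint means indistinguishable cut profiles", {
  sim <- simulate_atac(small_sim(seed = 14L, footprint_depth = 1),
                       withr::local_tempdir())
  fr <- read_fragments(sim$fragments)
  tracks <- build_cut_tracks(fr, setNames(200000L, sim$chrom))
  raw <- array(0, c(1L, 200L, nrow(sim$truth)))
  for (i in seq_len(nrow(sim$truth))) {
    ct <- sim$truth$center[i]
    raw[1, , i] <- colSums(
      footprintCNN:::extract_counts(tracks, sim$chrom, ct - 100L,
                                    ct + 100L)$counts)
  }
  prof <- metaprofile(raw, sim$truth$label)
  ks <- suppressWarnings(stats::ks.test(prof$bound[1, ],
                                        prof$unbound[1, ]))
  expect_gt(ks$p.value, 0.01)
})

test_that("metaprofile reduces to identity and averages correctly", {
  x <- array(seq_len(2 * 5), c(2, 5, 1))
  expect_equal(metaprofile(x, "a")$a, x[, , 1])
  x2 <- array(c(x[, , 1], x[, , 1]), c(2, 5, 2))
  expect_equal(metaprofile(x2, c("a", "a"))$a, x[, , 1])
  # planted depletion separates bound and unbound aggregate profiles
  sim <- simulate_atac(small_sim(seed = 15L), withr::local_tempdir())
  fr <- read_fragments(sim$fragments)
  tracks <- build_cut_tracks(fr, setNames(200000L, sim$chrom))
  raw <- array(0, c(1L, 200L, nrow(sim$truth)))
  for (i in seq_len(nrow(sim$truth))) {
    ct <- sim$truth$center[i]
    raw[1, , i] <- colSums(
      footprintCNN:::extract_counts(tracks, sim$chrom, ct - 100L,
                                    ct + 100L)$counts)
  }
  prof <- metaprofile(raw, sim$truth$label)
  center_idx <- 95:105
  flank_idx <- c(10:40, 160:190)
  expect_lt(mean(prof$bound[1, center_idx]),
            0.6 * mean(prof$bound[1, flank_idx]))
  expect_gt(mean(prof$unbound[1, center_idx]),
            0.7 * mean(prof$unbound[1, flank_idx]))
})

test_that("labeling recovers planted truth at zero ChIP jitter", {
  sim <- simulate_atac(small_sim(seed = 16L), withr::local_tempdir())
  genome <- Biostrings::readDNAStringSet(sim$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  thr <- pvalue_threshold(sim$pwm)
  mpbs <- scan_pwm(genome, sim$pwm, thr)
  mpbs <- restrict_to_open(mpbs, sim$atac)
  mpbs <- label_mpbs(mpbs, sim$chip)
  key <- paste(mpbs$chrom, mpbs$start, mpbs$strand)
  hit <- match(paste(sim$truth$chrom, sim$truth$start, "+"), key)
  expect_true(all(!is.na(hit)))
  agree <- mean(mpbs$label[hit] == sim$truth$label)
  expect_gte(agree, 0.95)
})
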
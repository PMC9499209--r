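# Full pipeline driver used by the acceptance tests: simulate -> scan ->
# restrict -> label -> balance/split -> assemble -> train -> predict.
acc_pipeline <- function(cfg, iterations = 10L, seed = 1L,
                         extra_layouts = character()) {
  sim <- simulate_atac(cfg, tempfile("acc"))
  genome <- Biostrings::readDNAStringSet(sim$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  thr <- pvalue_threshold(sim$pwm)
  mpbs <- scan_pwm(genome, sim$pwm, thr)
  mpbs <- restrict_to_open(mpbs, sim$atac)
  mpbs <- label_mpbs(mpbs, sim$chip)
  splits <- balance_and_split(mpbs, seed = seed)
  frags <- read_fragments(sim$fragments)
  tracks <- build_cut_tracks(frags,
                             stats::setNames(cfg$genome_len, sim$chrom))
  out <- list(sim = sim, tracks = tracks, splits = splits, mpbs = mpbs)
  for (lay in c("default", extra_layouts)) {
    tr <- assemble_dataset(splits$train, tracks, layout = lay)
    va <- assemble_dataset(splits$val, tracks, layout = lay)
    te <- assemble_dataset(splits$test, tracks, layout = lay)
    ens <- train_cnn(tr$x, tr$y, va$x, va$y,
                     config = train_config(max_iterations = iterations,
                                           seed = seed))
    p <- predict_ensemble(ens, te$x)
    out[[lay]] <- list(ensemble = ens, test = te, probs = p,
                       auroc = auroc(p, te$y))
  }
  out
}
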
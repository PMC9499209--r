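---
title: "Methods: classifying TF binding sites from ATAC-seq cleavage profiles"
author: "footprintCNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying TF binding sites from ATAC-seq cleavage profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

ATAC-seq measures chromatin accessibility: the Tn5 transposase inserts
preferentially into open chromatin, and each sequenced fragment records
two insertion ("cut") events, one at each end. A transcription factor
(TF) bound at its sequence motif shields a short stretch of DNA from
Tn5, leaving a local depletion of cuts — a *footprint* — inside an
otherwise accessible region. Classical footprinting tools score this
depletion directly; but many TFs leave shallow or strand-asymmetric
patterns that a single depletion statistic misses, and cut counts carry
a strong Tn5 sequence bias that those tools must first correct.

`footprintCNN` takes the alternative route: it encodes the cut profile
around each motif-predicted binding site (MPBS) into a multi-channel
per-base tensor — keeping footprint, strand and fragment-size
information separate — and lets a small supervised 1D convolutional
network learn whatever combination of footprint and non-footprint
features separates bound from unbound sites. Because the model learns
from the raw (uncorrected) encoding, no explicit Tn5 bias correction is
performed anywhere in the default path, and no correction hook is
provided.

## Signal model

For a site with center $c$ (the floor of the interval midpoint) the
default input is a $9 \times 1000$ matrix over the window
$[c-500, c+500)$:

* **Row 1 — footprint scores.** On strand- and size-pooled raw counts
  $x$, for each center width $w \in \{5,7,9,11\}$ the score at base $i$
  is the mean count in the two 30 bp flanks immediately outside the
  centered $w$-window minus the mean count inside it; the final score is
  the maximum over $w$, floored at 0. High where protection exists, 0 on
  flat or elevated signal. Computed on raw counts, so read depth scales
  the score linearly; depth effects are left to the learned model.
* **Rows 2–5 — normalized cleavage signal** for the four channels
  (forward/short, reverse/short, forward/long, reverse/long). A
  fragment's forward cut is its start, its reverse cut its last base;
  "short" means at most one nucleosome length (147 bp, inclusive).
  Each channel is `log1p`-transformed, boxcar-smoothed (9 bp, truncated
  at edges) and min–max scaled *within the window* — the per-MPBS window
  is the processing unit, so every site is encoded on a comparable
  $[0,1]$ scale regardless of local depth.
* **Rows 6–9 — slopes** of the normalized signals: centered
  least-squares linear slope over 9 bp, truncated windows at the edges.

Variant layouts drop the footprint row (`variant1`, $8\times1000$), keep
only it (`variant2`, $1\times1000$), or pool strands / sizes *before*
normalization (`variant3` / `variant4`, $5\times1000$). Pooling raw
counts first and recomputing normalization and slopes afterwards is the
mathematically consistent reading (the pooled signal is then normalized
exactly once), and the package asserts it on fixtures. Shorter windows
(half-width 250/100/50) only change $W$.

## Model and training

Per kernel size $k \in \{3,5,7\}$, three same-padded convolution filters
with ReLU produce three feature maps, max-pooled *across the filter
axis* at each base — one value per bp, so each kernel branch yields a
length-$W$ vector and their concatenation has length $3W$ (3000 by
default). Two fully connected layers (32 hidden units, ReLU; then one
sigmoid unit) output a binding probability. The reading of "repeated
convolution three times" as three parallel filters pooled across maps
(rather than three stacked layers) follows from the pooled map having
exactly one value per base position; hidden width 32 is a package
default (unstated upstream) and configurable.

Training is Adam (learning rate $10^{-3}$, a standard default) on binary
cross-entropy, minibatch 35, where one *iteration* is ten full shuffled
passes (epochs) over the training set, up to 100 iterations, no early
stopping, partial final batches kept. Validation loss is evaluated after
each iteration and the three lowest-loss snapshots form the ensemble;
test-time probability is their arithmetic mean. Everything is seeded:
the same seed reproduces losses bit for bit. Initialization is fan-in
scaled uniform. Gradients are hand-derived and verified against central
finite differences (relative error $<10^{-4}$).

## Sites, labels, datasets

MPBSs come from scanning both strands with a JASPAR-style PWM
(background-weighted pseudocount, log2-odds scores) at a threshold
chosen so a random background $L$-mer passes with probability at most
$10^{-4}$. For motifs up to 10 bp the threshold is exact (full score
distribution by iterated convolution over columns); longer motifs use a
dynamic program over scores discretized at 0.1 log2 units (error bounded
by the bin width; both branches are exposed and cross-tested). Windows
containing N are skipped; minus-strand hits are reported on forward
coordinates.

Only MPBSs fully contained in ATAC-seq peaks are kept. Labels come from
ChIP-seq peaks with summits: sites whose centers fall outside every peak
are *unbound*; within a peak, the single MPBS center nearest the peak's
highest summit — ties broken toward the smaller coordinate — and within
50 bp of it is *bound*; all other MPBSs in the peak are *unlabeled* and
excluded, which keeps likely-bound-but-unchosen sites out of the
negative class. "Inside a peak" is decided by the MPBS center (the same
anchor the distance rule uses); distances are summit-to-center, both
configurable. The majority class is randomly subsampled to the minority
size and equal numbers of bound and unbound sites go to train/val/test
at 70/20/10 (floored; the remainder goes to test), so every split is
exactly balanced.

## Evaluation

AUROC is rank-based (Mann–Whitney, ties count one half) and is checked
against a brute-force pairwise oracle. Two training-free baselines are
implemented: the mean footprint score over each MPBS interval, and the
footprint-overlap construction for region-emitting footprinters (PWM
score, plus the maximum PWM score when the MPBS overlaps a footprint
region by at least 1 bp — any overlap, since no minimum is stated — so
overlapping sites always outrank non-overlapping ones). Method
comparison ranks methods per TF and replicate (rank 1 = best, average
ranks on ties), averages ranks over replicates, and applies a Friedman
test across TFs with a Nemenyi post-hoc (studentized range, infinite
df). The reported mean rank follows the replicate-averaging protocol;
the test statistics use within-block re-ranks, the statistically proper
input for Friedman.

## The simulator: what it emulates, and what it does not

`simulate_atac()` builds a single-chromosome world: a uniform random
genome with a 12 bp strong-consensus motif (85:5:5:5 counts) planted at
every site; an ATAC peak (±500 bp) per site; fragment left cuts uniform
over the widened peak at `background_cut_rate` total cuts/bp, sizes from
a two-component normal mixture (70 bp and 250 bp, sd 25, 60% short,
clamped to the short/long classes) straddling the 147 bp nucleosome
length; plus a 5% off-peak background rate. At *bound* sites only, any
fragment with a cut within ±`footprint_halfwidth` (10 bp) of the center
is thinned to `footprint_depth` per protected cut, and an optional
strand-asymmetric excess of forward cuts is added 10–30 bp upstream of
the center (the dimer-like pattern only strand-separated channels can
capture). ChIP peaks (±150 bp, summit at the center plus optional
Gaussian jitter) exist for bound sites only. Fragments are emitted as
pre-shifted BED so the simulator stays alignment-free. Output is
byte-identical under a fixed seed.

Defaults are the acceptance world: 300 bound + 300 unbound sites on
1.2 Mb (about 2 kb spacing, so windows never overlap), rate 0.5, depth
0.2, no asymmetry, zero jitter.

The simulator does **not** emulate Tn5 sequence bias (bias handling is
out of scope by design), overlapping or variable-width peaks, copy
number, mappability, or correlated fragment placement. A green
end-to-end test therefore establishes that the pipeline's mechanics and
learning dynamics work on a world with the stated signal structure — not
that real-data AUROCs are reproduced; those depend on external
accessions outside desk scale.

## Numerical choices and edge cases

* Constant tracks (including all-zero) normalize to all zeros; the
  constancy test tolerates `cumsum` round-off (relative $10^{-9}$).
* Footprint scores and slopes use truncated windows at track edges;
  degenerate tracks shorter than the slope window fall back to truncated
  windows throughout (needed by the 2 bp shortened-window case).
* Windows crossing a chromosome end are zero-padded and flagged.
* Threshold calls use strict inequalities: probability exactly 0.5 is
  unbound, exactly 0.95 is bound but not constitutive.
* BAM fragments are built from the leftmost mate of each proper pair
  with +4/−5 shifts applied to the 5′ forward and 1-past reverse
  coordinates; BED input is taken verbatim (documented as pre-shifted).
  Each fragment contributes both of its end cuts — each transposition
  event cleaves at both termini.
* The probability in the loss is clamped to $[10^{-12}, 1-10^{-12}]$.

## Known limitations

Training is pure R (vectorized batch linear algebra); a 600-site world
trains in a few minutes on one CPU, but genome-scale training would want
compiled code or a deep-learning backend. The binned threshold DP
inherits a bin-width error on motifs longer than 10 bp. The
skipped-record counter for BAM input is an aggregate (total records
minus those consumed), not a per-flag breakdown. HINT-ATAC's HMM and
TOBIAS's bias-corrected scoring are not reimplemented; only their
published *scoring procedures* (footprint-score mean, footprint-overlap
rank construction) are, as evaluation baselines.
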
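---
title: "Models and methods behind splicecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind splicecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`splicecode` quantifies cell-type-specific exon inclusion (Ψ) from
long-read exon chains and models it from positional RNA-binding-protein
(RBP) binding and from primary sequence. This vignette explains the
models, their assumptions, the tunable parameters, the synthetic-data
generator that provides ground truth, and the numerical and design
choices a maintainer should know about. It states no empirical result
beyond what the package's tests and `scripts/acceptance.R` compute.

## Ψ quantification

A long read is one molecule: an ordered chain of exon intervals on a
chromosome. For every cassette exon the package counts, per individual
and cell type:

* `X_in` — molecules containing the exon with both splice sites exactly
  matching the (corrected) annotated boundaries. No fuzz window is
  applied: the package expects splice-site-corrected chains, so boundary
  matching is exact by design.
* `X_out` — molecules of the same gene that skip the exon and carry at
  least `min_side = 50` aligned bases on each side of it. Without this
  guard, truncated molecules that merely end before the exon would be
  mistaken for skipping evidence.
* `X_accIn` / `X_donIn` — truncated molecules that support only the
  acceptor (entering the exon and ending inside it) or only the donor
  (starting inside the exon and splicing out). They carry partial
  inclusion evidence and enter the numerator of the corresponding Ψ.
* `X_tot` — all molecules whose span overlaps the exon locus (≥ 1 bp
  overlap of the molecule's first-to-last footprint; this definition
  keeps `X_tot` an upper bound for all other classes, including
  skipping molecules that bridge the locus).

The three estimators are

$$\Psi_{overall} = \frac{X_{in}+X_{accIn}+X_{donIn}}
                        {X_{in}+X_{accIn}+X_{donIn}+X_{out}},\quad
  \Psi_{acceptor} = \frac{X_{in}+X_{accIn}}{X_{in}+X_{accIn}+X_{out}},\quad
  \Psi_{donor} = \frac{X_{in}+X_{donIn}}{X_{in}+X_{donIn}+X_{out}}.$$

Counts are depth-normalized per individual (each individual's counts are
divided by that individual's total molecule count) before pooling across
individuals, so deeply sequenced individuals do not dominate the
pseudo-bulk. Two thresholds gate the estimate: Ψ is reported only when
the **raw** (un-normalized) `X_tot`, summed over individuals, reaches
`min_reads = 10` — the support rule is about evidence, so it must not be
affected by normalization — and an exon is kept only when all three Ψ
values of the **jointly pooled** pseudo-bulk (both cell types together)
lie in [0.02, 0.98]. Pooling jointly is an assumption; the filter could
also be applied per region, but a single pooled filter keeps the exon
universe identical across cell types, which the fold construction
relies on. Division-by-zero denominators yield missing values.

Exon candidates that look like intron retention or alternative
acceptor/donor use — non-annotated intervals reusing one or two
annotated splice sites with ≥ 70 non-exonic bases — are excluded by
`exclude_retention_like()` before quantification.

ΔΨ is always glia − neuron. Exons with |ΔΨ| > 0.25 (strictly) are
`variable`, with |ΔΨ| > 0.1 `var0.1`, otherwise `non_variable`;
missing Ψ on either side gives `unmeasured`. Note one edge: |ΔΨ|
exactly 0.25 is *not* variable (strict inequality) but does exceed the
0.1 tier, so it is labelled `var0.1`.

Because most exons are almost always included, training tables are
de-skewed: the class {Ψ_neur > 0.9, Ψ_glia > 0.9, |ΔΨ| < 0.03} is
randomly subsampled without replacement to `target = 5000`; an
alternative predicate (Ψ exactly 1 in both cell types, `rule =
"mouse"`) covers datasets where the skew sits exactly at 1. The
downsampling RNG stream is independent of the read-simulation stream.

`coordination_test()` asks whether two exons on the same gene are
included on the same molecules more often than chance: only molecules
spanning both loci are used, each is called in/out per exon (exact
inclusion vs clean skip; ambiguous truncated molecules are dropped), and
the 2×2 table is tested two-sided with Fisher's exact test.

## Positional RBP features

Peaks from replicates or cell lines are union-merged per RBP
(overlapping or bookended intervals count once). Each merged peak near a
cassette exon falls into exactly one of six strand-aware categories:
`upstream` (fully in the transcriptionally 5' flank, nearest edge within
`flank_max = 400` bp of the acceptor), `acc_overlap` (crossing the
acceptor without containing the exon), `exonic` (fully inside, including
a peak exactly equal to the exon), `spanning` (containing the whole
exon), `don_overlap`, and `downstream`. The containment/crossing
definitions are mutually exclusive, so no precedence rule is needed. A
peak that overlaps the 400-bp flank but extends beyond it still counts:
the flank bounds the *window*, not the peak. Counts per (exon, RBP,
category) form the feature matrix — 6 columns per RBP, 732 for 122
RBPs. Exons without any peak across all RBPs are flagged; they cannot be
predicted from binding features and are excluded from training (and, for
fair model comparison, from all test sets).

Metagene binding profiles summarize where an RBP sits: at each of
400 + 50 + 400 strand-oriented positions (single-base flanks, exon body
rescaled into 50 equal bins; only exons ≥ 50 bp contribute), the
fraction of group exons covered by ≥ 1 merged peak. Profiles are
presence/absence per position, never length-weighted.
`profile_divergence()` builds the four groups per cell type — variable /
non-variable crossed with Ψ ≥ 0.5 / Ψ < 0.5 — computes the MSE between
the variable and non-variable profiles separately in the high- and
low-Ψ strata, and compares the two cell types' MSE distributions with a
two-sided paired Wilcoxon signed-rank test, pairing on (RBP, stratum).

## The logistic Ψ model

The feature-based predictor is intentionally minimal: one affine map
plus a sigmoid, trained with binary cross-entropy against *continuous*
Ψ targets (Ψ is a fraction, not a label; continuous-target BCE is the
natural generalization and keeps the fitted map a logistic regression).
The elastic-net penalty uses `alpha = 0.001` and `l1_ratio = 0.7`,
applied to the weights only (never the bias), scaled as a per-sample
mean so that duplicating every training row leaves the optimum
unchanged. Optimization is plain minibatch SGD (learning rate 0.005,
batch 256) with a proximal soft-thresholding step for the L1 part —
subgradients at zero are avoided, so exact sparsity is attainable.
Epoch count is not prescribed by the training recipe the package
follows; the default is at most 200 epochs with early stopping on a 10%
validation split (patience 10), restoring the best weights. With
`alpha = 0` and full-batch updates the fit converges to the
maximum-likelihood logistic solution (the test suite checks this
against `glm`; `glmnet` serves as an independent oracle elsewhere,
never as the implementation).

Cross-validated training (`fit_lr_cv()`) fits `runs_per_fold = 5`
replicates per fold, averages test-fold predictions across replicates,
and averages coefficients across all folds × runs (50 models in the
10-fold default). Coefficient comparisons between models filter
features to ≥ 50 supporting exons and |coefficient| > 0.05 in at least
one model, then rank by the absolute coefficient difference; the
training-set regimes (all exons, |ΔΨ| > 0.1, |ΔΨ| > 0.25) are a matter
of subsetting the target table before fitting.

## The sequence model

The sequence predictor is a hybrid convolutional + recurrent network
over a window with the exon of interest centered (window center =
`floor((start+end)/2)`, odd lengths rounding down; default 6,144 bp).
Input channels: 4 one-hot nucleotide channels (padding beyond
chromosome ends is all-zero), optionally one splice-site channel with
exactly two set positions (the first exon base and one-past-the-last,
in transcription orientation), and optionally one presence channel per
RBP marking merged-peak coverage. Minus-strand windows are
reverse-complemented so the model always reads in transcription
direction.

The trunk is a stack of same-padded 1-D convolution blocks
(convolution → ReLU → max pooling), then a GRU scanning the
downsampled positions, then one dense sigmoid head per dataset
(multi-head training shares the trunk and separates only the heads).
The head reads the **per-unit maximum over time** of the GRU states.
This pooling choice is deliberate: a cassette exon's regulatory signal
is sparse and localized (a motif occurrence), and max-over-time pooling
is the detector architecture that lets a localized activation reach the
loss directly; reading only the final state buries the detection under
dozens of recurrent steps, and averaging over time dilutes it by the
sequence length. Deeper convolution blocks with matching channel counts
are initialized near the identity (center tap plus small noise), so the
detections of the first block survive a randomly initialized stack —
without this, gradient search for a short motif through several random
layers stalls at desk scale.

Training uses Adam (not the plain SGD of the logistic model — a
conv+GRU trunk at these sizes does not train reliably with constant-rate
SGD), binary cross-entropy on continuous Ψ, optional per-epoch learning
rate decay, optional decoupled weight decay, early stopping on a
validation split, and optional random-shift augmentation (windows are
shifted by up to ±N bp each presentation, which suppresses
position-specific memorization while preserving motif content).
Prediction is deterministic given fixed weights and is averaged across
replicate runs. All weights, the backward pass (including
backpropagation through time) and the mutagenesis fast path are
implemented in `RcppArmadillo`; the gradient implementation is verified
against finite differences in the test suite.

Two presets matter:

* `seq_config()` — the full-scale shape: 6,144-bp window, six blocks of
  64 filters (width 5, 2× pooling), GRU hidden size 64. The exact layer
  sizes of the published architecture this family follows are not fully
  specified in text, so the trunk is configurable and these defaults are
  documented approximations, not claims of equivalence.
* `desk_seq_config()` — the desk-scale preset used by all tests and the
  acceptance script: 1,024-bp window, two blocks (kernel widths 9 and 5
  — the first wide enough to see a short motif in one step — with 16×
  and 4× pooling, 24 filters), GRU hidden size 24, Adam at 3e-3, batch
  32, ±128-bp shift augmentation, weight decay 1e-4, and a full 80-epoch
  budget with early stopping disabled. The last three matter: the
  optimization typically sits on a loss plateau for tens of epochs
  before the motif detector forms, and augmentation/weight decay keep
  memorization from winning the race during that plateau. One run
  trains in one to two minutes on a single CPU, and
  `fit_seq_replicates()` retrains a replicate (fresh seed) when its
  validation loss never clearly leaves the plateau — a selection made
  on validation data only.

Channel ablations ({seq}, {seq, splice}, {seq, splice, rbp}) are pure
configuration; the experiment matrix needs no code changes.

## Interpretation

`ism()` performs in-silico saturation mutagenesis: for every window
position, predict with each of the four nucleotides substituted
(non-sequence channels held fixed — only sequence is mutated), average
predictions across replicate models, and center per position:
$ISM_{e,p,n} = \Psi_{pred,e,p,n} - \tfrac14\sum_{i}\Psi_{pred,e,p,i}$.
Two exact identities follow algebraically and are asserted in tests:
the four scores at a position sum to zero, and prediction gaps
reconstruct as score differences
($\Psi(ref)-\Psi(mut_{p\to n}) = ISM_{p,ref}-ISM_{p,n}$). The 4×window
forward passes are batched internally; results are independent of the
batch partition (up to BLAS-order floating-point noise below 1e-9,
which is why exactness assertions use absolute tolerances).

`ism_profile()` averages per-position |ISM| (mean over the four
nucleotides) across exons after rescaling each exon's upstream flank,
body and downstream flank into fixed bin counts (default 300 for the
body; flanks are also binned per exon, since flank content near window
edges varies with exon length). `neighbor_exon_scores()` reports the
maximal |ISM| inside each annotated neighboring exon ± 150 bp within
the window, ranked — the entry point for spotting coordinated exons,
which `coordination_test()` can then corroborate from the molecules
themselves. `export_scores()` writes per-exon TSVs plus a JSON sidecar
(including the ≥ 25-sequences-per-strand bookkeeping constant) for
external motif-discovery tools; motif discovery itself is out of scope.

## Variant effects

`select_best_variants()` reduces a variant table to, per intron, the
lowest-p variants whose intron spans a quantified exon and whose
position falls inside the model window (multi-allelic rows are split
first; 1-based positions are converted to the internal 0-based
convention at this boundary). `delta_ism()` verifies the reference
allele against the genome (complementing alleles into reverse-
complemented windows — alleles are always given on the plus strand),
substitutes the alternative allele, and reports
ΔISM = mean prediction(alt) − mean prediction(ref) across replicates,
averaging before differencing (identical in expectation to the reverse
order). A variant carries an effect when |ΔISM| > 0.005. Expected
direction comes from the intron-excision slope: negative slopes
correspond to increased inclusion, so the expected ΔISM sign is the
opposite of the slope's. For exons with several effect-carrying
variants the largest |ΔISM| is the prioritized call. ΔISM is exactly
antisymmetric under allele swap, and raising the threshold can only
shrink the effect-carrying set; both are asserted in tests.

## Evaluation

`make_folds()` builds 10 folds over connected components of genes
(joined by homolog edges when a homolog map is supplied — the map is an
input; no retrieval is performed), assigning components greedily,
largest first, to the currently smallest fold after a seeded shuffle.
The balancing scheme is an implementation choice; what matters for
comparability is that the same exons always share a test fold across
models, which holds by construction. `spearman_eval()` reports per-fold
Spearman correlations and their median (the median across folds, not a
pooled correlation, is the headline number); constant vectors yield
missing values rather than errors. `subgroup_mse()` evaluates error per
exon subgroup: length classes (≤ 27, 28–100, 101–200, > 200 bp), frame
consistency (length divisible by three), flanking-intron length classes
(< 101, 101–1000, > 1000 bp, on the mean of the two flanking introns —
the grouping rule does not specify which intron, so the mean is used
and documented), and the number of annotated exons in the window. Empty
groups are reported as missing, never as zero.

## The synthetic-data generator

The generator exists so that every downstream claim can be tested
against planted truth. It emulates:

* a genome of single-gene chromosomes with a central cassette exon
  flanked by constitutive exons; cassette lengths from a mixture
  including ≤ 27-bp microexons (with enrichment of frame-consistent
  lengths) and intron lengths from short/medium/long classes, so the
  subgroup analyses are exercisable; 50% of genes on the minus strand
  to force strand-aware code paths; canonical GT/AG dinucleotides at
  every splice site on the coding strand;
* a planted grammar: per RBP, one or two active positional categories
  with effect weights on the inclusion logit (magnitudes 0.5–2 by
  default), shared between cell types except for a chosen number of
  QKI-like RBPs whose effects flip sign between glia and neurons;
  `true_psi = plogis(baseline + Σ effects + noise)` with exon-level
  logit noise (default sd 0.25) shared between cell types, plus optional
  per-cell-type noise for decoupling experiments;
* peak tracks: each cassette exon receives, per RBP, a peak at one of
  its active categories with probability `placement_rate`; flank peaks
  sit at an RBP-characteristic distance from the splice site (± 10 bp
  jitter), emulating the positional concentration of real binding
  codes; each RBP's short motif is written into the genome at its peak
  (reverse-complemented on minus-strand genes, never overwriting splice
  dinucleotides);
* read chains: inclusion ~ Binomial(depth, true Ψ) per exon,
  individual and cell type; a 5% fraction of inclusion reads (a free
  parameter — real truncation rates are not specified anywhere the
  package follows) is truncated to support only the acceptor or only
  the donor; skipping chains always cover the full flanking exons so
  the ≥ 50-bases rule can fire;
* variants: planted variants disrupt a motif of a shared-effect RBP
  and carry a slope whose sign matches the planted effect (an
  inclusion-raising motif gets a positive slope for the disrupting
  allele); neutral variants sit in peak-free intronic sequence with
  random-sign slopes. Ground-truth expected ΔISM signs are recorded.

Identical seeds give byte-identical outputs; independent seed streams
separate the genome, grammar, peaks, reads, variants, downsampling and
fold RNGs.

What the generator does **not** model: sequencing error, barcodes/UMIs,
alignment artifacts, multi-exon alternative events, expression
differences between cell types, or realistic motif degeneracy (each RBP
has one exact planted motif). Passing tests therefore demonstrate that
the machinery recovers a planted grammar under clean conditions — not
that real brain data would yield the same accuracy; real-data
correlations require the full datasets and are out of scope here.

## Problem sizes and study conditions used by tests and acceptance

* Ψ oracle equivalence: 1,000 exons at depth 60 per cell type, compared
  exactly (tolerance 1e-12) to an independently coded molecule-fraction
  oracle; recovery: 100 exons at depth 10,000 per cell type (two
  individuals × 5,000), requiring |Ψ̂ − Ψ| < 0.02 for ≥ 99% of
  exon × cell-type values.
* Logistic grammar recovery: 5,000 exons, 40 RBPs, placement rate 0.5,
  10-fold CV × 5 runs; ≥ 90% sign agreement for planted effects with
  |weight| ≥ 0.5 and ≥ 50 supporting exons, held-out median Spearman
  ≥ 0.6.
* Sequence-model recovery: 2,000 exons, one RBP with an 8-bp motif
  planted downstream of the donor (weight +5, baseline −2.5), desk
  preset, two replicate runs on nine folds, evaluated on the held-out
  fold (Spearman ≥ 0.6); |ISM| mass within ± 30 bp of the planted motif
  ≥ 50% on test exons carrying a peak.
* Variant effects: 25 motif-disrupting + 25 neutral variants on the
  same scenario; sign concordance ≥ 80% among effect-carrying planted
  variants, most neutral variants below the 0.005 threshold.
* Profile divergence: 1,600 exons, 40 RBPs with strong shared effects
  (weights 2.5–4), neuron grammar decoupled from peaks and given
  peak-independent logit noise (sd 1.5). Decoupling makes the variable
  class the set of exons whose neuronal inclusion ignores the binding
  code, so within neuronal Ψ strata the variable and non-variable
  binding profiles diverge (first-order composition difference), while
  within glial strata conditioning on glial Ψ aligns both groups'
  binding (second-order residual only): the neuronal MSEs stochastically
  dominate, tested by the paired Wilcoxon at p < 0.05 across 40 RBPs.

These sizes are the package's chosen study conditions: large enough for
the planted signal to be identifiable, small enough that the entire
suite runs on a single CPU in well under half an hour.

## Known limitations

* The Ψ counter assumes splice-site-corrected chains; uncorrected
  long-read data needs upstream correction before the exact boundary
  matching is appropriate.
* The sequence model's full-scale preset reflects a published
  architecture only approximately (its exact layer table is not
  reproduced here), and no GPU path exists; training the 6,144-bp
  six-block configuration on tens of thousands of exons is possible but
  slow in this implementation.
* Binding profiles and the feature matrix treat peaks as binary
  intervals; peak scores and shapes are ignored.
* The cell-type hierarchy is flat: finer subtypes are handled by
  relabelling the `cell_type` column, with no dedicated logic.
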
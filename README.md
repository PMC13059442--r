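# splicecode

Cell types of the brain — neurons and glia above all — include or skip
cassette exons at different rates, and the positional grammar of
RNA-binding-protein (RBP) binding around an exon encodes much of that
choice. `splicecode` implements, as a tested R pipeline, the quantitative
machinery for studying this cell-type-specific splicing code from
long-read sequencing:

* **Ψ quantification from exon chains.** One long read = one molecule =
  one ordered chain of exon intervals. Per exon, cell type and individual
  the package counts the five molecule classes
  (X<sub>in</sub>, X<sub>out</sub>, X<sub>accIn</sub>, X<sub>donIn</sub>,
  X<sub>tot</sub>) and computes

  Ψ<sub>overall</sub> = (X<sub>in</sub> + X<sub>accIn</sub> + X<sub>donIn</sub>) /
  (X<sub>in</sub> + X<sub>accIn</sub> + X<sub>donIn</sub> + X<sub>out</sub>),

  together with the acceptor- and donor-restricted variants. Skipping
  molecules must carry ≥ 50 aligned bases on both sides of the exon,
  depth is normalized per individual before pooling, Ψ requires ≥ 10 raw
  molecules per cell type, pooled Ψ must lie in [0.02, 0.98], and
  intron-retention-like exon candidates (≥ 70 non-exonic bases reusing an
  annotated splice site) are excluded. Exons with
  |ΔΨ<sub>glia−neur</sub>| > 0.25 are called *variable*.
* **Positional RBP features.** eCLIP-style peak BED files are
  replicate-merged and classified into six locations per exon (upstream
  ≤ 400 bp, acceptor-overlapping, exonic, spanning, donor-overlapping,
  downstream ≤ 400 bp), giving a 6 × n<sub>RBP</sub> feature matrix (732
  columns for 122 RBPs), plus 50-bin metagene binding profiles and their
  mean-squared-error divergence between variable and non-variable exons.
* **Two Ψ predictors.** An elastic-net logistic model (single affine map
  + sigmoid, binary cross-entropy on continuous Ψ, α = 0.001,
  L1-ratio = 0.7, learning rate 0.005, batch 256) on the positional
  features, and a hybrid convolutional + recurrent network on the raw
  sequence (6,144-bp window, exon centered, one-hot channels plus
  optional splice-site and per-RBP channels), both evaluated by
  gene-grouped 10-fold cross-validation with 5 runs per fold and
  Spearman correlation.
* **Interpretation.** Averaged coefficients across the 50 models per
  setting, ranked cell-type-specific feature differences, in-silico
  saturation mutagenesis (ISM<sub>e,p,n</sub> = Ψ<sub>pred,e,p,n</sub> −
  ¼ Σ<sub>i</sub> Ψ<sub>pred,e,p,i</sub>), aggregate |ISM| profiles,
  neighboring-exon scores and exon-coordination tests (Fisher exact on
  molecules spanning two exons).
* **Variant effects.** ΔISM<sub>alt−ref</sub> per splicing-QTL variant,
  the |ΔISM| > 0.005 effect call, and sign concordance with
  intron-excision slopes (negative slope ⇔ increased inclusion).
* **Synthetic data with planted ground truth.** A generator produces a
  genome, annotation, peak tracks with embedded motifs, read chains and
  variants whose statistics follow a planted position-dependent grammar,
  so every stage can be tested against known truth.

## Worked example

```r
library(splicecode)

sim <- simulate_dataset(n_genes = 200, rbp_names = sprintf("RBP%02d", 1:12),
                        n_cell_specific = 2, depth = 80, seed = 1)
psi <- psi_from_chains(sim$chains, sim$annotation)
head(subset(psi, cell_type == "glia"), 5)
#>  exon_id strand psi_overall  psi_donor n_reads delta_psi  variability
#> g0001_e2      -     0.16875 0.16875000     160  -0.12500       var0.1
#> g0002_e2      -     0.58750 0.58227848     160   0.00000 non_variable
#> g0003_e2      +     0.52500 0.52500000     160   0.05000 non_variable
#> g0004_e2      +     1.00000 1.00000000     160   0.19375       var0.1
#> g0006_e2      -     0.05625 0.05031447     160   0.02500 non_variable
```

Each row is one cassette exon in one cell type: the three Ψ estimates,
the raw molecule support, ΔΨ between glia and neurons and the
variability call (76 of 197 quantified exons are variable in this
simulation — the generator plants strong effects on purpose).

```r
ps   <- make_peaksets(sim$peaks)                     # replicate-merged peaks
wide <- psi_wide(psi[, c("exon_id", "cell_type", "psi_overall",
                         "psi_acceptor", "psi_donor", "n_reads")])
ann  <- sim$annotation[match(wide$exon_id, sim$annotation$exon_id), ]
fm   <- build_feature_matrix(ann, ps)
dim(fm)
#> [1] 197  72        # 12 RBPs x 6 positional categories

y     <- setNames(wide$psi_glia, wide$exon_id)
ok    <- !is.na(y)
folds <- make_folds(data.frame(exon_id = wide$exon_id[ok],
                               gene_id = ann$gene_id[ok]), k = 5, seed = 1)
fit   <- fit_lr_cv(fm[ok, ], y[ok], folds, lr_config(runs_per_fold = 2),
                   seed = 1)
spearman_eval(y, setNames(fit$predictions$pred, fit$predictions$exon_id),
              folds)$median
#> [1] 0.9160213
```

The cross-validated logistic model recovers the planted grammar: the
held-out rank correlation with the true inclusion is 0.92, and the
largest averaged coefficients sit on the planted (RBP, location) pairs:

```r
head(fit$coefficients[order(-abs(fit$coefficients$coefficient)), ], 3)
#>             feature coefficient support
#> 6  RBP01:downstream  0.07876669     101
#> 16   RBP03:spanning  0.05235188      41
#> 32 RBP06:acc_overlap 0.04538209      60
```

The sequence model side works the same way at a desk scale — see
`desk_seq_config()`, `build_inputs()`, `fit_seq_replicates()`,
`predict_seq()`, `ism()` and `delta_ism()`; the methods vignette
(`vignettes/splicecode-methods.Rmd`) walks through the model and every
tunable parameter.

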
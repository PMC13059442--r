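## Shared fixtures, built once per test session and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

## small full dataset exercising every module surface
fixture_sim <- function() {
  memo("sim", function() {
    simulate_dataset(n_genes = 40L, rbp_names = sprintf("RBP%02d", 1:10),
                     n_cell_specific = 2L, depth = 60L,
                     n_planted = 10L, n_neutral = 10L, seed = 7L)
  })
}

## a tiny trained sequence model on a 64-bp window (seconds to train)
fixture_tiny_seq <- function() {
  memo("tiny_seq", function() {
    cfg <- seq_config(window = 64L, channels = c("seq", "splice"),
                      blocks = 2L, filters = 8L, kernel = c(5L, 3L),
                      pool = c(2L, 2L), hidden = 8L,
                      learning_rate = 3e-3, batch_size = 16L,
                      epochs = 8L, patience = 8L)
    set.seed(402)
    n <- 120L
    x <- array(0, c(cfg$n_channels, cfg$window, n))
    for (i in seq_len(n)) {
      hit <- sample.int(4L, cfg$window, replace = TRUE)
      x[cbind(hit, seq_len(cfg$window), i)] <- 1
      x[5L, c(20L, 44L), i] <- 1
    }
    y <- runif(n, 0.1, 0.9)
    model <- train_seq_model(x, y, cfg, seed = 5L)
    list(config = cfg, x = x, y = y, model = model)
  })
}

## random sequence window for a given config
random_window <- function(cfg, seed = 1L) {
  set.seed(seed)
  x <- matrix(0, cfg$n_channels, cfg$window)
  hit <- sample.int(4L, cfg$window, replace = TRUE)
  x[cbind(hit, seq_len(cfg$window))] <- 1
  if ("splice" %in% cfg$channels) {
    x[5L, c(cfg$window %/% 4L, cfg$window %/% 2L)] <- 1
  }
  ref <- c("A", "C", "G", "T")[hit]
  list(x = x, meta = list(exon_id = "test_exon", chrom = "chrT",
                          strand = "+", w0 = 0L, w1 = cfg$window,
                          exon_from = cfg$window %/% 4L,
                          exon_to = cfg$window %/% 2L, ref = ref))
}

## desk-scale single-motif scenario with trained replicate models, shared
## by the sequence-model recovery, ISM and variant-effect checks
fixture_desk_grammar <- function() {
  memo("desk_grammar", function() {
    gg <- gen_genome(2000L, seed = 11L)
    gr <- splice_grammar(
      data.frame(rbp = "M1", category = "downstream",
                 cell_type = c("glia", "neuron"), weight = 5),
      baseline_logit = c(neuron = -2.5, glia = -2.5),
      motif_map = c(M1 = "GGTACGTT"))
    pk <- gen_peaks(gg$annotation, gr, placement_rate = 0.5, seed = 11L)
    pm <- plant_motifs(gg$genome, pk, gr, gg$annotation)
    ex <- cassette_exons(gg$annotation, pm$peaks, gr, noise_sd = 0.25,
                         seed = 11L)
    cfg <- desk_seq_config()
    win <- build_inputs(pm$genome, gg$annotation, ex$exon_id, cfg)
    folds <- make_folds(ex[, c("exon_id", "gene_id")], k = 10L,
                        seed = 11L)
    te <- which(ex$exon_id %in% folds$exon_id[folds$fold == 1L])
    tr <- setdiff(seq_len(nrow(ex)), te)
    models <- fit_seq_replicates(win$x[, , tr],
                                 ex$true_psi_glia[tr], cfg,
                                 runs = 2L, seed = 42L)
    list(genome = pm$genome, annotation = gg$annotation, grammar = gr,
         peaks = pm$peaks, exons = ex, config = cfg, windows = win,
         folds = folds, train = tr, test = te, models = models)
  })
}
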
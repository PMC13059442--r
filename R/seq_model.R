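## Sequence-based PSI predictor: input-window construction (one-hot
## sequence, optional splice-site and RBP-binding channels), training of
## the convolutional + recurrent trunk, and replicate-averaged prediction.

#' Configuration of the sequence model
#'
#' The default trunk uses a 6,144-bp window, six convolution blocks
#' (width 5, 64 filters, 2x max pooling each), a GRU with 64 hidden units
#' and one dense sigmoid head. `channels` selects the input stack:
#' `"seq"` (4 one-hot nucleotide channels), `"splice"` (one channel
#' marking the start and end of the exon of interest) and `"rbp"` (one
#' presence channel per RBP in `rbp_names`). Multi-dataset training adds
#' one output head per entry of `heads`, sharing the trunk.
#'
#' @param window input window length (bp); must be divisible by the
#'   product of the pooling factors.
#' @param channels subset of c("seq", "splice", "rbp").
#' @param rbp_names RBP channel order (required with channel "rbp").
#' @param blocks number of convolution blocks.
#' @param filters,kernel,pool per-block filter count, kernel width and
#'   pooling factor (scalars are recycled).
#' @param hidden GRU hidden size.
#' @param heads head (dataset) names; one sigmoid output each.
#' @param learning_rate,lr_decay,batch_size,epochs,patience,val_fraction
#'   Adam training schedule (per-epoch multiplicative learning-rate decay)
#'   with early stopping on a validation split.
#' @param weight_decay decoupled weight decay applied with each update.
#' @param augment_shift training-time augmentation: windows are randomly
#'   shifted by up to this many bp (0 disables).
#' @param runs_per_fold model replicates per cross-validation fold.
#' @return list of class `seq_config`.
#' @export
seq_config <- function(window = 6144L, channels = c("seq", "splice"),
                       rbp_names = NULL, blocks = 6L, filters = 64L,
                       kernel = 5L, pool = 2L, hidden = 64L,
                       heads = "default", learning_rate = 1e-3,
                       lr_decay = 1.0, weight_decay = 0,
                       augment_shift = 0L, batch_size = 64L,
                       epochs = 50L, patience = 6L, val_fraction = 0.1,
                       runs_per_fold = 5L) {
  stopifnot(all(channels %in% c("seq", "splice", "rbp")),
            "seq" %in% channels)
  if ("rbp" %in% channels && is.null(rbp_names)) {
    stop("channel 'rbp' requires rbp_names")
  }
  filters <- rep_len(as.integer(filters), blocks)
  kernel <- rep_len(as.integer(kernel), blocks)
  pool <- rep_len(as.integer(pool), blocks)
  if (window %% prod(pool) != 0L) {
    stop("window must be divisible by the product of the pooling factors")
  }
  n_channels <- 4L + ("splice" %in% channels) +
    if ("rbp" %in% channels) length(rbp_names) else 0L
  structure(list(window = as.integer(window), channels = channels,
                 rbp_names = rbp_names, n_channels = n_channels,
                 blocks = as.integer(blocks), filters = filters,
                 kernel = kernel, pool = pool,
                 hidden = as.integer(hidden), heads = heads,
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 weight_decay = weight_decay,
                 augment_shift = as.integer(augment_shift),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 runs_per_fold = as.integer(runs_per_fold)),
            class = "seq_config")
}

#' Desk-scale sequence-model preset
#'
#' A small configuration (1,024-bp window, two conv blocks with strong
#' pooling, 24 filters, GRU hidden size 24, shift augmentation and weight
#' decay on, early stopping off) used throughout the test suite and
#' examples; one run trains in one to two minutes on a single CPU.
#'
#' @param ... overrides passed to [seq_config()].
#' @export
desk_seq_config <- function(...) {
  args <- list(window = 1024L, blocks = 2L, filters = 24L,
               kernel = c(9L, 5L), pool = c(16L, 4L), hidden = 24L,
               learning_rate = 3e-3, batch_size = 32L, epochs = 80L,
               patience = 80L, augment_shift = 128L, weight_decay = 1e-4)
  override <- list(...)
  args[names(override)] <- override
  do.call(seq_config, args)
}

## config sub-list handed to the C++ kernels
.cpp_config <- function(config) {
  list(channels = config$n_channels, window = config$window,
       hidden = config$hidden, n_heads = length(config$heads),
       filters = config$filters, kernel = config$kernel,
       pool = config$pool)
}

#' Build the model input window for one exon
#'
#' The exon of interest is centered in the window (window center =
#' `floor((start + end) / 2)`); the sequence is read in transcription
#' orientation (reverse-complemented for minus-strand genes), one-hot
#' encoded into four channels; positions beyond the chromosome ends are
#' zero-padded. The optional splice channel sets exactly two positions:
#' the first exon base and the position one past the last exon base. RBP
#' channels mark window positions covered by a merged peak.
#'
#' @param genome named character vector of chromosome sequences.
#' @param annotation annotation data.frame.
#' @param exon_id exon of interest.
#' @param config `seq_config` object.
#' @param peaksets named list of `peak_set` objects (with channel "rbp").
#' @return list: `x` (channels x window matrix), `meta` (chrom, strand,
#'   genomic window, exon window positions, reference bases).
#' @export
build_input <- function(genome, annotation, exon_id, config,
                        peaksets = NULL) {
  a <- annotation[annotation$exon_id == exon_id, , drop = FALSE]
  if (nrow(a) == 0L) stop("unknown exon: ", exon_id)
  L <- config$window
  len <- a$end - a$start
  if (len >= L) stop("exon ", exon_id, " is longer than the input window")
  center <- (a$start + a$end) %/% 2L
  w0 <- center - L %/% 2L
  w1 <- w0 + L
  chrom_seq <- genome[[a$chrom]]
  clen <- nchar(chrom_seq)
  lo <- max(w0, 0L); hi <- min(w1, clen)
  seq_chars <- rep("N", L)
  if (hi > lo) {
    seq_chars[(lo - w0 + 1L):(hi - w0)] <-
      strsplit(substr(chrom_seq, lo + 1L, hi), "")[[1L]]
  }
  minus <- a$strand == "-"
  if (minus) seq_chars <- rev(complement_base(seq_chars))
  x <- matrix(0, config$n_channels, L)
  hit <- match(seq_chars, BASES)
  ok <- !is.na(hit)
  x[cbind(hit[ok], which(ok))] <- 1
  ## exon boundaries in (0-based) window coordinates, transcription
  ## orientation: first exon base and one-past-last exon base
  if (!minus) {
    pos_s <- a$start - w0; pos_e <- a$end - w0
  } else {
    pos_s <- w1 - a$end; pos_e <- w1 - a$start
  }
  row <- 5L
  if ("splice" %in% config$channels) {
    x[row, pos_s + 1L] <- 1
    x[row, pos_e + 1L] <- 1
    row <- row + 1L
  }
  if ("rbp" %in% config$channels) {
    for (r in config$rbp_names) {
      ps <- peaksets[[r]]
      if (!is.null(ps)) {
        ivs <- ps$intervals[ps$intervals$chrom == a$chrom, , drop = FALSE]
        for (i in seq_len(nrow(ivs))) {
          s0 <- max(ivs$start[i], w0); e0 <- min(ivs$end[i], w1)
          if (s0 < e0) {
            idx <- if (!minus) (s0 - w0 + 1L):(e0 - w0) else
              (w1 - e0 + 1L):(w1 - s0)
            x[row, idx] <- 1
          }
        }
      }
      row <- row + 1L
    }
  }
  list(x = x,
       meta = list(exon_id = exon_id, chrom = a$chrom, strand = a$strand,
                   w0 = w0, w1 = w1, exon_from = pos_s, exon_to = pos_e,
                   ref = seq_chars))
}

#' Build input windows for many exons
#'
#' @inheritParams build_input
#' @param exon_ids exons of interest.
#' @return list: `x` (channels x window x exon array), `meta` (list per
#'   exon).
#' @export
build_inputs <- function(genome, annotation, exon_ids, config,
                         peaksets = NULL) {
  xs <- lapply(exon_ids, function(id) {
    build_input(genome, annotation, id, config, peaksets)
  })
  arr <- array(0, c(config$n_channels, config$window, length(exon_ids)))
  for (i in seq_along(xs)) arr[, , i] <- xs[[i]]$x
  list(x = arr, meta = lapply(xs, `[[`, "meta"))
}

#' Train the sequence model
#'
#' Trains the convolutional + recurrent trunk with Adam on binary
#' cross-entropy against continuous PSI targets, with early stopping on a
#' held-out validation split. With several heads, samples carry a head
#' (dataset) label and only the dense output layer is head-specific.
#'
#' @param x input array (channels x window x samples) from
#'   [build_inputs()].
#' @param targets PSI targets between 0 and 1.
#' @param config `seq_config` object.
#' @param seed integer seed (weight init, shuffling, validation split).
#' @param heads optional character vector of head labels per sample.
#' @param verbose print per-epoch validation loss.
#' @return object of class `seq_model`.
#' @export
train_seq_model <- function(x, targets, config = desk_seq_config(),
                            seed = 1L, heads = NULL, verbose = FALSE) {
  stopifnot(length(dim(x)) == 3L)
  if (dim(x)[1L] != config$n_channels || dim(x)[2L] != config$window) {
    stop("input array does not match the configured channels/window")
  }
  n <- dim(x)[3L]
  if (any(targets < 0 | targets > 1) || anyNA(targets)) {
    stop("targets must lie in [0, 1]")
  }
  head_idx <- if (is.null(heads)) rep(0L, n) else {
    m <- match(heads, config$heads) - 1L
    if (anyNA(m)) stop("unknown head label")
    m
  }
  split <- with_seed(derive_seed(seed, "model"), {
    perm <- sample.int(n)
    n_val <- if (config$val_fraction > 0 && n >= 20L) {
      max(1L, floor(config$val_fraction * n))
    } else 0L
    list(val = perm[seq_len(n_val)],
         train = perm[setdiff(seq_len(n), seq_len(n_val))])
  })
  fit <- cpp_seq_train(x, as.numeric(targets), head_idx,
                       .cpp_config(config),
                       split$train - 1L, split$val - 1L,
                       config$learning_rate, config$lr_decay,
                       config$batch_size, config$epochs, config$patience,
                       as.integer(derive_seed(seed, "model")),
                       config$weight_decay, config$augment_shift,
                       isTRUE(verbose))
  structure(list(params = fit, config = config,
                 history = attr(fit, "history"),
                 best_epoch = attr(fit, "best_epoch"),
                 val_loss = attr(fit, "val_loss")),
            class = "seq_model")
}

#' Train replicate sequence models
#'
#' Trains `runs` replicates with different seeds. A replicate whose best
#' validation loss never clearly improves over its starting value (the
#' optimization can sit on a long plateau before the detector forms) is
#' retrained with a fresh seed up to `restarts` times; selection uses the
#' validation loss only.
#'
#' @inheritParams train_seq_model
#' @param runs number of replicates (different seeds).
#' @param restarts maximal validation-triggered retrainings per replicate.
#' @return list of `seq_model` objects.
#' @export
fit_seq_replicates <- function(x, targets, config = desk_seq_config(),
                               runs = config$runs_per_fold, seed = 1L,
                               heads = NULL, restarts = 2L,
                               verbose = FALSE) {
  lapply(seq_len(runs), function(r) {
    best <- NULL
    s <- seed * 100L + r
    for (attempt in seq_len(restarts + 1L)) {
      m <- train_seq_model(x, targets, config, seed = s,
                           heads = heads, verbose = verbose)
      if (is.null(best) || m$val_loss < best$val_loss) best <- m
      if (best$val_loss < 0.9 * best$history[1L]) break
      s <- ((s %% 1000003L) * 7L) %% 1000003L + 13L
    }
    best
  })
}

#' Predict PSI with (replicates of) the sequence model
#'
#' Predictions are averaged across replicate models; each replicate's
#' output is strictly inside (0, 1) and deterministic given its weights.
#'
#' @param models a `seq_model` or a list of replicate `seq_model`s.
#' @param x input array (channels x window x samples).
#' @param heads optional head labels per sample.
#' @return numeric vector of predicted PSI values.
#' @export
predict_seq <- function(models, x, heads = NULL) {
  if (inherits(models, "seq_model")) models <- list(models)
  stopifnot(length(models) >= 1L)
  config <- models[[1L]]$config
  n <- dim(x)[3L]
  head_idx <- if (is.null(heads)) rep(0L, n) else {
    m <- match(heads, config$heads) - 1L
    if (anyNA(m)) stop("unknown head label")
    m
  }
  preds <- vapply(models, function(m) {
    as.numeric(cpp_seq_predict(m$params, x, head_idx, .cpp_config(config)))
  }, numeric(n))
  if (n == 1L) mean(preds) else rowMeans(matrix(preds, nrow = n))
}

#' Save / load a sequence model
#'
#' Checkpoints use R's native serialization; the configuration travels
#' inside the object, so a loaded model predicts identically.
#'
#' @param model `seq_model` object.
#' @param path file path.
#' @export
save_seq_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_seq_model
#' @export
load_seq_model <- function(path) readRDS(path)
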
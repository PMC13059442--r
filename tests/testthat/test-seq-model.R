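test_that("input windows honor the channel configuration and window length", {
  default_cfg <- seq_config()
  expect_equal(default_cfg$window, 6144L)
  seq_only <- seq_config(channels = "seq")
  expect_equal(seq_only$n_channels, 4L)
  with_splice <- seq_config(channels = c("seq", "splice"))
  expect_equal(with_splice$n_channels, 5L)
  with_rbp <- seq_config(channels = c("seq", "splice", "rbp"),
                         rbp_names = c("A", "B", "C"))
  expect_equal(with_rbp$n_channels, 8L)
  expect_error(seq_config(channels = c("seq", "rbp")), "rbp_names")
  expect_error(seq_config(window = 1000L, pool = 4L, blocks = 2L),
               "divisible")
})

test_that("the exon is centered and splice marks sit at its boundaries", {
  ## 100-bp exon in a large genome: marks at window offsets 3022 and 3122
  genome <- c(chrA = paste(rep("ACGT", 4000), collapse = ""))
  ann <- data.frame(gene_id = "g", exon_id = "e", chrom = "chrA",
                    start = 8000L, end = 8100L, strand = "+",
                    role = "cassette", rank = 2L, stringsAsFactors = FALSE)
  cfg <- seq_config(window = 6144L, channels = c("seq", "splice"))
  win <- build_input(genome, ann, "e", cfg)
  expect_equal(win$meta$exon_from, 3022L)
  expect_equal(win$meta$exon_to, 3122L)
  expect_equal(which(win$x[5L, ] == 1), c(3023L, 3123L))
  ## one-hot columns sum to one on real sequence
  expect_true(all(colSums(win$x[1:4, ]) == 1))
  ## exon longer than the window is rejected
  ann_big <- ann; ann_big$end <- ann_big$start + 7000L
  expect_error(build_input(genome, ann_big, "e", cfg), "longer")
})

test_that("windows are read in transcription orientation with zero padding", {
  seqs <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  genome <- c(chrA = seqs)
  ann <- data.frame(gene_id = "g", exon_id = c("p", "m"), chrom = "chrA",
                    start = 250L, end = 350L, strand = c("+", "-"),
                    role = "cassette", rank = 2L, stringsAsFactors = FALSE)
  cfg <- seq_config(window = 256L, channels = "seq", blocks = 2L,
                    pool = 4L)
  wp <- build_input(genome, ann, "p", cfg)
  wm <- build_input(genome, ann, "m", cfg)
  expect_identical(paste(wm$meta$ref, collapse = ""),
                   revcomp(paste(wp$meta$ref, collapse = "")))
  ## near the chromosome start the window is N-padded and one-hot-free
  ann_edge <- ann[1, ]; ann_edge$start <- 10L; ann_edge$end <- 60L
  ann_edge$exon_id <- "edge"
  we <- build_input(genome, ann_edge, "edge", cfg)
  expect_true(any(we$meta$ref == "N"))
  pad_cols <- which(we$meta$ref == "N")
  expect_true(all(colSums(we$x[1:4, pad_cols, drop = FALSE]) == 0))
})

test_that("RBP channels mark merged peak coverage inside the window", {
  genome <- c(chrA = paste(rep("ACGT", 300), collapse = ""))
  ann <- data.frame(gene_id = "g", exon_id = "e", chrom = "chrA",
                    start = 500L, end = 560L, strand = "+",
                    role = "cassette", rank = 2L, stringsAsFactors = FALSE)
  ps <- make_peaksets(data.frame(rbp = "R1", chrom = "chrA",
                                 start = 470L, end = 480L))
  cfg <- seq_config(window = 256L, channels = c("seq", "splice", "rbp"),
                    rbp_names = "R1", blocks = 2L, pool = 4L)
  win <- build_input(genome, ann, "e", cfg, ps)
  ## window starts at 530 - 128 = 402; peak occupies offsets 69..78
  expect_equal(which(win$x[6L, ] == 1), 69:78)
})

test_that("training approaches a constant target and replicates average", {
  fx <- fixture_tiny_seq()
  n <- 80L
  x <- fx$x[, , 1:n, drop = FALSE]
  cfg <- fx$config
  m <- train_seq_model(x, rep(0.8, n),
                       seq_config(window = 64L,
                                  channels = c("seq", "splice"),
                                  blocks = 2L, filters = 8L,
                                  kernel = c(5L, 3L), pool = c(2L, 2L),
                                  hidden = 8L, learning_rate = 5e-3,
                                  batch_size = 16L, epochs = 40L,
                                  patience = 40L, val_fraction = 0),
                       seed = 8L)
  pr <- predict_seq(m, x)
  expect_lt(max(abs(pr - 0.8)), 0.02)
  ## prediction is deterministic and strictly inside (0, 1)
  expect_identical(pr, predict_seq(m, x))
  expect_true(all(pr > 0 & pr < 1))
  ## replicate averaging: list prediction equals the mean of singles
  reps <- fit_seq_replicates(x, rep(0.8, n), cfg, runs = 2, seed = 3)
  p1 <- predict_seq(reps[[1]], x)
  p2 <- predict_seq(reps[[2]], x)
  expect_equal(predict_seq(reps, x), (p1 + p2) / 2, tolerance = 1e-12)
  expect_equal(predict_seq(list(reps[[1]]), x), p1)
})

test_that("network gradients match finite differences", {
  cfg <- list(channels = 5L, window = 16L, hidden = 4L, n_heads = 2L,
              filters = c(3L, 4L), kernel = c(3L, 5L), pool = c(2L, 2L))
  set.seed(2)
  p <- splicecode:::cpp_seq_init(cfg, 7L)
  p$Wout <- matrix(rnorm(8) * 0.5, 2, 4); p$bout <- rnorm(2) * 0.1
  X <- array(rnorm(5 * 16 * 3), c(5, 16, 3))
  y <- c(0.2, 0.5, 0.9); h <- c(0L, 1L, 0L)
  g <- splicecode:::cpp_seq_loss_grad(p, X, y, h, cfg)
  num_grad <- function(nm, idx, conv_block = 0L) {
    eps <- 1e-6; p1 <- p; p2 <- p
    if (conv_block > 0L) {
      p1$conv_w[[conv_block]][idx] <- p1$conv_w[[conv_block]][idx] + eps
      p2$conv_w[[conv_block]][idx] <- p2$conv_w[[conv_block]][idx] - eps
    } else {
      p1[[nm]][idx] <- p1[[nm]][idx] + eps
      p2[[nm]][idx] <- p2[[nm]][idx] - eps
    }
    (splicecode:::cpp_seq_loss(p1, X, y, h, cfg) -
       splicecode:::cpp_seq_loss(p2, X, y, h, cfg)) / (2 * eps)
  }
  set.seed(3)
  for (nm in c("Wz", "Uh", "bh", "Wout", "bout")) {
    for (k in 1:3) {
      idx <- sample(length(p[[nm]]), 1)
      expect_equal(g[[nm]][idx], num_grad(nm, idx), tolerance = 1e-4)
    }
  }
  for (b in 1:2) {
    for (k in 1:3) {
      idx <- sample(length(p$conv_w[[b]]), 1)
      expect_equal(g$conv_w[[b]][idx], num_grad("", idx, b),
                   tolerance = 1e-4)
    }
  }
})

test_that("multi-head models recover per-dataset baselines on a shared trunk", {
  cfg <- seq_config(window = 64L, channels = "seq", blocks = 1L,
                    filters = 6L, kernel = 5L, pool = 4L, hidden = 6L,
                    heads = c("human", "mouse"), learning_rate = 5e-3,
                    batch_size = 16L, epochs = 40L, patience = 40L,
                    val_fraction = 0)
  set.seed(9)
  n <- 160L
  x <- array(0, c(4L, 64L, n))
  for (i in seq_len(n)) {
    hit <- sample.int(4L, 64L, TRUE)
    x[cbind(hit, 1:64, i)] <- 1
  }
  heads <- rep(c("human", "mouse"), each = n / 2)
  y <- ifelse(heads == "human", 0.85, 0.2)
  m <- train_seq_model(x, y, cfg, seed = 4L, heads = heads)
  pr_h <- predict_seq(m, x[, , 1:3, drop = FALSE], heads = rep("human", 3))
  pr_m <- predict_seq(m, x[, , 1:3, drop = FALSE], heads = rep("mouse", 3))
  expect_lt(max(abs(pr_h - 0.85)), 0.1)
  expect_lt(max(abs(pr_m - 0.2)), 0.1)
  expect_error(predict_seq(m, x[, , 1:2, drop = FALSE],
                           heads = c("human", "rat")), "unknown head")
})

test_that("saved models reload and predict identically", {
  fx <- fixture_tiny_seq()
  path <- withr::local_tempfile(fileext = ".rds")
  save_seq_model(fx$model, path)
  m2 <- load_seq_model(path)
  x <- fx$x[, , 1:5, drop = FALSE]
  expect_identical(predict_seq(m2, x), predict_seq(fx$model, x))
})
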
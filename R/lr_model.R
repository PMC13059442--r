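## Elastic-net regularized logistic PSI predictor on the positional
## feature matrix: a single affine map plus sigmoid trained by stochastic
## gradient descent with a proximal L1 step, binary cross-entropy on
## continuous PSI targets, per-fold/run coefficient averaging and
## cross-model comparison.

#' Configuration of the logistic PSI model
#'
#' Defaults follow the published training setup: elastic-net strength
#' `alpha = 0.001` with `l1_ratio = 0.7`, learning rate 0.005, batch size
#' 256, five runs per fold. The penalty is applied to the weights only
#' (not the bias), as a per-sample mean added to the mean batch loss.
#'
#' @param alpha elastic-net regularization strength (>= 0).
#' @param l1_ratio share of the penalty on the L1 term, between 0 and 1.
#' @param learning_rate SGD learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximal number of epochs.
#' @param runs_per_fold model replicates per cross-validation fold.
#' @param val_fraction fraction of the training data held out for early
#'   stopping.
#' @param patience epochs without validation improvement before stopping.
#' @return list of class `lr_config`.
#' @export
lr_config <- function(alpha = 0.001, l1_ratio = 0.7,
                      learning_rate = 0.005, batch_size = 256L,
                      epochs = 200L, runs_per_fold = 5L,
                      val_fraction = 0.1, patience = 10L) {
  stopifnot(alpha >= 0, l1_ratio >= 0, l1_ratio <= 1, learning_rate > 0,
            batch_size >= 1, epochs >= 1)
  structure(list(alpha = alpha, l1_ratio = l1_ratio,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 runs_per_fold = as.integer(runs_per_fold),
                 val_fraction = val_fraction,
                 patience = as.integer(patience)),
            class = "lr_config")
}

.bce <- function(y, p) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the logistic PSI model
#'
#' Fits `sigmoid(X w + b)` to continuous PSI targets with binary
#' cross-entropy loss and an elastic-net penalty on `w`, by minibatch SGD
#' with a proximal (soft-thresholding) L1 update. One model is trained per
#' cell type (single-task).
#'
#' @param features numeric matrix (exons x features).
#' @param targets PSI targets between 0 and 1, one per row of `features`.
#' @param config `lr_config` object.
#' @param seed integer seed for shuffling and the validation split.
#' @return object of class `lr_model`: list(weights, bias, feature_names,
#'   config, history).
#' @export
train_lr <- function(features, targets, config = lr_config(), seed = 1L) {
  if (nrow(features) == 0L) stop("empty training set")
  if (any(targets < 0 | targets > 1, na.rm = TRUE) || anyNA(targets)) {
    stop("targets must lie in [0, 1] and be non-missing")
  }
  X <- as.matrix(features)
  y <- as.numeric(targets)
  p <- ncol(X)
  lr <- config$learning_rate
  with_seed(derive_seed(seed, "model"), {
    n <- nrow(X)
    perm <- sample.int(n)
    n_val <- if (config$val_fraction > 0 && n >= 20L) {
      max(1L, floor(config$val_fraction * n))
    } else 0L
    val_idx <- if (n_val > 0L) perm[seq_len(n_val)] else integer(0L)
    tr_idx <- setdiff(perm, val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]
    w <- numeric(p); b <- 0
    best <- list(w = w, b = b, loss = Inf, epoch = 0L)
    wait <- 0L
    history <- numeric(0L)
    l1 <- config$alpha * config$l1_ratio
    l2 <- config$alpha * (1 - config$l1_ratio)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nrow(Xtr))
      starts <- seq(1L, nrow(Xtr), by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, nrow(Xtr))]
        Xb <- Xtr[idx, , drop = FALSE]
        resid <- plogis(drop(Xb %*% w) + b) - ytr[idx]
        gw <- drop(crossprod(Xb, resid)) / length(idx) + l2 * w
        w <- w - lr * gw
        w <- sign(w) * pmax(abs(w) - lr * l1, 0)  # proximal L1 step
        b <- b - lr * mean(resid)
      }
      mon <- if (n_val > 0L) {
        .bce(yval, plogis(drop(Xval %*% w) + b))
      } else {
        .bce(ytr, plogis(drop(Xtr %*% w) + b))
      }
      history <- c(history, mon)
      if (mon < best$loss - 1e-6) {
        best <- list(w = w, b = b, loss = mon, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(weights = stats::setNames(best$w, colnames(X)),
                   bias = best$b,
                   feature_names = colnames(X), config = config,
                   history = history, stopped_epoch = best$epoch),
              class = "lr_model")
  })
}

#' Predict PSI from binding features
#'
#' Deterministic affine map plus sigmoid; predictions are strictly inside
#' (0, 1).
#'
#' @param model `lr_model` object.
#' @param features numeric matrix with the training feature columns.
#' @return numeric vector of predicted PSI values.
#' @export
predict_lr <- function(model, features) {
  features <- as.matrix(features)
  if (!identical(colnames(features), model$feature_names)) {
    stop("feature columns do not match the training columns")
  }
  eta <- drop(features %*% model$weights) + model$bias
  pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
}

#' Average coefficients across folds and runs
#'
#' Arithmetic mean of each feature's coefficient over all fitted models
#' (10 folds x 5 runs = 50 models in the reference setup). When a feature
#' matrix is supplied, each feature's exon support (number of exons with
#' at least one site) is recorded alongside.
#'
#' @param models list of `lr_model` objects (no missing entries).
#' @param feature_matrix optional feature matrix for support counts.
#' @return data.frame of class `coef_table`: feature, coefficient,
#'   support; attribute `n_models` and `bias`.
#' @export
average_coefficients <- function(models, feature_matrix = NULL) {
  if (length(models) == 0L || any(vapply(models, is.null, logical(1L)))) {
    stop("missing fold/run model")
  }
  fn <- models[[1L]]$feature_names
  for (m in models) {
    if (!identical(m$feature_names, fn)) {
      stop("models do not share feature columns")
    }
  }
  W <- vapply(models, function(m) unname(m$weights),
              numeric(length(fn)))
  support <- if (!is.null(feature_matrix)) {
    as.integer(colSums(feature_matrix[, fn, drop = FALSE] > 0))
  } else NA_integer_
  out <- data.frame(feature = fn, coefficient = rowMeans(W),
                    support = support, stringsAsFactors = FALSE)
  attr(out, "n_models") <- length(models)
  attr(out, "bias") <- mean(vapply(models, `[[`, numeric(1L), "bias"))
  class(out) <- c("coef_table", class(out))
  out
}

#' Rank cell-type-specific feature differences between models
#'
#' Filters features to those supported by at least `min_support` exons and
#' with an absolute averaged coefficient above `min_abs` in at least one
#' model, then ranks them by the absolute coefficient difference between
#' the two tables.
#'
#' @param tables named list of two (or more) `coef_table` objects; the
#'   ranking compares the first two unless `pair` selects others.
#' @param min_support minimal exon support (applied per table where
#'   support is recorded).
#' @param min_abs minimal absolute coefficient in at least one table.
#' @param top_k number of top-ranked features to return.
#' @param pair length-2 character vector naming the tables to rank.
#' @return data.frame: feature, coefficient per table, diff, ordered by
#'   decreasing |diff|, truncated to `top_k`.
#' @export
compare_models <- function(tables, min_support = 50L, min_abs = 0.05,
                           top_k = 10L, pair = NULL) {
  if (length(tables) < 2L) stop("need at least two coefficient tables")
  if (is.null(names(tables))) {
    names(tables) <- paste0("model", seq_along(tables))
  }
  if (is.null(pair)) pair <- names(tables)[1:2]
  feats <- tables[[1L]]$feature
  for (tb in tables) stopifnot(identical(tb$feature, feats))
  coefs <- vapply(tables, `[[`, numeric(length(feats)), "coefficient")
  supports <- vapply(tables, function(tb) {
    if (all(is.na(tb$support))) rep(Inf, length(feats)) else tb$support
  }, numeric(length(feats)))
  keep <- apply(supports, 1L, min) >= min_support &
    apply(abs(coefs), 1L, max) > min_abs
  d <- abs(coefs[, pair[1L]] - coefs[, pair[2L]])
  out <- data.frame(feature = feats, coefs, diff = d,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$diff), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Cross-validated training of the logistic PSI model
#'
#' Trains `runs_per_fold` replicate models per fold on all non-test exons
#' with at least one binding feature, averages the test-fold predictions
#' over replicates, and averages coefficients over all fitted models.
#'
#' @param feature_matrix feature matrix (rownames = exon ids).
#' @param targets named numeric vector of PSI targets (by exon id).
#' @param folds data.frame (exon_id, fold) from [make_folds()].
#' @param config `lr_config` object.
#' @param seed integer seed.
#' @return list: `predictions` (exon_id, fold, pred, all_zero),
#'   `models` (flat list), `coefficients` (`coef_table`).
#' @export
fit_lr_cv <- function(feature_matrix, targets, folds,
                      config = lr_config(), seed = 1L) {
  ids <- rownames(feature_matrix)
  stopifnot(!is.null(ids), all(folds$exon_id %in% ids))
  all_zero <- rowSums(feature_matrix) == 0
  models <- list()
  preds <- list()
  for (f in sort(unique(folds$fold))) {
    test_ids <- folds$exon_id[folds$fold == f]
    train_ids <- setdiff(folds$exon_id, test_ids)
    train_ids <- train_ids[!all_zero[train_ids]]
    Xtr <- feature_matrix[train_ids, , drop = FALSE]
    ytr <- targets[train_ids]
    Xte <- feature_matrix[test_ids, , drop = FALSE]
    run_preds <- matrix(0, length(test_ids), config$runs_per_fold)
    for (r in seq_len(config$runs_per_fold)) {
      m <- train_lr(Xtr, ytr, config, seed = seed * 1000L + f * 10L + r)
      models[[length(models) + 1L]] <- m
      run_preds[, r] <- predict_lr(m, Xte)
    }
    preds[[length(preds) + 1L]] <- data.frame(
      exon_id = test_ids, fold = f, pred = rowMeans(run_preds),
      all_zero = unname(all_zero[test_ids]), stringsAsFactors = FALSE)
  }
  list(predictions = do.call(rbind, c(preds, list(make.row.names = FALSE))),
       models = models,
       coefficients = average_coefficients(models, feature_matrix))
}
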
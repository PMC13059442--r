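## Model interpretation: in-silico saturation mutagenesis (ISM), aggregate
## |ISM| profiles, neighboring-exon scores and export of score arrays for
## external motif discovery.

#' In-silico saturation mutagenesis of one input window
#'
#' For every window position, predicts PSI with each of the four
#' nucleotides substituted (all non-sequence channels held fixed),
#' averages the predictions across replicate models, and centers them per
#' position: `ISM[p, n] = pred[p, n] - mean_i pred[p, i]`. The four scores
#' at a position therefore sum to zero by construction.
#'
#' @param models a `seq_model` or list of replicate `seq_model`s (use the
#'   fold for which the exon was in the test set).
#' @param window input window from [build_input()].
#' @param head head label (multi-head models).
#' @param chunk internal forward-pass batch size.
#' @return object of class `ism_matrix`: list(exon_id, scores
#'   (window x 4 matrix, columns A/C/G/T), predictions, ref, meta).
#' @export
ism <- function(models, window, head = NULL, chunk = 256L) {
  if (inherits(models, "seq_model")) models <- list(models)
  config <- models[[1L]]$config
  head_idx <- if (is.null(head)) 0L else {
    m <- match(head, config$heads) - 1L
    if (is.na(m)) stop("unknown head label")
    m
  }
  P <- matrix(0, config$window, 4L)
  for (m in models) {
    P <- P + cpp_seq_ism(m$params, window$x, head_idx,
                         .cpp_config(config), as.integer(chunk))
  }
  P <- P / length(models)
  scores <- P - rowMeans(P)
  colnames(scores) <- BASES
  colnames(P) <- BASES
  structure(list(exon_id = window$meta$exon_id, scores = scores,
                 predictions = P, ref = window$meta$ref,
                 meta = window$meta),
            class = "ism_matrix")
}

## per-position score magnitude: mean |ISM| over the four nucleotides
.ism_magnitude <- function(mat) rowMeans(abs(mat$scores))

## rescale a numeric vector into a fixed number of bins (mean per bin)
.rebin <- function(v, nbins) {
  n <- length(v)
  if (n == 0L) return(rep(NA_real_, nbins))
  idx <- floor((seq_len(n) - 1L) * nbins / n) + 1L
  out <- rep(NA_real_, nbins)
  agg <- tapply(v, idx, mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' Aggregate |ISM| profile across exons
#'
#' Averages the per-position mean absolute ISM score across exons after
#' rescaling each exon's upstream flank, exon body and downstream flank
#' (which vary in length) into fixed numbers of bins.
#'
#' @param matrices list of `ism_matrix` objects.
#' @param exon_bins bins for the exon body (default 300).
#' @param flank_bins bins for each flank.
#' @return list: `upstream`, `exon`, `downstream` (mean |ISM| per bin),
#'   `n_exons`.
#' @export
ism_profile <- function(matrices, exon_bins = 300L, flank_bins = 300L) {
  stopifnot(length(matrices) >= 1L)
  up <- matrix(NA_real_, length(matrices), flank_bins)
  body <- matrix(NA_real_, length(matrices), exon_bins)
  down <- matrix(NA_real_, length(matrices), flank_bins)
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    v <- .ism_magnitude(m)
    s <- m$meta$exon_from; e <- m$meta$exon_to  # 0-based window coords
    up[i, ] <- .rebin(v[seq_len(s)], flank_bins)
    body[i, ] <- .rebin(v[(s + 1L):e], exon_bins)
    down[i, ] <- .rebin(v[(e + 1L):length(v)], flank_bins)
  }
  list(upstream = colMeans(up, na.rm = TRUE),
       exon = colMeans(body, na.rm = TRUE),
       downstream = colMeans(down, na.rm = TRUE),
       n_exons = length(matrices))
}

#' Maximal |ISM| inside neighboring exons
#'
#' For every annotated exon (other than the exon of interest) overlapping
#' the input window, reports the maximum absolute ISM score inside the
#' exon extended by `flank` bp on each side, ranked decreasingly.
#'
#' @param matrix an `ism_matrix`.
#' @param annotation annotation data.frame.
#' @param flank flanking sequence included per neighbor (bp).
#' @return data.frame: exon_id, max_abs_ism, rank (empty if no neighbor
#'   lies in the window).
#' @export
neighbor_exon_scores <- function(matrix, annotation, flank = 150L) {
  meta <- matrix$meta
  L <- length(meta$ref)
  nb <- annotation[annotation$chrom == meta$chrom &
                     annotation$exon_id != meta$exon_id &
                     annotation$start < meta$w1 &
                     annotation$end > meta$w0, , drop = FALSE]
  if (nrow(nb) == 0L) {
    return(data.frame(exon_id = character(), max_abs_ism = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  mag <- apply(abs(matrix$scores), 1L, max)
  score <- vapply(seq_len(nrow(nb)), function(i) {
    s <- nb$start[i] - flank; e <- nb$end[i] + flank
    if (meta$strand == "+") {
      i0 <- max(0L, s - meta$w0); i1 <- min(L, e - meta$w0)
    } else {
      i0 <- max(0L, meta$w1 - e); i1 <- min(L, meta$w1 - s)
    }
    if (i1 <= i0) return(NA_real_)
    max(mag[(i0 + 1L):i1])
  }, numeric(1L))
  out <- data.frame(exon_id = nb$exon_id, max_abs_ism = score,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$max_abs_ism), , drop = FALSE]
  out <- out[order(-out$max_abs_ism), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Export ISM scores for external motif discovery
#'
#' Writes one TSV per exon (position, reference base, and the four
#' per-nucleotide scores) plus a `metadata.json` sidecar that records the
#' window length, the exon list and the minimum number of sequences per
#' strand (25) required when interpreting strand-ambiguous motifs.
#'
#' @param matrices list of `ism_matrix` objects sharing a window length.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
export_scores <- function(matrices, dir) {
  stopifnot(length(matrices) >= 1L)
  L <- nrow(matrices[[1L]]$scores)
  for (m in matrices) {
    if (nrow(m$scores) != L) stop("inconsistent window lengths")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0L)
  for (m in matrices) {
    p <- file.path(dir, paste0(m$exon_id, "_ism.tsv"))
    df <- data.frame(position = seq_len(L), ref = m$ref,
                     round(m$scores, 10))
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- file.path(dir, "metadata.json")
  exon_list <- paste0('"', vapply(matrices, `[[`, "", "exon_id"), '"',
                      collapse = ", ")
  writeLines(sprintf(paste0(
    '{"n_exons": %d, "window": %d, "min_strand_sequences": 25, ',
    '"exons": [%s]}'), length(matrices), L, exon_list), meta)
  invisible(c(paths, meta))
}

#' Read back exported ISM scores
#'
#' @param path a `<exon>_ism.tsv` file written by [export_scores()].
#' @return list(scores, ref).
#' @export
read_ism_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  scores <- as.matrix(df[, BASES])
  dimnames(scores) <- list(NULL, BASES)
  list(scores = scores, ref = df$ref)
}
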
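## Gene/homolog-grouped fold construction, rank-correlation evaluation,
## subgroup error analyses and thin wrappers around the distribution
## comparisons used downstream.

#' Build gene-grouped cross-validation folds
#'
#' Exons from the same gene always share a fold; when a homolog map is
#' supplied, homologous genes (connected components over homolog edges)
#' also share a fold. Groups are assigned greedily, largest first, to the
#' currently smallest fold, after a seeded shuffle for tie-breaking.
#'
#' @param exons data.frame with exon_id and gene_id.
#' @param homolog_map optional data.frame (gene_a, gene_b) of homologous
#'   gene pairs.
#' @param k number of folds.
#' @param seed integer seed.
#' @return data.frame (exon_id, fold) of class `fold_assignment`.
#' @export
make_folds <- function(exons, homolog_map = NULL, k = 10L, seed = 1L) {
  stopifnot(all(c("exon_id", "gene_id") %in% names(exons)))
  genes <- unique(exons$gene_id)
  ## union-find over genes, joined by homolog edges
  parent <- stats::setNames(seq_along(genes), genes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(homolog_map) && nrow(homolog_map) > 0L) {
    for (r in seq_len(nrow(homolog_map))) {
      a <- homolog_map$gene_a[r]; b <- homolog_map$gene_b[r]
      if (a %in% genes && b %in% genes) {
        ra <- find(match(a, genes)); rb <- find(match(b, genes))
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  root <- vapply(seq_along(genes), find, numeric(1L))
  group_of_gene <- stats::setNames(match(root, unique(root)), genes)
  group_of_exon <- group_of_gene[exons$gene_id]
  n_groups <- max(group_of_exon)
  if (k > n_groups) {
    stop("k = ", k, " exceeds the number of gene groups (", n_groups, ")")
  }
  sizes <- tabulate(group_of_exon, n_groups)
  ord <- with_seed(derive_seed(seed, "folds"), sample.int(n_groups))
  ord <- ord[order(-sizes[ord])]  # largest first, seeded tie-break
  fold_sizes <- numeric(k)
  fold_of_group <- integer(n_groups)
  for (g in ord) {
    f <- which.min(fold_sizes)
    fold_of_group[g] <- f
    fold_sizes[f] <- fold_sizes[f] + sizes[g]
  }
  out <- data.frame(exon_id = exons$exon_id,
                    fold = fold_of_group[group_of_exon],
                    stringsAsFactors = FALSE)
  class(out) <- c("fold_assignment", class(out))
  out
}

#' Per-fold Spearman correlation and its median
#'
#' @param truth,pred numeric vectors named by exon id, or unnamed vectors
#'   aligned with `folds`.
#' @param folds data.frame (exon_id, fold).
#' @param subset optional character vector of exon ids to evaluate on
#'   (e.g. variable exons).
#' @param min_pairs minimal pairs per fold to report a coefficient.
#' @return list: `per_fold` (data.frame fold, spearman, n), `median`.
#' @export
spearman_eval <- function(truth, pred, folds, subset = NULL,
                          min_pairs = 3L) {
  ids <- folds$exon_id
  if (!is.null(names(truth))) truth <- truth[ids]
  if (!is.null(names(pred))) pred <- pred[ids]
  keep <- !is.na(truth) & !is.na(pred)
  if (!is.null(subset)) keep <- keep & ids %in% subset
  per_fold <- lapply(sort(unique(folds$fold)), function(f) {
    sel <- keep & folds$fold == f
    n <- sum(sel)
    rho <- if (n >= min_pairs) {
      t_sel <- truth[sel]; p_sel <- pred[sel]
      if (stats::sd(t_sel) == 0 || stats::sd(p_sel) == 0) NA_real_ else
        stats::cor(t_sel, p_sel, method = "spearman")
    } else NA_real_
    data.frame(fold = f, spearman = rho, n = n)
  })
  per_fold <- do.call(rbind, per_fold)
  list(per_fold = per_fold,
       median = stats::median(per_fold$spearman, na.rm = TRUE))
}

#' Exon metadata for subgroup error analyses
#'
#' Derives, per cassette exon: the length class (microexons of at most
#' 27 bp; 28-100; 101-200; over 200), frame consistency (length divisible
#' by three), the flanking-intron length class (below 101; 101-1000; over
#' 1000 bp, on the mean of the two flanking introns) and the number of
#' annotated exons inside the model window.
#'
#' @param annotation annotation data.frame.
#' @param window model window length (bp) for the exon count.
#' @return data.frame keyed by exon_id.
#' @export
exon_metadata <- function(annotation, window = 6144L) {
  cas <- annotation[annotation$role == "cassette", , drop = FALSE]
  len <- cas$end - cas$start
  len_class <- cut(len, c(-Inf, 27, 100, 200, Inf),
                   labels = c("<=27", "28-100", "101-200", ">200"))
  intron_mean <- numeric(nrow(cas))
  n_in_window <- integer(nrow(cas))
  for (i in seq_len(nrow(cas))) {
    g <- annotation[annotation$gene_id == cas$gene_id[i], ]
    left <- g[g$rank == cas$rank[i] - 1L, ]
    right <- g[g$rank == cas$rank[i] + 1L, ]
    intron_mean[i] <- mean(c(cas$start[i] - left$end,
                             right$start - cas$end))
    center <- (cas$start[i] + cas$end[i]) %/% 2L
    w0 <- center - window %/% 2L; w1 <- center + window %/% 2L
    n_in_window[i] <- sum(g$start < w1 & g$end > w0)
  }
  data.frame(
    exon_id = cas$exon_id, length = len, length_class = len_class,
    frame_consistent = len %% 3L == 0L,
    intron_class = cut(intron_mean, c(-Inf, 100, 1000, Inf),
                       labels = c("<101", "101-1000", ">1000")),
    n_exons_window = n_in_window, stringsAsFactors = FALSE)
}

#' Mean squared error per exon subgroup
#'
#' @param truth,pred numeric vectors named by exon id.
#' @param metadata data.frame from [exon_metadata()].
#' @param group_cols metadata columns to group by.
#' @return data.frame: grouping, group level, mse, n (empty groups are
#'   reported as missing, not zero).
#' @export
subgroup_mse <- function(truth, pred, metadata,
                         group_cols = c("length_class",
                                        "frame_consistent",
                                        "intron_class")) {
  ids <- metadata$exon_id
  t_v <- truth[ids]; p_v <- pred[ids]
  ok <- !is.na(t_v) & !is.na(p_v)
  out <- list()
  for (gc in group_cols) {
    levs <- if (is.factor(metadata[[gc]])) levels(metadata[[gc]]) else
      sort(unique(metadata[[gc]]))
    for (lv in levs) {
      sel <- ok & metadata[[gc]] == lv
      out[[length(out) + 1L]] <- data.frame(
        grouping = gc, level = as.character(lv),
        mse = if (any(sel)) mean((t_v[sel] - p_v[sel])^2) else NA_real_,
        n = sum(sel), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Distribution-comparison wrappers
#'
#' Thin named wrappers over the standard two-sided tests used when
#' comparing splicing statistics between exon groups: Kolmogorov-Smirnov,
#' Wilcoxon rank-sum, paired Wilcoxon signed-rank and Fisher's exact test
#' on a 2x2 table.
#'
#' @param x,y numeric vectors (for `fisher_2x2`, a 2x2 integer matrix
#'   `tab`).
#' @param tab 2x2 contingency matrix.
#' @return the corresponding `htest` object.
#' @name distribution_tests
NULL

#' @rdname distribution_tests
#' @export
ks_compare <- function(x, y) stats::ks.test(x, y, alternative = "two.sided")

#' @rdname distribution_tests
#' @export
ranksum_compare <- function(x, y) {
  stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
}

#' @rdname distribution_tests
#' @export
signedrank_compare <- function(x, y) {
  stats::wilcox.test(x, y, paired = TRUE, alternative = "two.sided",
                     exact = FALSE)
}

#' @rdname distribution_tests
#' @export
fisher_2x2 <- function(tab) stats::fisher.test(tab, alternative = "two.sided")
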
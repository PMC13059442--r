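## Positional RBP-binding features: replicate merging, the six-location
## category assignment, the exon x (RBP x category) count matrix, 50-bin
## metagene binding profiles and their divergence statistics.

#' Merge replicate peak files into one peak set
#'
#' Union-merges overlapping or bookended intervals across replicates (or
#' cell lines) so that multiply-measured peaks are counted only once.
#'
#' @param x either a character vector of BED paths for one RBP, or a peak
#'   data.frame (chrom, start, end) pooled over replicates.
#' @param rbp_name name of the RBP (taken from the first BED file name if
#'   missing).
#' @return object of class `peak_set`: list(rbp_name, intervals) with
#'   merged, sorted, 0-based half-open intervals.
#' @export
merge_replicates <- function(x, rbp_name = NULL) {
  if (is.character(x)) {
    if (is.null(rbp_name)) rbp_name <- sub("\\.bed$", "", basename(x[1L]))
    x <- read_peaks_bed(stats::setNames(x, rep(rbp_name, length(x))))
  }
  if (is.null(rbp_name)) {
    rbp_name <- if ("rbp" %in% names(x)) x$rbp[1L] else "RBP"
  }
  merged <- lapply(split(x, x$chrom), function(p) {
    r <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    data.frame(chrom = p$chrom[1L], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, c(merged, list(make.row.names = FALSE)))
  if (is.null(merged)) {
    merged <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  }
  structure(list(rbp_name = rbp_name, intervals = merged),
            class = "peak_set")
}

#' Build one merged peak set per RBP
#'
#' @param peaks pooled peak data.frame with an `rbp` column, or a directory
#'   of `<rbp>.bed` files.
#' @return named list of `peak_set` objects.
#' @export
make_peaksets <- function(peaks) {
  if (is.character(peaks)) peaks <- read_peaks_bed(peaks)
  lapply(split(peaks, peaks$rbp), function(p) {
    merge_replicates(p, rbp_name = p$rbp[1L])
  })
}

#' Assign a peak to one of the six positional categories
#'
#' Categories relative to a cassette exon, strand-aware: `spanning` (peak
#' contains the whole exon), `acc_overlap` / `don_overlap` (peak crosses
#' the acceptor / donor boundary without containing the exon), `exonic`
#' (fully inside the exon), and `upstream` / `downstream` (fully in the
#' transcriptionally 5' / 3' flank with its nearest edge within
#' `flank_max` bp of the splice site). Peaks entirely outside the window
#' return `NA`. The definitions are mutually exclusive.
#'
#' @param peak_start,peak_end peak interval(s), 0-based half-open
#'   (vectorized).
#' @param exon_start,exon_end exon interval, 0-based half-open.
#' @param strand "+" or "-".
#' @param flank_max maximal flank distance from the splice site (bp).
#' @return character vector of categories (NA when out of range).
#' @export
assign_category <- function(peak_start, peak_end, exon_start, exon_end,
                            strand, flank_max = 400L) {
  inside <- peak_start >= exon_start & peak_end <= exon_end
  contains <- peak_start <= exon_start & peak_end >= exon_end & !inside
  cross_l <- peak_start < exon_start & peak_end > exon_start &
    !inside & !contains
  cross_r <- peak_start < exon_end & peak_end > exon_end &
    !inside & !contains
  left_fl <- peak_end <= exon_start & peak_end > exon_start - flank_max
  right_fl <- peak_start >= exon_end & peak_start < exon_end + flank_max
  out <- rep(NA_character_, length(peak_start))
  if (strand == "+") {
    out[left_fl] <- "upstream"; out[right_fl] <- "downstream"
    out[cross_l] <- "acc_overlap"; out[cross_r] <- "don_overlap"
  } else {
    out[left_fl] <- "downstream"; out[right_fl] <- "upstream"
    out[cross_l] <- "don_overlap"; out[cross_r] <- "acc_overlap"
  }
  out[inside] <- "exonic"
  out[contains] <- "spanning"
  out
}

#' Build the exon x (RBP x category) feature matrix
#'
#' Counts merged peaks per exon, RBP and positional category. With 122
#' RBPs this yields the 732-column positional feature matrix. Exons
#' without any peak across all RBPs are flagged via the `all_zero`
#' attribute (they cannot be predicted from binding features).
#'
#' @param exons data.frame with exon_id, chrom, start, end, strand.
#' @param peaksets named list of `peak_set` objects (see
#'   [make_peaksets()]).
#' @param flank_max maximal flank distance (bp).
#' @return integer matrix (exons x features) with `RBP:category` column
#'   names and an `all_zero` logical attribute.
#' @export
build_feature_matrix <- function(exons, peaksets, flank_max = 400L) {
  stopifnot(nrow(exons) >= 1L, length(peaksets) >= 1L)
  rbps <- names(peaksets)
  fm <- matrix(0L, nrow = nrow(exons), ncol = 6L * length(rbps),
               dimnames = list(exons$exon_id,
                               paste(rep(rbps, each = 6L), CATEGORIES,
                                     sep = ":")))
  ## embed all chromosomes on one axis so each RBP needs one overlap query
  all_chroms <- unique(c(exons$chrom,
                         unlist(lapply(peaksets, function(p) {
                           p$intervals$chrom
                         }), use.names = FALSE)))
  span <- max(exons$end + flank_max,
              vapply(peaksets, function(p) {
                if (nrow(p$intervals) == 0L) 0L else max(p$intervals$end)
              }, numeric(1L))) + 2L * flank_max + 10L
  offset <- stats::setNames((seq_along(all_chroms) - 1L) * span,
                            all_chroms)
  e_off <- offset[exons$chrom]
  win <- IRanges::IRanges(exons$start + e_off - flank_max + 1L,
                          exons$end + e_off + flank_max)
  for (r in seq_along(rbps)) {
    ivs <- peaksets[[r]]$intervals
    if (nrow(ivs) == 0L) next
    p_off <- offset[ivs$chrom]
    pk <- IRanges::IRanges(ivs$start + p_off + 1L, ivs$end + p_off)
    ov <- IRanges::findOverlaps(win, pk)
    if (length(ov) == 0L) next
    e_row <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    for (strand in c("+", "-")) {
      sel <- exons$strand[e_row] == strand
      if (!any(sel)) next
      cat_k <- assign_category(ivs$start[si[sel]], ivs$end[si[sel]],
                               exons$start[e_row[sel]],
                               exons$end[e_row[sel]], strand, flank_max)
      valid <- !is.na(cat_k)
      if (!any(valid)) next
      col <- (r - 1L) * 6L + match(cat_k[valid], CATEGORIES)
      inc <- table(row = e_row[sel][valid], col = col)
      cells <- cbind(as.integer(rownames(inc))[row(inc)],
                     as.integer(colnames(inc))[col(inc)])
      fm[cells] <- fm[cells] + as.integer(inc)
    }
  }
  attr(fm, "all_zero") <- rowSums(fm) == 0L
  fm
}

## indicator matrix (qualifying exons x profile positions) for one RBP
.coverage_matrix <- function(exons, peakset, flank, bins, min_width) {
  keep <- (exons$end - exons$start) >= min_width
  exons <- exons[keep, , drop = FALSE]
  ivs_by_chrom <- split(peakset$intervals, peakset$intervals$chrom)
  out <- matrix(0, nrow(exons), 2L * flank + bins,
                dimnames = list(exons$exon_id, NULL))
  for (i in seq_len(nrow(exons))) {
    out[i, ] <- .profile_vector(exons[i, ],
                                ivs_by_chrom[[exons$chrom[i]]],
                                flank, bins)
  }
  out
}

## strand-oriented coverage vector over flank + 50 exon bins + flank
.profile_vector <- function(exon, ivs, flank, bins) {
  s <- exon$start; e <- exon$end; len <- e - s
  w0 <- s - flank; w1 <- e + flank
  cov <- logical(w1 - w0)
  if (!is.null(ivs) && nrow(ivs) > 0L) {
    ps <- pmax(ivs$start, w0); pe <- pmin(ivs$end, w1)
    for (i in which(ps < pe)) {
      cov[(ps[i] - w0 + 1L):(pe[i] - w0)] <- TRUE
    }
  }
  left <- cov[seq_len(flank)]
  body <- cov[(flank + 1L):(flank + len)]
  right <- cov[(flank + len + 1L):(flank + len + flank)]
  bin_idx <- floor((seq_len(len) - 1L) * bins / len) + 1L
  body_bins <- as.logical(tapply(body, bin_idx, any))
  if (exon$strand == "+") {
    c(left, body_bins, right)
  } else {
    c(rev(right), rev(body_bins), rev(left))
  }
}

#' Metagene binding profile of one RBP over an exon group
#'
#' At each of `flank + bins + flank` strand-oriented positions (flank
#' positions are single-base, the exon body is rescaled into `bins` equal
#' bins), the fraction of group exons covered by at least one merged peak
#' of this RBP. Only exons of at least `min_width` bp enter the profile;
#' exons should additionally be pre-filtered to those with at least one
#' binding site (any RBP).
#'
#' @param exons data.frame of group exons (exon_id, chrom, start, end,
#'   strand).
#' @param peakset `peak_set` object.
#' @param group_label free-text label of the exon group.
#' @param flank flank length (bp).
#' @param bins number of exon-body bins.
#' @param min_width minimal exon width (bp).
#' @return object of class `binding_profile`: list(rbp_name, group,
#'   fractions, n_exons).
#' @export
binding_profile <- function(exons, peakset, group_label = "all",
                            flank = 400L, bins = 50L, min_width = 50L) {
  keep <- (exons$end - exons$start) >= min_width
  exons <- exons[keep, , drop = FALSE]
  if (nrow(exons) == 0L) stop("no qualifying exons in group ", group_label)
  ivs_by_chrom <- split(peakset$intervals, peakset$intervals$chrom)
  acc <- numeric(2L * flank + bins)
  for (i in seq_len(nrow(exons))) {
    acc <- acc + .profile_vector(exons[i, ], ivs_by_chrom[[exons$chrom[i]]],
                                 flank, bins)
  }
  structure(list(rbp_name = peakset$rbp_name, group = group_label,
                 fractions = acc / nrow(exons), n_exons = nrow(exons)),
            class = "binding_profile")
}

#' Binding-profile divergence between variable and non-variable exons
#'
#' For every RBP and cell type, builds metagene profiles of the four exon
#' groups (variable / non-variable crossed with high / low PSI at
#' `psi_threshold`), computes the mean-squared error between the variable
#' and non-variable profiles separately in the high- and low-PSI strata,
#' and compares the per-RBP MSE distributions of the two cell types with a
#' two-sided paired Wilcoxon signed-rank test (pairing on RBP x stratum).
#'
#' @param wide wide PSI table ([psi_wide()]) with psi_neuron / psi_glia /
#'   delta_psi.
#' @param exons annotation rows for the exons in `wide` (exon_id, chrom,
#'   start, end, strand).
#' @param peaksets named list of `peak_set` objects.
#' @param feature_matrix optional feature matrix used to drop exons
#'   without any binding site (rebuilt when missing).
#' @param var_threshold variability threshold on |delta_psi|.
#' @param psi_threshold high/low PSI split.
#' @param flank,bins,min_width profile geometry (see [binding_profile()]).
#' @param min_exons minimal exons per group; RBP-independent groups below
#'   this size abort with an error.
#' @return list: `mse` (data.frame rbp, cell_type, stratum, mse),
#'   `wilcoxon` (htest), `skipped` (character vector of skipped RBPs).
#' @export
profile_divergence <- function(wide, exons, peaksets,
                               feature_matrix = NULL,
                               var_threshold = 0.25, psi_threshold = 0.5,
                               flank = 400L, bins = 50L, min_width = 50L,
                               min_exons = 3L) {
  exons <- exons[match(wide$exon_id, exons$exon_id), , drop = FALSE]
  if (is.null(feature_matrix)) {
    feature_matrix <- build_feature_matrix(exons, peaksets, flank)
  }
  has_site <- !attr(feature_matrix, "all_zero")[
    match(wide$exon_id, rownames(feature_matrix))]
  ok <- has_site & !is.na(wide$delta_psi)
  wide <- wide[ok, , drop = FALSE]; exons <- exons[ok, , drop = FALSE]
  is_var <- abs(wide$delta_psi) > var_threshold
  groups <- list()
  for (ct in CELL_TYPES) {
    psi_ct <- wide[[paste0("psi_", ct)]]
    for (stratum in c("high", "low")) {
      in_stratum <- if (stratum == "high") psi_ct >= psi_threshold else
        psi_ct < psi_threshold
      g_var <- exons[is_var & in_stratum, , drop = FALSE]
      g_non <- exons[!is_var & in_stratum, , drop = FALSE]
      big_enough <- function(g) {
        sum((g$end - g$start) >= min_width) >= min_exons
      }
      if (!big_enough(g_var) || !big_enough(g_non)) {
        stop("group too small: ", ct, "/", stratum,
             " (variable: ", nrow(g_var), ", non-variable: ",
             nrow(g_non), ")")
      }
      groups[[paste(ct, stratum)]] <- list(ct = ct, stratum = stratum,
                                           var = g_var$exon_id,
                                           non = g_non$exon_id)
    }
  }
  mse_rows <- list(); skipped <- character(0L)
  for (r in names(peaksets)) {
    if (nrow(peaksets[[r]]$intervals) == 0L) {
      skipped <- unique(c(skipped, r)); next
    }
    cov <- .coverage_matrix(exons, peaksets[[r]], flank, bins, min_width)
    for (g in groups) {
      fv <- colMeans(cov[rownames(cov) %in% g$var, , drop = FALSE])
      fn <- colMeans(cov[rownames(cov) %in% g$non, , drop = FALSE])
      mse_rows[[length(mse_rows) + 1L]] <- data.frame(
        rbp = r, cell_type = g$ct, stratum = g$stratum,
        mse = mean((fv - fn)^2), stringsAsFactors = FALSE)
    }
  }
  mse <- do.call(rbind, c(mse_rows, list(make.row.names = FALSE)))
  sub_n <- mse[mse$cell_type == "neuron", ]
  sub_g <- mse[mse$cell_type == "glia", ]
  kn <- paste(sub_n$rbp, sub_n$stratum)
  kg <- paste(sub_g$rbp, sub_g$stratum)
  common <- intersect(kn, kg)
  wt <- stats::wilcox.test(sub_n$mse[match(common, kn)],
                           sub_g$mse[match(common, kg)],
                           paired = TRUE, alternative = "two.sided",
                           exact = FALSE)
  list(mse = mse, wilcoxon = wt, skipped = skipped)
}
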
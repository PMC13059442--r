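## Percent-spliced-in quantification from long-read exon chains: the five
## read-count classes per exon, depth normalization across individuals,
## the three PSI formulas, range/support filters, variability calls,
## skew downsampling and the exon-coordination test.

## parse the encoded chain column once into flat arrays
parse_chains <- function(chains) {
  parts <- strsplit(chains$exons, ";", fixed = TRUE)
  n_iv <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  se <- matrix(as.integer(unlist(strsplit(flat, "-", fixed = TRUE),
                                 use.names = FALSE)),
               ncol = 2L, byrow = TRUE)
  lasts <- cumsum(n_iv)
  firsts <- lasts - n_iv + 1L
  list(
    read = data.frame(chrom = chains$chrom,
                      individual = chains$individual,
                      cell_type = chains$cell_type,
                      span_start = se[firsts, 1L],
                      span_end = se[lasts, 2L],
                      stringsAsFactors = FALSE),
    iv_start = se[, 1L], iv_end = se[, 2L],
    iv_read = rep.int(seq_along(parts), n_iv))
}

## the five count classes for one exon, over a set of parsed reads
## (indices `ridx` into parsed$read, all on the exon's chromosome)
.count_one_exon <- function(parsed, ridx, s, en, strand, min_side = 50L) {
  sel <- parsed$iv_read %in% ridx
  ivs <- parsed$iv_start[sel]; ive <- parsed$iv_end[sel]
  ivr <- parsed$iv_read[sel]
  rd <- parsed$read[ridx, , drop = FALSE]
  pos <- match(ivr, ridx)  # interval -> local read index

  ## exact inclusion: an interval matching both splice sites
  has_in <- logical(length(ridx))
  hit <- ivs == s & ive == en
  has_in[unique(pos[hit])] <- TRUE

  ## any overlap of an interval with the exon body
  ov <- ivs < en & ive > s
  has_ov <- logical(length(ridx))
  has_ov[unique(pos[ov])] <- TRUE

  ## aligned bases left / right of the exon
  left <- pmax(0L, pmin(ive, s) - ivs)
  right <- pmax(0L, ive - pmax(ivs, en))
  left_cov <- rowsum(left, pos, reorder = FALSE)
  right_cov <- rowsum(right, pos, reorder = FALSE)
  lc <- rc <- integer(length(ridx))
  ord <- as.integer(rownames(left_cov))
  lc[ord] <- left_cov[, 1L]; rc[ord] <- right_cov[, 1L]

  x_out <- !has_ov & lc >= min_side & rc >= min_side

  ## truncated reads ending on the exon, split by which splice site they
  ## support (strand decides which boundary is the acceptor)
  term_right <- ivs == s & ive < en & ive == rd$span_end[pos]   # ends inside,
  term_left <- ive == en & ivs > s & ivs == rd$span_start[pos]  # anchored
  r_right <- r_left <- logical(length(ridx))
  r_right[unique(pos[term_right])] <- TRUE
  r_left[unique(pos[term_left])] <- TRUE
  if (strand == "+") {
    x_acc <- r_right & !has_in
    x_don <- r_left & !has_in
  } else {
    x_acc <- r_left & !has_in
    x_don <- r_right & !has_in
  }

  ## X_tot: molecule span overlaps the exon locus (>= 1 bp)
  x_tot <- rd$span_start < en & rd$span_end > s

  grp <- paste(rd$individual, rd$cell_type, sep = "\r")
  agg <- function(x) {
    if (length(x) == 0L) return(integer(0L))
    tapply(as.integer(x), grp, sum)
  }
  u <- sort(unique(grp))
  tab <- function(x) {
    a <- agg(x)
    out <- stats::setNames(integer(length(u)), u)
    out[names(a)] <- as.integer(a)
    out
  }
  parts <- strsplit(u, "\r", fixed = TRUE)
  data.frame(
    individual = vapply(parts, `[[`, "", 1L),
    cell_type = vapply(parts, `[[`, "", 2L),
    X_in = unname(tab(has_in)), X_out = unname(tab(x_out)),
    X_accIn = unname(tab(x_acc)), X_donIn = unname(tab(x_don)),
    X_tot = unname(tab(x_tot)), stringsAsFactors = FALSE)
}

#' Count the five read classes for one exon
#'
#' Classifies every molecule overlapping an exon locus into the count
#' classes used for PSI: exact inclusion with both splice sites (`X_in`),
#' same-gene skipping with at least `min_side` aligned bases on each side
#' (`X_out`), truncated molecules supporting only the acceptor or only the
#' donor and ending on the exon (`X_accIn`, `X_donIn`), and all molecules
#' whose span overlaps the exon (`X_tot`).
#'
#' @param chains chain data.frame (see [gen_reads()] / [read_chains()]).
#' @param exon exon_id present in `annotation`.
#' @param annotation annotation data.frame.
#' @param min_side minimum aligned bases on each side for a skipping read.
#' @return data.frame with one row per (individual, cell_type):
#'   exon_id, individual, cell_type, X_in, X_out, X_accIn, X_donIn, X_tot.
#' @export
count_exon_reads <- function(chains, exon, annotation, min_side = 50L) {
  a <- annotation[annotation$exon_id == exon, , drop = FALSE]
  if (nrow(a) == 0L) stop("unknown exon: ", exon)
  off_chrom <- sum(chains$chrom != a$chrom)
  if (off_chrom > 0L) {
    message(off_chrom, " chains on other chromosomes ignored for ", exon)
  }
  sub <- chains[chains$chrom == a$chrom, , drop = FALSE]
  parsed <- parse_chains(sub)
  res <- .count_one_exon(parsed, seq_len(nrow(sub)), a$start, a$end,
                         a$strand, min_side)
  if (nrow(res) > 0L) res <- cbind(exon_id = exon, res)
  res
}

#' Count read classes for many exons at once
#'
#' Vectorized driver over all cassette exons (or a supplied subset),
#' parsing the chain table once.
#'
#' @param chains chain data.frame.
#' @param annotation annotation data.frame.
#' @param exon_ids exons to count (default: all cassette exons).
#' @param min_side minimum aligned bases on each side for a skipping read.
#' @return ExonCounts data.frame (one row per exon x individual x
#'   cell type).
#' @export
count_reads <- function(chains, annotation, exon_ids = NULL,
                        min_side = 50L) {
  if (is.null(exon_ids)) {
    exon_ids <- annotation$exon_id[annotation$role == "cassette"]
  }
  miss <- setdiff(exon_ids, annotation$exon_id)
  if (length(miss) > 0L) stop("unknown exon: ", miss[1L])
  parsed <- parse_chains(chains)
  by_chrom <- split(seq_len(nrow(chains)), chains$chrom)
  out <- vector("list", length(exon_ids))
  for (i in seq_along(exon_ids)) {
    a <- annotation[annotation$exon_id == exon_ids[i], ]
    ridx <- by_chrom[[a$chrom]]
    if (is.null(ridx)) ridx <- integer(0L)
    res <- .count_one_exon(parsed, ridx, a$start, a$end, a$strand, min_side)
    if (nrow(res) > 0L) out[[i]] <- cbind(exon_id = exon_ids[i], res)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) {
    res <- data.frame(exon_id = character(), individual = character(),
                      cell_type = character(), X_in = integer(),
                      X_out = integer(), X_accIn = integer(),
                      X_donIn = integer(), X_tot = integer())
  }
  res
}

#' Exclude intron-retention-like exon candidates
#'
#' Non-annotated exon candidates that reuse one or two annotated splice
#' sites and contain at least `min_nonexonic` bases that are non-exonic in
#' the annotation are removed as likely intron-retention events or
#' alternative acceptors/donors.
#'
#' @param candidates data.frame (chrom, start, end), 0-based half-open.
#' @param annotation annotation data.frame of annotated exons.
#' @param min_nonexonic threshold of non-exonic bases for removal.
#' @return the kept rows of `candidates`.
#' @export
exclude_retention_like <- function(candidates, annotation,
                                   min_nonexonic = 70L) {
  if (nrow(candidates) == 0L) return(candidates)
  keep <- logical(nrow(candidates))
  ann_by_chrom <- split(annotation, annotation$chrom)
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    a <- ann_by_chrom[[cand$chrom]]
    if (is.null(a)) a <- annotation[0L, ]
    annotated <- any(a$start == cand$start & a$end == cand$end)
    if (annotated) { keep[i] <- TRUE; next }
    sites <- sum(cand$start %in% c(a$start, a$end),
                 cand$end %in% c(a$start, a$end))
    exonic <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
    cand_ir <- IRanges::IRanges(cand$start + 1L, cand$end)
    ov <- sum(IRanges::width(IRanges::intersect(cand_ir, exonic)))
    nonexonic <- (cand$end - cand$start) - ov
    keep[i] <- !(sites >= 1L && nonexonic >= min_nonexonic)
  }
  candidates[keep, , drop = FALSE]
}

#' Depth-normalize counts and build the pseudo-bulk table
#'
#' Divides each individual's five count classes by that individual's total
#' read count, then sums the normalized counts across individuals per exon
#' and cell type. The raw (un-normalized) `X_tot`, summed across
#' individuals, is kept alongside for the minimum-support rule.
#'
#' @param counts ExonCounts data.frame from [count_reads()].
#' @param read_totals data.frame (individual, total); computed from
#'   `chains` when omitted.
#' @param chains chain data.frame used to derive totals if `read_totals`
#'   is missing.
#' @return pseudo-bulk data.frame per exon x cell type: normalized n_in,
#'   n_out, n_accIn, n_donIn, n_tot plus raw_tot.
#' @export
normalize_by_depth <- function(counts, read_totals = NULL, chains = NULL) {
  if (is.null(read_totals)) {
    if (is.null(chains)) stop("supply read_totals or chains")
    tb <- table(chains$individual)
    read_totals <- data.frame(individual = names(tb),
                              total = as.numeric(tb),
                              stringsAsFactors = FALSE)
  }
  zero <- read_totals$individual[read_totals$total == 0]
  if (length(zero) > 0L) {
    warning("dropping individuals with zero total reads: ",
            paste(zero, collapse = ", "))
    counts <- counts[!counts$individual %in% zero, , drop = FALSE]
    read_totals <- read_totals[read_totals$total > 0, , drop = FALSE]
  }
  tot <- read_totals$total[match(counts$individual,
                                 read_totals$individual)]
  if (anyNA(tot)) stop("individual missing from read_totals")
  key <- paste(counts$exon_id, counts$cell_type, sep = "\r")
  norm <- function(x) rowsum(x / tot, key, reorder = TRUE)
  m <- cbind(n_in = norm(counts$X_in), n_out = norm(counts$X_out),
             n_accIn = norm(counts$X_accIn),
             n_donIn = norm(counts$X_donIn), n_tot = norm(counts$X_tot))
  raw <- rowsum(counts$X_tot, key, reorder = TRUE)
  parts <- strsplit(rownames(m), "\r", fixed = TRUE)
  data.frame(exon_id = vapply(parts, `[[`, "", 1L),
             cell_type = vapply(parts, `[[`, "", 2L),
             n_in = m[, 1L], n_out = m[, 2L], n_accIn = m[, 3L],
             n_donIn = m[, 4L], n_tot = m[, 5L],
             raw_tot = raw[, 1L], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pool pseudo-bulk counts over cell types
#'
#' @param pseudo_bulk pseudo-bulk data.frame from [normalize_by_depth()].
#' @return one row per exon with counts summed over cell types
#'   (cell_type = "all").
#' @export
pool_cell_types <- function(pseudo_bulk) {
  num <- c("n_in", "n_out", "n_accIn", "n_donIn", "n_tot", "raw_tot")
  agg <- rowsum(as.matrix(pseudo_bulk[, num]), pseudo_bulk$exon_id,
                reorder = TRUE)
  data.frame(exon_id = rownames(agg), cell_type = "all",
             agg, row.names = NULL, stringsAsFactors = FALSE)
}

#' Compute the three PSI values
#'
#' `psi_overall = (n_in + n_accIn + n_donIn) / (n_in + n_accIn + n_donIn +
#' n_out)`; the acceptor and donor variants drop the count class supporting
#' the other splice site. PSI is missing when the raw read support is below
#' `min_reads` or a denominator is zero.
#'
#' @param pseudo_bulk pseudo-bulk data.frame from [normalize_by_depth()]
#'   (or [pool_cell_types()]).
#' @param min_reads minimum raw `X_tot` (summed over individuals) required
#'   to report PSI.
#' @return PsiRecord data.frame: exon_id, cell_type, psi_overall,
#'   psi_acceptor, psi_donor, n_reads.
#' @export
compute_psi <- function(pseudo_bulk, min_reads = 10L) {
  pb <- pseudo_bulk
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  num_o <- pb$n_in + pb$n_accIn + pb$n_donIn
  psi_o <- ratio(num_o, num_o + pb$n_out)
  psi_a <- ratio(pb$n_in + pb$n_accIn, pb$n_in + pb$n_accIn + pb$n_out)
  psi_d <- ratio(pb$n_in + pb$n_donIn, pb$n_in + pb$n_donIn + pb$n_out)
  low <- pb$raw_tot < min_reads
  psi_o[low] <- NA_real_; psi_a[low] <- NA_real_; psi_d[low] <- NA_real_
  data.frame(exon_id = pb$exon_id, cell_type = pb$cell_type,
             psi_overall = psi_o, psi_acceptor = psi_a, psi_donor = psi_d,
             n_reads = pb$raw_tot, stringsAsFactors = FALSE)
}

#' Keep exons whose pseudo-bulk PSI is away from the extremes
#'
#' An exon is kept iff all of psi_overall, psi_acceptor and psi_donor lie
#' in `[lo, hi]` (inclusive) in the supplied (typically cell-type-pooled)
#' records. Exons with any missing PSI are dropped.
#'
#' @param records PsiRecord data.frame from [compute_psi()].
#' @param lo,hi inclusive bounds (defaults 0.02 and 0.98).
#' @return character vector of kept exon ids.
#' @export
filter_psi_range <- function(records, lo = 0.02, hi = 0.98) {
  ok <- records$psi_overall >= lo & records$psi_overall <= hi &
    records$psi_acceptor >= lo & records$psi_acceptor <= hi &
    records$psi_donor >= lo & records$psi_donor <= hi
  ok[is.na(ok)] <- FALSE
  unique(records$exon_id[ok])
}

#' Classify exon variability between glia and neurons
#'
#' `delta_psi = psi_glia - psi_neuron`; an exon is `variable` when
#' `|delta_psi| > 0.25` (strict), `var0.1` when `|delta_psi| > 0.1`,
#' otherwise `non_variable`; `unmeasured` when either PSI is missing.
#'
#' @param psi_glia,psi_neuron numeric vectors of PSI values.
#' @param var_threshold threshold for `variable` (default 0.25).
#' @param var01_threshold threshold for `var0.1` (default 0.1).
#' @return data.frame with `delta_psi` and `variability`.
#' @export
classify_variability <- function(psi_glia, psi_neuron,
                                 var_threshold = 0.25,
                                 var01_threshold = 0.1) {
  delta <- psi_glia - psi_neuron
  lab <- ifelse(is.na(delta), "unmeasured",
                ifelse(abs(delta) > var_threshold, "variable",
                       ifelse(abs(delta) > var01_threshold, "var0.1",
                              "non_variable")))
  data.frame(delta_psi = delta, variability = lab,
             stringsAsFactors = FALSE)
}

#' Full chain-to-PSI pipeline
#'
#' Counts read classes per exon, normalizes by individual depth, applies
#' the pooled PSI-range filter, computes per-cell-type PSI and variability
#' calls, and returns the long PSI table.
#'
#' @param chains chain data.frame.
#' @param annotation annotation data.frame.
#' @param min_reads minimum raw read support per cell type.
#' @param psi_range inclusive pooled-PSI bounds; NULL disables the filter.
#' @param exon_ids exons to quantify (default: cassette exons).
#' @return PSI table: exon_id, chrom, start, end, strand, gene, cell_type,
#'   psi_overall, psi_acceptor, psi_donor, n_reads, delta_psi, variability.
#' @export
psi_from_chains <- function(chains, annotation, min_reads = 10L,
                            psi_range = c(0.02, 0.98), exon_ids = NULL) {
  counts <- count_reads(chains, annotation, exon_ids = exon_ids)
  pb <- normalize_by_depth(counts, chains = chains)
  if (!is.null(psi_range)) {
    pooled <- compute_psi(pool_cell_types(pb), min_reads = min_reads)
    keep <- filter_psi_range(pooled, psi_range[1L], psi_range[2L])
    pb <- pb[pb$exon_id %in% keep, , drop = FALSE]
  }
  rec <- compute_psi(pb, min_reads = min_reads)
  wide <- psi_wide(rec)
  ann_i <- match(rec$exon_id, annotation$exon_id)
  w_i <- match(rec$exon_id, wide$exon_id)
  data.frame(
    exon_id = rec$exon_id, chrom = annotation$chrom[ann_i],
    start = annotation$start[ann_i], end = annotation$end[ann_i],
    strand = annotation$strand[ann_i], gene = annotation$gene_id[ann_i],
    cell_type = rec$cell_type, psi_overall = rec$psi_overall,
    psi_acceptor = rec$psi_acceptor, psi_donor = rec$psi_donor,
    n_reads = rec$n_reads, delta_psi = wide$delta_psi[w_i],
    variability = wide$variability[w_i], stringsAsFactors = FALSE)
}

#' Reshape PSI records to one row per exon
#'
#' @param records PsiRecord data.frame covering both cell types.
#' @return data.frame: exon_id, psi_neuron, psi_glia, delta_psi,
#'   variability.
#' @export
psi_wide <- function(records) {
  ids <- unique(records$exon_id)
  get_ct <- function(ct) {
    sub <- records[records$cell_type == ct, ]
    sub$psi_overall[match(ids, sub$exon_id)]
  }
  pn <- get_ct("neuron"); pg <- get_ct("glia")
  cl <- classify_variability(pg, pn)
  data.frame(exon_id = ids, psi_neuron = pn, psi_glia = pg,
             delta_psi = cl$delta_psi, variability = cl$variability,
             stringsAsFactors = FALSE)
}

#' Downsample the inclusion-skewed exon class
#'
#' The class of exons with `psi_neuron > 0.9`, `psi_glia > 0.9` and
#' `|delta_psi| < 0.03` (rule "human"; rule "mouse": PSI equal to 1 in
#' both cell types) is randomly subsampled without replacement to
#' `min(target, class size)`; all other exons are kept untouched.
#'
#' @param wide wide PSI table from [psi_wide()].
#' @param target class size after downsampling (default 5000).
#' @param seed integer seed (independent of the read simulation).
#' @param rule skew predicate: "human" or "mouse".
#' @return the retained rows of `wide`.
#' @export
downsample_skewed <- function(wide, target = 5000L, seed = 1L,
                              rule = c("human", "mouse")) {
  rule <- match.arg(rule)
  in_class <- switch(rule,
    human = wide$psi_neuron > 0.9 & wide$psi_glia > 0.9 &
      abs(wide$delta_psi) < 0.03,
    mouse = wide$psi_neuron == 1 & wide$psi_glia == 1)
  in_class[is.na(in_class)] <- FALSE
  idx <- which(in_class)
  if (length(idx) > target) {
    keep_idx <- with_seed(derive_seed(seed, "downsample"),
                          sample(idx, target))
    drop <- setdiff(idx, keep_idx)
    wide <- wide[-drop, , drop = FALSE]
  }
  rownames(wide) <- NULL
  wide
}

#' Test coordination of two exons on shared molecules
#'
#' Restricts to molecules whose span covers both exon loci, classifies
#' each as including or skipping each exon (exact inclusion vs skip with
#' sufficient flanking coverage; ambiguous molecules are dropped), and
#' tests the 2x2 inclusion table with a two-sided Fisher exact test.
#'
#' @param chains chain data.frame.
#' @param exon_a,exon_b exon ids (same chromosome).
#' @param annotation annotation data.frame.
#' @param min_side minimum flanking coverage for a skip call.
#' @return list: `table` (2x2 matrix), `odds_ratio`, `p_value`, `n`.
#' @export
coordination_test <- function(chains, exon_a, exon_b, annotation,
                              min_side = 50L) {
  a <- annotation[annotation$exon_id == exon_a, ]
  b <- annotation[annotation$exon_id == exon_b, ]
  if (nrow(a) == 0L || nrow(b) == 0L) stop("unknown exon id")
  if (a$chrom != b$chrom) stop("exons must share a chromosome")
  sub <- chains[chains$chrom == a$chrom, , drop = FALSE]
  parsed <- parse_chains(sub)
  span_ok <- parsed$read$span_start <= min(a$start, b$start) &
    parsed$read$span_end >= max(a$end, b$end)
  ridx <- which(span_ok)
  if (length(ridx) < 1L) stop("no molecules span both exons")
  ## per-read inclusion calls
  per_read_call <- function(e) {
    sel <- parsed$iv_read %in% ridx
    ivs <- parsed$iv_start[sel]; ive <- parsed$iv_end[sel]
    pos <- match(parsed$iv_read[sel], ridx)
    inc <- logical(length(ridx))
    inc[unique(pos[ivs == e$start & ive == e$end])] <- TRUE
    ovl <- logical(length(ridx))
    ovl[unique(pos[ivs < e$end & ive > e$start])] <- TRUE
    ifelse(inc, "in", ifelse(!ovl, "out", NA))
  }
  ca <- per_read_call(a); cb <- per_read_call(b)
  ok <- !is.na(ca) & !is.na(cb)
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(exon_a = c("in", "out"),
                                exon_b = c("in", "out")))
  t0 <- table(factor(ca[ok], c("in", "out")),
              factor(cb[ok], c("in", "out")))
  tab[] <- as.integer(t0)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds_ratio = unname(ft$estimate),
       p_value = ft$p.value, n = sum(ok))
}
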
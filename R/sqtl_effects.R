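## Splicing-QTL effect prioritization: best-variant selection per intron,
## predicted inclusion change (delta-ISM) per variant, and sign
## concordance with the intron-excision slope.

#' Select the best variant(s) per intron
#'
#' Keeps, per intron, the variants with the lowest p-value; requires the
#' intron to span a quantified exon and the variant to fall inside the
#' model's input window around that exon. Multi-allelic ALT entries are
#' split into biallelic rows first.
#'
#' @param variants variant data.frame (CHROM, POS 1-based, REF, ALT,
#'   INTRON_START, INTRON_END 0-based half-open, SLOPE, PVAL, ...).
#' @param exons data.frame of quantified exons (exon_id, chrom, start,
#'   end).
#' @param window model window length (bp) for the range check.
#' @return list: `kept` (with linked exon_id) and `dropped` (with a
#'   `reason` column: no_spanned_exon / out_of_range / not_best).
#' @export
select_best_variants <- function(variants, exons, window = 6144L) {
  v <- variants
  ## split multi-allelic rows
  multi <- grepl(",", v$ALT, fixed = TRUE)
  if (any(multi)) {
    split_rows <- lapply(which(multi), function(i) {
      alts <- strsplit(v$ALT[i], ",", fixed = TRUE)[[1L]]
      out <- v[rep(i, length(alts)), , drop = FALSE]
      out$ALT <- alts
      out
    })
    v <- rbind(v[!multi, , drop = FALSE], do.call(rbind, split_rows))
  }
  if (any(v$REF == v$ALT)) stop("variant with REF == ALT")
  intron_key <- paste(v$CHROM, v$INTRON_START, v$INTRON_END, sep = ":")
  exon_id <- rep(NA_character_, nrow(v))
  in_window <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    cand <- exons[exons$chrom == v$CHROM[i] &
                    exons$start >= v$INTRON_START[i] &
                    exons$end <= v$INTRON_END[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    cand <- cand[1L, ]
    exon_id[i] <- cand$exon_id
    center <- (cand$start + cand$end) %/% 2L
    pos0 <- v$POS[i] - 1L
    in_window[i] <- pos0 >= center - window %/% 2L &
      pos0 < center + window %/% 2L
  }
  reason <- rep(NA_character_, nrow(v))
  reason[is.na(exon_id)] <- "no_spanned_exon"
  reason[is.na(reason) & !in_window] <- "out_of_range"
  ok <- is.na(reason)
  best <- ok
  for (key in unique(intron_key[ok])) {
    sel <- which(ok & intron_key == key)
    pmin_val <- min(v$PVAL[sel])
    best[sel[v$PVAL[sel] > pmin_val]] <- FALSE
  }
  reason[ok & !best] <- "not_best"
  kept <- v[best, , drop = FALSE]
  kept$exon_id <- exon_id[best]
  dropped <- v[!best, , drop = FALSE]
  dropped$reason <- reason[!best]
  rownames(kept) <- rownames(dropped) <- NULL
  list(kept = kept, dropped = dropped)
}

#' Predicted inclusion change of one variant
#'
#' Builds the reference window for the linked exon, verifies the
#' reference allele against the genome, substitutes the alternative
#' allele (alleles are given on the plus strand and complemented when the
#' window is reverse-complemented), and returns
#' `delta_ism = mean_prediction(alt) - mean_prediction(ref)` across
#' replicate models, plus the distance to the nearest splice site.
#'
#' @param models a `seq_model` or list of replicates.
#' @param genome named character vector of chromosome sequences.
#' @param annotation annotation data.frame.
#' @param variant one-row variant data.frame with a linked `exon_id`.
#' @param config `seq_config` of the models.
#' @param peaksets peak sets for RBP channels (if configured).
#' @param head head label.
#' @return one-row data.frame: exon_id, CHROM, POS, REF, ALT, SLOPE,
#'   delta_ism, pred_ref, pred_alt, dist_splice_site, in_exon.
#' @export
delta_ism <- function(models, genome, annotation, variant, config,
                      peaksets = NULL, head = NULL) {
  if (inherits(models, "seq_model")) models <- list(models)
  a <- annotation[annotation$exon_id == variant$exon_id, , drop = FALSE]
  if (nrow(a) == 0L) stop("unknown exon: ", variant$exon_id)
  win <- build_input(genome, annotation, variant$exon_id, config,
                     peaksets)
  pos0 <- variant$POS - 1L
  minus <- a$strand == "-"
  wp <- if (!minus) pos0 - win$meta$w0 else win$meta$w1 - 1L - pos0
  if (wp < 0L || wp >= config$window) {
    stop("variant outside the input window")
  }
  ref_tx <- if (minus) complement_base(variant$REF) else variant$REF
  alt_tx <- if (minus) complement_base(variant$ALT) else variant$ALT
  obs <- win$meta$ref[wp + 1L]
  if (obs != ref_tx) {
    stop("reference mismatch at ", variant$CHROM, ":", variant$POS,
         ": expected ", variant$REF, " (plus strand), window shows ", obs)
  }
  x_alt <- win$x
  x_alt[1:4, wp + 1L] <- 0
  x_alt[match(alt_tx, BASES), wp + 1L] <- 1
  arr <- array(0, c(config$n_channels, config$window, 2L))
  arr[, , 1L] <- win$x
  arr[, , 2L] <- x_alt
  heads <- if (is.null(head)) NULL else rep(head, 2L)
  pr <- predict_seq(models, arr, heads = heads)
  d_acc <- abs(pos0 - a$start)
  d_don <- abs(pos0 - (a$end - 1L))
  data.frame(
    exon_id = variant$exon_id, CHROM = variant$CHROM, POS = variant$POS,
    REF = variant$REF, ALT = variant$ALT, SLOPE = variant$SLOPE,
    delta_ism = pr[2L] - pr[1L], pred_ref = pr[1L], pred_alt = pr[2L],
    dist_splice_site = min(d_acc, d_don),
    in_exon = pos0 >= a$start && pos0 < a$end,
    stringsAsFactors = FALSE)
}

#' Delta-ISM for a table of variants
#'
#' @inheritParams delta_ism
#' @param variants variant data.frame with linked `exon_id` (e.g. the
#'   `kept` table of [select_best_variants()]).
#' @return data.frame with one row per variant (see [delta_ism()]),
#'   carrying over any `label` column.
#' @export
delta_ism_all <- function(models, genome, annotation, variants, config,
                          peaksets = NULL, head = NULL) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    out <- delta_ism(models, genome, annotation, variants[i, ], config,
                     peaksets, head)
    if ("label" %in% names(variants)) out$label <- variants$label[i]
    if ("expected_dism_sign" %in% names(variants)) {
      out$expected_dism_sign <- variants$expected_dism_sign[i]
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Concordance of predicted variant effects with sQTL slopes
#'
#' A variant carries an effect when `|delta_ism| > threshold`. The
#' expected direction comes from the intron-excision slope: negative
#' slopes correspond to increased inclusion, so the expected sign of
#' `delta_ism` is the opposite of the slope's sign. For exons with
#' several effect-carrying variants, the variant with the largest
#' |delta_ism| is the prioritized call.
#'
#' @param effects data.frame from [delta_ism_all()] (columns delta_ism,
#'   SLOPE, exon_id).
#' @param threshold effect threshold on |delta_ism| (default 0.005).
#' @return list: `effects` (augmented with has_effect / expected_sign /
#'   concordant), `n_effect`, `n_concordant`, `concordance`,
#'   `quadrants` (2x2 sign table among effect-carrying variants),
#'   `prioritized` (per-exon top-effect calls).
#' @export
concordance_report <- function(effects, threshold = 0.005) {
  e <- effects
  e$has_effect <- abs(e$delta_ism) > threshold
  e$expected_sign <- -sign(e$SLOPE)
  e$concordant <- ifelse(e$has_effect,
                         sign(e$delta_ism) == e$expected_sign, NA)
  n_effect <- sum(e$has_effect)
  n_conc <- sum(e$concordant, na.rm = TRUE)
  quad <- table(
    slope = factor(ifelse(e$SLOPE[e$has_effect] > 0, "slope>0",
                          "slope<0"), c("slope<0", "slope>0")),
    delta = factor(ifelse(e$delta_ism[e$has_effect] > 0, "dISM>0",
                          "dISM<0"), c("dISM<0", "dISM>0")))
  prioritized <- do.call(rbind, lapply(split(e[e$has_effect, ],
                                             e$exon_id[e$has_effect]),
                                       function(g) {
    g[which.max(abs(g$delta_ism)), , drop = FALSE]
  }))
  rownames(prioritized) <- NULL
  list(effects = e, n_effect = n_effect, n_concordant = n_conc,
       concordance = if (n_effect > 0) n_conc / n_effect else NA_real_,
       quadrants = quad, prioritized = prioritized)
}
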
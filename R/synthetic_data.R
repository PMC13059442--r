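## Synthetic-data generators: genome + annotation, planted positional
## splicing grammar, RBP peak tracks with embedded motifs, long-read exon
## chains and variants. Every downstream module is exercised against the
## ground truth planted here.

#' Generate a synthetic genome with cassette-exon genes
#'
#' Each gene lives on its own chromosome and consists of
#' `exons_per_gene` exons; the middle exon is the cassette exon, all others
#' are constitutive. Cassette lengths are drawn from a mixture that covers
#' microexons (<= 27 bp) up to long exons, intron lengths from a short /
#' medium / long mixture, and half of the genes sit on the minus strand.
#' Canonical GT/AG dinucleotides are written at every donor/acceptor on the
#' coding strand. Coordinates are 0-based half-open.
#'
#' @param n_genes number of genes (>= 1).
#' @param exons_per_gene exons per gene (>= 3; odd counts center the
#'   cassette exon).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param pad intergenic/terminal padding per chromosome end (bp).
#' @param p_minus probability a gene is on the minus strand.
#' @return list with `genome` (named character vector) and `annotation`
#'   (data.frame: gene_id, exon_id, chrom, start, end, strand, role, rank).
#' @export
gen_genome <- function(n_genes, exons_per_gene = 3L, seed = 1L,
                       pad = 600L, p_minus = 0.5) {
  stopifnot_scalar_count(n_genes, "n_genes", min = 1L)
  stopifnot_scalar_count(exons_per_gene, "exons_per_gene", min = 3L)
  with_seed(derive_seed(seed, "genome"), {
    genome <- character(n_genes)
    ann <- vector("list", n_genes)
    chroms <- sprintf("chr%d", seq_len(n_genes))
    genes <- sprintf("g%04d", seq_len(n_genes))
    cas_idx <- ceiling(exons_per_gene / 2)
    for (g in seq_len(n_genes)) {
      strand <- if (runif(1) < p_minus) "-" else "+"
      exon_len <- integer(exons_per_gene)
      for (j in seq_len(exons_per_gene)) {
        if (j == cas_idx) {
          cls <- sample.int(4L, 1L, prob = c(0.15, 0.40, 0.30, 0.15))
          len <- switch(cls,
                        sample(18:27, 1L),
                        sample(28:100, 1L),
                        sample(101:200, 1L),
                        sample(201:300, 1L))
          # enrich frame-consistent lengths without leaving the class
          if (runif(1) < 0.5) len <- max(18L, len - len %% 3L)
        } else {
          len <- sample(80:200, 1L)
        }
        exon_len[j] <- len
      }
      n_intron <- exons_per_gene - 1L
      intron_len <- vapply(seq_len(n_intron), function(i) {
        cls <- sample.int(3L, 1L, prob = c(0.2, 0.5, 0.3))
        switch(cls, sample(70:100, 1L), sample(101:1000, 1L),
               sample(1001:3000, 1L))
      }, integer(1L))
      starts <- integer(exons_per_gene)
      pos <- pad
      for (j in seq_len(exons_per_gene)) {
        starts[j] <- pos
        pos <- pos + exon_len[j]
        if (j < exons_per_gene) pos <- pos + intron_len[j]
      }
      chrom_len <- pos + pad
      seq_chars <- sample(BASES, chrom_len, replace = TRUE)
      ends <- starts + exon_len
      for (j in seq_len(n_intron)) {
        i0 <- ends[j]            # intron start (0-based)
        i1 <- starts[j + 1L]     # intron end (one past last base)
        if (strand == "+") {
          seq_chars[i0 + 1L] <- "G"; seq_chars[i0 + 2L] <- "T"
          seq_chars[i1 - 1L] <- "A"; seq_chars[i1] <- "G"
        } else {
          # coding strand reads GT..AG right-to-left after complementation
          seq_chars[i0 + 1L] <- "C"; seq_chars[i0 + 2L] <- "T"
          seq_chars[i1 - 1L] <- "A"; seq_chars[i1] <- "C"
        }
      }
      genome[g] <- paste(seq_chars, collapse = "")
      role <- rep("constitutive", exons_per_gene)
      role[cas_idx] <- "cassette"
      ann[[g]] <- data.frame(
        gene_id = genes[g],
        exon_id = sprintf("%s_e%d", genes[g], seq_len(exons_per_gene)),
        chrom = chroms[g], start = starts, end = ends, strand = strand,
        role = role, rank = seq_len(exons_per_gene),
        stringsAsFactors = FALSE)
    }
    names(genome) <- chroms
    list(genome = genome, annotation = do.call(rbind, ann))
  })
}

#' Plant a position-dependent splicing grammar
#'
#' Assigns each RBP an effect weight (on the logit of exon inclusion) at one
#' or two of the six positional categories. `n_cell_specific` RBPs get
#' effects of opposite sign between the two cell types (QKI-like
#' behaviour); all other RBPs share their effects across cell types. Each
#' RBP also receives a short planted motif written into the genome wherever
#' its peaks sit.
#'
#' @param rbp_names character vector of unique RBP names.
#' @param n_cell_specific how many RBPs get opposite-sign effects between
#'   cell types (<= length(rbp_names)).
#' @param seed integer seed.
#' @param weight_range magnitude range for effect weights (logit units).
#' @param baseline_logit named numeric, baseline inclusion logit per cell
#'   type.
#' @param motif_width planted motif width (bp).
#' @return object of class `splice_grammar`: list with `effects` (full
#'   rbp x category x cell_type grid of weights), `baseline_logit`,
#'   `motif_map`, `rbp_names`, `cell_specific`.
#' @export
plant_grammar <- function(rbp_names, n_cell_specific = 0L, seed = 1L,
                          weight_range = c(0.5, 2),
                          baseline_logit = c(neuron = 0.9, glia = 0.9),
                          motif_width = 6L) {
  if (anyDuplicated(rbp_names)) stop("duplicate rbp_names are not allowed")
  stopifnot_scalar_count(n_cell_specific, "n_cell_specific", min = 0L)
  if (n_cell_specific > length(rbp_names)) {
    stop("n_cell_specific exceeds the number of RBPs")
  }
  stopifnot(all(CELL_TYPES %in% names(baseline_logit)))
  with_seed(derive_seed(seed, "grammar"), {
    n <- length(rbp_names)
    effects <- expand.grid(rbp = rbp_names, category = CATEGORIES,
                           cell_type = CELL_TYPES,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
    effects$weight <- 0
    cell_specific <- if (n_cell_specific > 0L) {
      sample(rbp_names, n_cell_specific)
    } else character(0L)
    for (r in rbp_names) {
      k <- sample(1:2, 1L)
      cats <- sample(CATEGORIES, k)
      w <- runif(k, weight_range[1L], weight_range[2L]) *
        sample(c(-1, 1), k, replace = TRUE)
      for (i in seq_len(k)) {
        sel_g <- effects$rbp == r & effects$category == cats[i] &
          effects$cell_type == "glia"
        sel_n <- effects$rbp == r & effects$category == cats[i] &
          effects$cell_type == "neuron"
        effects$weight[sel_g] <- w[i]
        effects$weight[sel_n] <- if (r %in% cell_specific) -w[i] else w[i]
      }
    }
    motif_map <- character(n)
    repeat {
      motif_map <- vapply(seq_len(n), function(i) {
        paste(sample(BASES, motif_width, replace = TRUE), collapse = "")
      }, character(1L))
      if (!anyDuplicated(motif_map)) break
    }
    names(motif_map) <- rbp_names
    structure(list(effects = effects,
                   baseline_logit = baseline_logit[CELL_TYPES],
                   motif_map = motif_map, rbp_names = rbp_names,
                   cell_specific = cell_specific),
              class = "splice_grammar")
  })
}

#' Look up a planted effect weight
#'
#' @param grammar `splice_grammar` object.
#' @param rbp,category,cell_type coordinates of the effect.
#' @return numeric weight (0 if the RBP is inactive there).
#' @export
grammar_effect <- function(grammar, rbp, category, cell_type) {
  e <- grammar$effects
  w <- e$weight[e$rbp == rbp & e$category == category &
                  e$cell_type == cell_type]
  if (length(w) == 0L) 0 else w
}

## genomic interval for a peak of a given positional category, strand-aware;
## flank peaks sit at the RBP's characteristic distance from the splice
## site (`char_gap`) with a small jitter, emulating a positional code
.category_interval <- function(category, start, end, strand,
                               peak_width, flank_max, char_gap = NULL) {
  len <- end - start
  gap <- if (is.null(char_gap)) {
    sample(5:(flank_max - peak_width - 5L), 1L)
  } else {
    max(5L, min(flank_max - peak_width - 5L,
                char_gap + sample(-10:10, 1L)))
  }
  into_exon <- min(12L, len - 2L)
  exon_w <- min(peak_width, max(2L, len - 4L))
  exon_off <- if (len > exon_w + 2L) sample.int(len - exon_w - 1L, 1L) else 1L
  if (strand == "+") {
    switch(category,
           upstream    = c(start - gap - peak_width, start - gap),
           acc_overlap = c(start - 12L, start + into_exon),
           exonic      = c(start + exon_off, start + exon_off + exon_w),
           spanning    = c(start - 8L, end + 8L),
           don_overlap = c(end - into_exon, end + 12L),
           downstream  = c(end + gap, end + gap + peak_width))
  } else {
    switch(category,
           upstream    = c(end + gap, end + gap + peak_width),
           acc_overlap = c(end - into_exon, end + 12L),
           exonic      = c(start + exon_off, start + exon_off + exon_w),
           spanning    = c(start - 8L, end + 8L),
           don_overlap = c(start - 12L, start + into_exon),
           downstream  = c(start - gap - peak_width, start - gap))
  }
}

#' Generate RBP peak tracks following the planted grammar
#'
#' For every cassette exon, each RBP independently receives one peak with
#' probability `placement_rate`, placed at one of that RBP's grammar-active
#' positional categories (geometry respects the 400-bp flank bound used by
#' the feature extractor).
#'
#' @param annotation annotation data.frame from [gen_genome()].
#' @param grammar `splice_grammar` object.
#' @param placement_rate per-(exon, RBP) peak probability in (0, 1].
#' @param seed integer seed.
#' @param peak_width peak width for flank/exonic peaks (bp).
#' @param flank_max maximal flank distance (bp).
#' @param positional when TRUE (default), each (RBP, category) pair gets a
#'   characteristic distance from the splice site, and peaks sit there
#'   with +/- 10 bp jitter; when FALSE, flank peaks are placed uniformly
#'   within the flank.
#' @return data.frame: rbp, chrom, start, end, exon_id, category, strand.
#' @export
gen_peaks <- function(annotation, grammar, placement_rate = 0.5, seed = 1L,
                      peak_width = 30L, flank_max = 400L,
                      positional = TRUE) {
  if (!is.numeric(placement_rate) || placement_rate <= 0 ||
      placement_rate > 1) {
    stop("placement_rate must be in (0, 1]")
  }
  cas <- annotation[annotation$role == "cassette", , drop = FALSE]
  eff <- grammar$effects[grammar$effects$weight != 0, , drop = FALSE]
  active <- split(unique(eff[, c("rbp", "category")])$category,
                  unique(eff[, c("rbp", "category")])$rbp)
  with_seed(derive_seed(seed, "peaks"), {
    out <- list()
    for (r in grammar$rbp_names) {
      cats <- active[[r]]
      if (is.null(cats)) next
      hit <- runif(nrow(cas)) < placement_rate
      if (!any(hit)) next
      idx <- which(hit)
      cat_pick <- if (length(cats) == 1L) rep(cats, length(idx)) else
        sample(cats, length(idx), replace = TRUE)
      char_gap <- if (positional) {
        stats::setNames(sample(20:(flank_max - peak_width - 20L),
                               length(cats), replace = TRUE), cats)
      } else NULL
      ivs <- t(vapply(seq_along(idx), function(i) {
        e <- cas[idx[i], ]
        .category_interval(cat_pick[i], e$start, e$end, e$strand,
                           peak_width, flank_max,
                           char_gap = char_gap[[cat_pick[i]]])
      }, numeric(2L)))
      out[[r]] <- data.frame(
        rbp = r, chrom = cas$chrom[idx], start = as.integer(ivs[, 1L]),
        end = as.integer(ivs[, 2L]), exon_id = cas$exon_id[idx],
        category = cat_pick, strand = cas$strand[idx],
        stringsAsFactors = FALSE)
    }
    if (length(out) == 0L) {
      return(data.frame(rbp = character(), chrom = character(),
                        start = integer(), end = integer(),
                        exon_id = character(), category = character(),
                        strand = character(), stringsAsFactors = FALSE))
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Write planted motifs into the genome at peak locations
#'
#' Each peak gets its RBP's motif embedded near the peak center on the
#' coding strand (reverse-complemented into the genome for minus-strand
#' genes). Splice-site dinucleotides are never overwritten.
#'
#' @param genome named character vector from [gen_genome()].
#' @param peaks peak data.frame from [gen_peaks()].
#' @param grammar `splice_grammar` object.
#' @param annotation annotation data.frame (to locate splice-site
#'   dinucleotides).
#' @return list with the modified `genome` and `peaks` gaining a
#'   `motif_start` column (0-based genomic start of the planted motif).
#' @export
plant_motifs <- function(genome, peaks, grammar, annotation) {
  if (nrow(peaks) == 0L) return(list(genome = genome, peaks = peaks))
  mw <- nchar(grammar$motif_map[[1L]])
  ann_idx <- split(seq_len(nrow(annotation)), annotation$exon_id)
  motif_start <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    e <- annotation[ann_idx[[p$exon_id]], ]
    forbid <- rbind(c(e$start - 2L, e$start), c(e$end, e$end + 2L))
    cand <- seq.int(p$start, p$end - mw)
    ok <- !vapply(cand, function(s) {
      any(s < forbid[, 2L] & s + mw > forbid[, 1L])
    }, logical(1L))
    cand <- cand[ok]
    if (length(cand) == 0L) cand <- p$start  # degenerate peak; accept
    center <- (p$start + p$end - mw) %/% 2L
    s <- cand[which.min(abs(cand - center))]
    motif <- grammar$motif_map[[p$rbp]]
    if (p$strand == "-") motif <- revcomp(motif)
    substr(genome[[p$chrom]], s + 1L, s + mw) <- motif
    motif_start[i] <- s
  }
  peaks$motif_start <- motif_start
  list(genome = genome, peaks = peaks)
}

#' Assemble cassette exons with ground-truth inclusion
#'
#' Computes the true per-cell-type inclusion probability of every cassette
#' exon from the planted grammar and the peaks placed on it:
#' `true_psi = plogis(baseline + sum of planted effects + noise)`, with a
#' per-exon noise term shared between cell types.
#'
#' @param annotation annotation data.frame.
#' @param peaks peak data.frame from [gen_peaks()].
#' @param grammar `splice_grammar` object.
#' @param noise_sd standard deviation of the shared exon-level logit noise.
#' @param ct_noise_sd named numeric (per cell type): additional independent
#'   logit noise per cell type (defaults to none). Used to model
#'   peak-independent inclusion variation in one cell type.
#' @param seed integer seed for the noise draw.
#' @return data.frame with one row per cassette exon: coordinates, the
#'   transcriptionally upstream/downstream flanking exons, and
#'   `true_psi_neuron` / `true_psi_glia`.
#' @export
cassette_exons <- function(annotation, peaks, grammar, noise_sd = 0.25,
                           ct_noise_sd = c(neuron = 0, glia = 0),
                           seed = 1L) {
  cas <- annotation[annotation$role == "cassette", , drop = FALSE]
  eff <- grammar$effects
  key <- paste(eff$rbp, eff$category, eff$cell_type)
  wmap <- stats::setNames(eff$weight, key)
  logit_add <- matrix(0, nrow(cas), 2L,
                      dimnames = list(cas$exon_id, CELL_TYPES))
  if (nrow(peaks) > 0L) {
    for (ct in CELL_TYPES) {
      w <- wmap[paste(peaks$rbp, peaks$category, ct)]
      agg <- tapply(w, peaks$exon_id, sum)
      logit_add[names(agg), ct] <- logit_add[names(agg), ct] + unname(agg)
    }
  }
  noise_all <- with_seed(derive_seed(seed, "grammar") + 1L, {
    shared <- rnorm(nrow(cas), 0, noise_sd)
    per_ct <- lapply(CELL_TYPES, function(ct) {
      sd_ct <- if (ct %in% names(ct_noise_sd)) ct_noise_sd[[ct]] else 0
      if (sd_ct > 0) rnorm(nrow(cas), 0, sd_ct) else numeric(nrow(cas))
    })
    names(per_ct) <- CELL_TYPES
    list(shared = shared, per_ct = per_ct)
  })
  out <- cas
  for (ct in CELL_TYPES) {
    out[[paste0("true_psi_", ct)]] <-
      plogis(grammar$baseline_logit[[ct]] + logit_add[, ct] +
               noise_all$shared + noise_all$per_ct[[ct]])
  }
  ## transcriptionally upstream/downstream constitutive neighbours
  up <- down <- matrix(NA_integer_, nrow(cas), 2L)
  for (i in seq_len(nrow(cas))) {
    g <- annotation[annotation$gene_id == cas$gene_id[i], ]
    left <- g[g$rank == cas$rank[i] - 1L, ]
    right <- g[g$rank == cas$rank[i] + 1L, ]
    if (cas$strand[i] == "+") {
      up[i, ] <- c(left$start, left$end); down[i, ] <- c(right$start, right$end)
    } else {
      up[i, ] <- c(right$start, right$end); down[i, ] <- c(left$start, left$end)
    }
  }
  out$up_start <- up[, 1L]; out$up_end <- up[, 2L]
  out$down_start <- down[, 1L]; out$down_end <- down[, 2L]
  rownames(out) <- NULL
  out
}

#' Simulate long-read exon chains
#'
#' Per exon, individual and cell type, `depth` molecules are drawn;
#' inclusion follows `Binomial(depth, true_psi)`. A configurable fraction of
#' inclusion reads is truncated so that they support only the acceptor or
#' only the donor and end on the exon (populating the partial-evidence
#' count classes). Skipping chains always cover the full flanking exons, so
#' the >= 50-bases-on-both-sides skip rule can fire.
#'
#' @param exons cassette-exon data.frame from [cassette_exons()].
#' @param depth_table data.frame (individual, cell_type, depth): molecules
#'   per exon for that individual and cell type.
#' @param seed integer seed.
#' @param truncation_frac fraction of inclusion reads truncated on the exon.
#' @return chain data.frame: read_id, individual, cell_type, chrom, strand,
#'   exons (encoded intervals).
#' @export
gen_reads <- function(exons, depth_table, seed = 1L,
                      truncation_frac = 0.05) {
  stopifnot(all(c("individual", "cell_type", "depth") %in%
                  names(depth_table)))
  if (any(depth_table$depth < 0)) stop("depths must be >= 0")
  need <- c("exon_id", "chrom", "strand", "start", "end", "up_start",
            "up_end", "down_start", "down_end", "true_psi_neuron",
            "true_psi_glia")
  if (!all(need %in% names(exons))) {
    stop("exons must come from cassette_exons(); missing columns: ",
         paste(setdiff(need, names(exons)), collapse = ", "))
  }
  with_seed(derive_seed(seed, "reads"), {
    chains <- list(); ind <- list(); ct_l <- list(); chrom_l <- list()
    strand_l <- list(); k <- 0L
    for (i in seq_len(nrow(exons))) {
      e <- exons[i, ]
      len <- e$end - e$start
      ivs <- rbind(c(e$up_start, e$up_end), c(e$start, e$end),
                   c(e$down_start, e$down_end))
      ivs <- ivs[order(ivs[, 1L]), , drop = FALSE]
      full_str <- encode_chain(ivs)
      skip_str <- encode_chain(ivs[-2L, , drop = FALSE])
      up_str <- encode_chain(matrix(c(e$up_start, e$up_end), 1L))
      down_str <- encode_chain(matrix(c(e$down_start, e$down_end), 1L))
      for (r in seq_len(nrow(depth_table))) {
        n <- depth_table$depth[r]
        if (n == 0L) next
        ct <- depth_table$cell_type[r]
        psi <- e[[paste0("true_psi_", ct)]]
        n_in <- rbinom(1L, n, psi)
        n_out <- n - n_in
        n_tr <- rbinom(1L, n_in, truncation_frac)
        n_acc <- rbinom(1L, n_tr, 0.5)
        n_don <- n_tr - n_acc
        n_full <- n_in - n_tr
        make_partial <- function(m, side) {
          # side "acc": anchored at the acceptor, ends inside the exon
          # side "don": starts inside the exon, splices out of the donor
          at_acc <- (side == "acc")
          anchored_left <- xor(e$strand == "-", at_acc)  # genomic-left anchor?
          if (anchored_left) {
            part <- sprintf("%d-%d", e$start, e$start + m)
          } else {
            part <- sprintf("%d-%d", e$end - m, e$end)
          }
          if (at_acc) {
            if (e$strand == "+") paste(up_str, part, sep = ";")
            else paste(part, up_str, sep = ";")
          } else {
            if (e$strand == "+") paste(part, down_str, sep = ";")
            else paste(down_str, part, sep = ";")
          }
        }
        acc_str <- if (n_acc > 0L)
          make_partial(sample.int(len - 1L, n_acc, replace = TRUE), "acc")
        else character(0L)
        don_str <- if (n_don > 0L)
          make_partial(sample.int(len - 1L, n_don, replace = TRUE), "don")
        else character(0L)
        v <- c(rep(full_str, n_full), acc_str, don_str, rep(skip_str, n_out))
        k <- k + 1L
        chains[[k]] <- v
        ind[[k]] <- rep(depth_table$individual[r], length(v))
        ct_l[[k]] <- rep(ct, length(v))
        chrom_l[[k]] <- rep(e$chrom, length(v))
        strand_l[[k]] <- rep(e$strand, length(v))
      }
    }
    ex <- unlist(chains, use.names = FALSE)
    if (is.null(ex)) ex <- character(0L)
    data.frame(
      read_id = sprintf("r%08d", seq_along(ex)),
      individual = unlist(ind, use.names = FALSE)[seq_along(ex)],
      cell_type = unlist(ct_l, use.names = FALSE)[seq_along(ex)],
      chrom = unlist(chrom_l, use.names = FALSE)[seq_along(ex)],
      strand = unlist(strand_l, use.names = FALSE)[seq_along(ex)],
      exons = ex, stringsAsFactors = FALSE)
  })
}

#' Generate variants with known expected effect direction
#'
#' Planted variants disrupt a planted motif inside a peak of an RBP whose
#' effect is shared between cell types; their intron-excision slope is set
#' so that a motif that raises inclusion when intact gets a positive slope
#' for the disrupting allele (negative slopes correspond to increased
#' inclusion). Neutral variants sit in peak-free intronic sequence and
#' carry a slope of random sign.
#'
#' @param exons cassette-exon data.frame from [cassette_exons()].
#' @param grammar `splice_grammar` object.
#' @param peaks peak data.frame with `motif_start` (from [plant_motifs()]).
#' @param genome named character vector of chromosome sequences.
#' @param n_planted,n_neutral variant counts per class.
#' @param seed integer seed.
#' @return data.frame: CHROM, POS (1-based), REF, ALT, INTRON_START,
#'   INTRON_END (0-based half-open), SLOPE, PVAL, exon_id, label, rbp,
#'   expected_dism_sign.
#' @export
gen_variants <- function(exons, grammar, peaks, genome,
                         n_planted = 20L, n_neutral = 20L, seed = 1L) {
  if (!"motif_start" %in% names(peaks)) {
    stop("peaks must carry motif_start (run plant_motifs() first)")
  }
  eff <- grammar$effects
  shared <- setdiff(grammar$rbp_names, grammar$cell_specific)
  pk <- peaks[peaks$rbp %in% shared & peaks$exon_id %in% exons$exon_id, ]
  if (nrow(pk) < n_planted) {
    stop("not enough shared-effect peaks to plant ", n_planted, " variants")
  }
  exmap <- exons[match(pk$exon_id, exons$exon_id), ]
  with_seed(derive_seed(seed, "variants"), {
    idx <- sample.int(nrow(pk), n_planted)
    rows <- list()
    for (j in seq_along(idx)) {
      p <- pk[idx[j], ]; e <- exmap[idx[j], ]
      pos0 <- p$motif_start + 2L
      ref <- substr(genome[[p$chrom]], pos0 + 1L, pos0 + 1L)
      alt <- sample(setdiff(BASES, ref), 1L)
      w <- grammar_effect(grammar, p$rbp, p$category, "glia")
      intron <- sort(c(e$up_start, e$up_end, e$down_start, e$down_end))
      rows[[j]] <- data.frame(
        CHROM = p$chrom, POS = pos0 + 1L, REF = ref, ALT = alt,
        INTRON_START = intron[2L], INTRON_END = intron[3L],
        SLOPE = sign(w) * runif(1L, 0.2, 1),
        PVAL = runif(1L, 1e-6, 0.01),
        exon_id = p$exon_id, label = "planted", rbp = p$rbp,
        expected_dism_sign = -sign(w), stringsAsFactors = FALSE)
    }
    neutral <- list()
    chrom_peaks <- split(peaks, peaks$chrom)
    tries <- 0L
    while (length(neutral) < n_neutral && tries < 50L * n_neutral) {
      tries <- tries + 1L
      e <- exons[sample.int(nrow(exons), 1L), ]
      intron <- sort(c(e$up_start, e$up_end, e$down_start, e$down_end))
      # intronic sequence flanking the cassette exon, away from peaks,
      # motifs and splice-site dinucleotides
      cand <- c(seq.int(intron[2L] + 12L, e$start - 12L),
                seq.int(e$end + 12L, intron[3L] - 12L))
      cp <- chrom_peaks[[e$chrom]]
      if (!is.null(cp) && nrow(cp) > 0L) {
        bad <- unlist(lapply(seq_len(nrow(cp)), function(i) {
          seq.int(cp$start[i] - 6L, cp$end[i] + 6L)
        }))
        cand <- setdiff(cand, bad)
      }
      if (length(cand) == 0L) next
      pos0 <- sample(cand, 1L)
      ref <- substr(genome[[e$chrom]], pos0 + 1L, pos0 + 1L)
      neutral[[length(neutral) + 1L]] <- data.frame(
        CHROM = e$chrom, POS = pos0 + 1L, REF = ref,
        ALT = sample(setdiff(BASES, ref), 1L),
        INTRON_START = intron[2L], INTRON_END = intron[3L],
        SLOPE = sample(c(-1, 1), 1L) * runif(1L, 0.2, 1),
        PVAL = runif(1L, 1e-4, 0.05),
        exon_id = e$exon_id, label = "neutral", rbp = NA_character_,
        expected_dism_sign = 0, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(rows, neutral, list(make.row.names = FALSE)))
    if (any(out$REF == out$ALT)) stop("variant with REF == ALT generated")
    out
  })
}

#' Simulate a complete synthetic dataset
#'
#' Orchestrates genome, grammar, peaks (with planted motifs), ground-truth
#' inclusion, read chains and variants. Identical seeds give identical
#' datasets.
#'
#' @param n_genes number of genes.
#' @param rbp_names RBP names for the grammar and peak tracks.
#' @param n_cell_specific RBPs with opposite-sign effects between cell
#'   types.
#' @param placement_rate per-(exon, RBP) peak probability.
#' @param depth molecules per exon per individual per cell type.
#' @param individuals individual identifiers.
#' @param noise_sd exon-level logit noise (shared across cell types).
#' @param truncation_frac fraction of inclusion reads truncated on the exon.
#' @param n_planted,n_neutral variant counts (0 disables variants).
#' @param seed master integer seed.
#' @param out_dir optional directory; when given, all standard files are
#'   written (genome.fa, annotation.tsv, peaks/<rbp>.bed, chains.tsv,
#'   variants.tsv).
#' @return list: genome, annotation, grammar, peaks, exons, chains,
#'   variants (NULL if disabled).
#' @export
simulate_dataset <- function(n_genes = 60L,
                             rbp_names = sprintf("RBP%03d", 1:20),
                             n_cell_specific = 2L, placement_rate = 0.5,
                             depth = 30L,
                             individuals = c("ind1", "ind2"),
                             noise_sd = 0.25, truncation_frac = 0.05,
                             n_planted = 20L, n_neutral = 20L, seed = 1L,
                             out_dir = NULL) {
  gg <- gen_genome(n_genes, seed = seed)
  grammar <- plant_grammar(rbp_names, n_cell_specific, seed = seed)
  peaks <- gen_peaks(gg$annotation, grammar, placement_rate, seed = seed)
  pm <- plant_motifs(gg$genome, peaks, grammar, gg$annotation)
  exons <- cassette_exons(gg$annotation, pm$peaks, grammar,
                          noise_sd = noise_sd, seed = seed)
  depth_table <- expand.grid(individual = individuals,
                             cell_type = CELL_TYPES,
                             KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
  depth_table$depth <- depth
  chains <- gen_reads(exons, depth_table, seed = seed,
                      truncation_frac = truncation_frac)
  variants <- if (n_planted > 0L && nrow(pm$peaks) > 0L) {
    gen_variants(exons, grammar, pm$peaks, pm$genome,
                 n_planted = n_planted, n_neutral = n_neutral, seed = seed)
  } else NULL
  out <- list(genome = pm$genome, annotation = gg$annotation,
              grammar = grammar, peaks = pm$peaks, exons = exons,
              chains = chains, variants = variants)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_genome_fasta(out$genome, file.path(out_dir, "genome.fa"))
    write_annotation(out$annotation, file.path(out_dir, "annotation.tsv"))
    write_peaks_bed(out$peaks, file.path(out_dir, "peaks"))
    write_chains(out$chains, file.path(out_dir, "chains.tsv"))
    if (!is.null(variants)) {
      write_variants(out$variants, file.path(out_dir, "variants.tsv"))
    }
  }
  out
}

#' Decouple one cell type from the planted grammar
#'
#' Sets all effect weights of the given cell type to zero, so that its
#' inclusion values no longer depend on the peak tracks. Used to emulate a
#' cell type whose splicing diverges from the measured binding data.
#'
#' @param grammar `splice_grammar` object.
#' @param cell_type cell type to decouple.
#' @return the modified grammar.
#' @export
decouple_cell_type <- function(grammar, cell_type) {
  stopifnot(cell_type %in% CELL_TYPES)
  grammar$effects$weight[grammar$effects$cell_type == cell_type] <- 0
  grammar
}

#' Construct a splicing grammar explicitly
#'
#' Low-level constructor used when a controlled grammar is needed (e.g. a
#' single RBP with one strong positional effect). The effects data.frame
#' needs columns rbp, category, cell_type, weight; missing grid entries
#' are filled with zero weight.
#'
#' @param effects data.frame of non-zero effects.
#' @param baseline_logit named numeric per cell type.
#' @param motif_map named character vector (rbp -> motif).
#' @return `splice_grammar` object.
#' @export
splice_grammar <- function(effects,
                           baseline_logit = c(neuron = 0.9, glia = 0.9),
                           motif_map = NULL) {
  stopifnot(all(c("rbp", "category", "cell_type", "weight") %in%
                  names(effects)),
            all(effects$category %in% CATEGORIES),
            all(effects$cell_type %in% CELL_TYPES),
            all(is.finite(effects$weight)))
  rbp_names <- unique(effects$rbp)
  full <- expand.grid(rbp = rbp_names, category = CATEGORIES,
                      cell_type = CELL_TYPES, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  full$weight <- 0
  for (i in seq_len(nrow(effects))) {
    sel <- full$rbp == effects$rbp[i] &
      full$category == effects$category[i] &
      full$cell_type == effects$cell_type[i]
    full$weight[sel] <- effects$weight[i]
  }
  if (is.null(motif_map)) {
    motif_map <- stats::setNames(
      vapply(seq_along(rbp_names), function(i) {
        paste(BASES[1L + (floor((i - 1L) / 4^(0:5)) %% 4L)],
              collapse = "")
      }, character(1L)), rbp_names)
  }
  cs <- vapply(rbp_names, function(r) {
    w <- full[full$rbp == r, ]
    any(w$weight[w$cell_type == "glia"] *
          w$weight[w$cell_type == "neuron"] < 0)
  }, logical(1L))
  structure(list(effects = full,
                 baseline_logit = baseline_logit[CELL_TYPES],
                 motif_map = motif_map, rbp_names = rbp_names,
                 cell_specific = rbp_names[cs]),
            class = "splice_grammar")
}
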
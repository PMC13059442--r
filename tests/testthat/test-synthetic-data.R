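test_that("gen_genome builds valid cassette-exon genes deterministically", {
  gg <- gen_genome(1, exons_per_gene = 3, seed = 42)
  ann <- gg$annotation
  expect_equal(sum(ann$role == "cassette"), 1L)

  gg2 <- gen_genome(1, exons_per_gene = 3, seed = 42)
  expect_identical(gg$genome, gg2$genome)
  expect_identical(gg$annotation, gg2$annotation)

  gg50 <- gen_genome(50, seed = 3)
  ann50 <- gg50$annotation
  expect_length(unique(ann50$gene_id), 50L)
  cas <- ann50[ann50$role == "cassette", ]
  for (i in seq_len(nrow(cas))) {
    g <- ann50[ann50$gene_id == cas$gene_id[i], ]
    expect_gt(cas$start[i], min(g$start))
    expect_lt(cas$end[i], max(g$end))
    expect_lt(cas$end[i], nchar(gg50$genome[[cas$chrom[i]]]))
  }

  expect_error(gen_genome(0), "n_genes")
  expect_error(gen_genome(5, exons_per_gene = 2), "exons_per_gene")
})

test_that("donor/acceptor dinucleotides are canonical on the coding strand", {
  gg <- gen_genome(20, seed = 9)
  ann <- gg$annotation
  for (gid in unique(ann$gene_id)) {
    g <- ann[ann$gene_id == gid, ]
    g <- g[order(g$rank), ]
    chrom <- gg$genome[[g$chrom[1]]]
    for (j in seq_len(nrow(g) - 1L)) {
      intron <- substr(chrom, g$end[j] + 1L, g$start[j + 1L])
      if (g$strand[1] == "-") intron <- revcomp(intron)
      expect_identical(substr(intron, 1L, 2L), "GT")
      expect_identical(substr(intron, nchar(intron) - 1L, nchar(intron)),
                       "AG")
    }
  }
})

test_that("plant_grammar covers the full effect grid and controls cell specificity", {
  rbps <- sprintf("R%03d", 1:122)
  gr <- plant_grammar(rbps, n_cell_specific = 5, seed = 1)
  expect_equal(nrow(gr$effects), 122L * 6L * 2L)
  expect_length(gr$cell_specific, 5L)
  expect_true(all(is.finite(gr$effects$weight)))

  ## cell-specific RBPs flip sign, all others share effects
  eff <- gr$effects[gr$effects$weight != 0, ]
  for (r in unique(eff$rbp)) {
    e <- eff[eff$rbp == r, ]
    for (cat in unique(e$category)) {
      wg <- e$weight[e$category == cat & e$cell_type == "glia"]
      wn <- e$weight[e$category == cat & e$cell_type == "neuron"]
      if (r %in% gr$cell_specific) expect_equal(wn, -wg)
      else expect_equal(wn, wg)
    }
  }

  gr0 <- plant_grammar(rbps[1:6], n_cell_specific = 0, seed = 2)
  eg <- gr0$effects[gr0$effects$cell_type == "glia", "weight"]
  en <- gr0$effects[gr0$effects$cell_type == "neuron", "weight"]
  expect_identical(eg, en)

  expect_error(plant_grammar(c("A", "A")), "duplicate")
  expect_error(plant_grammar(c("A", "B"), n_cell_specific = 3), "exceeds")
})

test_that("an explicit grammar can emulate opposite-sign acceptor effects", {
  gr <- splice_grammar(data.frame(
    rbp = "QKI", category = "acc_overlap",
    cell_type = c("glia", "neuron"), weight = c(-0.15, 0.12)))
  expect_equal(grammar_effect(gr, "QKI", "acc_overlap", "glia"), -0.15)
  expect_equal(grammar_effect(gr, "QKI", "acc_overlap", "neuron"), 0.12)
  expect_identical(gr$cell_specific, "QKI")
})

test_that("gen_peaks places peaks at grammar-active categories", {
  gg <- gen_genome(40, seed = 5)
  gr <- splice_grammar(data.frame(rbp = "R1", category = "exonic",
                                  cell_type = c("glia", "neuron"),
                                  weight = 1))
  pk <- gen_peaks(gg$annotation, gr, placement_rate = 1, seed = 5)
  cas <- gg$annotation[gg$annotation$role == "cassette", ]
  expect_equal(nrow(pk), nrow(cas))           # every exon exactly one peak
  expect_true(all(pk$category == "exonic"))
  expect_error(gen_peaks(gg$annotation, gr, placement_rate = 0), "placement")
})

test_that("peak counts follow the placement rate binomially", {
  gg <- gen_genome(1000, seed = 6)
  gr <- splice_grammar(data.frame(rbp = "R1", category = "downstream",
                                  cell_type = c("glia", "neuron"),
                                  weight = 1))
  pk <- gen_peaks(gg$annotation, gr, placement_rate = 0.5, seed = 6)
  ## 99% binomial interval around 500
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(nrow(pk), bounds[1])
  expect_lte(nrow(pk), bounds[2])
})

test_that("planted peaks re-classify to their planted categories", {
  gg <- gen_genome(60, seed = 8)
  gr <- plant_grammar(sprintf("R%02d", 1:6), n_cell_specific = 1, seed = 8)
  pk <- gen_peaks(gg$annotation, gr, placement_rate = 0.8, seed = 8)
  ann <- gg$annotation
  for (i in seq_len(nrow(pk))) {
    e <- ann[ann$exon_id == pk$exon_id[i], ]
    got <- assign_category(pk$start[i], pk$end[i], e$start, e$end,
                           e$strand)
    expect_identical(got, pk$category[i])
  }
})

test_that("gen_reads reflects true inclusion and depth", {
  gg <- gen_genome(3, seed = 4)
  gr <- splice_grammar(data.frame(rbp = "R1", category = "exonic",
                                  cell_type = c("glia", "neuron"),
                                  weight = 0.5))
  ex <- cassette_exons(gg$annotation, gen_peaks(gg$annotation, gr, 0.5, 4),
                       gr, noise_sd = 0, seed = 4)
  ex$true_psi_neuron <- c(1, 0.5, 0.3)
  ex$true_psi_glia <- c(1, 0.5, 0.3)

  dt <- data.frame(individual = "i1", cell_type = "glia", depth = 200L)
  ch <- gen_reads(ex, dt, seed = 1, truncation_frac = 0)
  ## true_psi = 1: every chain includes the cassette exon
  e1 <- ex[1, ]
  ch1 <- ch[ch$chrom == e1$chrom, ]
  expect_true(all(grepl(sprintf("%d-%d", e1$start, e1$end), ch1$exons,
                        fixed = TRUE)))

  ## depth 0 for one individual: no rows for it
  dt2 <- data.frame(individual = c("i1", "i2"), cell_type = "glia",
                    depth = c(10L, 0L))
  ch2 <- gen_reads(ex, dt2, seed = 1)
  expect_false("i2" %in% ch2$individual)

  ## same seed, same chains
  expect_identical(gen_reads(ex, dt, seed = 9), gen_reads(ex, dt, seed = 9))
  expect_error(gen_reads(ex, data.frame(individual = "a",
                                        cell_type = "glia", depth = -1L)),
               "depths")
})

test_that("inclusion fraction concentrates around true psi at high depth", {
  gg <- gen_genome(1, seed = 13)
  gr <- splice_grammar(data.frame(rbp = "R1", category = "exonic",
                                  cell_type = c("glia", "neuron"),
                                  weight = 0))
  ex <- cassette_exons(gg$annotation, gen_peaks(gg$annotation, gr, 0.5, 13),
                       gr, noise_sd = 0, seed = 13)
  ex$true_psi_glia <- 0.5
  dt <- data.frame(individual = "i1", cell_type = "glia", depth = 10000L)
  ch <- gen_reads(ex, dt, seed = 2, truncation_frac = 0)
  frac <- mean(grepl(sprintf("%d-%d", ex$start[1], ex$end[1]), ch$exons,
                     fixed = TRUE))
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("skipping chains keep enough flank for the skip rule", {
  sim <- fixture_sim()
  cas <- sim$annotation[sim$annotation$role == "cassette", ]
  two_iv <- sim$chains[!grepl(";.*;", sim$chains$exons), ]
  ivs <- decode_chain(two_iv$exons)
  is_skip <- vapply(seq_along(ivs), function(i) {
    e <- cas[cas$chrom == two_iv$chrom[i], ]
    !any(ivs[[i]][, 1] < e$end & ivs[[i]][, 2] > e$start)
  }, logical(1))
  widths <- vapply(ivs[is_skip], function(m) min(m[, 2] - m[, 1]),
                   numeric(1))
  expect_gt(length(widths), 0)
  expect_true(all(widths >= 50))
})

test_that("gen_variants labels planted and neutral variants consistently", {
  sim <- fixture_sim()
  v <- sim$variants
  expect_equal(nrow(v), 20L)
  expect_true(all(v$REF != v$ALT))
  expect_setequal(unique(v$label), c("planted", "neutral"))

  planted <- v[v$label == "planted", ]
  for (i in seq_len(nrow(planted))) {
    w <- grammar_effect(sim$grammar, planted$rbp[i],
                        sim$peaks$category[sim$peaks$rbp == planted$rbp[i] &
                                             sim$peaks$exon_id ==
                                               planted$exon_id[i]][1],
                        "glia")
    ## disrupting a +effect motif lowers inclusion: expected dISM < 0,
    ## and the intron-excision slope carries the opposite sign
    expect_equal(planted$expected_dism_sign[i], -sign(w))
    expect_equal(sign(planted$SLOPE[i]), sign(w))
  }
  expect_true(all(v$expected_dism_sign[v$label == "neutral"] == 0))
})

test_that("the whole simulation is reproducible from one seed", {
  a <- simulate_dataset(n_genes = 6, rbp_names = c("A", "B"),
                        n_cell_specific = 0L, depth = 15,
                        n_planted = 2, n_neutral = 2, seed = 123)
  b <- simulate_dataset(n_genes = 6, rbp_names = c("A", "B"),
                        n_cell_specific = 0L, depth = 15,
                        n_planted = 2, n_neutral = 2, seed = 123)
  expect_identical(a$genome, b$genome)
  expect_identical(a$chains, b$chains)
  expect_identical(a$variants, b$variants)
})
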
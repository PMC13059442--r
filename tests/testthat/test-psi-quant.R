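## a hand-built three-exon gene on the plus strand
.toy_ann <- function(strand = "+") {
  data.frame(gene_id = "g1",
             exon_id = c("g1_e1", "g1_e2", "g1_e3"),
             chrom = "chr1",
             start = c(100L, 300L, 500L), end = c(200L, 360L, 600L),
             strand = strand, role = c("constitutive", "cassette",
                                       "constitutive"),
             rank = 1:3, stringsAsFactors = FALSE)
}

.toy_chains <- function(exons_strings, individual = "i1",
                        cell_type = "glia") {
  data.frame(read_id = sprintf("r%d", seq_along(exons_strings)),
             individual = individual, cell_type = cell_type,
             chrom = "chr1", strand = "+", exons = exons_strings,
             stringsAsFactors = FALSE)
}

test_that("count_exon_reads assigns molecules to the five count classes", {
  ch <- .toy_chains(c(
    "100-200;300-360;500-600",  # exact inclusion
    "100-200;500-600",          # skip, 100 bp on both sides
    "150-200;500-550",          # skip, exactly 50 bp on both sides
    "160-200;500-600",          # skip, only 40 bp on the left
    "100-200;300-330",          # enters at the acceptor, ends on exon
    "340-360;500-600",          # leaves by the donor, starts on exon
    "310-350"))                 # overlap only, no splice-site support
  cnt <- count_exon_reads(ch, "g1_e2", .toy_ann())
  expect_equal(cnt$X_in, 1L)
  expect_equal(cnt$X_out, 2L)   # the 40-bp-side skip does not count
  expect_equal(cnt$X_accIn, 1L)
  expect_equal(cnt$X_donIn, 1L)
  expect_equal(cnt$X_tot, 7L)   # every span overlaps the exon locus
  expect_true(all(cnt$X_tot >= cnt[, c("X_in", "X_out", "X_accIn",
                                       "X_donIn")]))
})

test_that("acceptor/donor truncation classes follow the strand", {
  ch <- .toy_chains(c("100-200;300-330", "340-360;500-600"))
  plus <- count_exon_reads(ch, "g1_e2", .toy_ann("+"))
  minus <- count_exon_reads(ch, "g1_e2", .toy_ann("-"))
  expect_equal(plus$X_accIn, 1L); expect_equal(plus$X_donIn, 1L)
  ## on the minus strand the acceptor is the right boundary
  expect_equal(minus$X_accIn, 1L); expect_equal(minus$X_donIn, 1L)
  ## and the specific molecules swap classes
  one <- count_exon_reads(.toy_chains("100-200;300-330"), "g1_e2",
                          .toy_ann("-"))
  expect_equal(one$X_accIn, 0L); expect_equal(one$X_donIn, 1L)
})

test_that("chains on other chromosomes are ignored with a note", {
  ch <- .toy_chains("100-200;300-360;500-600")
  ch2 <- ch; ch2$chrom <- "chr9"
  expect_message(cnt <- count_exon_reads(rbind(ch, ch2), "g1_e2",
                                         .toy_ann()),
                 "1 chains")
  expect_equal(cnt$X_in, 1L)
  expect_error(count_exon_reads(ch, "nope", .toy_ann()), "unknown exon")
})

test_that("mirror-image genes give identical counts (strand symmetry)", {
  sim <- fixture_sim()
  cas <- sim$annotation[sim$annotation$role == "cassette", ][1, ]
  sub_ann <- sim$annotation[sim$annotation$chrom == cas$chrom, ]
  sub_ch <- sim$chains[sim$chains$chrom == cas$chrom, ]
  L <- nchar(sim$genome[[cas$chrom]])
  flip_iv <- function(str) {
    m <- decode_chain(str)[[1L]]
    m2 <- cbind(L - m[, 2L], L - m[, 1L])
    encode_chain(m2[order(m2[, 1L]), , drop = FALSE])
  }
  ann_m <- sub_ann
  ann_m$start <- L - sub_ann$end; ann_m$end <- L - sub_ann$start
  ann_m$strand <- ifelse(sub_ann$strand == "+", "-", "+")
  ch_m <- sub_ch
  ch_m$exons <- vapply(sub_ch$exons, flip_iv, character(1L))
  ch_m$strand <- ann_m$strand[1L]
  a <- count_exon_reads(sub_ch, cas$exon_id, sub_ann)
  b <- count_exon_reads(ch_m, cas$exon_id, ann_m)
  expect_equal(a, b)
})

test_that("intron-retention-like candidates are excluded by the 70-base rule", {
  ann <- .toy_ann()
  cand <- data.frame(chrom = "chr1",
                     start = c(100L, 300L, 300L, 220L),
                     end = c(200L, 440L, 420L, 290L))
  kept <- exclude_retention_like(cand, ann)
  ## annotated exon kept
  expect_true(any(kept$start == 100 & kept$end == 200))
  ## novel, one annotated site, 80 non-exonic bases: removed
  expect_false(any(kept$start == 300 & kept$end == 440))
  ## novel, one annotated site, only 60 non-exonic bases: kept
  expect_true(any(kept$start == 300 & kept$end == 420))
  ## novel with no annotated site: kept regardless
  expect_true(any(kept$start == 220 & kept$end == 290))
})

test_that("depth normalization matches the hand-computed two-individual oracle", {
  counts <- data.frame(
    exon_id = "e", cell_type = "glia", individual = c("i1", "i2"),
    X_in = c(100L, 10L), X_out = c(100L, 90L), X_accIn = 0L, X_donIn = 0L,
    X_tot = c(200L, 100L))
  totals <- data.frame(individual = c("i1", "i2"), total = c(1e6, 1e4))
  pb <- normalize_by_depth(counts, totals)
  n_in <- 100 / 1e6 + 10 / 1e4
  n_out <- 100 / 1e6 + 90 / 1e4
  expect_equal(pb$n_in, n_in)
  expect_equal(pb$n_out, n_out)
  expect_equal(pb$raw_tot, 300)
  psi <- compute_psi(pb)
  expect_equal(psi$psi_overall, n_in / (n_in + n_out))

  ## one individual: normalization cancels in the ratio
  pb1 <- normalize_by_depth(counts[1, ], totals[1, ])
  expect_equal(compute_psi(pb1)$psi_overall, 100 / 200)

  ## zero-depth individuals are dropped with a warning
  totals0 <- data.frame(individual = c("i1", "i2"), total = c(1e6, 0))
  expect_warning(pb0 <- normalize_by_depth(counts, totals0), "zero total")
  expect_equal(compute_psi(pb0)$psi_overall, 0.5)
})

test_that("the three PSI formulas and the support rule behave as specified", {
  pb <- data.frame(exon_id = c("a", "b", "c"), cell_type = "glia",
                   n_in = c(8, 12, 5), n_out = c(10, 0, 5),
                   n_accIn = c(1, 0, 0), n_donIn = c(1, 0, 0),
                   n_tot = c(20, 12, 10), raw_tot = c(20, 12, 9))
  psi <- compute_psi(pb)
  expect_equal(psi$psi_overall[1], 0.5)
  expect_equal(psi$psi_acceptor[1], 9 / 19)
  expect_equal(psi$psi_donor[1], 9 / 19)
  expect_equal(psi$psi_overall[2], 1)
  expect_true(is.na(psi$psi_overall[3]))  # below 10 raw reads
})

test_that("the PSI range filter is inclusive at both bounds", {
  rec <- data.frame(
    exon_id = c("a", "b", "c", "d"), cell_type = "all",
    psi_overall = c(0.5, 0.5, 0.02, 0.5),
    psi_acceptor = c(0.5, 0.5, 0.02, 0.5),
    psi_donor = c(0.5, 0.99, 0.02, NA),
    n_reads = 100)
  kept <- filter_psi_range(rec)
  expect_setequal(kept, c("a", "c"))
})

test_that("variability labels use strict thresholds and handle missing PSI", {
  cl <- classify_variability(psi_glia = c(0.8, 0.65, 0.55, NA, 0.9),
                             psi_neuron = c(0.4, 0.4, 0.5, 0.5, 0.79))
  expect_equal(cl$variability,
               c("variable", "var0.1", "non_variable", "unmeasured",
                 "var0.1"))
  ## |delta| = 0.25 exactly is not "variable" (strict >)
  expect_false(cl$variability[2] == "variable")
  expect_equal(cl$delta_psi[1], 0.4)
})

test_that("skew downsampling retains exactly the target within the class", {
  set.seed(30)
  n <- 200
  wide <- data.frame(exon_id = sprintf("e%03d", 1:n),
                     psi_neuron = c(runif(120, 0.95, 1),
                                    runif(80, 0.2, 0.8)),
                     psi_glia = c(runif(120, 0.95, 1),
                                  runif(80, 0.2, 0.8)))
  wide$psi_glia[1:120] <- wide$psi_neuron[1:120] +
    runif(120, -0.01, 0.01)
  wide$psi_glia <- pmin(wide$psi_glia, 1)
  wide$delta_psi <- wide$psi_glia - wide$psi_neuron
  in_class <- wide$psi_neuron > 0.9 & wide$psi_glia > 0.9 &
    abs(wide$delta_psi) < 0.03
  ds <- downsample_skewed(wide, target = 50, seed = 1)
  expect_equal(nrow(ds), nrow(wide) - (sum(in_class) - 50L))
  expect_equal(sum(ds$exon_id %in% wide$exon_id[!in_class]),
               sum(!in_class))
  ## below-target class is a no-op
  ds2 <- downsample_skewed(wide, target = 5000, seed = 1)
  expect_equal(nrow(ds2), nrow(wide))
  ## seeded determinism
  expect_identical(downsample_skewed(wide, 50, seed = 3),
                   downsample_skewed(wide, 50, seed = 3))
  ## mouse rule uses exact unity
  wide$psi_neuron[1:10] <- 1; wide$psi_glia[1:10] <- 1
  wide$delta_psi <- wide$psi_glia - wide$psi_neuron
  dm <- downsample_skewed(wide, target = 4, seed = 2, rule = "mouse")
  expect_equal(sum(dm$psi_neuron == 1 & dm$psi_glia == 1), 4L)
})

test_that("coordination test flags perfect association and balanced tables", {
  ann <- data.frame(gene_id = "g1",
                    exon_id = sprintf("g1_e%d", 1:5), chrom = "chr1",
                    start = c(0L, 200L, 400L, 600L, 800L),
                    end = c(100L, 260L, 500L, 660L, 900L),
                    strand = "+",
                    role = c("constitutive", "cassette", "constitutive",
                             "cassette", "constitutive"),
                    rank = 1:5, stringsAsFactors = FALSE)
  both_in <- "0-100;200-260;400-500;600-660;800-900"
  b_only <- "0-100;200-260;400-500;800-900"
  d_only <- "0-100;400-500;600-660;800-900"
  none <- "0-100;400-500;800-900"

  perfect <- .toy_chains(c(rep(both_in, 10), rep(none, 10)))
  res <- coordination_test(perfect, "g1_e2", "g1_e4", ann)
  expect_true(is.infinite(res$odds_ratio))
  expect_lt(res$p_value, 0.05)

  balanced <- .toy_chains(c(rep(both_in, 5), rep(b_only, 5),
                            rep(d_only, 5), rep(none, 5)))
  res2 <- coordination_test(balanced, "g1_e2", "g1_e4", ann)
  expect_equal(unname(res2$table), matrix(5L, 2, 2))
  expect_equal(res2$odds_ratio, 1, tolerance = 1e-6)

  expect_error(coordination_test(.toy_chains("0-100;200-260"),
                                 "g1_e2", "g1_e4", ann), "span")
})

test_that("the coordination test is calibrated under independence", {
  ann <- data.frame(gene_id = "g1",
                    exon_id = sprintf("g1_e%d", 1:5), chrom = "chr1",
                    start = c(0L, 200L, 400L, 600L, 800L),
                    end = c(100L, 260L, 500L, 660L, 900L),
                    strand = "+",
                    role = c("constitutive", "cassette", "constitutive",
                             "cassette", "constitutive"),
                    rank = 1:5, stringsAsFactors = FALSE)
  types <- c("0-100;200-260;400-500;600-660;800-900",
             "0-100;200-260;400-500;800-900",
             "0-100;400-500;600-660;800-900",
             "0-100;400-500;800-900")
  set.seed(77)
  n <- 500
  rejections <- vapply(seq_len(200), function(rep) {
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    idx <- 1L + (1L - a) * 1L + (1L - b) * 2L
    ch <- .toy_chains(types[idx])
    coordination_test(ch, "g1_e2", "g1_e4", ann)$p_value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(rate, 0.09)   # near the nominal 5% level
  expect_gt(rate, 0.005)  # (Fisher is mildly conservative)
})

test_that("psi_from_chains produces a coherent long table", {
  sim <- fixture_sim()
  psi <- psi_from_chains(sim$chains, sim$annotation, psi_range = NULL)
  expect_setequal(unique(psi$cell_type), c("glia", "neuron"))
  ok <- !is.na(psi$psi_overall)
  expect_true(all(psi$psi_overall[ok] >= 0 & psi$psi_overall[ok] <= 1))
  ## delta is glia minus neuron
  one <- psi[psi$exon_id == psi$exon_id[1], ]
  d <- one$psi_overall[one$cell_type == "glia"] -
    one$psi_overall[one$cell_type == "neuron"]
  expect_equal(unique(one$delta_psi), d)
})
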
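test_that("replicate peaks union-merge, counting overlaps only once", {
  p <- data.frame(rbp = "R1", chrom = "chr1",
                  start = c(100L, 150L, 0L, 20L, 100L, 100L),
                  end = c(200L, 250L, 10L, 30L, 200L, 200L))
  ps <- merge_replicates(p)
  expect_identical(class(ps), "peak_set")
  got <- ps$intervals[order(ps$intervals$start), ]
  expect_equal(got$start, c(0L, 20L, 100L))
  expect_equal(got$end, c(10L, 30L, 250L))
})

test_that("category assignment is strand-aware and mutually exclusive", {
  ## plus-strand exon [1000, 1200)
  expect_identical(assign_category(950L, 1050L, 1000L, 1200L, "+"),
                   "acc_overlap")
  expect_identical(assign_category(950L, 1250L, 1000L, 1200L, "+"),
                   "spanning")
  expect_identical(assign_category(1050L, 1100L, 1000L, 1200L, "+"),
                   "exonic")
  expect_identical(assign_category(1150L, 1250L, 1000L, 1200L, "+"),
                   "don_overlap")
  expect_identical(assign_category(500L, 700L, 1000L, 1200L, "+"),
                   "upstream")
  expect_identical(assign_category(1300L, 1350L, 1000L, 1200L, "+"),
                   "downstream")
  ## minus strand: the acceptor is at 1200
  expect_identical(assign_category(1190L, 1260L, 1000L, 1200L, "-"),
                   "acc_overlap")
  expect_identical(assign_category(500L, 700L, 1000L, 1200L, "-"),
                   "downstream")
  ## out of range on both sides
  expect_true(is.na(assign_category(100L, 200L, 1000L, 1200L, "+")))
  expect_true(is.na(assign_category(1700L, 1800L, 1000L, 1200L, "+")))
  ## a peak equal to the exon is exonic, not spanning
  expect_identical(assign_category(1000L, 1200L, 1000L, 1200L, "+"),
                   "exonic")
})

test_that("every in-range peak maps to exactly one category", {
  set.seed(41)
  for (strand in c("+", "-")) {
    s <- 1000L; e <- 1150L
    starts <- sample(400:1800, 300, replace = TRUE)
    ends <- starts + sample(5:300, 300, replace = TRUE)
    cat <- assign_category(starts, ends, s, e, strand)
    in_range <- ends > s - 400L & starts < e + 400L
    ## peaks overlapping the window (or its boundary geometry) must be
    ## classified; peaks fully outside must not
    touching <- ends > s - 400L & starts < e + 400L
    expect_true(all(!is.na(cat[touching])))
    expect_true(all(is.na(cat[!in_range])))
  }
})

test_that("flipping the strand swaps upstream/downstream and acc/don", {
  set.seed(42)
  s <- 1000L; e <- 1150L
  starts <- sample(500:1700, 200, replace = TRUE)
  ends <- starts + sample(5:200, 200, replace = TRUE)
  plus <- assign_category(starts, ends, s, e, "+")
  minus <- assign_category(starts, ends, s, e, "-")
  swap <- c(upstream = "downstream", downstream = "upstream",
            acc_overlap = "don_overlap", don_overlap = "acc_overlap",
            exonic = "exonic", spanning = "spanning")
  expect_identical(unname(swap[plus]), minus)
})

test_that("the feature matrix has 6 columns per RBP and flags empty rows", {
  sim <- fixture_sim()
  cas <- sim$annotation[sim$annotation$role == "cassette", ]
  ps <- make_peaksets(sim$peaks)
  fm <- build_feature_matrix(cas, ps)
  expect_equal(ncol(fm), 6L * length(ps))
  expect_identical(rownames(fm), cas$exon_id)
  expect_true(all(fm >= 0))
  az <- attr(fm, "all_zero")
  expect_identical(unname(az), unname(rowSums(fm) == 0L))

  one <- build_feature_matrix(cas, ps[1], flank_max = 400L)
  expect_equal(ncol(one), 6L)
})

test_that("feature-matrix column sums count the planted peak incidences", {
  sim <- fixture_sim()
  cas <- sim$annotation[sim$annotation$role == "cassette", ]
  ps <- make_peaksets(sim$peaks)
  fm <- build_feature_matrix(cas, ps)
  for (r in names(ps)) {
    planted <- sum(sim$peaks$rbp == r & sim$peaks$exon_id %in% cas$exon_id)
    cols <- grep(paste0("^", r, ":"), colnames(fm))
    ## merged peaks can only reduce the count (overlapping replicates)
    expect_lte(sum(fm[, cols]), planted)
    expect_gte(sum(fm[, cols]), 1L)
  }
  ## planted categories are recovered in the right column
  for (i in seq_len(min(nrow(sim$peaks), 50L))) {
    p <- sim$peaks[i, ]
    if (!p$exon_id %in% rownames(fm)) next
    expect_gte(fm[p$exon_id, paste0(p$rbp, ":", p$category)], 1L)
  }
})

test_that("binding profiles report coverage fractions over 850 positions", {
  exons <- data.frame(exon_id = c("a", "b", "c"), chrom = "chr1",
                      start = c(1000L, 3000L, 5000L),
                      end = c(1100L, 3100L, 5049L), strand = "+",
                      stringsAsFactors = FALSE)
  ## one peak covering flank position -10 of every qualifying exon
  pk <- data.frame(rbp = "R1", chrom = "chr1",
                   start = c(985L, 2985L), end = c(995L, 2995L))
  ps <- merge_replicates(pk)
  bp <- binding_profile(exons, ps, "toy")
  expect_length(bp$fractions, 400L + 50L + 400L)
  ## the 49-bp exon is excluded from the group
  expect_equal(bp$n_exons, 2L)
  ## positions -15..-6 (window indices 386..395) are covered for all
  expect_equal(unname(bp$fractions[391]), 1)
  expect_equal(unname(bp$fractions[200]), 0)
  expect_true(all(bp$fractions >= 0 & bp$fractions <= 1))
  expect_error(binding_profile(exons[3, ], ps, "empty"), "qualifying")
})

test_that("minus-strand profiles are the mirror of plus-strand ones", {
  exons_p <- data.frame(exon_id = "a", chrom = "chr1", start = 1000L,
                        end = 1100L, strand = "+", stringsAsFactors = FALSE)
  exons_m <- exons_p; exons_m$strand <- "-"
  pk <- data.frame(rbp = "R1", chrom = "chr1", start = 950L, end = 990L)
  ps <- merge_replicates(pk)
  fp <- binding_profile(exons_p, ps)$fractions
  fm <- binding_profile(exons_m, ps)$fractions
  expect_equal(fm, rev(fp))
})

test_that("profile divergence pairs cell types over RBP x stratum", {
  sim <- fixture_sim()
  psi <- psi_from_chains(sim$chains, sim$annotation, psi_range = NULL)
  rec <- psi[, c("exon_id", "cell_type", "psi_overall", "psi_acceptor",
                 "psi_donor", "n_reads")]
  wide <- psi_wide(rec)
  ps <- make_peaksets(sim$peaks)
  ann_ex <- sim$annotation[match(wide$exon_id, sim$annotation$exon_id), ]
  pd <- profile_divergence(wide, ann_ex, ps, var_threshold = 0.1,
                           min_exons = 1L)
  expect_true(all(pd$mse$mse >= 0))
  expect_setequal(unique(pd$mse$cell_type), c("neuron", "glia"))
  expect_setequal(unique(pd$mse$stratum), c("high", "low"))
  expect_true(is.numeric(pd$wilcoxon$p.value))
  ## identical groups give MSE zero
  g <- ann_ex[1:5, ]
  pv <- binding_profile(g, ps[[1]], "x")
  expect_equal(mean((pv$fractions - pv$fractions)^2), 0)
})
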
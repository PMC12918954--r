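toy_atlas <- function(seed = 3L, ...) {
  generate_synthetic_expression(n_genes = 600, cells_per_class = 20,
                                markers_per_class = 15, seed = seed, ...)
}

test_that("the expression generator is seeded and labelled", {
  a <- toy_atlas()
  b <- toy_atlas()
  expect_identical(a$sc, b$sc)
  expect_identical(a$bulk, b$bulk)
  expect_equal(length(a$cell_classes), ncol(a$sc))
  expect_equal(sort(names(a$markers)), sort(a$classes))
  expect_error(generate_synthetic_expression(n_genes = 10,
                                             markers_per_class = 5,
                                             seed = 1),
               "markers")
})

test_that("pseudobulk aggregation is CPM-normalised per class", {
  d <- toy_atlas()
  pb <- pseudobulk(d$sc, d$cell_classes)
  expect_equal(unname(colSums(pb$cpm)), rep(1e6, length(d$classes)))
  expect_equal(pb$logcpm, log2(pb$cpm + 0.5))
  # single cell: pseudobulk equals that cell's own CPM
  one <- pseudobulk(d$sc[, 1, drop = FALSE], "glia")
  expect_equal(unname(one$cpm[, "glia"]),
               unname(d$sc[, 1] / sum(d$sc[, 1]) * 1e6))
  # duplicating a cell leaves the class profile unchanged (scale-free)
  two <- pseudobulk(cbind(d$sc[, 1], d$sc[, 1]), c("glia", "glia"))
  expect_equal(two$cpm, one$cpm)
  zero <- matrix(0L, 4, 2,
                 dimnames = list(paste0("g", 1:4), c("c1", "c2")))
  expect_error(pseudobulk(zero, c("glia", "glia")), "zero total")
})

test_that("TMM factors are 1 for identical or purely rescaled samples", {
  d <- toy_atlas()
  pb <- pseudobulk(d$sc, d$cell_classes)$counts
  same <- cbind(s1 = pb[, 1], s2 = pb[, 1])
  expect_equal(unname(tmm_factors(same)), c(1, 1))
  scaled <- cbind(s1 = pb[, 1], s2 = pb[, 1] * 2L)
  norm <- tmm_log_cpm(scaled)
  expect_equal(norm$logcpm[, 1], norm$logcpm[, 2], tolerance = 1e-8)
  expect_equal(exp(mean(log(norm$factors))), 1, tolerance = 1e-12)
  bad <- cbind(s1 = pb[, 1], s2 = rep(0L, nrow(pb)))
  expect_error(tmm_factors(bad), "zero counts")
})

test_that("TMM factors match the edgeR implementation within 2% on spiked data", {
  withr::with_seed(17, {
    mu <- rlnorm(1500, 4, 1.5)
    counts <- sapply(1:4, function(i) rnbinom(1500, mu = mu, size = 5))
    # asymmetric differential expression in sample 4
    hot <- 1:120
    counts[hot, 4] <- counts[hot, 4] * 8L
    rownames(counts) <- paste0("g", 1:1500)
    colnames(counts) <- paste0("s", 1:4)
  })
  ours <- tmm_factors(counts)
  ref <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_lt(max(abs(ours - ref) / ref), 0.02)
})

test_that("shared HVG selection clamps, drops constants and finds markers", {
  d <- toy_atlas()
  pb <- pseudobulk(d$sc, d$cell_classes)
  bulk_norm <- tmm_log_cpm(d$bulk)$logcpm
  all_genes <- hvg_shared(bulk_norm, pb$logcpm, n = 1e6)
  expect_setequal(all_genes, rownames(d$sc))
  # a constant gene ranks last
  flat_bulk <- bulk_norm
  flat_bulk["g00599", ] <- 3
  flat_pb <- pb$logcpm
  flat_pb["g00599", ] <- 3
  top <- hvg_shared(flat_bulk, flat_pb, n = nrow(flat_bulk) - 1)
  expect_false("g00599" %in% top)
  # planted markers are over-represented among the top genes
  hv <- hvg_shared(bulk_norm, pb$logcpm, n = 150)
  markers <- unlist(d$markers)
  res <- enrichment(intersect(hv, markers), rownames(d$sc),
                    list(mk = markers), fdr_cutoff = 1.1)
  expect_lt(res$p, 1e-6)
  expect_error(hvg_shared(bulk_norm[0, , drop = FALSE], pb$logcpm),
               "shared")
})

test_that("Spearman similarity is rank-invariant and identifies the source class", {
  d <- toy_atlas()
  pb <- pseudobulk(d$sc, d$cell_classes)
  genes <- rownames(d$sc)[1:300]
  ident <- similarity(pb$logcpm[, "glia"], pb$logcpm, genes)
  expect_equal(unname(ident$spearman[ident$class == "glia"]), 1)
  cubed <- similarity(pb$logcpm[, "glia"]^3, pb$logcpm, genes)
  expect_equal(unname(cubed$spearman[cubed$class == "glia"]), 1)
  # glia-derived bulk is most similar to the glia pseudobulk class
  joint <- tmm_log_cpm(cbind(d$bulk, pb$counts))
  hv <- hvg_shared(joint$logcpm[, colnames(d$bulk)],
                   joint$logcpm[, d$classes], n = 300)
  sim <- similarity(joint$logcpm[, colnames(d$bulk)],
                    joint$logcpm[, d$classes], hv)
  expect_equal(sim$class[1], "glia")
  expect_error(similarity(pb$logcpm[, 1], pb$logcpm, genes[1:2]), "3 genes")
})

test_that("specificity ratios use the pseudocount floor and rank as defined", {
  counts <- matrix(c(50, 5, 2,
                     80, 0, 0,
                     10, 40, 1), nrow = 3, byrow = TRUE,
                   dimnames = list(c("gA", "gB", "gC"),
                                   c("glia", "neurons", "immune")))
  pb <- structure(list(counts = counts,
                       cpm = counts, logcpm = log2(counts + 0.5),
                       prior = 0.5),
                  class = "pseudobulk_profile")
  rk <- specificity_and_rank(c("gA", "gB", "gC"), pb)
  expect_equal(rk$specificity_ratio[rk$gene == "gA"], 10)
  expect_equal(rk$specificity_ratio[rk$gene == "gB"], 80 / 0.01)
  expect_equal(sort(rk$rank_expression), 1:3)
  expect_equal(sort(rk$rank_specificity), 1:3)
  expect_error(specificity_and_rank("gZ", pb), "absent")
  pb2 <- pb
  colnames(pb2$cpm) <- c("x", "neurons", "immune")
  expect_error(specificity_and_rank("gA", pb2), "glia")
})

test_that("planted glia-specific candidates occupy the top combined ranks", {
  # the candidate list emulates a secreted-protein screen: the planted
  # glia-specific genes are abundant (mass spectrometry only sees
  # well-expressed proteins), the decoys are expressed but unspecific
  ok <- vapply(1:3, function(s) {
    d <- toy_atlas(seed = s)
    pb <- pseudobulk(d$sc, d$cell_classes)
    glia_cpm <- pb$cpm[, "glia"]
    planted <- names(sort(glia_cpm[d$markers$glia],
                          decreasing = TRUE))[1:4]
    pool <- setdiff(rownames(d$sc), unlist(d$markers))
    pool <- pool[glia_cpm[pool] < min(glia_cpm[planted])]
    decoys <- names(sort(glia_cpm[pool], decreasing = TRUE))[1:36]
    rk <- specificity_and_rank(c(planted, decoys), pb)
    all(planted %in% rk$gene[1:4])
  }, logical(1))
  expect_true(all(ok))
})

test_that("delta-CT fold changes follow the power-of-two rule", {
  ct <- tibble::tibble(
    gene = rep(c("Gapdh", "Fbln2", "Dbi", "Me1"), each = 4),
    sample = rep(paste0("s", 1:4), 4),
    condition = rep(rep(c("ctrl", "ko"), each = 2), 4),
    ct = c(20, 20, 20, 20,      # housekeeping
           24, 24, 25, 25,      # Fbln2: dCT 4 -> 5, fold 0.5
           28, 28, 27, 27,      # Dbi: ddCT -1, fold 2
           22, 22, 22, 22))     # Me1: unchanged
  res <- dct_fold_change(ct, "Gapdh", reference = "ctrl")
  expect_equal(res$relative$rel_expr[res$relative$gene == "Me1"],
               rep(2^-2, 4))
  fc <- res$fold_change
  expect_equal(fc$fold_change[fc$gene == "Dbi"], 2)
  expect_equal(fc$fold_change[fc$gene == "Fbln2"], 0.5)
  expect_equal(fc$fold_change[fc$gene == "Me1"], 1)
  # hand-enumerated spreadsheet oracle for one gene
  rel_fbln2 <- 2^-(c(24, 24, 25, 25) - 20)
  expect_equal(fc$fold_change[fc$gene == "Fbln2"],
               mean(rel_fbln2[3:4]) / mean(rel_fbln2[1:2]))
  expect_error(dct_fold_change(dplyr::filter(ct, gene != "Gapdh"),
                               "Gapdh"), "housekeeping")
})

test_that("CPM is invariant to integer rescaling of one sample", {
  d <- toy_atlas()
  pb1 <- pseudobulk(d$sc, d$cell_classes)
  sc2 <- d$sc
  sc2[, 1] <- sc2[, 1] * 3L
  pb2 <- pseudobulk(sc2, d$cell_classes)
  # only the rescaled cell's class total changes; its CPM column does not
  # change direction beyond the re-weighting of that one cell
  one1 <- pseudobulk(d$sc[, 1, drop = FALSE], "glia")
  one2 <- pseudobulk(sc2[, 1, drop = FALSE], "glia")
  expect_equal(one1$cpm, one2$cpm)
})
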
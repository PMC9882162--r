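cytRec <- function(chrom, pos, strand, meth, unmeth, context = "CG") {
  data.frame(chrom = chrom, pos = pos, strand = strand,
             count_methylated = meth, count_unmethylated = unmeth,
             context = context, stringsAsFactors = FALSE)
}

test_that("cytosine coverage filter and CG dyad averaging", {
  recs <- rbind(
    cytRec("Chr1", 100, "+", 2, 2),            # 4 reads: dropped
    cytRec("Chr1", 200, "+", 8, 2),            # 80%
    cytRec("Chr1", 201, "-", 6, 4),            # 60% -> dyad mean 70 at 200
    cytRec("Chr1", 300, "+", 5, 0),            # 100%, partner below coverage
    cytRec("Chr1", 301, "-", 1, 1),
    cytRec("Chr1", 400, "+", 0, 10, "CHG"))    # other context ignored
  out <- filterAndPairCG(recs, minCoverage = 5)
  expect_equal(out$pos, c(200, 300))
  expect_equal(out$meth_pct, c(70, 100))
  expect_equal(out$n_cytosines, c(2L, 1L))
})

test_that("a minus-strand cytosine with no plus partner is used alone with a warning", {
  recs <- cytRec("Chr1", 501, "-", 10, 0)
  expect_warning(out <- filterAndPairCG(recs), "no plus-strand partner")
  expect_equal(out$pos, 500)
  expect_equal(out$meth_pct, 100)
})

test_that("gene-body methylation averages sites then replicates, unweighted", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "Chr1",
                      start = c(100, 1000), end = c(400, 1100))
  rep1 <- data.frame(chrom = "Chr1", pos = c(150, 250, 350),
                     meth_pct = c(100, 0, 50), n_cytosines = 1L)
  gm1 <- geneBodyMethylation(rep1, genes)
  expect_equal(gm1$cg_methylation_pct[gm1$gene_id == "g1"], 50)
  expect_true(is.na(gm1$cg_methylation_pct[gm1$gene_id == "g2"]))
  expect_equal(gm1$flag[gm1$gene_id == "g2"], "no-covered-cytosines")

  rep2 <- data.frame(chrom = "Chr1", pos = 150, meth_pct = 20, n_cytosines = 1L)
  gm2 <- geneBodyMethylation(list(rep1, rep2), genes)
  expect_equal(gm2$cg_methylation_pct[gm2$gene_id == "g1"], (50 + 20) / 2)
  expect_equal(gm2$n_replicates_covered[gm2$gene_id == "g1"], 2L)

  # replicate means are unweighted: 40% and 60% average to 50%
  ra <- data.frame(chrom = "Chr1", pos = c(150, 250), meth_pct = c(40, 40),
                   n_cytosines = 1L)
  rb <- data.frame(chrom = "Chr1", pos = 150, meth_pct = 60, n_cytosines = 1L)
  gm3 <- geneBodyMethylation(list(ra, rb), genes)
  expect_equal(gm3$cg_methylation_pct[gm3$gene_id == "g1"], 50)

  # invariant to site order and to splitting a replicate into chunks
  shuf <- rep1[c(3, 1, 2), ]
  expect_equal(geneBodyMethylation(shuf, genes)$cg_methylation_pct,
               gm1$cg_methylation_pct)
})

test_that("TPM normalisation sums to one million and is monotone in counts", {
  t1 <- tpmFromCounts(c(g1 = 10, g2 = 10), c(1000, 2000))
  expect_equal(unname(t1), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  even <- tpmFromCounts(rep(7, 5), rep(1500, 5))
  expect_equal(unname(even), rep(2e5, 5))

  set.seed(3)
  m <- matrix(rpois(40, 50), 10, 4)
  tm <- tpmFromCounts(m, runif(10, 500, 5000))
  expect_equal(unname(colSums(tm)), rep(1e6, 4))

  m2 <- m; m2[1, 1] <- m2[1, 1] + 10
  expect_gt(tpmFromCounts(m2, rep(1000, 10))[1, 1],
            tpmFromCounts(m, rep(1000, 10))[1, 1])

  expect_error(tpmFromCounts(c(0, 0), c(100, 100)), "zero total")

  expect_equal(meanLog2Tpm(cbind(c(3, 0), c(5, 0))), c(log2(5), 0))
})

test_that("TE distance uses the inclusive gap convention with 0 on overlap", {
  genes <- data.frame(gene_id = "g1", chrom = "Chr1", start = 1000, end = 2000)
  inside <- data.frame(chrom = "Chr1", start = 1500, end = 1600)
  expect_equal(teDistance(genes, inside)$te_distance_bp, 0)
  expect_true(teDistance(genes, inside)$te_within_gene)

  gap <- data.frame(chrom = "Chr1", start = 2501, end = 2600)
  expect_equal(teDistance(genes, gap)$te_distance_bp, 500)

  both <- data.frame(chrom = "Chr1", start = c(2501, 2301), end = c(2600, 2400))
  expect_equal(teDistance(genes, both)$te_distance_bp, 300)

  adjacent <- data.frame(chrom = "Chr1", start = 2001, end = 2100)
  expect_equal(teDistance(genes, adjacent)$te_distance_bp, 0)

  # symmetric under swapping the roles of the two interval sets
  g <- data.frame(gene_id = "x", chrom = "Chr1", start = 10, end = 20)
  t <- data.frame(gene_id = "y", chrom = "Chr1", start = 50, end = 60)
  expect_equal(teDistance(g, t)$te_distance_bp, teDistance(t, g)$te_distance_bp)

  far <- data.frame(gene_id = "g2", chrom = "Chr9", start = 1, end = 10)
  expect_warning(d <- teDistance(rbind(genes, far), gap), "without any TE")
  expect_true(is.na(d$te_distance_bp[d$gene_id == "g2"]))
})

test_that("feature table join keeps excluded genes flagged, not dropped", {
  hv <- data.frame(gene_id = c("g1", "g2"), label = c("hv", "non-hv"))
  expr <- data.frame(gene_id = c("g1", "g2", "g3"),
                     mean_log2_tpm = c(5, 1, 2))
  meth <- data.frame(gene_id = c("g1", "g3"), cg_methylation_pct = c(10, 60),
                     n_cg_sites = c(12, 30), n_replicates_covered = c(4L, 4L),
                     flag = c("", ""))
  te <- data.frame(gene_id = c("g1", "g2", "g3"),
                   te_distance_bp = c(0, 2070, 900),
                   te_within_gene = c(TRUE, FALSE, FALSE))
  tab <- assembleFeatureTable(hv, expr, meth, te, exclusions = "g2")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$hv_label, c("hv", "non-hv", "non-NLR"))
  expect_true(grepl("unmappable", tab$excluded_flags[tab$gene_id == "g2"]))
  expect_true(is.na(tab$mean_log2_tpm[tab$gene_id == "g2"]))
  expect_true(is.na(tab$cg_methylation_pct[tab$gene_id == "g2"]))
  expect_equal(tab$te_distance_bp[tab$gene_id == "g3"], 900)

  dup <- data.frame(gene_id = c("g1", "g1"), mean_log2_tpm = c(1, 2))
  expect_error(assembleFeatureTable(hv, dup), "duplicate gene_id")

  # round-trip through TSV is lossless for the joined table
  f <- tempfile(fileext = ".tsv")
  writeTsv(tab, f)
  back <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                     na.strings = "NA")
  expect_equal(back$gene_id, tab$gene_id)
  expect_equal(back$te_distance_bp, tab$te_distance_bp)
  expect_equal(back$mean_log2_tpm, tab$mean_log2_tpm)
})
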
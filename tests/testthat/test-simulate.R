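test_that("simulators are deterministic under a seed and leave the RNG alone", {
  a1 <- simulateCoalescent(8, 4, 500, seed = 42)
  a2 <- simulateCoalescent(8, 4, 500, seed = 42)
  expect_identical(as.character(alnSeqs(a1)), as.character(alnSeqs(a2)))

  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulateCoalescent(5, 2, 100, seed = 9))
  expect_identical(runif(1), before)  # caller's stream restored

  c1 <- simulateCodonPopulation(randomCodingSequence(30, seed = 1), 6, 4, 0.5,
                                seed = 77)
  c2 <- simulateCodonPopulation(randomCodingSequence(30, seed = 1), 6, 4, 0.5,
                                seed = 77)
  expect_identical(as.character(alnSeqs(c1)), as.character(alnSeqs(c2)))

  f1 <- simulateFeatureTable(nGenes = 100, nHv = 5, nNonHv = 20, seed = 3)
  f2 <- simulateFeatureTable(nGenes = 100, nHv = 5, nNonHv = 20, seed = 3)
  expect_identical(f1$table, f2$table)
})

test_that("coalescent samples have the expected diversity at n = 2", {
  # E[mean pairwise differences] = theta for a sample of two
  reps <- 400
  pis <- vapply(seq_len(reps), function(i) {
    aln <- simulateCoalescent(2, 3, 600, seed = 1000 + i)
    popGenStats(aln)@PiTotal
  }, numeric(1))
  se <- sd(pis) / sqrt(reps)
  expect_lt(abs(mean(pis) - 3), 3 * se)
})

test_that("coalescent mutation bookkeeping matches the alignment", {
  aln <- simulateCoalescent(10, 8, 900, seed = 5)
  truth <- attr(aln, "truth")
  st <- popGenStats(aln)
  # under infinite sites without collisions, S equals the mutation count
  expect_lte(st@S, truth$nMutations)
  expect_true(all(attr(aln, "truth")$tipCounts >= 1))
  expect_true(all(truth$tipCounts <= 9))  # no mutation above the root carries all tips
})

test_that("coalescent site frequency spectrum matches the neutral expectation", {
  # E[number of mutations carried by i of n tips] = theta / i
  n <- 10; theta <- 5; reps <- 2000
  counts <- matrix(0L, reps, n - 1)
  for (r in seq_len(reps)) {
    aln <- simulateCoalescent(n, theta, 999, seed = 80000 + r)
    tc <- attr(aln, "truth")$tipCounts
    counts[r, ] <- tabulate(tc, n - 1)
  }
  for (i in seq_len(n - 1)) {
    se <- sd(counts[, i]) / sqrt(reps)
    expect_lt(abs(mean(counts[, i]) - theta / i), 3 * se,
              label = sprintf("xi_%d", i))
  }
})

test_that("codon populations respect the nonsynonymous acceptance knob", {
  anc <- randomCodingSequence(80, seed = 21)
  none <- simulateCodonPopulation(anc, 8, 10, omegaAccept = 0, seed = 31)
  expect_equal(sum(attr(none, "truth")$retainedNonsyn), 0L)
  # measured piN is exactly 0 unless a codon was hit at two distinct
  # positions, where pathway averaging can attribute fractional
  # nonsynonymous differences; either way it stays far below neutral scale
  lg0 <- attr(none, "truth")$changeLog
  multiHit <- any(tapply((lg0$pos - 1L) %% 3L, (lg0$pos - 1L) %/% 3L,
                         function(x) length(unique(x))) > 1)
  pin0 <- piNpiS(none)$piN
  if (!multiHit) expect_equal(pin0, 0)
  expect_lt(pin0, 0.005)

  neutral <- simulateCodonPopulation(anc, 8, 10, omegaAccept = 1, seed = 32)
  truth <- attr(neutral, "truth")
  expect_gt(sum(truth$retainedNonsyn), 0)

  # replaying the retained-change log onto the ancestor reproduces every lineage
  for (i in seq_len(8)) {
    cur <- strsplit(anc, "")[[1]]
    lg <- truth$changeLog[truth$changeLog$lineage == i, , drop = FALSE]
    if (nrow(lg)) for (r in seq_len(nrow(lg))) cur[lg$pos[r]] <- lg$to[r]
    expect_identical(paste(cur, collapse = ""),
                     as.character(alnSeqs(neutral))[[paste0("s", i)]])
  }

  # with at most one hit per codon, the log classes match a direct recount
  sparse <- simulateCodonPopulation(randomCodingSequence(200, seed = 2), 4, 2,
                                    omegaAccept = 1, seed = 33)
  lg <- attr(sparse, "truth")$changeLog
  codonOf <- (lg$pos - 1) %/% 3
  if (!anyDuplicated(paste(lg$lineage, codonOf))) {
    anc2 <- attr(sparse, "truth")$ancestral
    for (r in seq_len(nrow(lg))) {
      k <- codonOf[r]
      c1 <- substr(anc2, 3 * k + 1, 3 * k + 3)
      seq <- as.character(alnSeqs(sparse))[[paste0("s", lg$lineage[r])]]
      c2 <- substr(seq, 3 * k + 1, 3 * k + 3)
      same <- GENCODE[[c1]] == GENCODE[[c2]]
      expect_identical(lg$class[r], if (same) "syn" else "nonsyn")
    }
  }

  expect_error(simulateCodonPopulation("TTTTAA", 4, 2), "stop codon")
})

test_that("hv bench alignments have exactly the requested variable columns", {
  aln <- simulateHvAlignment(nSeqs = 32, length = 120, nVariable = 12, seed = 19)
  truth <- attr(aln, "truth")
  expect_length(truth$variableColumns, 12)
  m <- alnMatrix(aln)
  varied <- which(apply(m, 2, function(col) length(unique(col)) > 1))
  expect_true(all(varied %in% truth$variableColumns))
  expect_equal(hvLabel(classifyHv(entropyProfile(aln))), "hv")
  flat <- simulateHvAlignment(nSeqs = 32, length = 120, nVariable = 0, seed = 20)
  expect_equal(hvLabel(classifyHv(entropyProfile(flat))), "non-hv")
})

test_that("feature tables carry the requested group structure and missingness", {
  sim <- simulateFeatureTable(nGenes = 1500, nHv = 15, nNonHv = 150,
                              effectSizes = c(expression = 1, methylation = -1,
                                              te = 1, mutation = 1),
                              missingRate = 0.1, seed = 51)
  tab <- sim$table
  expect_equal(table(tab$hv_label)[["hv"]], 15)
  expect_equal(table(tab$hv_label)[["non-hv"]], 150)
  expect_equal(nrow(tab), 1500)

  isHv <- tab$hv_label == "hv"
  expect_gt(mean(tab$mean_log2_tpm[isHv], na.rm = TRUE),
            mean(tab$mean_log2_tpm[!isHv], na.rm = TRUE))
  expect_lt(mean(tab$cg_methylation_pct[isHv], na.rm = TRUE),
            mean(tab$cg_methylation_pct[!isHv], na.rm = TRUE))
  expect_lt(mean(tab$te_distance_bp[isHv], na.rm = TRUE),
            mean(tab$te_distance_bp[!isHv], na.rm = TRUE))

  miss <- mean(is.na(tab$mean_log2_tpm))
  expect_lt(abs(miss - 0.1), 3 * sqrt(0.1 * 0.9 / 1500))
  expect_true(all(tab$te_within_gene == (!is.na(tab$te_distance_bp) &
                                           tab$te_distance_bp == 0)))
  # methylation covariate correlation present for the matched test
  expect_gt(cor(tab$n_cg_sites, tab$cg_methylation_pct,
                use = "complete.obs"), 0.2)
  expect_error(simulateFeatureTable(nGenes = 10, nHv = 8, nNonHv = 8),
               "exceed")
})
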
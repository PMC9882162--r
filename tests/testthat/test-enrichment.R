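test_that("rank-sum test: exact small-sample p-values and shift invariance", {
  rs <- rankSumTest(c(1, 2), c(3, 4))
  expect_equal(rs$p.value, 1 / 3, tolerance = 1e-12)

  same <- rankSumTest(c(5, 7, 9), c(5, 7, 9))
  expect_equal(same$p.value, 1)

  a <- c(1.2, 3.4, 2.2, 8); b <- c(4.5, 0.1, 6)
  r1 <- rankSumTest(a, b)
  r2 <- rankSumTest(a + 100, b + 100)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p.value, r2$p.value)

  expect_error(rankSumTest(numeric(0), 1:3), "non-empty")
})

test_that("Fisher 2x2 agrees with hypergeometric enumeration", {
  bal <- fisherTest2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(bal$p.value, 1)

  tab <- matrix(c(1, 11, 9, 3), 2)  # [[1,9],[11,3]]
  got <- fisherTest2x2(tab)
  # enumerate all tables with the observed margins
  m <- 10; nn <- 14; k <- 12
  probs <- dhyper(0:10, m, nn, k)
  pEnum <- sum(probs[probs <= dhyper(1, m, nn, k) * (1 + 1e-7)])
  expect_equal(got$p.value, pEnum, tolerance = 1e-9)
  expect_equal(fisherTest2x2(t(tab))$p.value, got$p.value)

  expect_error(fisherTest2x2(matrix(c(0, 0, 3, 4), 2)), "degenerate")
  expect_error(fisherTest2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("permutation diff test switches to exhaustive enumeration and matches it", {
  v <- c(3.1, 0.2, 5.5, 2.2, 8.8, 1.0)
  lab <- rep(c("A", "B"), each = 3)
  got <- permDiffTest(v, lab, "mean", nReplicates = 50)
  expect_true(got@exhaustive)
  expect_equal(got@nReplicates, choose(6L, 3L))
  expect_equal(pValue(got), oraclePermP(v, lab, mean), tolerance = 1e-12)

  gotMed <- permDiffTest(v, lab, "median")
  expect_equal(pValue(gotMed), oraclePermP(v, lab, median), tolerance = 1e-12)

  for (tail in c("greater", "less")) {
    g <- permDiffTest(v, lab, "mean", tail = tail)
    expect_equal(pValue(g), oraclePermP(v, lab, mean, tail = tail),
                 tolerance = 1e-12, label = tail)
  }

  # identical group values: delta 0, two-sided p 1
  flat <- permDiffTest(rep(2, 8), rep(c("A", "B"), 4), "mean")
  expect_equal(observedStat(flat), 0)
  expect_equal(pValue(flat), 1)
})

test_that("Monte Carlo permutation p-values are seed-reproducible and near exact", {
  set.seed(1)
  v <- rnorm(40, mean = rep(c(0, 0.5), each = 20))
  lab <- rep(c("A", "B"), each = 20)
  a <- permDiffTest(v, lab, "mean", nReplicates = 400, seed = 7,
                    exhaustiveLimit = 10)
  b <- permDiffTest(v, lab, "mean", nReplicates = 400, seed = 7,
                    exhaustiveLimit = 10)
  expect_identical(pValue(a), pValue(b))
  expect_false(a@exhaustive)

  withOne <- permDiffTest(v, lab, "mean", nReplicates = 400, seed = 7,
                          exhaustiveLimit = 10, addOne = TRUE)
  expect_gt(pValue(withOne), 0)

  # MC approximates the exhaustive value on a small instance
  v2 <- c(0.3, 1.9, 4.2, 0.1, 2.2, 3.3, 5.1, 0.8)
  lab2 <- rep(c("A", "B"), each = 4)
  exact <- pValue(permDiffTest(v2, lab2, "mean"))
  mc <- pValue(permDiffTest(v2, lab2, "mean", nReplicates = 4000, seed = 5,
                            exhaustiveLimit = 1))
  expect_lt(abs(mc - exact), 0.05)
})

test_that("matched permutation draws reproduce the target stratum profile", {
  sim <- simulateFeatureTable(nGenes = 300, nHv = 12, nNonHv = 0,
                              effectSizes = c(methylation = 0), seed = 9)
  tab <- sim$table
  res <- matchedPermTest(tab, sim$truth$hvIds, "cg_methylation_pct",
                         "n_cg_sites", nReplicates = 50, seed = 2)
  expect_equal(sum(res@details$targetStratumCounts), res@details$nTargets)
  expect_identical(pValue(res),
                   pValue(matchedPermTest(tab, sim$truth$hvIds,
                                          "cg_methylation_pct", "n_cg_sites",
                                          nReplicates = 50, seed = 2)))

  # targets sharing the pool minimum response give one-sided p = 0
  tab2 <- data.frame(gene_id = sprintf("g%03d", 1:120),
                     resp = c(rep(-50, 10), rnorm(110, 5)),
                     cov = rep(1:12, 10))
  res2 <- matchedPermTest(tab2, sprintf("g%03d", 1:10), "resp", "cov",
                          nReplicates = 200, seed = 3, tail = "less")
  expect_equal(pValue(res2), 0)
})

test_that("tail count test finds planted tails and reports expected counts", {
  set.seed(5)
  vals <- setNames(rnorm(400), sprintf("g%03d", 1:400))
  top <- names(sort(vals, decreasing = TRUE))[1:20]
  res <- tailCountTest(vals, top, percentile = 0.05, direction = "top",
                       nReplicates = 300, seed = 11)
  expect_equal(res@observedInTail, 20L)
  expect_equal(res@expectedInTail, 1.0)
  expect_equal(pValue(res), 0)
  resAdd <- tailCountTest(vals, top, percentile = 0.05, direction = "top",
                          nReplicates = 300, seed = 11, addOne = TRUE)
  expect_equal(pValue(resAdd), 1 / 301)

  # bottom direction mirrors the top
  bottom <- names(sort(vals))[1:20]
  resB <- tailCountTest(vals, bottom, percentile = 0.05, direction = "bottom",
                        nReplicates = 300, seed = 12)
  expect_equal(resB@observedInTail, 20L)

  # random subsets: mean observed close to expected
  obs <- replicate(300, {
    sub <- sample(names(vals), 40)
    sum(vals[sub] >= quantile(vals, 0.95, type = 7))
  })
  expect_lt(abs(mean(obs) - 2), 3 * sd(obs) / sqrt(300))

  expect_error(tailCountTest(vals, character(0)), "non-empty")
})

test_that("balancing-selection candidates require both tails jointly", {
  set.seed(8)
  ids <- sprintf("g%03d", 1:200)
  pi <- setNames(rnorm(200), ids)
  d <- setNames(rnorm(200), ids)
  # plant one gene at the top of both distributions
  pi["g001"] <- max(pi) + 1
  d["g001"] <- max(d) + 1
  cands <- balancingSelectionCandidates(pi, d)
  expect_true("g001" %in% cands)
  # top pi but median D is not a candidate
  pi["g002"] <- max(pi) + 2
  d["g002"] <- median(d)
  expect_false("g002" %in% balancingSelectionCandidates(pi, d))
  # disjoint tails give an empty result
  pi2 <- setNames(c(10, 1, 1, 1), c("a", "b", "c", "d"))
  d2 <- setNames(c(1, 10, 1, 1), c("a", "b", "c", "d"))
  expect_length(balancingSelectionCandidates(pi2, d2, percentile = 0.9), 0)
})

test_that("rank set score spans [0, 1] with 0.5 for random sets", {
  set.seed(14)
  expr <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  topk <- names(sort(expr, decreasing = TRUE))[1:15]
  bottomk <- names(sort(expr))[1:15]
  expect_equal(observedStat(rankSetScore(expr, topk, nReplicates = 50, seed = 1)), 1)
  expect_equal(observedStat(rankSetScore(expr, bottomk, nReplicates = 50, seed = 1)), 0)
  expect_lt(pValue(rankSetScore(expr, topk, nReplicates = 200, seed = 2)), 0.05)

  scores <- replicate(300, {
    observedStat(rankSetScore(expr, sample(names(expr), 15), nReplicates = 1,
                              seed = 3))
  })
  expect_lt(abs(mean(scores) - 0.5), 3 * sd(scores) / sqrt(300))
})

test_that("BH adjustment is monotone, order-preserving and validated", {
  expect_equal(bhAdjust(0.02), 0.02)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(4)
  p <- runif(50)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p))
  expect_equal(order(adj[order(p)]), 1:50)  # order preserved
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
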
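toy4x16 <- function() {
  NucAlignment(c(s1 = strrep("A", 16),
                 s2 = paste0(strrep("A", 15), "T"),
                 s3 = paste0(strrep("A", 8), "T", strrep("A", 7)),
                 s4 = paste0(strrep("A", 8), "T", strrep("A", 6), "T")))
}

test_that("segregating sites and pi match direct tallies on toy alignments", {
  ident <- NucAlignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(segregatingSites(ident), 0L)
  expect_equal(nucleotideDiversity(ident), 0)

  expect_equal(segregatingSites(NucAlignment(c(a = "AAAA", b = "AAAT"))), 1L)

  toy <- toy4x16()
  expect_equal(segregatingSites(toy), 2L)
  expect_equal(nucleotideDiversity(toy), 8 / 6 / 16, tolerance = 1e-12)

  two <- NucAlignment(c(a = strrep("A", 100),
                        b = paste0(strrep("A", 97), "TTT")))
  expect_equal(nucleotideDiversity(two), 0.03)
})

test_that("Tajima's D follows the constants formula, with undefined flags", {
  toy <- toy4x16()
  st <- popGenStats(toy)
  orc <- oraclePopgen(alnMatrix(toy))
  expect_equal(st@tajimaD, orc$D, tolerance = 1e-12)
  expect_equal(st@PiTotal, 8 / 6, tolerance = 1e-12)

  # Pi == S/a1 by construction at n = 4: eight singleton columns
  # (Pi contribution 1/2 each) plus three 2:2 columns (2/3 each) give
  # Pi = 6 = 11 / a1(4)
  singleCols <- sapply(rep(1:4, 2), function(i) {
    v <- rep("A", 4); v[i] <- "T"; v
  })
  doubleton <- matrix(rep(c("T", "T", "A", "A"), 3), nrow = 4)
  m <- cbind(singleCols, doubleton)
  balanced <- matToNucAlignment(m)
  stB <- popGenStats(balanced)
  expect_equal(stB@PiTotal, stB@S / stB@constants[["a1"]], tolerance = 1e-12)
  expect_equal(stB@tajimaD, 0, tolerance = 1e-12)

  # n = 3 has identically zero variance constants: D undefined with reason
  tri <- popGenStats(NucAlignment(c(a = "TAA", b = "ATA", c = "AAT")))
  expect_true(is.na(tri@tajimaD))
  expect_equal(tri@dReason, "zero_variance")

  mono <- popGenStats(NucAlignment(c(a = "AAAA", b = "AAAA", c = "AAAA")))
  expect_true(is.na(mono@tajimaD))
  expect_equal(mono@dReason, "no_segregating_sites")

  pair <- popGenStats(NucAlignment(c(a = "AAAA", b = "AAAT")))
  expect_true(is.na(pair@tajimaD))
  expect_equal(pair@dReason, "n_lt_3")

  expect_error(popGenStats(NucAlignment(c(a = "A-", b = "-A"))), "no analyzable")
})

test_that("complete deletion drops any column with a gap or ambiguity", {
  aln <- NucAlignment(c(a = "ACGTN", b = "AC-TA", c = "ACGTA"))
  st <- popGenStats(aln)
  expect_equal(st@nSitesAnalyzed, 3L)  # columns 3 and 5 removed
  expect_equal(st@S, 0L)
})

test_that("estimators agree with brute-force enumeration on random alignments", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    L <- sample(6:60, 1)
    mat <- randomNucMatrix(n, L, gapRate = 0.03, ambigRate = 0.02)
    orc <- oraclePopgen(mat)
    if (is.null(orc)) next
    st <- tryCatch(popGenStats(matToNucAlignment(mat)), error = function(e) NULL)
    if (is.null(st)) { expect_null(orc); next }
    expect_identical(st@S, as.integer(orc$S))
    expect_equal(st@PiTotal, orc$Pi, tolerance = 1e-12)
    expect_equal(st@pi, orc$pi, tolerance = 1e-12)
    expect_equal(st@thetaW, orc$thetaW, tolerance = 1e-12)
    if (is.na(orc$D)) expect_true(is.na(st@tajimaD))
    else expect_equal(st@tajimaD, orc$D, tolerance = 1e-12)
  }
})

test_that("pi equals mean pairwise Hamming distance over length when ungapped", {
  set.seed(7)
  for (rep in 1:10) {
    mat <- randomNucMatrix(sample(3:8, 1), sample(10:60, 1))
    aln <- matToNucAlignment(mat)
    n <- nrow(mat)
    hams <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      hams <- c(hams, sum(mat[i, ] != mat[j, ]))
    expect_equal(nucleotideDiversity(aln), mean(hams) / ncol(mat),
                 tolerance = 1e-12)
  }
})

test_that("Tajima constants satisfy their defining sums", {
  for (n in c(4, 10, 62)) {
    k <- tajimaConstants(n)
    i <- seq_len(n - 1)
    expect_equal(k[["a1"]], sum(1 / i))
    expect_equal(k[["a2"]], sum(1 / i^2))
    expect_equal(k[["e1"]], k[["c1"]] / k[["a1"]])
  }
})

test_that("genotype-matrix statistics handle missing calls pairwise-complete", {
  one <- matrix(c("T", "A", "A", "A"), ncol = 1)
  expect_equal(statsFromGenotypes(one)@pi, 0.5)

  mono <- matrix(0, nrow = 5, ncol = 4)
  stM <- statsFromGenotypes(mono)
  expect_equal(stM@S, 0L)
  expect_equal(stM@pi, 0)
  expect_true(is.na(stM@tajimaD))

  # random 6-haplotype, 20-site matrix against brute force over all pairs
  set.seed(13)
  g <- matrix(sample(c(0L, 1L, 2L), 120, replace = TRUE, prob = c(.5, .4, .1)),
              nrow = 6)
  g[runif(120) < 0.15] <- NA
  st <- statsFromGenotypes(g)
  piSites <- sapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]; x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    pairs <- combn(length(x), 2)
    mean(x[pairs[1, ]] != x[pairs[2, ]])
  })
  kept <- !is.na(piSites)
  expect_equal(st@nSitesAnalyzed, sum(kept))
  expect_equal(st@PiTotal, sum(piSites[kept]), tolerance = 1e-12)
  S <- sum(sapply(which(kept), function(j) {
    x <- g[, j]; length(unique(x[!is.na(x)])) > 1
  }))
  expect_identical(st@S, as.integer(S))

  allNA <- matrix(NA_integer_, 4, 3)
  expect_error(statsFromGenotypes(allNA), "no site")
})
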
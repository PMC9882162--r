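# Inference layer: rank-sum and Fisher tests, label-permutation tests,
# covariate-matched permutation control, empirical-tail enrichment,
# rank-based gene-set scoring and BH adjustment.
#
# Permutation p-values use the plain b / n denominator by default so that a
# reported 0 means "never reached in n replicates"; the (b + 1) / (n + 1)
# variant is available through addOne = TRUE and is the safer choice when a
# p-value feeds a downstream multiple-testing step.

#' Wilcoxon rank-sum test between two groups
#'
#' Mann-Whitney / Wilcoxon rank-sum with midrank ties: exact enumeration when
#' the smaller group has at most 8 values and there are no ties, normal
#' approximation (with continuity and tie correction) otherwise.
#'
#' @param x,y Numeric value vectors for the two groups (non-empty).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return The `htest` object from [stats::wilcox.test()] (statistic `W` and
#'   `p.value`).
#' @export
rankSumTest <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= 8L
  suppressWarnings(wilcox.test(x, y, alternative = alternative, exact = exact,
                               correct = !exact))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p by hypergeometric enumeration (tables with probability
#' at most that of the observed one).
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param alternative Passed to [stats::fisher.test()].
#' @return The `htest` object (odds-ratio estimate and `p.value`).
#' @export
fisherTest2x2 <- function(tab, alternative = "two.sided") {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margin: a row or column sums to zero")
  fisher.test(tab, alternative = alternative)
}

#' Permutation test for a difference in group means or medians
#'
#' Observed statistic is `stat(group A) - stat(group B)` (A = first factor
#' level); the null is built by reshuffling the group labels without
#' replacement. When the number of distinct label assignments
#' `choose(n, nA)` is at most `exhaustiveLimit`, the full assignment set is
#' enumerated and the p-value is exact; otherwise `nReplicates` random
#' shuffles are drawn.
#'
#' @param values Numeric vector.
#' @param labels Two-level factor (or coercible) aligned with `values`.
#' @param stat `"mean"` or `"median"`.
#' @param nReplicates Random shuffles when not exhaustive (default 10000).
#' @param seed Seed for reproducibility (restored afterwards).
#' @param tail `"two-sided"`, `"greater"` or `"less"`.
#' @param addOne Use the `(b + 1) / (n + 1)` estimator.
#' @param exhaustiveLimit Enumeration threshold (default 10000 assignments).
#' @return A [PermutationTestResult-class].
#' @export
permDiffTest <- function(values, labels, stat = c("mean", "median"),
                         nReplicates = 10000L, seed = NULL,
                         tail = "two-sided", addOne = FALSE,
                         exhaustiveLimit = 10000L) {
  stat <- match.arg(stat)
  if (nReplicates < 1L) stop("nReplicates must be at least 1")
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]
  labels <- factor(labels[ok])
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  f <- if (stat == "mean") mean else median
  idxA <- which(labels == levels(labels)[1L])
  n <- length(values)
  nA <- length(idxA)
  if (nA == 0L || nA == n) stop("both groups must be non-empty")
  delta <- function(ia) f(values[ia]) - f(values[-ia])
  obs <- delta(idxA)
  nAssign <- choose(n, nA)
  if (nAssign <= exhaustiveLimit) {
    combs <- combn(n, nA)
    null <- apply(combs, 2L, delta)
    b <- .tailCount(null, obs, tail)
    p <- .pvalFromCount(b, ncol(combs), addOne = FALSE)  # exact; no add-one
    return(new("PermutationTestResult",
               statisticName = if (stat == "mean") "diff_means" else "diff_medians",
               observed = obs, nReplicates = as.integer(ncol(combs)),
               pValue = p, seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
               tail = tail, exhaustive = TRUE,
               details = list(nullMean = mean(null))))
  }
  null <- .withSeed(seed, vapply(seq_len(nReplicates), function(i) {
    delta(sample.int(n, nA))
  }, numeric(1)))
  b <- .tailCount(null, obs, tail)
  new("PermutationTestResult",
      statisticName = if (stat == "mean") "diff_means" else "diff_medians",
      observed = obs, nReplicates = as.integer(nReplicates),
      pValue = .pvalFromCount(b, nReplicates, addOne),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      tail = tail, exhaustive = FALSE, details = list(nullMean = mean(null)))
}

#' Covariate-matched permutation test
#'
#' Compares the mean response of a target gene set against null sets drawn
#' to match the target's covariate distribution — the control used when a
#' covariate (e.g. measured CG sites per gene) biases a naive permutation.
#' The pool (non-target genes with complete data) is cut into covariate
#' deciles; each replicate draws, for every target gene, one pool gene from
#' the same stratum, without replacement within the replicate. Strata with
#' too few pool genes are widened symmetrically to the nearest non-empty
#' neighbours, with a warning.
#'
#' @param table Feature `data.frame` with a `gene_id` column.
#' @param targetIds Gene ids of the target set (must appear in `table`).
#' @param response Column name of the response feature.
#' @param covariate Column name of the matching covariate.
#' @param nReplicates Null replicates (default 10000).
#' @param seed,tail,addOne As in [permDiffTest()].
#' @param nStrata Number of covariate strata (default 10, i.e. deciles).
#' @return A [PermutationTestResult-class]; `details` carries the stratum
#'   counts and any widening.
#' @export
matchedPermTest <- function(table, targetIds, response, covariate,
                            nReplicates = 10000L, seed = NULL,
                            tail = "two-sided", addOne = FALSE, nStrata = 10L) {
  stopifnot(all(c("gene_id", response, covariate) %in% names(table)))
  isTarget <- table$gene_id %in% targetIds
  if (!any(isTarget)) stop("no target gene found in the table")
  tgt <- table[isTarget & !is.na(table[[response]]) & !is.na(table[[covariate]]), ]
  pool <- table[!isTarget & !is.na(table[[response]]) & !is.na(table[[covariate]]), ]
  if (nrow(tgt) == 0L || nrow(pool) == 0L)
    stop("target or pool empty after removing missing values")
  qs <- quantile(pool[[covariate]], probs = seq(0, 1, length.out = nStrata + 1L),
                 names = FALSE, type = 7)
  breaks <- unique(qs)
  poolStr <- findInterval(pool[[covariate]], breaks, all.inside = TRUE)
  tgtStr <- findInterval(tgt[[covariate]], breaks, all.inside = TRUE)
  nStr <- length(breaks) - 1L
  tgtCounts <- tabulate(tgtStr, nStr)
  poolByStr <- split(seq_len(nrow(pool)), factor(poolStr, levels = seq_len(nStr)))
  # widen strata that cannot supply the required draws
  widened <- FALSE
  strataPools <- vector("list", nStr)
  for (s in seq_len(nStr)) {
    if (tgtCounts[s] == 0L) next
    cand <- poolByStr[[s]]
    r <- 1L
    while (length(cand) < tgtCounts[s] && r <= nStr) {
      lo <- s - r; hi <- s + r
      if (lo >= 1L) cand <- c(cand, poolByStr[[lo]])
      if (hi <= nStr) cand <- c(cand, poolByStr[[hi]])
      widened <- TRUE
      r <- r + 1L
    }
    if (length(cand) < tgtCounts[s])
      stop("pool too small to match the target covariate distribution")
    strataPools[[s]] <- cand
  }
  if (widened)
    warning("one or more covariate strata were widened to nearest neighbours")
  respPool <- pool[[response]]
  obs <- mean(tgt[[response]])
  k <- nrow(tgt)
  active <- which(tgtCounts > 0L)
  null <- .withSeed(seed, vapply(seq_len(nReplicates), function(i) {
    tot <- 0
    for (s in active) {
      cand <- strataPools[[s]]
      pick <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), tgtCounts[s])]
      tot <- tot + sum(respPool[pick])
    }
    tot / k
  }, numeric(1)))
  new("PermutationTestResult", statisticName = "matched_mean", observed = obs,
      nReplicates = as.integer(nReplicates),
      pValue = .dirPval(null, obs, tail, nReplicates, addOne),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      tail = tail, exhaustive = FALSE,
      details = list(targetStratumCounts = tgtCounts, widened = widened,
                     nullMean = mean(null), nTargets = k))
}

#' Empirical-tail enrichment test for a gene subset
#'
#' Tests whether more subset genes than expected fall in the top (or bottom)
#' tail of a genome-wide empirical distribution. The cutoff is the empirical
#' percentile of all non-missing values; tail membership is inclusive of the
#' cutoff value. The null draws random gene sets of the subset's size
#' without replacement from the universe of genes with a value.
#'
#' @param values Named per-gene statistic (names are gene ids).
#' @param subsetIds Gene ids of the subset (must be drawn from the universe).
#' @param percentile Tail size (default 0.05).
#' @param direction `"top"` or `"bottom"`.
#' @param nReplicates,seed,addOne As in [permDiffTest()].
#' @param tail `"greater"` (enrichment, default) or `"less"` (depletion).
#' @return A [TailTestResult-class].
#' @export
tailCountTest <- function(values, subsetIds, percentile = 0.05,
                          direction = c("top", "bottom"),
                          nReplicates = 10000L, seed = NULL,
                          tail = "greater", addOne = FALSE) {
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  if (is.null(names(values))) stop("values must be named by gene id")
  if (length(subsetIds) == 0L) stop("subset must be non-empty")
  missing <- setdiff(subsetIds, names(values))
  subsetIds <- intersect(subsetIds, names(values))
  if (length(subsetIds) == 0L) stop("no subset gene has a value")
  cutoff <- quantile(values,
                     probs = if (direction == "top") 1 - percentile else percentile,
                     names = FALSE, type = 7)
  inTail <- if (direction == "top") values >= cutoff else values <= cutoff
  observed <- sum(inTail[subsetIds])
  k <- length(subsetIds)
  N <- length(values)
  null <- .withSeed(seed, vapply(seq_len(nReplicates), function(i) {
    sum(inTail[sample.int(N, k)])
  }, numeric(1)))
  new("TailTestResult", percentile = percentile, direction = direction,
      cutoff = cutoff, observedInTail = as.integer(observed),
      expectedInTail = percentile * k,
      pValue = .dirPval(null, observed, tail, nReplicates, addOne),
      nReplicates = as.integer(nReplicates),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed), tail = tail)
}

#' Balancing-selection candidates from joint pi / D tails
#'
#' Genes at or above the `percentile` cutoff (default 95th) of both the
#' genome-wide pi distribution and the genome-wide Tajima's D distribution —
#' the empirical operationalisation of balancing selection used for
#' gene-level calls.
#'
#' @param pi,d Named per-gene statistics on the same gene universe.
#' @param percentile Joint cutoff (default 0.95).
#' @return Character vector of candidate gene ids (possibly empty).
#' @export
balancingSelectionCandidates <- function(pi, d, percentile = 0.95) {
  common <- intersect(names(pi), names(d))
  pi <- pi[common]; d <- d[common]
  ok <- !is.na(pi) & !is.na(d)
  pi <- pi[ok]; d <- d[ok]
  cp <- quantile(pi, percentile, names = FALSE, type = 7)
  cd <- quantile(d, percentile, names = FALSE, type = 7)
  names(pi)[pi >= cp & d >= cd]
}

#' Rank-based gene-set score for one sample
#'
#' Scores a gene set within one sample's expression ranking:
#' `score = (mean midrank of the set - min attainable mean rank) /
#' (max attainable - min attainable)`, which lies in `[0, 1]` (1 when the
#' set occupies the top of the ranking). Significance comes from random
#' same-size gene sets. This is a deliberately simple rank-mean score, not a
#' reimplementation of published bidirectional single-sample scoring
#' methods; the result is tagged accordingly in `details$method`.
#'
#' @param expression Named per-gene expression values for one sample.
#' @param geneSet Gene ids to score (subset of the named genes).
#' @param nReplicates,seed,addOne As in [permDiffTest()].
#' @param tail `"greater"` (enrichment at the top, default), `"less"`, or
#'   `"two-sided"`.
#' @return A [PermutationTestResult-class] with the score as `observed`.
#' @export
rankSetScore <- function(expression, geneSet, nReplicates = 1000L,
                         seed = NULL, tail = "greater", addOne = FALSE) {
  expression <- expression[!is.na(expression)]
  if (is.null(names(expression))) stop("expression must be named by gene id")
  geneSet <- intersect(geneSet, names(expression))
  if (length(geneSet) == 0L) stop("empty gene set")
  r <- rank(expression, ties.method = "average")
  N <- length(r)
  k <- length(geneSet)
  lo <- mean(seq_len(k))
  hi <- mean(seq.int(N - k + 1L, N))
  toScore <- function(meanRank) (meanRank - lo) / (hi - lo)
  obs <- toScore(mean(r[geneSet]))
  null <- .withSeed(seed, vapply(seq_len(nReplicates), function(i) {
    toScore(mean(r[sample.int(N, k)]))
  }, numeric(1)))
  new("PermutationTestResult", statisticName = "set_score", observed = obs,
      nReplicates = as.integer(nReplicates),
      pValue = .dirPval(null, obs, tail, nReplicates, addOne),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      tail = tail, exhaustive = FALSE,
      details = list(method = "rank-mean set score (simplified)",
                     nullMean = mean(null)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-preserving.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values, `adjusted >= raw` elementwise.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
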
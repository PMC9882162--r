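# Alignment-based population genetics: segregating sites, nucleotide
# diversity, Watterson's theta and Tajima's D under complete deletion.

# Column-wise A/C/G/T counts for the columns retained under complete
# deletion (every sequence has an unambiguous base; any gap or IUPAC
# ambiguity removes the whole column from analysis, keeping all pairs on an
# identical site set and the D constants internally consistent).
.completeColumnCounts <- function(aln) {
  stopifnot(is(aln, "NucAlignment"))
  n <- nSeq(aln)
  if (n < 2L) stop("at least 2 sequences are required")
  cm <- Biostrings::consensusMatrix(alnSeqs(aln))
  acgt <- cm[intersect(c("A", "C", "G", "T"), rownames(cm)), , drop = FALSE]
  keep <- colSums(acgt) == n
  list(counts = acgt[, keep, drop = FALSE], nKept = sum(keep), n = n)
}

.pairwiseDiffTotal <- function(counts, n) {
  # Mean pairwise difference count: per column the number of differing
  # pairs is (n^2 - sum(n_a^2)) / 2; divide the grand total by C(n, 2).
  if (ncol(counts) == 0L) return(0)
  perCol <- (n^2 - colSums(counts^2)) / 2
  sum(perCol) / choose(n, 2)
}

#' Tajima (1989) constants
#'
#' The sample-size constants entering Watterson's estimator and the variance
#' term of Tajima's D: `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for
#' `i = 1..n-1`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`.
#'
#' @param n Sample size (number of sequences), `n >= 2`.
#' @return Named numeric vector `a1,a2,b1,b2,c1,c2,e1,e2`.
#' @export
tajimaConstants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Segregating sites of an alignment
#'
#' Counts retained columns (complete deletion: no gaps or ambiguity codes in
#' any sequence) carrying two or more distinct bases.
#'
#' @param aln A [NucAlignment] or [CodonAlignment] with `>= 2` sequences.
#' @return Integer count.
#' @export
segregatingSites <- function(aln) {
  cc <- .completeColumnCounts(aln)
  if (cc$nKept == 0L)
    stop("no analyzable columns: every column contains a gap or ambiguity")
  as.integer(sum(colSums(cc$counts > 0) >= 2L))
}

#' Per-site nucleotide diversity (pi)
#'
#' Mean, over all unordered sequence pairs, of the per-pair difference count
#' at retained columns, divided by the number of retained columns.
#'
#' @inheritParams segregatingSites
#' @return Per-site pi.
#' @export
nucleotideDiversity <- function(aln) {
  cc <- .completeColumnCounts(aln)
  if (cc$nKept == 0L)
    stop("no analyzable columns: every column contains a gap or ambiguity")
  .pairwiseDiffTotal(cc$counts, cc$n) / cc$nKept
}

.popGenFromCounts <- function(counts, nKept, n) {
  S <- as.integer(sum(colSums(counts > 0) >= 2L))
  Pi <- .pairwiseDiffTotal(counts, n)
  konst <- tajimaConstants(n)
  thetaW <- S / (konst[["a1"]] * nKept)
  if (n < 3L) {
    D <- NA_real_; reason <- "n_lt_3"
  } else if (S == 0L) {
    D <- NA_real_; reason <- "no_segregating_sites"
  } else {
    denom <- sqrt(konst[["e1"]] * S + konst[["e2"]] * S * (S - 1))
    if (!is.finite(denom) || denom <= 0) {
      # at n = 3 the variance constants vanish identically
      D <- NA_real_; reason <- "zero_variance"
    } else {
      D <- (Pi - S / konst[["a1"]]) / denom
      reason <- "ok"
    }
  }
  new("PopGenResult", nSequences = as.integer(n),
      nSitesAnalyzed = as.integer(nKept), S = S, PiTotal = Pi,
      pi = Pi / nKept, thetaW = thetaW, tajimaD = D, dReason = reason,
      constants = konst)
}

#' Summary population-genetics statistics of an alignment
#'
#' Computes `S`, the mean pairwise difference count `Pi` (total scale), the
#' per-site diversity `pi = Pi / sites`, Watterson's `thetaW` and Tajima's
#' `D = (Pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` under complete deletion.
#' `D` is `NA` with a reason code when `S == 0` or fewer than three
#' sequences are present. With `codon = TRUE` on a [CodonAlignment], the
#' Nei-Gojobori `piN`, `piS` and their ratio are filled in as well.
#'
#' @inheritParams segregatingSites
#' @param codon Also compute [piNpiS()] (requires a `CodonAlignment`).
#' @return A [PopGenResult-class].
#' @examples
#' aln <- NucAlignment(c(a = "AAAA", b = "AAAT", c = "AATA", d = "AATT"))
#' popGenStats(aln)
#' @export
popGenStats <- function(aln, codon = FALSE) {
  cc <- .completeColumnCounts(aln)
  if (cc$nKept == 0L)
    stop("no analyzable columns: every column contains a gap or ambiguity")
  res <- .popGenFromCounts(cc$counts, cc$nKept, cc$n)
  if (codon) {
    ns <- piNpiS(aln)
    res@piN <- ns$piN
    res@piS <- ns$piS
    res@piNpiS <- ns$ratio
  }
  res
}

#' Tajima's D of an alignment
#'
#' @inheritParams segregatingSites
#' @return Tajima's D (may be `NA`; see [popGenStats()]).
#' @export
tajimasD <- function(aln) popGenStats(aln)@tajimaD

#' Population statistics from a haplotype genotype matrix
#'
#' Computes per-site diversity, segregating sites and Tajima's D from a
#' haplotype-by-site allele matrix (for example the expansion of a VCF's GT
#' fields), with pairwise-complete handling of missing calls: each site uses
#' its own called sample size `m`, with
#' `pi_site = sum_{a<b} 2 n_a n_b / (m (m - 1))`. Sites with fewer than two
#' called haplotypes support no pair and are dropped (the all-missing case
#' included). `S` and `D` use the median called sample size across retained
#' sites; per-site normalisation is over retained sites.
#'
#' @param genotypes Matrix (haplotypes in rows, sites in columns) of allele
#'   codes; `NA` marks a missing call. Any atomic code type works.
#' @return A [PopGenResult-class].
#' @examples
#' g <- rbind(c(0, 0), c(0, 1), c(0, 1), c(1, NA))
#' statsFromGenotypes(g)
#' @export
statsFromGenotypes <- function(genotypes) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) >= 2L)
  m <- colSums(!is.na(genotypes))
  keep <- which(m >= 2L)
  if (length(keep) == 0L) stop("no site has two or more called haplotypes")
  piSite <- numeric(length(keep))
  nAll <- integer(length(keep))
  for (j in seq_along(keep)) {
    x <- genotypes[, keep[j]]
    x <- x[!is.na(x)]
    tab <- table(x)
    mm <- length(x)
    piSite[j] <- (mm^2 - sum(tab^2)) / (mm * (mm - 1))
    nAll[j] <- length(tab)
  }
  S <- as.integer(sum(nAll >= 2L))
  nMed <- as.integer(round(median(m[keep])))
  nMed <- max(nMed, 2L)
  Pi <- sum(piSite)
  nSites <- length(keep)
  konst <- tajimaConstants(nMed)
  thetaW <- S / (konst[["a1"]] * nSites)
  if (nMed < 3L) {
    D <- NA_real_; reason <- "n_lt_3"
  } else if (S == 0L) {
    D <- NA_real_; reason <- "no_segregating_sites"
  } else {
    denom <- sqrt(konst[["e1"]] * S + konst[["e2"]] * S * (S - 1))
    if (!is.finite(denom) || denom <= 0) {
      D <- NA_real_; reason <- "zero_variance"
    } else {
      D <- (Pi - S / konst[["a1"]]) / denom
      reason <- "ok"
    }
  }
  new("PopGenResult", nSequences = nMed, nSitesAnalyzed = as.integer(nSites),
      S = S, PiTotal = Pi, pi = Pi / nSites, thetaW = thetaW, tajimaD = D,
      dReason = reason, constants = konst)
}
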
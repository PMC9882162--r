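# Nei-Gojobori (1986) synonymous / nonsynonymous site and difference
# counting, with the standard refinement that mutational pathways passing
# through stop codons are excluded.

.BASES <- c("A", "C", "G", "T")

.ngCache <- new.env(parent = emptyenv())

.codonAA <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

.isStop <- function(codon) .codonAA(codon) == "*"

.senseCodons <- function() {
  all <- names(Biostrings::GENETIC_CODE)
  all[Biostrings::GENETIC_CODE != "*"]
}

.ngSitesOne <- function(codon) {
  aa <- .codonAA(codon)
  syn <- 0
  for (pos in 1:3) {
    s <- 0L; denom <- 0L
    for (b in setdiff(.BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (.isStop(mut)) next  # changes to stops excluded from the denominator
      denom <- denom + 1L
      if (.codonAA(mut) == aa) s <- s + 1L
    }
    syn <- syn + s / denom
  }
  c(syn_sites = syn, nonsyn_sites = 3 - syn)
}

# Pathway-averaged syn/nonsyn difference counts between two sense codons.
.ngDiffsOne <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  h <- length(pos)
  if (h == 0L)
    return(list(syn = 0, nonsyn = 0, flagged = FALSE))
  orderings <- if (h == 1L) list(pos) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
      out
    }
    perms(pos)
  }
  score <- function(path, allowStops) {
    cur <- c1
    syn <- 0L; nonsyn <- 0L
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allowStops && .isStop(nxt)) return(NULL)
      if (.codonAA(nxt) == .codonAA(cur)) syn <- syn + 1L else nonsyn <- nonsyn + 1L
      cur <- nxt
    }
    c(syn, nonsyn)
  }
  legal <- Filter(Negate(is.null), lapply(orderings, score, allowStops = FALSE))
  flagged <- FALSE
  if (length(legal) == 0L) {
    # Every minimal pathway passes through a stop codon: fall back to the
    # unrestricted pathway set and flag the pair.
    legal <- lapply(orderings, score, allowStops = TRUE)
    flagged <- TRUE
  }
  m <- do.call(rbind, legal)
  list(syn = mean(m[, 1]), nonsyn = mean(m[, 2]), flagged = flagged)
}

# Lazily built lookup tables over the 61 sense codons: per-codon fractional
# site counts and 61 x 61 pathway-averaged difference counts.
.ngTables <- function() {
  if (!is.null(.ngCache$tables)) return(.ngCache$tables)
  sense <- .senseCodons()
  k <- length(sense)
  sites <- t(vapply(sense, .ngSitesOne, numeric(2)))
  synD <- matrix(0, k, k, dimnames = list(sense, sense))
  nonsynD <- matrix(0, k, k, dimnames = list(sense, sense))
  flag <- matrix(FALSE, k, k, dimnames = list(sense, sense))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    d <- .ngDiffsOne(sense[i], sense[j])
    synD[i, j] <- d$syn
    nonsynD[i, j] <- d$nonsyn
    flag[i, j] <- d$flagged
  }
  .ngCache$tables <- list(sense = sense, sites = sites, synD = synD,
                          nonsynD = nonsynD, flag = flag)
  .ngCache$tables
}

.checkCodon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      grepl("[^ACGT]", codon))
    stop(sprintf("'%s' is not a fully resolved codon", codon))
  if (.isStop(codon))
    stop(sprintf("'%s' is a stop codon; stop codons carry no NG sites", codon))
  invisible(codon)
}

#' Nei-Gojobori fractional site counts of a codon
#'
#' For each of the three positions, the synonymous fraction is the share of
#' single-base changes preserving the amino acid among the non-stop
#' single-base changes (changes creating a stop codon are dropped from the
#' denominator). `syn_sites` sums the three fractions and
#' `nonsyn_sites = 3 - syn_sites`.
#'
#' @param codon A sense codon as a 3-character `ACGT` string.
#' @return Named numeric vector `syn_sites, nonsyn_sites`.
#' @examples
#' neiGojoboriSites("GGG")  # third position fully degenerate: 1 syn site
#' neiGojoboriSites("ATG")  # Met: 0 syn sites
#' @export
neiGojoboriSites <- function(codon) {
  codon <- toupper(codon)
  .checkCodon(codon)
  .ngTables()$sites[codon, ]
}

#' Pathway-averaged synonymous / nonsynonymous differences of a codon pair
#'
#' Classifies the nucleotide differences between two sense codons by
#' averaging over all minimal mutational pathways (orderings of the
#' differing positions), excluding pathways that pass through a stop codon.
#' If every pathway is illegal, the unrestricted pathway set is used and the
#' result carries attribute `flagged = TRUE`.
#'
#' @param c1,c2 Sense codons as 3-character `ACGT` strings.
#' @return Named numeric vector `syn_diffs, nonsyn_diffs` (summing to the
#'   Hamming distance of the codons), with attribute `flagged`.
#' @examples
#' codonPairDiffs("TTT", "TTC")  # one synonymous difference (Phe -> Phe)
#' @export
codonPairDiffs <- function(c1, c2) {
  c1 <- toupper(c1); c2 <- toupper(c2)
  .checkCodon(c1); .checkCodon(c2)
  tb <- .ngTables()
  out <- c(syn_diffs = tb$synD[c1, c2], nonsyn_diffs = tb$nonsynD[c1, c2])
  attr(out, "flagged") <- unname(tb$flag[c1, c2])
  out
}

# Integer codon index (into the sense-codon table) per aligned codon column
# per sequence; NA where the codon has a gap/ambiguity or is a stop.
.codonIndexMatrix <- function(aln) {
  tb <- .ngTables()
  L <- alnWidth(aln)
  stopifnot(L %% 3L == 0L)
  seqs <- as.character(alnSeqs(aln))
  nC <- L %/% 3L
  starts <- 3L * (seq_len(nC) - 1L) + 1L
  idx <- matrix(NA_integer_, nrow = length(seqs), ncol = nC,
                dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    codons <- substring(seqs[i], starts, starts + 2L)
    idx[i, ] <- match(codons, tb$sense)
  }
  idx
}

#' Nei-Gojobori piN and piS of a codon alignment
#'
#' For every unordered sequence pair, codons where either sequence has a
#' gap, an ambiguity code or a stop codon are excluded for that pair; over
#' the remaining codons the pathway-averaged synonymous and nonsynonymous
#' difference counts are summed and the two sequences' fractional site
#' counts averaged. Per pair, `piS_pair = syn_diffs / syn_sites` and
#' `piN_pair` analogously; `piS` and `piN` are the means over pairs. The
#' ratio is `NA` when `piS == 0`. Raw proportions are reported (no
#' Jukes-Cantor correction) unless `jukesCantor = TRUE`, matching the
#' low-divergence intraspecies regime the estimator is used in here.
#'
#' @param aln A [CodonAlignment] with `>= 2` sequences.
#' @param jukesCantor Apply the Jukes-Cantor correction
#'   `-3/4 log(1 - 4 p / 3)` to the per-pair proportions.
#' @return List with `piN`, `piS`, `ratio`, `nPairs`, and `flaggedPairs`
#'   (pairs where a stop-free pathway was unavailable for some codon).
#' @examples
#' piNpiS(CodonAlignment(c(a = "TTTGGG", b = "TTCGGG")))
#' @export
piNpiS <- function(aln, jukesCantor = FALSE) {
  stopifnot(is(aln, "CodonAlignment"))
  n <- nSeq(aln)
  if (n < 2L) stop("at least 2 sequences are required")
  tb <- .ngTables()
  idx <- .codonIndexMatrix(aln)
  synSitesTab <- tb$sites[, "syn_sites"]
  nonsynSitesTab <- tb$sites[, "nonsyn_sites"]
  piNs <- piSs <- numeric(0)
  flagged <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
    if (!any(ok)) next
    a <- idx[i, ok]; b <- idx[j, ok]
    synD <- sum(tb$synD[cbind(a, b)])
    nonsynD <- sum(tb$nonsynD[cbind(a, b)])
    if (any(tb$flag[cbind(a, b)])) flagged <- flagged + 1L
    synS <- (sum(synSitesTab[a]) + sum(synSitesTab[b])) / 2
    nonsynS <- (sum(nonsynSitesTab[a]) + sum(nonsynSitesTab[b])) / 2
    pS <- if (synS > 0) synD / synS else NA_real_
    pN <- if (nonsynS > 0) nonsynD / nonsynS else NA_real_
    if (jukesCantor) {
      jc <- function(p) if (!is.na(p) && p < 0.75) -0.75 * log(1 - 4 * p / 3) else p
      pS <- jc(pS); pN <- jc(pN)
    }
    piSs <- c(piSs, pS); piNs <- c(piNs, pN)
  }
  if (length(piSs) == 0L)
    stop("no analyzable codons shared by any sequence pair")
  piS <- mean(piSs, na.rm = TRUE)
  piN <- mean(piNs, na.rm = TRUE)
  list(piN = piN, piS = piS,
       ratio = if (!is.na(piS) && piS > 0) piN / piS else NA_real_,
       nPairs = length(piSs), flaggedPairs = flagged)
}
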
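# Per-column Shannon entropy of population protein alignments and the
# hv / non-hv classification built on it.

# Characters excluded from residue frequency tallies: alignment gaps and the
# unknown-residue code. An 'X' carries no diversity information, and counting
# gaps would conflate indel polymorphism with substitution diversity.
.AA_EXCLUDE <- c("-", ".", "+", "X", "*")

#' Shannon entropy of one alignment column
#'
#' Computes `H = -sum(p * log2(p))` over the residue frequencies of a single
#' column, gaps and ambiguity codes having been excluded by the caller. For a
#' protein column `0 <= H <= log2(20)` bits; invariant columns score 0.
#'
#' @param counts Named vector of residue counts (residue -> count), or an
#'   unnamed vector of counts. Zero counts are ignored.
#' @return Entropy in bits.
#' @examples
#' columnEntropy(c(A = 4))               # 0
#' columnEntropy(c(A = 2, G = 2))        # 1 bit
#' columnEntropy(c(A = 2, C = 1, G = 1)) # 1.5 bits
#' @export
columnEntropy <- function(counts) {
  counts <- counts[!is.na(counts) & counts > 0]
  if (length(counts) == 0L)
    stop("empty count map: all-gap column; filter such columns before scoring")
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Per-column entropy profile of a population protein alignment
#'
#' Scores every column of a population protein alignment with Shannon entropy
#' over residue frequencies. Gaps (`-`, `.`) and unknown residues (`X`) are
#' excluded from the tallies; the non-gap share of each column is recorded as
#' its occupancy. Columns with occupancy below `minOccupancy` are retained in
#' the profile (entropy and occupancy are reported for every column) but are
#' excluded later when [classifyHv()] counts high-entropy positions, so that
#' sparse insertion columns cannot inflate a gene's hv count.
#'
#' @param aln A [ProteinAlignment] with at least two sequences.
#' @param minOccupancy Minimum non-gap fraction for a column to count toward
#'   classification (default 0.5).
#' @param geneId Gene identifier recorded in the profile.
#' @return An [EntropyProfile-class].
#' @seealso [classifyHv()]
#' @export
entropyProfile <- function(aln, minOccupancy = 0.5, geneId = "gene") {
  stopifnot(is(aln, "ProteinAlignment"))
  if (nSeq(aln) < 2L)
    stop("entropy of a single-sequence alignment is not a diversity measure")
  if (minOccupancy < 0 || minOccupancy > 1)
    stop("minOccupancy must be in [0, 1]")
  cm <- Biostrings::consensusMatrix(alnSeqs(aln))
  keep <- setdiff(rownames(cm), .AA_EXCLUDE)
  res <- cm[keep, , drop = FALSE]
  tot <- colSums(res)
  n <- nSeq(aln)
  bits <- rep(NA_real_, ncol(res))
  nz <- tot > 0
  bits[nz] <- vapply(which(nz), function(j) columnEntropy(res[, j]), numeric(1))
  new("EntropyProfile", geneId = geneId, bits = bits, occupancy = tot / n,
      nSequences = as.integer(n), minOccupancy = minOccupancy)
}

#' Classify a gene as hv or non-hv from its entropy profile
#'
#' A gene is called highly variable (hv) when at least `minPositions` columns
#' have Shannon entropy strictly greater than `thresholdBits`, counting only
#' columns whose occupancy meets the profile's `minOccupancy` filter. The
#' defaults (10 positions, 1.5 bits) reflect the bimodal split of mean
#' per-gene entropy observed across the Arabidopsis NLRome.
#'
#' @param profile An [EntropyProfile-class].
#' @param thresholdBits Entropy threshold in bits; comparison is strict
#'   (default 1.5).
#' @param minPositions Minimum number of qualifying columns (default 10).
#' @return An [HvCall-class].
#' @examples
#' aln <- ProteinAlignment(c(a = "AAAA", b = "AAAC", c = "AAAG", d = "AAAT"))
#' classifyHv(entropyProfile(aln), minPositions = 1)
#' @export
classifyHv <- function(profile, thresholdBits = 1.5, minPositions = 10L) {
  stopifnot(is(profile, "EntropyProfile"))
  minPositions <- as.integer(minPositions)
  qual <- !is.na(profile@bits) & profile@occupancy >= profile@minOccupancy
  nHigh <- sum(profile@bits[qual] > thresholdBits)
  new("HvCall", geneId = profile@geneId, nHighEntropy = as.integer(nHigh),
      label = if (nHigh >= minPositions) "hv" else "non-hv",
      thresholdBits = thresholdBits, minPositions = minPositions,
      minOccupancy = profile@minOccupancy)
}

#' Tabulate entropy profiles and hv calls for a set of genes
#'
#' Convenience wrapper running [entropyProfile()] and [classifyHv()] over a
#' named list of protein alignments.
#'
#' @param alignments Named list of [ProteinAlignment] objects (names are gene
#'   ids).
#' @param thresholdBits,minPositions,minOccupancy Passed through.
#' @return A list with `profiles` (data.frame `gene_id, column_index`
#'   (0-based), `entropy_bits, occupancy`) and `calls` (data.frame `gene_id,
#'   n_high_entropy, label`).
#' @export
entropyTable <- function(alignments, thresholdBits = 1.5, minPositions = 10L,
                         minOccupancy = 0.5) {
  stopifnot(length(alignments) > 0L, !is.null(names(alignments)))
  profs <- calls <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    gid <- names(alignments)[i]
    pr <- entropyProfile(alignments[[i]], minOccupancy = minOccupancy,
                         geneId = gid)
    cl <- classifyHv(pr, thresholdBits = thresholdBits,
                     minPositions = minPositions)
    profs[[i]] <- data.frame(gene_id = gid,
                             column_index = seq_along(pr@bits) - 1L,
                             entropy_bits = pr@bits,
                             occupancy = pr@occupancy,
                             stringsAsFactors = FALSE)
    calls[[i]] <- data.frame(gene_id = gid, n_high_entropy = cl@nHighEntropy,
                             label = cl@label, stringsAsFactors = FALSE)
  }
  list(profiles = do.call(rbind, profs), calls = do.call(rbind, calls))
}
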
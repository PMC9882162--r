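#' @import methods
#' @importFrom stats median quantile rbeta rexp rnorm rpois runif sd setNames
#'   p.adjust wilcox.test fisher.test var
#' @importFrom utils combn head read.table write.table
NULL

#' Population alignment classes
#'
#' `PopAlignment` is the virtual parent of the equal-width sequence
#' collections the package operates on. `ProteinAlignment` holds a population
#' protein alignment (the substrate for per-column Shannon entropy),
#' `NucAlignment` an aligned nucleotide population, and `CodonAlignment` an
#' in-frame nucleotide alignment (width divisible by 3), the substrate for
#' codon-level population genetics.
#'
#' Sequences are stored as a [Biostrings::XStringSet] with unique names;
#' residues are uppercase, with `-` as the gap character and the usual
#' ambiguity letters permitted (`X` for protein, IUPAC codes for nucleotide).
#'
#' @slot seqs An `AAStringSet` (protein) or `DNAStringSet` (nucleotide) of
#'   identical widths with unique names.
#' @aliases PopAlignment-class ProteinAlignment-class NucAlignment-class
#'   CodonAlignment-class
#' @name PopAlignment
#' @rdname PopAlignment
#' @exportClass PopAlignment
setClass("PopAlignment", representation("VIRTUAL", seqs = "ANY"))

.validPopAlignment <- function(object) {
  s <- object@seqs
  if (length(s) < 1L) return("alignment must contain at least one sequence")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L) {
    bad <- names(s)[w != w[1L]][1L]
    return(sprintf("ragged alignment: sequence '%s' has width %d, expected %d",
                   bad, w[w != w[1L]][1L], w[1L]))
  }
  if (is.null(names(s)) || anyDuplicated(names(s)) || any(!nzchar(names(s))))
    return("sequence names must be present and unique")
  TRUE
}

setValidity("PopAlignment", .validPopAlignment)

#' @exportClass ProteinAlignment
setClass("ProteinAlignment", contains = "PopAlignment")
setValidity("ProteinAlignment", function(object) {
  if (!is(object@seqs, "AAStringSet")) return("seqs must be an AAStringSet")
  TRUE
})

#' @exportClass NucAlignment
setClass("NucAlignment", contains = "PopAlignment")
setValidity("NucAlignment", function(object) {
  if (!is(object@seqs, "DNAStringSet")) return("seqs must be a DNAStringSet")
  TRUE
})

#' @exportClass CodonAlignment
setClass("CodonAlignment", contains = "NucAlignment")
setValidity("CodonAlignment", function(object) {
  if (length(object@seqs) && Biostrings::width(object@seqs)[1L] %% 3L != 0L)
    return("codon alignment width must be divisible by 3")
  TRUE
})

.asNamedSet <- function(seqs, ctor) {
  if (is.character(seqs)) {
    if (is.null(names(seqs)))
      names(seqs) <- sprintf("seq%d", seq_along(seqs))
    seqs <- ctor(toupper(seqs))
  }
  seqs
}

#' @param seqs Named character vector or `AAStringSet`/`DNAStringSet` of
#'   aligned (equal-length) sequences.
#' @return An object of the corresponding alignment class.
#' @examples
#' aln <- ProteinAlignment(c(a = "MKV-", b = "MKI-"))
#' nSeq(aln)
#' @rdname PopAlignment
#' @export
ProteinAlignment <- function(seqs) {
  new("ProteinAlignment", seqs = .asNamedSet(seqs, Biostrings::AAStringSet))
}

#' @rdname PopAlignment
#' @export
NucAlignment <- function(seqs) {
  new("NucAlignment", seqs = .asNamedSet(seqs, Biostrings::DNAStringSet))
}

#' @rdname PopAlignment
#' @export
CodonAlignment <- function(seqs) {
  new("CodonAlignment", seqs = .asNamedSet(seqs, Biostrings::DNAStringSet))
}

#' Alignment accessors
#'
#' @param x A `PopAlignment`.
#' @return `nSeq` the number of sequences, `alnWidth` the common alignment
#'   width, `seqIds` the sequence names, `alnMatrix` a character matrix
#'   (sequences in rows, columns in columns), `alnSeqs` the underlying
#'   `XStringSet`.
#' @name alignment-accessors
#' @export
nSeq <- function(x) length(x@seqs)

#' @rdname alignment-accessors
#' @export
alnWidth <- function(x) if (length(x@seqs)) Biostrings::width(x@seqs)[1L] else 0L

#' @rdname alignment-accessors
#' @export
seqIds <- function(x) names(x@seqs)

#' @rdname alignment-accessors
#' @export
alnMatrix <- function(x) {
  m <- as.matrix(x@seqs)
  rownames(m) <- names(x@seqs)
  m
}

#' @rdname alignment-accessors
#' @export
alnSeqs <- function(x) x@seqs

setMethod("show", "PopAlignment", function(object) {
  cat(sprintf("%s: %d sequences x %d columns\n", class(object),
              nSeq(object), alnWidth(object)))
  ids <- seqIds(object)
  shown <- head(ids, 4L)
  cat("  ids:", paste(shown, collapse = ", "),
      if (length(ids) > 4L) sprintf("... (+%d)", length(ids) - 4L) else "", "\n")
})

#' EntropyProfile: per-column Shannon entropy of a population alignment
#'
#' Holds the per-column entropy (bits) and per-column occupancy (non-gap
#' share) of one gene's population protein alignment. Columns where every
#' sequence is a gap (or `X`) have entropy `NA`.
#'
#' @slot geneId Gene identifier.
#' @slot bits Numeric vector of per-column entropies in bits (`NA` for
#'   all-gap columns).
#' @slot occupancy Fraction of sequences with an unambiguous residue at each
#'   column.
#' @slot nSequences Number of sequences scored.
#' @slot minOccupancy Occupancy threshold below which a column is excluded
#'   from hv counting.
#' @exportClass EntropyProfile
setClass("EntropyProfile",
  representation(geneId = "character", bits = "numeric", occupancy = "numeric",
                 nSequences = "integer", minOccupancy = "numeric"))

setValidity("EntropyProfile", function(object) {
  if (length(object@bits) != length(object@occupancy))
    return("bits and occupancy must have equal length")
  b <- object@bits[!is.na(object@bits)]
  if (length(b) && (any(b < -1e-9) || any(b > log2(20) + 1e-9)))
    return("entropies must lie in [0, log2(20)] bits")
  if (any(object@occupancy < -1e-9 | object@occupancy > 1 + 1e-9))
    return("occupancy must lie in [0, 1]")
  TRUE
})

setMethod("show", "EntropyProfile", function(object) {
  cat(sprintf("EntropyProfile '%s': %d columns, %d sequences\n",
              object@geneId, length(object@bits), object@nSequences))
  cat(sprintf("  mean entropy %.3f bits; %d columns > 1.5 bits (occupancy >= %.2f)\n",
              mean(object@bits, na.rm = TRUE),
              sum(object@bits > 1.5 & object@occupancy >= object@minOccupancy,
                  na.rm = TRUE),
              object@minOccupancy))
})

#' @rdname EntropyProfile-class
#' @param x An `EntropyProfile`.
#' @export
entropyBits <- function(x) x@bits

#' @rdname EntropyProfile-class
#' @export
columnOccupancy <- function(x) x@occupancy

#' HvCall: hv / non-hv classification of one gene
#'
#' The binary classification of a gene as a highly variable (hv) or non-hv
#' NLR: `label == "hv"` exactly when the number of qualifying alignment
#' columns with entropy strictly greater than `thresholdBits` is at least
#' `minPositions`.
#'
#' @slot geneId Gene identifier.
#' @slot nHighEntropy Number of qualifying high-entropy columns.
#' @slot label `"hv"` or `"non-hv"`.
#' @slot thresholdBits Entropy threshold in bits (default 1.5).
#' @slot minPositions Minimum number of high-entropy positions (default 10).
#' @slot minOccupancy Occupancy filter inherited from the profile.
#' @exportClass HvCall
setClass("HvCall",
  representation(geneId = "character", nHighEntropy = "integer",
                 label = "character", thresholdBits = "numeric",
                 minPositions = "integer", minOccupancy = "numeric"))

setValidity("HvCall", function(object) {
  if (!object@label %in% c("hv", "non-hv")) return("label must be hv or non-hv")
  want <- if (object@nHighEntropy >= object@minPositions) "hv" else "non-hv"
  if (object@label != want)
    return("label inconsistent with nHighEntropy and minPositions")
  TRUE
})

setMethod("show", "HvCall", function(object) {
  cat(sprintf("HvCall '%s': %s (%d positions > %.2f bits; rule >= %d)\n",
              object@geneId, object@label, object@nHighEntropy,
              object@thresholdBits, object@minPositions))
})

#' @rdname HvCall-class
#' @param x An `HvCall`.
#' @export
hvLabel <- function(x) x@label

#' PopGenResult: summary population-genetics statistics
#'
#' Container for the alignment- or genotype-based summary statistics of one
#' region: segregating sites `S`, mean pairwise difference count `PiTotal`
#' (unnormalised), per-site nucleotide diversity `pi`, Watterson's
#' `thetaW = S / (a1 * sites)`, and Tajima's D with its 1989 constants
#' retained for audit. `tajimaD` is `NA` (with `dReason`) when `S == 0` or
#' fewer than 3 sequences are available.
#'
#' @slot nSequences Sample size used.
#' @slot nSitesAnalyzed Number of columns retained after complete deletion
#'   (or called sites for genotype input).
#' @slot S Segregating-site count.
#' @slot PiTotal Mean pairwise difference count across the region.
#' @slot pi Per-site nucleotide diversity.
#' @slot thetaW Per-site Watterson estimator.
#' @slot tajimaD Tajima's D, or `NA`.
#' @slot dReason Reason code when `tajimaD` is `NA` (`"ok"` otherwise).
#' @slot constants Named numeric vector `a1,a2,b1,b2,c1,c2,e1,e2`.
#' @slot piN,piS,piNpiS Nei-Gojobori per-site diversities and their ratio
#'   (`NA` unless computed from a codon alignment).
#' @exportClass PopGenResult
setClass("PopGenResult",
  representation(nSequences = "integer", nSitesAnalyzed = "integer",
                 S = "integer", PiTotal = "numeric", pi = "numeric",
                 thetaW = "numeric", tajimaD = "numeric", dReason = "character",
                 constants = "numeric", piN = "numeric", piS = "numeric",
                 piNpiS = "numeric"),
  prototype(piN = NA_real_, piS = NA_real_, piNpiS = NA_real_,
            dReason = "ok"))

setValidity("PopGenResult", function(object) {
  if (object@S < 0L) return("S must be non-negative")
  if (!is.na(object@pi) && object@pi < 0) return("pi must be non-negative")
  if (!is.na(object@thetaW) && object@thetaW < 0)
    return("thetaW must be non-negative")
  TRUE
})

setMethod("show", "PopGenResult", function(object) {
  cat(sprintf("PopGenResult: n=%d, sites=%d, S=%d, pi=%.5g, thetaW=%.5g, D=%s\n",
              object@nSequences, object@nSitesAnalyzed, object@S, object@pi,
              object@thetaW,
              if (is.na(object@tajimaD)) sprintf("NA (%s)", object@dReason)
              else sprintf("%.4f", object@tajimaD)))
  if (!is.na(object@piN) || !is.na(object@piS))
    cat(sprintf("  piN=%.5g, piS=%.5g, piN/piS=%s\n", object@piN, object@piS,
                if (is.na(object@piNpiS)) "NA" else sprintf("%.4f", object@piNpiS)))
})

#' Turn a PopGenResult into a one-row data.frame
#'
#' @param x A `PopGenResult`.
#' @param region Optional region label (e.g. `"CDS"`, `"NBARC"`,
#'   `"window:1-300"`).
#' @return A one-row `data.frame` with columns `region, n, sites, S, pi,
#'   theta_w, tajima_d, piN, piS, piN_piS`.
#' @export
popGenRow <- function(x, region = "CDS") {
  data.frame(region = region, n = x@nSequences, sites = x@nSitesAnalyzed,
             S = x@S, pi = x@pi, theta_w = x@thetaW, tajima_d = x@tajimaD,
             piN = x@piN, piS = x@piS, piN_piS = x@piNpiS,
             stringsAsFactors = FALSE)
}

#' PermutationTestResult
#'
#' Result of a label-permutation, matched-resampling, empirical-tail or
#' rank-set test: the observed statistic, how the null was built, the
#' replicate count and seed (for bit-for-bit reproducibility) and the
#' p-value. With the default no-add-one denominator the p-value resolution
#' is `1/nReplicates` and a reported 0 means "never as extreme in
#' nReplicates draws".
#'
#' @slot statisticName One of `diff_means`, `diff_medians`, `matched_mean`,
#'   `tail_count`, `set_score`.
#' @slot observed Observed statistic.
#' @slot nReplicates Number of null replicates (or enumerated permutations).
#' @slot pValue Permutation p-value.
#' @slot seed Seed used (NA if none supplied).
#' @slot tail `"two-sided"`, `"greater"` or `"less"`.
#' @slot exhaustive TRUE when the full permutation set was enumerated.
#' @slot details List of method-specific extras (null mean, flags, ...).
#' @exportClass PermutationTestResult
setClass("PermutationTestResult",
  representation(statisticName = "character", observed = "numeric",
                 nReplicates = "integer", pValue = "numeric",
                 seed = "integer", tail = "character",
                 exhaustive = "logical", details = "list"),
  prototype(exhaustive = FALSE, details = list(), seed = NA_integer_))

setValidity("PermutationTestResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("p-value must be in [0, 1]")
  if (!object@tail %in% c("two-sided", "greater", "less"))
    return("tail must be two-sided, greater or less")
  TRUE
})

setMethod("show", "PermutationTestResult", function(object) {
  cat(sprintf("PermutationTestResult [%s]%s: observed=%.5g, p=%.5g (%s, %d replicates%s)\n",
              object@statisticName,
              if (object@exhaustive) " (exhaustive)" else "",
              object@observed, object@pValue, object@tail, object@nReplicates,
              if (is.na(object@seed)) "" else sprintf(", seed=%d", object@seed)))
})

#' @rdname PermutationTestResult-class
#' @param x A `PermutationTestResult` or `TailTestResult`.
#' @export
pValue <- function(x) x@pValue

#' @rdname PermutationTestResult-class
#' @export
observedStat <- function(x) x@observed

#' TailTestResult: empirical-tail enrichment of a gene subset
#'
#' Result of testing whether a gene subset is over-represented in the top or
#' bottom tail of a genome-wide empirical distribution (cutoff at the given
#' percentile, membership inclusive of the cutoff value).
#'
#' @slot percentile Tail size as a fraction (default 0.05).
#' @slot direction `"top"` or `"bottom"`.
#' @slot cutoff Empirical cutoff value used.
#' @slot observedInTail Number of subset genes in the tail.
#' @slot expectedInTail `percentile * length(subset)`.
#' @slot pValue Permutation p-value from random same-size gene sets.
#' @slot nReplicates,seed,tail As in [PermutationTestResult-class].
#' @exportClass TailTestResult
setClass("TailTestResult",
  representation(percentile = "numeric", direction = "character",
                 cutoff = "numeric", observedInTail = "integer",
                 expectedInTail = "numeric", pValue = "numeric",
                 nReplicates = "integer", seed = "integer", tail = "character"),
  prototype(seed = NA_integer_, tail = "greater"))

setValidity("TailTestResult", function(object) {
  if (!object@direction %in% c("top", "bottom"))
    return("direction must be top or bottom")
  if (object@pValue < 0 || object@pValue > 1) return("p-value must be in [0, 1]")
  TRUE
})

setMethod("show", "TailTestResult", function(object) {
  cat(sprintf("TailTestResult: %d of subset in %s %.0f%% tail (expected %.2f), p=%.5g\n",
              object@observedInTail, object@direction, 100 * object@percentile,
              object@expectedInTail, object@pValue))
})
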
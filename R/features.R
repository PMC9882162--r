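# Per-gene genomic features: gene-body CG methylation, TPM expression,
# distance to the nearest transposable element, and the joined feature table.

.asGRanges <- function(x, idCol = "feature_id") {
  if (is(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*")
  id <- intersect(c(idCol, "feature_id", "gene_id", "name"), names(x))
  if (length(id)) S4Vectors::mcols(gr)$feature_id <- x[[id[1L]]]
  gr
}

.featureIds <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  for (col in c("feature_id", "gene_id", "ID", "name"))
    if (col %in% names(mc)) return(as.character(mc[[col]]))
  as.character(seq_along(gr))
}

#' Filter cytosine calls and pair symmetric CG dyads
#'
#' Applies the coverage filter (sites with fewer than `minCoverage` reads
#' dropped) and averages the symmetric cytosines of each CG dyad: the plus
#' strand cytosine at position `p` pairs with the minus strand cytosine at
#' `p + 1`, the site is anchored at the plus strand position, and its value
#' is the mean of the two percent-methylation values when both pass
#' coverage, or the surviving one's value otherwise. Minus strand sites with
#' no plus strand record anywhere in the input (a malformed pairing rather
#' than a coverage casualty) are used alone, anchored at `p - 1`, with a
#' warning.
#'
#' @param records `data.frame` with columns `chrom, pos, strand,
#'   count_methylated, count_unmethylated, context` (Bismark cytosine-report
#'   layout; see [readCytosineReport()]).
#' @param minCoverage Minimum total reads per cytosine (default 5).
#' @param context Sequence context to summarise (default `"CG"`; `"CHG"` and
#'   `"CHH"` run through the same machinery for descriptive use).
#' @return `data.frame` with columns `chrom, pos, meth_pct, n_cytosines`
#'   (1 or 2 cytosines contributing per site).
#' @export
filterAndPairCG <- function(records, minCoverage = 5L, context = "CG") {
  need <- c("chrom", "pos", "strand", "count_methylated", "count_unmethylated",
            "context")
  stopifnot(all(need %in% names(records)))
  rawPlus <- records[records$context == context & records$strand == "+", ]
  r <- records[records$context == context, , drop = FALSE]
  cov <- r$count_methylated + r$count_unmethylated
  r <- r[cov >= minCoverage, , drop = FALSE]
  if (nrow(r) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      meth_pct = numeric(0), n_cytosines = integer(0)))
  r$pct <- 100 * r$count_methylated /
    (r$count_methylated + r$count_unmethylated)
  # anchor: plus strand cytosines at pos, minus strand partners at pos - 1
  anchor <- ifelse(r$strand == "+", r$pos, r$pos - 1L)
  orphanMinus <- r$strand == "-" &
    !paste(r$chrom, r$pos - 1L) %in% paste(rawPlus$chrom, rawPlus$pos)
  if (any(orphanMinus))
    warning(sprintf("%d minus-strand cytosine(s) had no plus-strand partner record; used alone",
                    sum(orphanMinus)))
  key <- paste(r$chrom, anchor)
  agg <- tapply(r$pct, key, mean)
  cnt <- tapply(r$pct, key, length)
  first <- !duplicated(key)
  out <- data.frame(chrom = r$chrom[first], pos = anchor[first],
                    meth_pct = as.numeric(agg[key[first]]),
                    n_cytosines = as.integer(cnt[key[first]]),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Gene-body methylation from per-site values
#'
#' Averages per-CG-site percent methylation over each gene body (the full
#' annotated span, introns and UTRs included), per replicate, then averages
#' across the replicates that have at least one covered site in the gene.
#' Both means are unweighted: each covered site counts equally regardless of
#' its read depth, and each covered replicate counts equally. Genes with no
#' qualifying site in any replicate get `NA` and the
#' `no-covered-cytosines` flag.
#'
#' @param siteValues A `data.frame` as returned by [filterAndPairCG()], or a
#'   list of such data.frames (one per biological replicate).
#' @param genes `GRanges` (with a `feature_id`/`gene_id` metadata column) or
#'   `data.frame` with `chrom, start, end, gene_id`.
#' @return `data.frame` with columns `gene_id, cg_methylation_pct,
#'   n_cg_sites` (mean covered sites per replicate), `n_replicates_covered`,
#'   and `flag` (`""` or `"no-covered-cytosines"`).
#' @export
geneBodyMethylation <- function(siteValues, genes) {
  if (is.data.frame(siteValues)) siteValues <- list(siteValues)
  gr <- .asGRanges(genes, idCol = "gene_id")
  gid <- .featureIds(gr)
  perRep <- matrix(NA_real_, nrow = length(gr), ncol = length(siteValues))
  perRepN <- matrix(0L, nrow = length(gr), ncol = length(siteValues))
  for (k in seq_along(siteValues)) {
    sv <- siteValues[[k]]
    if (nrow(sv) == 0L) next
    sgr <- GenomicRanges::GRanges(sv$chrom, IRanges::IRanges(sv$pos, sv$pos))
    hits <- GenomicRanges::findOverlaps(sgr, gr, ignore.strand = TRUE)
    if (length(hits) == 0L) next
    val <- sv$meth_pct[S4Vectors::queryHits(hits)]
    g <- S4Vectors::subjectHits(hits)
    mu <- tapply(val, g, mean)
    nn <- tapply(val, g, length)
    ix <- as.integer(names(mu))
    perRep[ix, k] <- as.numeric(mu)
    perRepN[ix, k] <- as.integer(nn)
  }
  covered <- rowSums(!is.na(perRep))
  pct <- ifelse(covered > 0, rowMeans(perRep, na.rm = TRUE), NA_real_)
  data.frame(gene_id = gid, cg_methylation_pct = pct,
             n_cg_sites = rowMeans(perRepN),
             n_replicates_covered = as.integer(covered),
             flag = ifelse(covered == 0, "no-covered-cytosines", ""),
             stringsAsFactors = FALSE)
}

#' Transcripts per million
#'
#' `rate_g = counts_g / (length_g / 1000)`; `TPM_g = 10^6 * rate_g /
#' sum(rates)`, so each column (replicate) sums to one million.
#'
#' @param counts Numeric vector or gene-by-replicate matrix of read counts.
#' @param lengths Per-gene effective lengths in bp (> 0), recycled across
#'   replicates. Effective length is best taken as the exon-union length
#'   from the annotation (see [readGff3Genes()]), since counts come from
#'   exonic reads.
#' @return TPM in the same shape as `counts`.
#' @examples
#' tpmFromCounts(c(g1 = 10, g2 = 10), c(1000, 2000))
#' @export
tpmFromCounts <- function(counts, lengths) {
  stopifnot(all(lengths > 0))
  vec <- is.null(dim(counts))
  m <- as.matrix(counts)
  stopifnot(nrow(m) == length(lengths))
  if (any(colSums(m) == 0)) stop("a replicate has zero total counts")
  rate <- m / (lengths / 1000)
  tpm <- sweep(rate, 2L, colSums(rate), "/") * 1e6
  if (vec) tpm[, 1L] else tpm
}

#' Mean log2 expression across replicates
#'
#' Averages TPM across replicates first, then applies `log2(TPM + 1)` — the
#' display/analysis scale for per-gene expression.
#'
#' @param tpm Gene-by-replicate TPM matrix (or vector).
#' @return Per-gene `log2(mean TPM + 1)`.
#' @export
meanLog2Tpm <- function(tpm) {
  m <- as.matrix(tpm)
  log2(rowMeans(m) + 1)
}

#' Distance to the nearest transposable element
#'
#' For each gene, the gap in bp to the nearest TE on the same chromosome
#' under 1-based inclusive coordinates (`max(starts) - min(ends) - 1` for
#' disjoint features): 0 when the TE overlaps the gene span (UTRs and
#' introns included) and 0 for direct adjacency. Strand is ignored. Genes on
#' a chromosome with no TE get `NA` with a warning.
#'
#' @param genes,tes `GRanges` or `data.frame`s with `chrom, start, end` (and
#'   an id column for genes).
#' @return `data.frame` with `gene_id, te_distance_bp, te_within_gene`.
#' @export
teDistance <- function(genes, tes) {
  g <- .asGRanges(genes, idCol = "gene_id")
  t <- .asGRanges(tes)
  hits <- GenomicRanges::distanceToNearest(g, t, ignore.strand = TRUE)
  d <- rep(NA_real_, length(g))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  if (anyNA(d))
    warning(sprintf("%d gene(s) on chromosomes without any TE; distance NA",
                    sum(is.na(d))))
  data.frame(gene_id = .featureIds(g), te_distance_bp = d,
             te_within_gene = !is.na(d) & d == 0, stringsAsFactors = FALSE)
}

#' Assemble the per-gene feature table
#'
#' Outer join, keyed by `gene_id`, of hv calls, expression, methylation, TE
#' distance, mutation-probability scores and optional cluster / class
#' labels. Genes on the exclusion list (e.g. unmappable under short reads)
#' are flagged, their expression blanked, but never dropped; missing values
#' stay explicit `NA`s.
#'
#' @param hvCalls `data.frame` with `gene_id, label` (and optionally
#'   `n_high_entropy`). Genes absent from it are labelled `non-NLR`.
#' @param expression `data.frame` with `gene_id, mean_log2_tpm`.
#' @param methylation Output of [geneBodyMethylation()].
#' @param te Output of [teDistance()].
#' @param mutationScores `data.frame` with `gene_id, mutation_probability`.
#' @param cluster Optional `data.frame` with `gene_id, cluster_member`.
#' @param nlrClass Optional `data.frame` with `gene_id, nlr_class`.
#' @param exclusions Character vector of gene ids flagged `unmappable`.
#' @return `data.frame`, one row per gene, with an `excluded_flags` column
#'   (comma-separated flag set, `""` when clean).
#' @export
assembleFeatureTable <- function(hvCalls = NULL, expression = NULL,
                                 methylation = NULL, te = NULL,
                                 mutationScores = NULL, cluster = NULL,
                                 nlrClass = NULL, exclusions = character(0)) {
  pieces <- list(hv = hvCalls, expr = expression, meth = methylation,
                 te = te, mut = mutationScores, cluster = cluster,
                 class = nlrClass)
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0L) stop("no inputs to join")
  for (nm in names(pieces)) {
    stopifnot("gene_id" %in% names(pieces[[nm]]))
    if (anyDuplicated(pieces[[nm]]$gene_id))
      stop(sprintf("duplicate gene_id in '%s' input", nm))
  }
  tab <- Reduce(function(a, b) merge(a, b, by = "gene_id", all = TRUE),
                pieces)
  if ("label" %in% names(tab)) {
    tab$hv_label <- ifelse(is.na(tab$label), "non-NLR", tab$label)
    tab$label <- NULL
  } else tab$hv_label <- "non-NLR"
  flags <- tab$flag
  if (is.null(flags)) flags <- rep("", nrow(tab))
  flags[is.na(flags)] <- ""
  tab$flag <- NULL
  excl <- tab$gene_id %in% exclusions
  if (any(excl)) {
    flags[excl] <- ifelse(nzchar(flags[excl]),
                          paste(flags[excl], "unmappable", sep = ","),
                          "unmappable")
    if ("mean_log2_tpm" %in% names(tab)) tab$mean_log2_tpm[excl] <- NA_real_
  }
  tab$excluded_flags <- flags
  tab[order(tab$gene_id), , drop = FALSE]
}
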
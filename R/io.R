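# Readers and writers for the external formats the pipeline consumes:
# FASTA alignments, GFF3 gene annotation, TAIR-style TE tables, Bismark
# cytosine reports, count and score TSVs, domain tables and minimal VCF.
# Coordinates are 1-based inclusive internally (the GFF3/TAIR convention);
# BED export converts to 0-based half-open at the boundary.

#' Read a multi-FASTA alignment
#'
#' Parses a multi-FASTA file into an alignment object, validating that all
#' records have equal length (the offending record is named otherwise) and
#' uppercasing residues. The file stem serves as the default gene id.
#'
#' @param path FASTA file.
#' @param alphabet `"protein"`, `"nucleotide"` or `"codon"`.
#' @return A [ProteinAlignment], [NucAlignment] or [CodonAlignment]; the
#'   gene id is attached as attribute `geneId`.
#' @export
readFastaAlignment <- function(path, alphabet = c("protein", "nucleotide", "codon")) {
  alphabet <- match.arg(alphabet)
  .assertFile(path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop(sprintf("empty FASTA file: %s", path))
  w <- Biostrings::width(raw)
  if (length(unique(w)) != 1L) {
    bad <- names(raw)[which(w != w[1L])[1L]]
    stop(sprintf("ragged alignment in %s: record '%s' has length %d, expected %d",
                 basename(path), bad, w[w != w[1L]][1L], w[1L]))
  }
  seqs <- setNames(toupper(as.character(raw)), sub("\\s.*$", "", names(raw)))
  aln <- switch(alphabet,
                protein = ProteinAlignment(seqs),
                nucleotide = NucAlignment(seqs),
                codon = CodonAlignment(seqs))
  attr(aln, "geneId") <- tools::file_path_sans_ext(basename(path))
  aln
}

#' Write an alignment as multi-FASTA
#'
#' @param aln A [PopAlignment].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeFastaAlignment <- function(aln, path) {
  Biostrings::writeXStringSet(alnSeqs(aln), filepath = path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 gene annotation and returns one interval per gene (the
#' full annotated span, UTRs and introns included) together with the
#' exon-union length per gene (overlapping exons merged), the effective
#' length used for TPM. Exons are attached to genes through their mRNA
#' parents; features lacking an `ID` are skipped with a warning.
#'
#' @param path GFF3 file with gene/mRNA/exon features.
#' @return A `GRanges` of gene spans with metadata columns `feature_id` and
#'   `exon_union_length` (NA when a gene has no annotated exon).
#' @export
readGff3Genes <- function(path) {
  .assertFile(path)
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  genes <- gff[type == "gene"]
  if (length(genes) == 0L) stop("no gene features in GFF3")
  gid <- as.character(genes$ID)
  if (anyNA(gid) || any(!nzchar(gid))) {
    warning(sprintf("%d gene feature(s) without ID skipped", sum(is.na(gid) | !nzchar(gid))))
    keep <- !is.na(gid) & nzchar(gid)
    genes <- genes[keep]; gid <- gid[keep]
  }
  mrna <- gff[type %in% c("mRNA", "transcript")]
  mrnaParent <- vapply(mrna$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                       character(1))
  mrnaId <- as.character(mrna$ID)
  exons <- gff[type == "exon"]
  exonParent <- vapply(exons$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                       character(1))
  exonGene <- mrnaParent[match(exonParent, mrnaId)]
  # exons parented directly on a gene are allowed too
  direct <- is.na(exonGene) & exonParent %in% gid
  exonGene[direct] <- exonParent[direct]
  exLen <- rep(NA_real_, length(genes))
  keep <- !is.na(exonGene)
  if (any(keep)) {
    byGene <- split(GenomicRanges::ranges(exons[keep]), exonGene[keep])
    u <- vapply(byGene, function(r) sum(IRanges::width(IRanges::reduce(r))),
                numeric(1))
    exLen[match(names(u), gid)] <- u
  }
  S4Vectors::mcols(genes) <- NULL
  S4Vectors::mcols(genes)$feature_id <- gid
  S4Vectors::mcols(genes)$exon_union_length <- exLen
  genes
}

#' Read a TAIR-style transposable-element table
#'
#' Accepts the canonical TAIR layout (tab-separated with columns
#' `Transposon_Name`, `orientation_is_5prime`, `Transposon_min_Start`,
#' `Transposon_max_End`, ...). The chromosome is inferred from the TE name
#' prefix (`AT3TE...` is chromosome 3); rows whose name does not encode a
#' chromosome are skipped with a warning. Coordinates with start > end are
#' swapped and the strand set from the orientation flag.
#'
#' @param path TE table file.
#' @return A `GRanges` with metadata column `feature_id` (the TE name).
#' @export
readTeTable <- function(path) {
  .assertFile(path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "")
  nmCol <- grep("name", names(tab), ignore.case = TRUE, value = TRUE)[1L]
  stCol <- grep("start", names(tab), ignore.case = TRUE, value = TRUE)[1L]
  enCol <- grep("end", names(tab), ignore.case = TRUE, value = TRUE)[1L]
  orCol <- grep("orientation", names(tab), ignore.case = TRUE, value = TRUE)[1L]
  if (anyNA(c(nmCol, stCol, enCol)))
    stop("TE table must carry name, start and end columns")
  name <- tab[[nmCol]]
  chrom <- sub("^AT([0-9CM]+)TE.*$", "\\1", name, ignore.case = TRUE)
  bad <- chrom == name
  if (any(bad)) {
    warning(sprintf("%d TE row(s) with unparseable chromosome skipped", sum(bad)))
    tab <- tab[!bad, , drop = FALSE]; name <- name[!bad]; chrom <- chrom[!bad]
  }
  if (nrow(tab) == 0L) stop("no parseable TE rows")
  st <- as.integer(tab[[stCol]]); en <- as.integer(tab[[enCol]])
  swap <- st > en
  tmp <- st[swap]; st[swap] <- en[swap]; en[swap] <- tmp
  strand <- rep("*", nrow(tab))
  if (!is.na(orCol)) {
    fw <- tab[[orCol]] %in% c("true", "TRUE", TRUE, "+", "1")
    strand <- ifelse(fw, "+", "-")
    strand[swap] <- ifelse(fw[swap], "-", "+")
  }
  gr <- GenomicRanges::GRanges(paste0("Chr", chrom),
                               IRanges::IRanges(st, en), strand = strand)
  S4Vectors::mcols(gr)$feature_id <- name
  gr
}

#' Read a Bismark-style cytosine report
#'
#' Tab-separated, no header: chromosome, 1-based position, strand,
#' methylated count, unmethylated count, context (and optionally the
#' trinucleotide, ignored).
#'
#' @param path Cytosine report file.
#' @return `data.frame` with columns `chrom, pos, strand, count_methylated,
#'   count_unmethylated, context`.
#' @export
readCytosineReport <- function(path) {
  .assertFile(path)
  tab <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) stop("cytosine report must have at least 6 columns")
  out <- tab[, 1:6]
  names(out) <- c("chrom", "pos", "strand", "count_methylated",
                  "count_unmethylated", "context")
  out
}

#' Read a gene-by-replicate count table
#'
#' Tab-separated with a header: first column `gene_id`, remaining columns
#' one replicate each.
#'
#' @param path Counts TSV.
#' @return Numeric matrix with genes in rows (rownames = gene ids).
#' @export
readCountsTable <- function(path) {
  .assertFile(path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read per-gene mutation-probability scores
#'
#' @param path TSV with columns `gene_id` and `score` (header optional in
#'   that order).
#' @return `data.frame` with `gene_id, mutation_probability`.
#' @export
readMutationScores <- function(path) {
  .assertFile(path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  data.frame(gene_id = tab[[1L]], mutation_probability = as.numeric(tab[[2L]]),
             stringsAsFactors = FALSE)
}

#' Read a per-sequence domain annotation table
#'
#' @param path TSV with header columns `sequence_id, domain, start, end`
#'   (residue coordinates, 1-based inclusive).
#' @return `data.frame` in that layout.
#' @export
readDomainTable <- function(path) {
  .assertFile(path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("sequence_id", "domain", "start", "end") %in% names(tab)))
  tab
}

#' Expand a minimal VCF into a haplotype allele matrix
#'
#' GT-only parsing: each sample's genotype is split on `/` or `|` (phased
#' and unphased treated identically, as an allele multiset) and stacked into
#' a haplotype-by-site matrix of allele indices; `.` becomes `NA`.
#'
#' @param path VCF file (plain text or gzipped).
#' @return Integer matrix, haplotypes in rows, sites in columns; column
#'   names `CHROM:POS`.
#' @seealso [statsFromGenotypes()]
#' @export
readVcfGenotypes <- function(path) {
  .assertFile(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0L) stop("no GT records in VCF")
  ploidy <- max(lengths(strsplit(gt[!is.na(gt)], "[/|]")), 1L)
  nSites <- nrow(gt)
  hap <- matrix(NA_integer_, nrow = ncol(gt) * ploidy, ncol = nSites)
  for (s in seq_len(ncol(gt))) {
    parts <- strsplit(gt[, s], "[/|]")
    for (k in seq_len(ploidy)) {
      a <- vapply(parts, function(p) if (length(p) >= k) p[[k]] else NA_character_,
                  character(1))
      a[a == "."] <- NA_character_
      hap[(s - 1L) * ploidy + k, ] <- suppressWarnings(as.integer(a))
    }
  }
  colnames(hap) <- paste(v@fix[, "CHROM"], v@fix[, "POS"], sep = ":")
  hap
}

#' Convert between 1-based inclusive and BED coordinates
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open.
#' `toBed` and `fromBed` are exact inverses.
#'
#' @param start,end Interval coordinates.
#' @return Two-column matrix `start, end` in the target convention.
#' @export
toBed <- function(start, end) cbind(start = start - 1L, end = end)

#' @rdname toBed
#' @export
fromBed <- function(start, end) cbind(start = start + 1L, end = end)

#' Write a data.frame as TSV
#'
#' @param x `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
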
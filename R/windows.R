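# Sliding-window statistics and domain subsetting of codon alignments.

#' Sliding-window population statistics
#'
#' Runs [popGenStats()] over complete windows of the alignment (default 300
#' bp windows advancing by 75 bp, the scale used for per-gene selection
#' scans). Coordinates are 1-based inclusive alignment coordinates; a
#' trailing incomplete window is dropped so every window is directly
#' comparable. Windows where every column carries a gap or ambiguity yield
#' `NA` statistics.
#'
#' @param aln A [NucAlignment] or [CodonAlignment].
#' @param windowBp Window size in alignment columns (default 300).
#' @param stepBp Step size (default 75).
#' @return A `data.frame` with columns `window_start, window_end, midpoint,
#'   n, sites, S, pi, theta_w, tajima_d` (zero rows, with a warning, when
#'   the alignment is shorter than one window).
#' @export
slidingWindowStats <- function(aln, windowBp = 300L, stepBp = 75L) {
  stopifnot(is(aln, "NucAlignment"), windowBp >= 1L, stepBp >= 1L)
  L <- alnWidth(aln)
  empty <- data.frame(window_start = integer(0), window_end = integer(0),
                      midpoint = numeric(0), n = integer(0), sites = integer(0),
                      S = integer(0), pi = numeric(0), theta_w = numeric(0),
                      tajima_d = numeric(0))
  if (L < windowBp) {
    warning(sprintf("alignment (%d bp) shorter than one %d bp window", L, windowBp))
    return(empty)
  }
  starts <- seq.int(1L, L - windowBp + 1L, by = stepBp)
  rows <- lapply(starts, function(s) {
    e <- s + windowBp - 1L
    sub <- NucAlignment(Biostrings::subseq(alnSeqs(aln), start = s, end = e))
    st <- tryCatch(popGenStats(sub), error = function(err) NULL)
    if (is.null(st))
      data.frame(window_start = s, window_end = e, midpoint = (s + e) / 2,
                 n = nSeq(aln), sites = 0L, S = NA_integer_, pi = NA_real_,
                 theta_w = NA_real_, tajima_d = NA_real_)
    else
      data.frame(window_start = s, window_end = e, midpoint = (s + e) / 2,
                 n = st@nSequences, sites = st@nSitesAnalyzed, S = st@S,
                 pi = st@pi, theta_w = st@thetaW, tajima_d = st@tajimaD)
  })
  do.call(rbind, rows)
}

# Map each sequence's aligned codon columns to unaligned residue indices.
# A codon column is "present" for a sequence when none of its three
# nucleotides is a gap; ambiguity codes still represent a residue.
.residueIndexMatrix <- function(aln) {
  m <- alnMatrix(aln)
  L <- ncol(m)
  stopifnot(L %% 3L == 0L)
  nC <- L %/% 3L
  gap <- m == "-" | m == "."
  codGap <- matrix(FALSE, nrow(m), nC)
  for (k in 1:3) codGap <- codGap | gap[, seq.int(k, L, by = 3L), drop = FALSE]
  present <- !codGap
  resIdx <- matrix(NA_integer_, nrow(m), nC, dimnames = list(rownames(m), NULL))
  for (i in seq_len(nrow(m))) resIdx[i, present[i, ]] <- seq_len(sum(present[i, ]))
  resIdx
}

#' Domain label of every codon column by majority vote
#'
#' Maps each sequence's per-residue domain annotation (1-based residue
#' ranges in the unaligned sequence) through its alignment gaps and assigns
#' each codon column the domain claimed by a strict majority (> 50%) of the
#' sequences with a residue at that column. Ties and columns where no
#' annotated residue is present are left unassigned (`NA`).
#'
#' @param aln A [CodonAlignment].
#' @param annotations `data.frame` with columns `sequence_id, domain, start,
#'   end` (residue coordinates, 1-based inclusive). Later rows take
#'   precedence where ranges overlap.
#' @return Character vector of length `alnWidth(aln) / 3` with the assigned
#'   domain per codon column (`NA` where unassigned).
#' @seealso [domainSubset()]
#' @export
domainAssignments <- function(aln, annotations) {
  stopifnot(is(aln, "CodonAlignment"),
            all(c("sequence_id", "domain", "start", "end") %in% names(annotations)))
  ids <- seqIds(aln)
  unknown <- setdiff(unique(annotations$sequence_id), ids)
  if (length(unknown))
    stop(sprintf("annotation references unknown sequence(s): %s",
                 paste(unknown, collapse = ", ")))
  resIdx <- .residueIndexMatrix(aln)
  nC <- ncol(resIdx)
  lab <- matrix(NA_character_, nrow(resIdx), nC, dimnames = dimnames(resIdx))
  for (i in seq_along(ids)) {
    ann <- annotations[annotations$sequence_id == ids[i], , drop = FALSE]
    if (nrow(ann) == 0L) next
    maxRes <- max(resIdx[i, ], 0L, na.rm = TRUE)
    perRes <- rep(NA_character_, max(maxRes, max(ann$end)))
    for (r in seq_len(nrow(ann))) {
      if (ann$start[r] < 1L || ann$start[r] > ann$end[r])
        stop("annotation ranges must satisfy 1 <= start <= end")
      perRes[ann$start[r]:ann$end[r]] <- ann$domain[r]
    }
    has <- !is.na(resIdx[i, ]) & resIdx[i, ] <= length(perRes)
    lab[i, has] <- perRes[resIdx[i, has]]
  }
  present <- !is.na(resIdx)
  out <- rep(NA_character_, nC)
  for (j in seq_len(nC)) {
    voters <- lab[present[, j], j]
    voters <- voters[!is.na(voters)]
    nPresent <- sum(present[, j])
    if (length(voters) == 0L || nPresent == 0L) next
    tab <- table(voters)
    top <- which(tab == max(tab))
    # strict majority among sequences with a residue at this column
    if (length(top) == 1L && max(tab) > nPresent / 2) out[j] <- names(tab)[top]
  }
  out
}

#' Extract the codon columns assigned to one domain
#'
#' Concatenates the codon columns that [domainAssignments()] attributes to
#' `domainLabel` into a new [CodonAlignment] (all sequences retained, gaps
#' and all). An empty alignment with a warning is returned when no column is
#' assigned to the requested domain.
#'
#' @inheritParams domainAssignments
#' @param domainLabel Domain to extract (e.g. `"NBARC"`, `"LRR"`).
#' @return A [CodonAlignment] of the selected codon columns.
#' @export
domainSubset <- function(aln, annotations, domainLabel) {
  assign <- domainAssignments(aln, annotations)
  sel <- which(!is.na(assign) & assign == domainLabel)
  if (length(sel) == 0L) {
    warning(sprintf("no codon column assigned to domain '%s'", domainLabel))
    empty <- Biostrings::DNAStringSet(rep("", nSeq(aln)))
    names(empty) <- seqIds(aln)
    return(new("CodonAlignment", seqs = empty))
  }
  m <- alnMatrix(aln)
  cols <- as.vector(vapply(sel, function(c) (3L * (c - 1L) + 1L):(3L * c),
                           integer(3)))
  seqs <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
  CodonAlignment(setNames(seqs, seqIds(aln)))
}

#' Per-gene, per-region population statistics table
#'
#' Convenience wrapper producing the tidy per-region output: whole-CDS
#' statistics (with piN/piS), one row per annotated domain, and optionally
#' sliding windows.
#'
#' @param aln A [CodonAlignment].
#' @param annotations Optional domain annotation `data.frame` (see
#'   [domainAssignments()]).
#' @param domains Domains to report when annotations are given.
#' @param windows `NULL`, or `c(windowBp, stepBp)`.
#' @param geneId Gene id stamped on every row.
#' @return `data.frame` with columns `gene_id, region, n, sites, S, pi,
#'   theta_w, tajima_d, piN, piS, piN_piS`.
#' @export
popGenTable <- function(aln, annotations = NULL,
                        domains = c("CC", "TIR", "NBARC", "LRR"),
                        windows = NULL, geneId = "gene") {
  rows <- list(cbind(gene_id = geneId, popGenRow(popGenStats(aln, codon = TRUE), "CDS")))
  if (!is.null(annotations)) {
    for (d in intersect(domains, unique(annotations$domain))) {
      sub <- withCallingHandlers(domainSubset(aln, annotations, d),
                                 warning = function(w) invokeRestart("muffleWarning"))
      if (alnWidth(sub) == 0L) next
      st <- tryCatch(popGenStats(sub, codon = TRUE), error = function(e) NULL)
      if (!is.null(st)) rows <- c(rows, list(cbind(gene_id = geneId, popGenRow(st, d))))
    }
  }
  if (!is.null(windows)) {
    w <- slidingWindowStats(aln, windows[1], windows[2])
    if (nrow(w)) {
      wrows <- data.frame(gene_id = geneId,
                          region = sprintf("window:%d-%d", w$window_start, w$window_end),
                          n = w$n, sites = w$sites, S = w$S, pi = w$pi,
                          theta_w = w$theta_w, tajima_d = w$tajima_d,
                          piN = NA_real_, piS = NA_real_, piN_piS = NA_real_,
                          stringsAsFactors = FALSE)
      rows <- c(rows, list(wrows))
    }
  }
  do.call(rbind, rows)
}
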
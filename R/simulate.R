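# Synthetic-data generators with known ground truth: neutral coalescent
# alignments, codon populations with a tunable nonsynonymous acceptance
# rate, entropy-bench protein alignments, and per-gene feature tables with
# injected group effects. Every simulator is deterministic under its seed
# and returns its ground truth alongside the data.

#' Simulate a neutral coalescent sample of aligned sequences
#'
#' Draws a standard Kingman coalescent genealogy (exponential coalescence
#' times with rate `k (k - 1) / 2` while `k` lineages remain), drops
#' mutations on each lineage as a Poisson process with rate `theta / 2` per
#' coalescent time unit, and places them under the infinite-sites model at
#' distinct positions of a sequence of `lengthBp` sites. The expected number
#' of segregating sites is `theta * a1(n)` and the expected mean pairwise
#' difference count is `theta`. If more mutations arise than there are
#' positions (finite-length collision), positions are reused with a warning.
#'
#' @param nSamples Number of sampled sequences (`>= 2`).
#' @param theta Population-scaled mutation rate per locus (`4 N mu L`).
#' @param lengthBp Sequence length in bp.
#' @param seed Seed; the surrounding RNG state is restored afterwards.
#' @return A [NucAlignment] with attribute `truth`: a list with
#'   `nMutations` and `theta`.
#' @examples
#' aln <- simulateCoalescent(10, theta = 5, lengthBp = 999, seed = 1)
#' popGenStats(aln)
#' @export
simulateCoalescent <- function(nSamples, theta, lengthBp, seed = NULL) {
  stopifnot(nSamples >= 2L, theta > 0, lengthBp >= 1L)
  .withSeed(seed, {
    lineages <- lapply(seq_len(nSamples), identity)  # tip sets
    mutTips <- list()
    k <- nSamples
    while (k > 1L) {
      t <- rexp(1L, rate = k * (k - 1) / 2)
      nm <- rpois(k, theta / 2 * t)
      for (i in which(nm > 0L))
        mutTips <- c(mutTips, rep(lineages[i], nm[i]))
      pair <- sample.int(k, 2L)
      merged <- c(lineages[[pair[1L]]], lineages[[pair[2L]]])
      lineages <- c(lineages[-pair], list(merged))
      k <- k - 1L
    }
    S <- length(mutTips)
    anc <- sample(.BASES, lengthBp, replace = TRUE)
    mat <- matrix(rep(anc, each = nSamples), nrow = nSamples)
    if (S > 0L) {
      if (S <= lengthBp) pos <- sample.int(lengthBp, S)
      else {
        warning("more mutations than positions: finite-length collision, positions reused")
        pos <- sample.int(lengthBp, S, replace = TRUE)
      }
      for (m in seq_len(S)) {
        derived <- sample(setdiff(.BASES, anc[pos[m]]), 1L)
        mat[mutTips[[m]], pos[m]] <- derived
      }
    }
    seqs <- setNames(apply(mat, 1L, paste, collapse = ""),
                     sprintf("s%d", seq_len(nSamples)))
    aln <- NucAlignment(seqs)
    attr(aln, "truth") <- list(nMutations = S, theta = theta,
                               tipCounts = lengths(mutTips))
    aln
  })
}

#' Simulate a codon population with tunable nonsynonymous acceptance
#'
#' Evolves `nSamples` lineages independently from a stop-free ancestral
#' coding sequence (star genealogy, which keeps the synonymous /
#' nonsynonymous bookkeeping exact). Each lineage receives
#' `Poisson(mutationsPerLineage)` proposed single-base changes at uniform
#' positions; proposals creating a stop codon are rejected outright,
#' synonymous proposals are always retained, and nonsynonymous proposals are
#' retained with probability `omegaAccept`. With `omegaAccept = 1` the
#' retained changes are neutral with respect to coding effect and measured
#' piN/piS is centred at 1 after Nei-Gojobori site normalisation; with
#' `omegaAccept = 0` no nonsynonymous change is ever retained, and measured
#' piN is exactly 0 unless some codon is hit at two distinct positions, in
#' which case pathway averaging can attribute a small fractional
#' nonsynonymous difference to the pair (an inherent property of
#' pathway-based counting, not of the constraint).
#'
#' @param ancestralCodons Stop-free in-frame coding sequence (character
#'   string, length divisible by 3).
#' @param nSamples Number of lineages.
#' @param mutationsPerLineage Expected retained-or-rejected proposals per
#'   lineage.
#' @param omegaAccept Retention probability for nonsynonymous proposals.
#' @param seed Seed.
#' @return A [CodonAlignment] with attribute `truth`: a list with the
#'   per-lineage retained syn/nonsyn counts and the full retained-change log
#'   (`data.frame` lineage, pos, from, to, class).
#' @export
simulateCodonPopulation <- function(ancestralCodons, nSamples,
                                    mutationsPerLineage, omegaAccept = 1,
                                    seed = NULL) {
  anc <- toupper(ancestralCodons)
  L <- nchar(anc)
  stopifnot(L %% 3L == 0L, !grepl("[^ACGT]", anc), nSamples >= 2L,
            omegaAccept >= 0, omegaAccept <= 1)
  starts <- seq.int(1L, L, by = 3L)
  if (any(.isStop(substring(anc, starts, starts + 2L))))
    stop("ancestral sequence contains a stop codon in frame")
  .withSeed(seed, {
    seqs <- character(nSamples)
    logs <- list()
    retSyn <- retNonsyn <- integer(nSamples)
    for (i in seq_len(nSamples)) {
      cur <- strsplit(anc, "")[[1L]]
      nProp <- rpois(1L, mutationsPerLineage)
      for (m in seq_len(nProp)) {
        p <- sample.int(L, 1L)
        newBase <- sample(setdiff(.BASES, cur[p]), 1L)
        cStart <- 3L * ((p - 1L) %/% 3L) + 1L
        oldCodon <- paste(cur[cStart:(cStart + 2L)], collapse = "")
        newCodonChars <- cur[cStart:(cStart + 2L)]
        newCodonChars[p - cStart + 1L] <- newBase
        newCodon <- paste(newCodonChars, collapse = "")
        if (.isStop(newCodon)) next  # stop-creating proposals rejected
        syn <- .codonAA(newCodon) == .codonAA(oldCodon)
        if (!syn && runif(1L) >= omegaAccept) next
        cur[p] <- newBase
        if (syn) retSyn[i] <- retSyn[i] + 1L else retNonsyn[i] <- retNonsyn[i] + 1L
        logs[[length(logs) + 1L]] <-
          data.frame(lineage = i, pos = p, from = substr(oldCodon, p - cStart + 1L,
                                                         p - cStart + 1L),
                     to = newBase, class = if (syn) "syn" else "nonsyn",
                     stringsAsFactors = FALSE)
      }
      seqs[i] <- paste(cur, collapse = "")
    }
    names(seqs) <- sprintf("s%d", seq_len(nSamples))
    aln <- CodonAlignment(seqs)
    attr(aln, "truth") <- list(
      retainedSyn = retSyn, retainedNonsyn = retNonsyn,
      changeLog = if (length(logs)) do.call(rbind, logs)
                  else data.frame(lineage = integer(0), pos = integer(0),
                                  from = character(0), to = character(0),
                                  class = character(0)),
      ancestral = anc, omegaAccept = omegaAccept)
    aln
  })
}

#' Random stop-free coding sequence
#'
#' @param nCodons Number of codons.
#' @param seed Seed.
#' @return Character string of `3 * nCodons` bases with no in-frame stop.
#' @export
randomCodingSequence <- function(nCodons, seed = NULL) {
  .withSeed(seed, {
    sense <- .senseCodons()
    paste(sample(sense, nCodons, replace = TRUE), collapse = "")
  })
}

#' Synthetic protein alignment with a known number of high-diversity columns
#'
#' Builds an `nSeq x length` protein alignment in which exactly
#' `nVariable` columns are drawn independently and uniformly over
#' `alphabetSize` residues (entropy `log2(alphabetSize)` bits in
#' expectation) and every other column is constant — the construction used
#' to verify the hv classification boundary.
#'
#' @param nSeqs Number of sequences (default 32; large enough that realized
#'   entropy at variable columns comfortably exceeds 1.5 bits for 8
#'   residues).
#' @param length Alignment length.
#' @param nVariable Number of uniform high-diversity columns.
#' @param alphabetSize Number of residues used at variable columns (<= 20).
#' @param seed Seed.
#' @return A [ProteinAlignment] with attribute `truth` (the variable column
#'   indices).
#' @export
simulateHvAlignment <- function(nSeqs = 32L, length = 200L, nVariable = 0L,
                                alphabetSize = 8L, seed = NULL) {
  stopifnot(nVariable <= length, alphabetSize >= 2L, alphabetSize <= 20L)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  .withSeed(seed, {
    mat <- matrix(rep(sample(aas, length, replace = TRUE), each = nSeqs),
                  nrow = nSeqs)
    varCols <- if (nVariable > 0L) sort(sample.int(length, nVariable)) else integer(0)
    for (j in varCols)
      mat[, j] <- sample(aas[seq_len(alphabetSize)], nSeqs, replace = TRUE)
    seqs <- setNames(apply(mat, 1L, paste, collapse = ""),
                     sprintf("acc%02d", seq_len(nSeqs)))
    aln <- ProteinAlignment(seqs)
    attr(aln, "truth") <- list(variableColumns = varCols)
    aln
  })
}

#' Simulate a per-gene feature table with injected group effects
#'
#' Generates the joined feature table the enrichment layer consumes, with
#' known ground truth: `nHv` hv NLRs, `nNonHv` non-hv NLRs and a non-NLR
#' background. Baselines emulate rosette-leaf data: expression
#' `log2(TPM+1) ~ N(3, 2)`; gene-body CG methylation `100 * Beta(1.5, 3)`
#' percent (SD about 20 points); TE distance a zero-inflated exponential
#' (point mass 0.25 at 0 bp — a TE inside the gene span — and mean 2 kb
#' otherwise); mutation-probability score `N(1, 0.25)` (relative scale).
#' `n_cg_sites` is Poisson with rate increasing in methylation, giving the
#' covariate correlation the matched permutation test is designed to
#' absorb. Effects are injected into the hv group in SD units of the
#' corresponding baseline: positive `expression` raises hv expression,
#' negative `methylation` hypomethylates, positive `te` moves hv genes
#' toward (and onto) TEs, positive `mutation` raises the score. Features are
#' masked at random with probability `missingRate`.
#'
#' @param nGenes Total genes including the non-NLR background (default
#'   2000).
#' @param nHv,nNonHv hv and non-hv NLR counts (defaults 15 and 150).
#' @param effectSizes Named numeric vector with any of `expression,
#'   methylation, te, mutation` (SD units; default all 0).
#' @param missingRate Per-feature missingness probability (default 0).
#' @param seed Seed.
#' @return List with `table` (the feature `data.frame`) and `truth` (group
#'   indices, baselines and injected effects).
#' @export
simulateFeatureTable <- function(nGenes = 2000L, nHv = 15L, nNonHv = 150L,
                                 effectSizes = c(expression = 0, methylation = 0,
                                                 te = 0, mutation = 0),
                                 missingRate = 0, seed = NULL) {
  if (nHv + nNonHv > nGenes) stop("group sizes exceed nGenes")
  eff <- c(expression = 0, methylation = 0, te = 0, mutation = 0)
  eff[names(effectSizes)] <- effectSizes
  .withSeed(seed, {
    gid <- sprintf("G%05d", seq_len(nGenes))
    label <- rep("non-NLR", nGenes)
    label[seq_len(nHv)] <- "hv"
    label[nHv + seq_len(nNonHv)] <- "non-hv"
    isHv <- label == "hv"
    isNlr <- label != "non-NLR"

    exprSd <- 2
    expr <- rnorm(nGenes, mean = 3, sd = exprSd)
    expr[isHv] <- expr[isHv] + eff[["expression"]] * exprSd

    methSd <- 100 * sqrt(1.5 * 3 / ((1.5 + 3)^2 * (1.5 + 3 + 1)))
    meth <- 100 * rbeta(nGenes, 1.5, 3)
    if (eff[["methylation"]] != 0) {
      # shift the hv group's Beta mean by the requested number of SDs at
      # fixed concentration, so the injected effect is an exact mean shift
      # with no boundary pile-up
      conc <- 1.5 + 3
      muHv <- min(0.97, max(0.03, 1.5 / conc + eff[["methylation"]] * methSd / 100))
      meth[isHv] <- 100 * rbeta(sum(isHv), muHv * conc, (1 - muHv) * conc)
    }
    nCg <- rpois(nGenes, lambda = 10 + 0.4 * meth)

    p0 <- rep(0.25, nGenes)
    teMean <- rep(2000, nGenes)
    e <- eff[["te"]]
    p0[isHv] <- pmin(0.95, pmax(0.01, 0.25 + 0.2 * e))
    teMean[isHv] <- 2000 * exp(-e)
    te <- ifelse(runif(nGenes) < p0, 0, rexp(nGenes, rate = 1 / teMean))

    mutSd <- 0.25
    mut <- rnorm(nGenes, mean = 1, sd = mutSd)
    mut[isHv] <- mut[isHv] + eff[["mutation"]] * mutSd

    cluster <- ifelse(isNlr, runif(nGenes) < 0.6, NA)
    nlrClass <- rep(NA_character_, nGenes)
    nlrClass[isNlr] <- sample(c("CNL", "TNL", "RNL"), sum(isNlr),
                              replace = TRUE, prob = c(0.5, 0.45, 0.05))

    mask <- function(x) { x[runif(length(x)) < missingRate] <- NA; x }
    tab <- data.frame(gene_id = gid, hv_label = label,
                      mean_log2_tpm = mask(expr),
                      cg_methylation_pct = mask(meth),
                      n_cg_sites = nCg,
                      te_distance_bp = mask(te),
                      te_within_gene = NA,
                      mutation_probability = mask(mut),
                      cluster_member = cluster, nlr_class = nlrClass,
                      excluded_flags = "", stringsAsFactors = FALSE)
    tab$te_within_gene <- !is.na(tab$te_distance_bp) & tab$te_distance_bp == 0
    list(table = tab,
         truth = list(effects = eff, hvIds = gid[isHv],
                      nonHvIds = gid[label == "non-hv"],
                      baselineSd = c(expression = exprSd, methylation = methSd,
                                     mutation = mutSd),
                      missingRate = missingRate))
  })
}
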
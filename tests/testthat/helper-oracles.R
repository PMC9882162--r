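# Independent oracles used to check the package's estimators: plain,
# single-purpose re-derivations that share no code path with the package.

# Brute-force population statistics of a character matrix (sequences in
# rows): complete deletion, then explicit pairwise enumeration, then
# Tajima's D evaluated constant by constant from the 1989 formulas.
oraclePopgen <- function(mat) {
  keep <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- mat[, keep, drop = FALSE]
  n <- nrow(m)
  L <- ncol(m)
  if (L == 0) return(NULL)
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  diffs <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    diffs <- c(diffs, sum(m[i, ] != m[j, ]))
  Pi <- mean(diffs)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  D <- if (S == 0 || n < 3 || !is.finite(denom) || denom <= 0) NA_real_ else
    (Pi - S / a1) / denom
  list(S = S, Pi = Pi, pi = Pi / L, thetaW = S / (a1 * L), D = D, sites = L)
}

# Random test alignment with optional gaps and ambiguity characters.
randomNucMatrix <- function(n, L, gapRate = 0, ambigRate = 0) {
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (gapRate > 0) mat[runif(n * L) < gapRate] <- "-"
  if (ambigRate > 0) {
    hit <- runif(n * L) < ambigRate
    mat[hit] <- sample(c("N", "R", "Y"), sum(hit), replace = TRUE)
  }
  mat
}

matToNucAlignment <- function(mat) {
  NucAlignment(setNames(apply(mat, 1, paste, collapse = ""),
                        sprintf("s%d", seq_len(nrow(mat)))))
}

GENCODE <- Biostrings::GENETIC_CODE

# Nei-Gojobori site fractions by direct neighbor enumeration.
oracleNgSites <- function(codon) {
  aa <- GENCODE[[codon]]
  syn <- 0
  for (pos in 1:3) {
    nSyn <- 0; nTot <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon; substr(mut, pos, pos) <- b
      if (GENCODE[[mut]] == "*") next
      nTot <- nTot + 1
      if (GENCODE[[mut]] == aa) nSyn <- nSyn + 1
    }
    syn <- syn + nSyn / nTot
  }
  c(syn, 3 - syn)
}

# Pathway enumeration for codon pair differences (recursive, independent of
# the package's permutation-based implementation).
oracleNgDiffs <- function(c1, c2) {
  walk <- function(cur, target, allowStop) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (length(pos) == 0) return(list(c(0, 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur; substr(nxt, p, p) <- substr(target, p, p)
      if (!allowStop && GENCODE[[nxt]] == "*") next
      step <- if (GENCODE[[nxt]] == GENCODE[[cur]]) c(1, 0) else c(0, 1)
      for (tail in walk(nxt, target, allowStop))
        out <- c(out, list(step + tail))
    }
    out
  }
  paths <- walk(c1, c2, allowStop = FALSE)
  flagged <- FALSE
  if (length(paths) == 0) { paths <- walk(c1, c2, allowStop = TRUE); flagged <- TRUE }
  m <- do.call(rbind, paths)
  list(syn = mean(m[, 1]), nonsyn = mean(m[, 2]), flagged = flagged)
}

senseCodonList <- function() {
  all <- names(GENCODE)
  all[GENCODE != "*"]
}

# Exhaustive label-permutation p-value for a two-group difference test.
oraclePermP <- function(values, labels, stat = mean, tail = "two-sided") {
  lev <- levels(factor(labels))
  idxA <- which(labels == lev[1])
  n <- length(values)
  combs <- combn(n, length(idxA))
  delta <- apply(combs, 2, function(ia) stat(values[ia]) - stat(values[-ia]))
  obs <- stat(values[idxA]) - stat(values[-idxA])
  eps <- 1e-12
  b <- switch(tail,
              "two-sided" = sum(abs(delta) >= abs(obs) - eps),
              "greater" = sum(delta >= obs - eps),
              "less" = sum(delta <= obs + eps))
  b / ncol(combs)
}
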
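# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL means "use the current
# stream" (no save/restore).
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer or NULL")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream of child seeds from one user-facing seed, kept within
# 32-bit integer range.
.childSeeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(.withSeed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

.pvalFromCount <- function(nExtreme, nTotal, addOne = FALSE) {
  if (addOne) (nExtreme + 1) / (nTotal + 1) else nExtreme / nTotal
}

# Numeric tolerance used when comparing permuted statistics with the
# observed one (ties must count as "as extreme").
.PERM_EPS <- 1e-12

.tailCount <- function(null, observed, tail) {
  switch(tail,
    "greater"   = sum(null >= observed - .PERM_EPS),
    "less"      = sum(null <= observed + .PERM_EPS),
    "two-sided" = sum(abs(null) >= abs(observed) - .PERM_EPS),
    stop("tail must be two-sided, greater or less"))
}

# Directional permutation p-value for statistics that are not centred at
# zero under the null (matched means, tail counts, set scores): two-sided is
# twice the smaller directional tail, capped at 1.
.dirPval <- function(null, observed, tail, nTotal, addOne = FALSE) {
  bg <- sum(null >= observed - .PERM_EPS)
  bl <- sum(null <= observed + .PERM_EPS)
  switch(tail,
    "greater" = .pvalFromCount(bg, nTotal, addOne),
    "less" = .pvalFromCount(bl, nTotal, addOne),
    "two-sided" = min(1, 2 * min(.pvalFromCount(bg, nTotal, addOne),
                                 .pvalFromCount(bl, nTotal, addOne))),
    stop("tail must be two-sided, greater or less"))
}

.assertFile <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(sprintf("file not found: %s", paste(path, collapse = ", ")))
  invisible(path)
}
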
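# Independent oracles used to cross-check the package's statistics.
# These deliberately take different computational routes than the package.

# Hypergeometric upper tail by exhaustive enumeration of all n-subsets of a
# universe of size N whose first K elements are marked.
enumHyperP <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Upper tail by direct combinatorial summation (for universes too large to
# enumerate); still independent of stats::phyper.
sumHyperP <- function(k, K, n, N) {
  i <- seq(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Signed KS enrichment by a running walk over every rank of the full list:
# F(r) is the fraction of positives at rank <= r; the top-concentration
# deviation is max_r (F(r) - r/N), the bottom-concentration deviation is
# max_r (r/N - F(r-1)).
walkKs <- function(positions, N) {
  t <- length(positions)
  Fr <- cumsum(tabulate(positions, nbins = N)) / t
  a <- max(Fr - seq_len(N) / N)
  b <- max(seq_len(N) / N - c(0, Fr[-N]))
  if (a >= b) a else -b
}

# Reference Welch t via stats::t.test (independent of the package's .welch)
refWelch <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = FALSE)
  c(statistic = unname(tt$statistic), p = tt$p.value)
}

# small, fast simulation spec shared by tests that iterate over many runs
tinySpec <- function(...) {
  args <- list(nGenes = 150L, nMirnas = 6L, nTerms = 18L,
               termSizeRange = c(15L, 30L), targetDensity = 0.12,
               nCase = 20L, nControl = 20L, nPatients = 60L,
               pcrFraction = 0.3, nTrueDrugs = 2L, nDecoys = 10L)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulationSpec, args)
}

# profile built directly from statistics, for screen-level tests that do not
# need expression data underneath
statProfile <- function(stats, conditionId = "cond",
                        pvals = rep(0.01, length(stats))) {
  keys <- names(stats)
  parts <- strsplit(keys, "|", fixed = TRUE)
  comireg:::newCoMiProfile(
    conditionId = conditionId,
    mirna = vapply(parts, `[[`, character(1), 1L),
    term = vapply(parts, `[[`, character(1), 2L),
    nT = rep(5L, length(stats)), nNT = rep(10L, length(stats)),
    statistic = unname(stats), pValue = pvals)
}

# named statistics vector -> keys mirN|termN
mkStats <- function(values) {
  setNames(values, sprintf("mir-%03d|term-%03d", seq_along(values),
                           seq_along(values)))
}

# single-pattern set with explicit gene partition
onePattern <- function(targets, nontargets, mirna = "mir-x",
                       term = "term-x") {
  new("CoMiPatternSet", mirna = mirna, term = term,
      targetGenes = list(targets), nontargetGenes = list(nontargets),
      overlapP = 0.01, universeSize = length(c(targets, nontargets)),
      alpha = 0.05)
}
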
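#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of drawing at least `kOverlap` marked genes when `nSet` genes
#' are drawn without replacement from a universe of `nUniverse` genes of
#' which `kTargets` are marked (the miRNA's targets). This is the enrichment
#' test that gates CoMi pattern discovery.
#'
#' @param kOverlap observed overlap (targets inside the set).
#' @param kTargets number of target genes in the universe.
#' @param nSet size of the gene set (restricted to the universe).
#' @param nUniverse universe size.
#' @return p-value in (0, 1]; `P(X >= kOverlap)`.
#' @examples
#' hypergeomOverlapP(0, 5, 4, 10)   # 1
#' hypergeomOverlapP(4, 5, 4, 10)   # 5/210
#' @export
hypergeomOverlapP <- function(kOverlap, kTargets, nSet, nUniverse) {
  if (any(c(kOverlap, kTargets, nSet, nUniverse) < 0) ||
      kTargets > nUniverse || nSet > nUniverse ||
      kOverlap > min(kTargets, nSet))
    stop("impossible hypergeometric counts: k=", kOverlap, " K=", kTargets,
         " n=", nSet, " N=", nUniverse)
  stats::phyper(kOverlap - 1, kTargets, nUniverse - kTargets, nSet,
                lower.tail = FALSE)
}

#' Discover CoMi patterns by hypergeometric overlap
#'
#' For every (miRNA, term) pair, the term's genes (restricted to the declared
#' universe) are partitioned into the miRNA's targets and non-targets. Pairs
#' whose overlap passes the upper-tail hypergeometric test at `alpha`, with at
#' least one gene on each side of the partition, become CoMi patterns. The
#' partition is frozen into the pattern; expression data never changes it.
#'
#' @param targets named list: miRNA -> character vector of target genes.
#' @param sets named list: term -> character vector of member genes.
#' @param universe character vector of gene symbols; the hypergeometric
#'   universe. Must cover all genes referenced by `sets`.
#' @param alpha significance cutoff in (0, 1).
#' @return a [CoMiPatternSet-class], ordered by miRNA then term.
#' @export
discoverPatterns <- function(targets, sets, universe, alpha = 0.05) {
  if (!length(targets)) stop("empty target map")
  if (!length(sets)) stop("empty gene set collection")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  universe <- unique(universe)
  setGenes <- unlist(sets, use.names = FALSE)
  if (!all(setGenes %in% universe))
    stop("gene sets reference genes outside the declared universe")
  N <- length(universe)
  mirnas <- names(targets)[.ord(names(targets))]
  terms <- names(sets)[.ord(names(sets))]
  res_m <- character(0); res_t <- character(0)
  res_tg <- list(); res_ng <- list(); res_p <- numeric(0)
  for (m in mirnas) {
    tg_all <- intersect(targets[[m]], universe)
    K <- length(tg_all)
    if (!K) next
    for (te in terms) {
      g <- intersect(sets[[te]], universe)
      tg <- intersect(g, tg_all)
      nT <- length(tg)
      nNT <- length(g) - nT
      if (nT < 1L || nNT < 1L) next
      p <- hypergeomOverlapP(nT, K, length(g), N)
      if (p <= alpha) {
        res_m <- c(res_m, m); res_t <- c(res_t, te)
        res_tg <- c(res_tg, list(sort(tg, method = "radix")))
        res_ng <- c(res_ng, list(sort(setdiff(g, tg), method = "radix")))
        res_p <- c(res_p, p)
      }
    }
  }
  new("CoMiPatternSet", mirna = res_m, term = res_t, targetGenes = res_tg,
      nontargetGenes = res_ng, overlapP = res_p,
      universeSize = N, alpha = alpha)
}
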
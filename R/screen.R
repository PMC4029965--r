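## run expr with a private RNG stream seeded by `seed`, restoring the
## caller's stream afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Build the up/down-tag signature of a CoMi profile
#'
#' The query signature combines the k most up-regulated CoMi patterns (the
#' up-tag, descending by statistic) with the k most down-regulated (the
#' down-tag, ascending). The window size k runs from 5 up to a third of the
#' profile; ties at the boundary are broken lexicographically by pattern key
#' so the signature is deterministic.
#'
#' @param profile a [CoMiProfile-class] with at least 15 indices.
#' @param k window size, `5 <= k <= floor(length(profile) / 3)`.
#' @return a [CoMiSignature-class].
#' @export
makeSignature <- function(profile, k) {
  stopifnot(is(profile, "CoMiProfile"))
  n <- length(profile)
  kmax <- floor(n / 3)
  if (k < 5L || k > kmax)
    stop("k must lie in [5, ", kmax, "] for a profile of ", n, " indices")
  keys <- patternKeys(profile)
  ord <- .ord(profile@statistic, keys)   # ascending, ties by key
  down <- keys[ord][seq_len(k)]
  up <- keys[rev(ord)][seq_len(k)]
  new("CoMiSignature", k = as.integer(k), upTags = up, downTags = down)
}

#' Spearman connectivity score between disease and drug profiles
#'
#' Rank correlation between the disease and drug CoMi statistics over the
#' signature's patterns (up-tag and down-tag jointly) present in both
#' profiles. A strongly negative score means the drug's CoMi pattern inverts
#' the disease pattern -- the treatment-like direction. Instances sharing
#' fewer than 3 signature patterns with the disease profile are not scorable
#' and return `NA` with a warning.
#'
#' @param sig a [CoMiSignature-class].
#' @param disease the disease [CoMiProfile-class] the signature came from.
#' @param drug a drug instance's [CoMiProfile-class].
#' @return Spearman rho in \[-1, 1\], or `NA_real_` if unscorable.
#' @export
connectivityScore <- function(sig, disease, drug) {
  stopifnot(is(sig, "CoMiSignature"))
  tags <- c(sig@upTags, sig@downTags)
  dstat <- statistics(disease)
  gstat <- statistics(drug)
  shared <- tags[tags %in% names(dstat) & tags %in% names(gstat)]
  if (length(shared) < 3L) {
    warning("fewer than 3 shared signature patterns; instance unscorable")
    return(NA_real_)
  }
  stats::cor(dstat[shared], gstat[shared], method = "spearman")
}

#' Rank a drug library against a disease signature
#'
#' Scores every instance with [connectivityScore()] and sorts ascending, so
#' the most anti-correlated (predicted treatment) instance has rank 1. Ties
#' are broken by instance id; unscorable instances are excluded with a
#' warning.
#'
#' @param sig a [CoMiSignature-class].
#' @param disease the disease [CoMiProfile-class].
#' @param library a [DrugLibrary-class].
#' @return a [RankedDrugList-class].
#' @export
rankLibrary <- function(sig, disease, library) {
  stopifnot(is(library, "DrugLibrary"))
  ids <- instanceIds(library)
  pos <- isPositive(library)
  scores <- vapply(library@instances, function(inst)
    connectivityScore(sig, disease, inst@profile), numeric(1))
  ok <- !is.na(scores)
  if (!any(ok)) stop("no scorable instance in the library")
  if (!all(ok))
    warning(sum(!ok), " instance(s) excluded as unscorable")
  ord <- .ord(scores[ok], ids[ok])
  ids <- ids[ok][ord]; scores <- scores[ok][ord]; pos <- pos[ok][ord]
  new("RankedDrugList",
      instanceIds = ids, scores = scores, isPositive = pos,
      positivePositions = which(pos), N = length(ids),
      nPos = as.integer(sum(pos)))
}

#' Signed KS enrichment score of positive ranks
#'
#' Connectivity-map style two-sided Kolmogorov-Smirnov enrichment of the
#' positive instances' rank positions within a ranked list of length N. With
#' positions `V(1) < ... < V(t)` of the `t` positives,
#' `a = max_j( j/t - V(j)/N )` and `b = max_j( V(j)/N - (j-1)/t )`; the score
#' is `a` if `a >= b`, else `-b`. Positive scores mean the positives
#' concentrate at the top of the list.
#'
#' @param positions integer ranks of the positive instances (strictly
#'   increasing, within 1..N).
#' @param nPos number of positives (defaults to `length(positions)`).
#' @param N length of the ranked list.
#' @return signed score in (-1, 1].
#' @examples
#' ksScore(c(1, 2), N = 10)    #  0.8
#' ksScore(c(9, 10), N = 10)   # -0.9
#' @export
ksScore <- function(positions, nPos = length(positions), N) {
  positions <- as.integer(positions)
  if (nPos != length(positions)) stop("nPos does not match positions")
  if (!nPos) stop("need at least one positive position")
  if (anyDuplicated(positions)) stop("duplicate positions")
  if (any(positions < 1L | positions > N)) stop("positions outside 1..N")
  if (is.unsorted(positions, strictly = TRUE)) positions <- sort(positions)
  j <- seq_len(nPos)
  a <- max(j / nPos - positions / N)
  b <- max(positions / N - (j - 1) / nPos)
  if (a >= b) a else -b
}

#' Drug Screening Performance permutation p-value
#'
#' The DSP p-value of an observed ranking: the positive instances' ranks are
#' re-placed uniformly at random (without replacement) among the N list
#' positions `nPerm` times, and the p-value is the add-one estimate
#' `(#{|KS_perm| >= |KS_obs|} + 1) / (nPerm + 1)`, never exactly zero.
#'
#' @param observed a [RankedDrugList-class], or a list with elements
#'   `positions` (integer ranks) and `N`.
#' @param nPerm number of permutations (1000 in the reference protocol).
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @return a [DSPResult-class].
#' @export
dspPvalue <- function(observed, nPerm = 1000L, seed = 1L) {
  if (is(observed, "RankedDrugList")) {
    positions <- observed@positivePositions
    N <- observed@N
  } else {
    positions <- as.integer(observed$positions)
    N <- as.integer(observed$N)
  }
  nPos <- length(positions)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  obs <- ksScore(positions, N = N)
  if (nPos == N) {
    warning("every instance is positive; no null variability")
    return(new("DSPResult", ksScore = obs, pValue = 1,
               nPerm = as.integer(nPerm), seed = as.integer(seed)))
  }
  exceed <- .withSeed(seed, {
    cnt <- 0L
    for (i in seq_len(nPerm)) {
      perm <- sort.int(sample.int(N, nPos))
      if (abs(ksScore(perm, N = N)) >= abs(obs)) cnt <- cnt + 1L
    }
    cnt
  })
  new("DSPResult", ksScore = obs, pValue = (exceed + 1) / (nPerm + 1),
      nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' DSP sweep over signature window sizes
#'
#' Repeats the screen (signature, ranking, KS, permutation p-value) for each
#' window size k, mirroring the protocol of evaluating a screen across
#' signatures of different lengths. Per-k seeds are derived from `seed` by a
#' fixed counter so individual rows are reproducible in isolation.
#'
#' @param disease the disease [CoMiProfile-class].
#' @param library a [DrugLibrary-class].
#' @param kValues integer vector of window sizes (all valid per
#'   [makeSignature()]); default `5:floor(length(disease)/3)`.
#' @param nPerm permutations per k.
#' @param seed base RNG seed.
#' @return a [DSPSweep-class]: a (k, ks, p) table, the signatures used, and
#'   the median/quartile summary of the ks column.
#' @export
dspSweep <- function(disease, library,
                     kValues = seq(5L, floor(length(disease) / 3)),
                     nPerm = 1000L, seed = 1L) {
  if (!length(kValues)) stop("empty k list")
  sigs <- vector("list", length(kValues))
  ks <- numeric(length(kValues)); p <- numeric(length(kValues))
  for (i in seq_along(kValues)) {
    sigs[[i]] <- makeSignature(disease, kValues[i])
    ranked <- rankLibrary(sigs[[i]], disease, library)
    res <- dspPvalue(ranked, nPerm = nPerm, seed = seed + i)
    ks[i] <- res@ksScore; p[i] <- res@pValue
  }
  qs <- stats::quantile(ks, c(0.25, 0.5, 0.75), names = FALSE)
  new("DSPSweep",
      table = data.frame(k = as.integer(kValues), ks = ks, p = p),
      signatures = sigs,
      summary = c(q1 = qs[1], median = qs[2], q3 = qs[3]))
}

#' Most discriminative CoMi patterns of a sweep
#'
#' Collects the signature patterns (up- and down-tags) of the signatures
#' whose DSP index falls in the top fraction of the sweep -- the patterns
#' most responsible for separating true treatments from decoys.
#'
#' @param sweep a [DSPSweep-class].
#' @param topFraction fraction in (0, 1] of sweep rows to keep, ranked by
#'   descending ks.
#' @return sorted character vector of pattern keys (deterministic).
#' @export
discriminativeFeatures <- function(sweep, topFraction = 0.25) {
  stopifnot(is(sweep, "DSPSweep"))
  if (!(topFraction > 0 && topFraction <= 1))
    stop("topFraction must lie in (0, 1]")
  nr <- nrow(sweep@table)
  keep <- ceiling(topFraction * nr)
  ord <- .ord(-sweep@table$ks, sweep@table$k)
  idx <- ord[seq_len(keep)]
  keys <- unique(unlist(lapply(sweep@signatures[idx], function(s)
    c(s@upTags, s@downTags))))
  sort(keys, method = "radix")
}
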
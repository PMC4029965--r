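## Welch two-sample contrast used by every CoMi index.
## Returns c(statistic, p, degenerate). Conventions for degenerate inputs:
##   - both subsets constant with equal means: statistic 0, p 1
##   - both subsets constant with unequal means: statistic capped at +/-1e6,
##     p at the smallest positive double (an unbounded t is never returned)
##   - a singleton subset: statistic computed with that subset's variance
##     taken as 0, p forced to 1 (no Welch df exists)
.welch <- function(x, y) {
  nT <- length(x); nNT <- length(y)
  mT <- mean(x); mNT <- mean(y)
  vT <- if (nT > 1L) stats::var(x) else 0
  vNT <- if (nNT > 1L) stats::var(y) else 0
  a <- vT / nT; b <- vNT / nNT
  if (a + b == 0) {
    if (mT == mNT) return(c(0, 1, 1))
    return(c(sign(mT - mNT) * 1e6, .Machine$double.xmin, 1))
  }
  stat <- (mT - mNT) / sqrt(a + b)
  if (nT < 2L || nNT < 2L) return(c(stat, 1, 1))
  df <- (a + b)^2 / (ifelse(a > 0, a^2 / (nT - 1), 0) +
                     ifelse(b > 0, b^2 / (nNT - 1), 0))
  p <- 2 * stats::pt(-abs(stat), df)
  c(stat, p, 0)
}

#' Per-gene fold-change vector between two conditions
#'
#' On the log2 scale the fold change is a difference of log values: for
#' paired designs, the mean over pairs of (case - control); for unpaired,
#' mean(case) - mean(control).
#'
#' @param case,control expression matrices (genes x samples) or
#'   SummarizedExperiments with assay `"exprs"`; identical gene ids required.
#' @param paired if TRUE, columns are matched pairs (equal counts, same
#'   order).
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
foldChange <- function(case, control, paired = FALSE) {
  cm <- .exprs(case); km <- .exprs(control)
  if (!identical(rownames(cm), rownames(km)))
    stop("case and control gene ids differ")
  if (paired) {
    if (ncol(cm) != ncol(km))
      stop("paired design needs equal sample counts")
    fc <- rowMeans(cm - km)
  } else {
    fc <- rowMeans(cm) - rowMeans(km)
  }
  fc
}

#' CoMi index of one pattern
#'
#' The CoMi index quantifies a miRNA's regulatory influence on a gene set as
#' a signed Welch contrast between the pattern's target genes and its
#' non-target genes. In `"differential"` mode the contrasted values are
#' per-gene fold changes (case vs control); in `"per_sample"` mode they are
#' one sample's raw expression values, giving a per-patient CoMi statistic.
#' The statistic is positive when targets are up-regulated relative to
#' non-targets.
#'
#' The statistic is `(mean(T) - mean(NT)) / sqrt(s2_T/n_T + s2_NT/n_NT)` with
#' a two-sided p-value on Welch-Satterthwaite degrees of freedom. Patterns
#' with a singleton subset get a statistic but a p-value of 1 and a
#' degenerate flag; two constant subsets with unequal means yield a capped
#' statistic and a floor p-value rather than an infinity.
#'
#' @param pattern a single-pattern [CoMiPatternSet-class] (or an index into
#'   `patterns` via [computeProfile()]).
#' @param values named numeric vector covering the pattern's genes: fold
#'   changes (differential) or one sample's expression (per_sample).
#' @return list with `statistic`, `pValue`, `direction`, `degenerate`.
#' @export
comiIndex <- function(pattern, values) {
  stopifnot(is(pattern, "CoMiPatternSet"), length(pattern) == 1L)
  tg <- pattern@targetGenes[[1]]; ng <- pattern@nontargetGenes[[1]]
  miss <- setdiff(c(tg, ng), names(values))
  if (length(miss))
    stop("values missing for pattern genes: ", paste(head(miss, 3),
                                                     collapse = ", "))
  w <- .welch(values[tg], values[ng])
  list(statistic = w[1], pValue = w[2],
       direction = if (w[1] > 0) "target_up"
                   else if (w[1] < 0) "target_down" else "null",
       degenerate = w[3] == 1)
}

#' Compute a CoMi profile over a pattern set
#'
#' One CoMi index per pattern, against either a fold-change vector
#' (`mode = "differential"`) or a single sample's expression
#' (`mode = "per_sample"`). Patterns whose genes are not fully covered by
#' `values` are dropped with a warning that reports the count; if every
#' pattern is dropped this is an error.
#'
#' @param patterns a [CoMiPatternSet-class].
#' @param values named numeric vector (fold changes or one sample's
#'   expression).
#' @param mode `"differential"` or `"per_sample"` (recorded in the condition
#'   label only; the contrast is the same Welch form).
#' @param conditionId label for the resulting profile.
#' @return a [CoMiProfile-class] in the pattern set's (deterministic) order.
#' @export
computeProfile <- function(patterns, values,
                           mode = c("differential", "per_sample"),
                           conditionId = "condition") {
  mode <- match.arg(mode)
  if (!length(patterns)) stop("empty pattern set")
  if (!all(is.finite(values))) stop("non-finite input values")
  have <- names(values)
  ok <- vapply(seq_len(length(patterns)), function(i) {
    all(patterns@targetGenes[[i]] %in% have) &&
      all(patterns@nontargetGenes[[i]] %in% have)
  }, logical(1))
  if (!any(ok))
    stop("no pattern has full gene coverage in the input")
  if (!all(ok))
    warning(sum(!ok), " pattern(s) dropped for missing gene coverage")
  idx <- which(ok)
  stat <- numeric(length(idx)); pval <- numeric(length(idx))
  degen <- logical(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    w <- .welch(values[patterns@targetGenes[[i]]],
                values[patterns@nontargetGenes[[i]]])
    stat[j] <- w[1]; pval[j] <- w[2]; degen[j] <- w[3] == 1
  }
  newCoMiProfile(
    conditionId = conditionId,
    mirna = patterns@mirna[idx], term = patterns@term[idx],
    nT = lengths(patterns@targetGenes)[idx],
    nNT = lengths(patterns@nontargetGenes)[idx],
    statistic = stat, pValue = pval, degenerate = degen)
}

#' Per-sample CoMi matrix for a cohort
#'
#' Applies the per-sample CoMi contrast to every column of an expression
#' matrix, yielding a feature (pattern) x sample matrix of CoMi statistics --
#' the input to response prediction.
#'
#' @param patterns a [CoMiPatternSet-class].
#' @param expr matrix or SummarizedExperiment (genes x samples).
#' @param labels optional integer 0/1 outcome per sample; stored in colData.
#' @return SummarizedExperiment with assay `"comi"` (patterns x samples) and,
#'   if given, `colData()$label`.
#' @export
comiMatrix <- function(patterns, expr, labels = NULL) {
  m <- .exprs(expr)
  profs <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    names(v) <- rownames(m)
    computeProfile(patterns, v, mode = "per_sample",
                   conditionId = colnames(m)[j])
  })
  keys <- patternKeys(profs[[1]])
  vals <- vapply(profs, function(p) p@statistic, numeric(length(keys)))
  dimnames(vals) <- list(keys, colnames(m))
  cd <- S4Vectors::DataFrame(row.names = colnames(m))
  if (!is.null(labels)) cd$label <- as.integer(labels)
  SummarizedExperiment::SummarizedExperiment(assays = list(comi = vals),
                                             colData = cd)
}
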
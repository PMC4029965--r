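#' @import methods
#' @importFrom stats var pt phyper cor sd quantile median glm binomial predict
#'   rnorm setNames runif
#' @importFrom utils read.delim write.table head tail
NULL

.key <- function(mirna, term) paste(mirna, term, sep = "|")

## locale-independent ordering used everywhere a deterministic order is promised
.ord <- function(...) order(..., method = "radix")

#' CoMiPatternSet: fixed miRNA/gene-set pairs with significant target overlap
#'
#' A CoMi pattern is a (miRNA, gene set) pair whose overlap between the miRNA's
#' predicted targets and the set's genes is significant by an upper-tail
#' hypergeometric test. The pattern freezes the partition of the set into
#' target and non-target genes; condition- or sample-level statistics are
#' computed later against this fixed partition.
#'
#' @slot mirna character vector of miRNA identifiers, one per pattern.
#' @slot term character vector of gene-set (term) identifiers, parallel to
#'   `mirna`.
#' @slot targetGenes list of character vectors: the miRNA's targets inside the
#'   set (restricted to the declared universe).
#' @slot nontargetGenes list of character vectors: the set's remaining genes.
#' @slot overlapP numeric vector of hypergeometric upper-tail p-values.
#' @slot universeSize integer scalar, the size of the gene universe used for
#'   the overlap test.
#' @slot alpha numeric scalar, the significance cutoff applied at discovery.
#' @exportClass CoMiPatternSet
setClass("CoMiPatternSet",
  representation(
    mirna = "character",
    term = "character",
    targetGenes = "list",
    nontargetGenes = "list",
    overlapP = "numeric",
    universeSize = "integer",
    alpha = "numeric"
  )
)

setValidity("CoMiPatternSet", function(object) {
  n <- length(object@mirna)
  if (length(object@term) != n || length(object@targetGenes) != n ||
      length(object@nontargetGenes) != n || length(object@overlapP) != n)
    return("pattern slots must have equal length")
  if (anyDuplicated(.key(object@mirna, object@term)))
    return("duplicated (miRNA, term) pattern")
  nT <- lengths(object@targetGenes)
  nNT <- lengths(object@nontargetGenes)
  if (any(nT < 1L) || any(nNT < 1L))
    return("every pattern needs >= 1 target and >= 1 non-target gene in the set")
  for (i in seq_len(n)) {
    if (length(intersect(object@targetGenes[[i]], object@nontargetGenes[[i]])))
      return("target and non-target gene sets must be disjoint")
  }
  if (any(object@overlapP < 0 | object@overlapP > 1))
    return("overlapP outside [0, 1]")
  TRUE
})

#' CoMiProfile: the CoMi indices of one condition or sample
#'
#' One signed Welch-type statistic (and two-sided p-value) per CoMi pattern,
#' contrasting target vs non-target values -- fold changes for a differential
#' profile, raw expression for a per-sample profile. The sign convention is
#' positive when targets are up-regulated relative to non-targets.
#'
#' @slot conditionId single character label for the condition or sample.
#' @slot mirna,term character vectors identifying each pattern.
#' @slot nT,nNT integer vectors: target / non-target gene counts.
#' @slot statistic numeric vector of signed Welch statistics.
#' @slot pValue numeric vector of two-sided p-values in \[0, 1\].
#' @slot direction character: "target_up", "target_down" or "null", consistent
#'   with the sign of `statistic`.
#' @slot degenerate logical: TRUE where a subset was too small or had zero
#'   variance and the p-value is a convention rather than a Welch tail area.
#' @exportClass CoMiProfile
setClass("CoMiProfile",
  representation(
    conditionId = "character",
    mirna = "character",
    term = "character",
    nT = "integer",
    nNT = "integer",
    statistic = "numeric",
    pValue = "numeric",
    direction = "character",
    degenerate = "logical"
  )
)

setValidity("CoMiProfile", function(object) {
  n <- length(object@mirna)
  for (sl in c("term", "nT", "nNT", "statistic", "pValue", "direction",
               "degenerate"))
    if (length(slot(object, sl)) != n) return("profile slots of unequal length")
  if (length(object@conditionId) != 1L) return("conditionId must be length 1")
  if (anyDuplicated(.key(object@mirna, object@term)))
    return("duplicated pattern key in profile")
  if (any(object@pValue < 0 | object@pValue > 1))
    return("p-values outside [0, 1]")
  want <- ifelse(object@statistic > 0, "target_up",
                 ifelse(object@statistic < 0, "target_down", "null"))
  if (!all(object@direction == want))
    return("direction inconsistent with statistic sign")
  TRUE
})

#' CoMiSignature: the up/down tags of a profile
#'
#' The k most up-regulated ("up-tag") and k most down-regulated ("down-tag")
#' patterns of a CoMi profile, used as the query signature for connectivity
#' scoring.
#'
#' @slot k integer window size.
#' @slot upTags,downTags character vectors of pattern keys, each of length k,
#'   disjoint; `upTags` descending by statistic, `downTags` ascending.
#' @exportClass CoMiSignature
setClass("CoMiSignature",
  representation(k = "integer", upTags = "character", downTags = "character")
)

setValidity("CoMiSignature", function(object) {
  if (length(object@k) != 1L || object@k < 1L) return("k must be a positive scalar")
  if (length(object@upTags) != object@k || length(object@downTags) != object@k)
    return("tag lists must have length k")
  if (length(intersect(object@upTags, object@downTags)))
    return("up and down tags must be disjoint")
  TRUE
})

#' CoMiNetwork: signed bipartite miRNA-to-term network
#'
#' Edges are the significant CoMi indices of a profile (p < alpha). Edge
#' weight is -log10(p); edge sign/direction records whether the miRNA's
#' targets are up- or down-regulated relative to the non-targets. miRNAs carry
#' outgoing edges, terms incoming edges.
#'
#' @slot edges data.frame with columns mirna, term, statistic, p_value,
#'   weight, direction.
#' @slot alpha numeric scalar used at construction.
#' @exportClass CoMiNetwork
setClass("CoMiNetwork",
  representation(edges = "data.frame", alpha = "numeric")
)

setValidity("CoMiNetwork", function(object) {
  need <- c("mirna", "term", "statistic", "p_value", "weight", "direction")
  if (!all(need %in% names(object@edges)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(.key(object@edges$mirna, object@edges$term)))
    return("more than one edge for a (miRNA, term) pair")
  if (nrow(object@edges) && any(object@edges$p_value >= object@alpha))
    return("edge p-values must be < alpha")
  TRUE
})

#' DrugInstance: one perturbation profile in a drug library
#'
#' @slot instanceId unique identifier within a library.
#' @slot drugName,cellLine,concentration free-text annotations.
#' @slot profile the instance's [CoMiProfile-class].
#' @slot isPositive TRUE for instances of drugs that are established
#'   treatments for the screened indication.
#' @exportClass DrugInstance
setClass("DrugInstance",
  representation(
    instanceId = "character",
    drugName = "character",
    cellLine = "character",
    concentration = "character",
    profile = "CoMiProfile",
    isPositive = "logical"
  )
)

#' DrugLibrary: a collection of drug perturbation instances
#'
#' @slot instances list of [DrugInstance-class] objects with unique ids.
#' @exportClass DrugLibrary
setClass("DrugLibrary", representation(instances = "list"))

setValidity("DrugLibrary", function(object) {
  if (!all(vapply(object@instances, is, logical(1), "DrugInstance")))
    return("instances must all be DrugInstance objects")
  ids <- vapply(object@instances, function(x) x@instanceId, character(1))
  if (anyDuplicated(ids)) return("instance ids must be unique")
  TRUE
})

#' RankedDrugList: a library ordered by connectivity score
#'
#' Instances are sorted ascending by Spearman connectivity score, so the most
#' anti-correlated (treatment-like) instance is rank 1.
#'
#' @slot instanceIds character, in rank order.
#' @slot scores numeric Spearman coefficients, ascending.
#' @slot isPositive logical, parallel to `instanceIds`.
#' @slot positivePositions integer ranks of the positive instances.
#' @slot N,nPos integer scalars: list length and number of positives.
#' @exportClass RankedDrugList
setClass("RankedDrugList",
  representation(
    instanceIds = "character",
    scores = "numeric",
    isPositive = "logical",
    positivePositions = "integer",
    N = "integer",
    nPos = "integer"
  )
)

setValidity("RankedDrugList", function(object) {
  if (is.unsorted(object@scores)) return("scores must be ascending")
  if (length(object@instanceIds) != object@N) return("N mismatch")
  if (!identical(object@positivePositions, which(object@isPositive)))
    return("positivePositions inconsistent with isPositive")
  if (length(object@positivePositions) != object@nPos) return("nPos mismatch")
  TRUE
})

#' DSPResult: drug screening performance statistic and permutation p-value
#'
#' @slot ksScore signed KS enrichment score in \[-1, 1\]; positive means the
#'   positive instances concentrate at the top of the ranking.
#' @slot pValue permutation p-value with the add-one floor 1/(nPerm + 1).
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used for the permutations.
#' @exportClass DSPResult
setClass("DSPResult",
  representation(ksScore = "numeric", pValue = "numeric",
                 nPerm = "integer", seed = "integer")
)

setValidity("DSPResult", function(object) {
  if (abs(object@ksScore) > 1) return("|ksScore| must be <= 1")
  if (object@pValue > 1 ||
      object@pValue < 1 / (object@nPerm + 1) - 1e-12)
    return("pValue outside (1/(nPerm+1), 1]")
  TRUE
})

#' DSPSweep: DSP results across signature window sizes
#'
#' @slot table data.frame with columns k, ks, p (one row per window size).
#' @slot signatures list of [CoMiSignature-class], parallel to the rows.
#' @slot summary named numeric: median and quartiles of the ks column.
#' @exportClass DSPSweep
setClass("DSPSweep",
  representation(table = "data.frame", signatures = "list",
                 summary = "numeric")
)

#' PredictionReport: cross-validated response prediction results
#'
#' @slot meanAuc mean test-set AUC over repeats.
#' @slot aucPerRepeat AUC of each repeat (held-out scores pooled over folds).
#' @slot rocPoints two-column matrix (fpr, tpr) of the pooled ROC curve.
#' @slot selectedFeatures pattern keys ordered by how often they were selected
#'   across training folds.
#' @slot classifier one of "logistic", "naive_bayes", "svm".
#' @slot nRepeats,nFolds,seed run parameters.
#' @exportClass PredictionReport
setClass("PredictionReport",
  representation(
    meanAuc = "numeric",
    aucPerRepeat = "numeric",
    rocPoints = "matrix",
    selectedFeatures = "character",
    classifier = "character",
    nRepeats = "integer",
    nFolds = "integer",
    seed = "integer"
  )
)

setValidity("PredictionReport", function(object) {
  if (object@meanAuc < 0 || object@meanAuc > 1) return("meanAuc outside [0, 1]")
  rp <- object@rocPoints
  if (ncol(rp) != 2L) return("rocPoints must have two columns (fpr, tpr)")
  if (nrow(rp)) {
    if (any(rp[1, ] != 0) || any(rp[nrow(rp), ] != 1))
      return("ROC must start at (0,0) and end at (1,1)")
    if (is.unsorted(rp[, 1]) || is.unsorted(rp[, 2]))
      return("ROC must be monotone non-decreasing")
  }
  TRUE
})

#' SimulationSpec: parameters of the synthetic study
#'
#' Encodes the generative assumptions of the method: a miRNA represses its
#' target genes inside a functional gene set, disease shifts those targets in
#' case samples, effective drugs invert the shift, and responders' predictive
#' patterns shift with treatment response. See [simulationSpec()] for the
#' defaults and their rationale.
#'
#' @slot nGenes,nMirnas,nTerms problem sizes.
#' @slot termSizeRange integer length-2: min/max genes per term.
#' @slot targetDensity probability a gene is a target of a given miRNA.
#' @slot plantedEffects data.frame(mirna, term, shift, condition) of location
#'   shifts in noise-SD units; condition is "disease", "drug" or "response".
#' @slot noiseSd measurement noise SD (log2 scale).
#' @slot nCase,nControl,nPatients cohort sizes.
#' @slot pcrFraction fraction of responders among patients.
#' @slot nTrueDrugs,nDecoys,instancesPerDrug drug library composition.
#' @exportClass SimulationSpec
setClass("SimulationSpec",
  representation(
    nGenes = "integer", nMirnas = "integer", nTerms = "integer",
    termSizeRange = "integer", targetDensity = "numeric",
    plantedEffects = "data.frame", noiseSd = "numeric",
    nCase = "integer", nControl = "integer", nPatients = "integer",
    pcrFraction = "numeric", nTrueDrugs = "integer", nDecoys = "integer",
    instancesPerDrug = "integer"
  )
)

setValidity("SimulationSpec", function(object) {
  counts <- c(object@nGenes, object@nMirnas, object@nTerms, object@nCase,
              object@nControl, object@nPatients, object@nTrueDrugs,
              object@instancesPerDrug)
  if (any(counts < 1L)) return("all counts must be positive")
  if (object@nDecoys < 0L) return("nDecoys must be non-negative")
  if (object@pcrFraction <= 0 || object@pcrFraction >= 1)
    return("pcrFraction must lie in (0, 1)")
  if (length(object@termSizeRange) != 2L ||
      object@termSizeRange[1] > object@termSizeRange[2])
    return("termSizeRange must be (min, max) with min <= max")
  if (object@termSizeRange[2] > object@nGenes)
    return("term size cannot exceed nGenes")
  if (object@targetDensity <= 0 || object@targetDensity >= 1)
    return("targetDensity must lie in (0, 1)")
  if (nrow(object@plantedEffects) &&
      !all(is.finite(object@plantedEffects$shift)))
    return("planted shifts must be finite")
  TRUE
})
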
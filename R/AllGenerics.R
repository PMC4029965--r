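#' @rdname patternKeys
#' @export
setGeneric("patternKeys", function(x) standardGeneric("patternKeys"))

#' Pattern keys of a CoMi object
#'
#' A pattern key is `"<mirna>|<term>"`; it identifies a CoMi pattern across
#' profiles, signatures and networks.
#'
#' @param x a [CoMiPatternSet-class], [CoMiProfile-class] or
#'   [CoMiNetwork-class].
#' @return character vector of keys, in the object's order.
#' @examples
#' ann <- generateAnnotation(simulationSpec(nGenes = 60, nMirnas = 2,
#'   nTerms = 3, termSizeRange = c(10, 20)), seed = 1)
#' pats <- discoverPatterns(ann$targets, ann$sets, ann$universe, alpha = 0.5)
#' patternKeys(pats)
#' @rdname patternKeys
#' @export
setMethod("patternKeys", "CoMiPatternSet", function(x) .key(x@mirna, x@term))

#' @rdname patternKeys
#' @export
setMethod("patternKeys", "CoMiProfile", function(x) .key(x@mirna, x@term))

#' @rdname patternKeys
#' @export
setMethod("patternKeys", "CoMiNetwork",
          function(x) .key(x@edges$mirna, x@edges$term))

#' Accessors for CoMi objects
#'
#' Small typed accessors in place of direct slot access: `statistics()` and
#' `pValues()` return the per-pattern statistic and p-value of a profile,
#' `conditionId()` its label, `directions()` the up/down/null calls,
#' `upTags()`/`downTags()` the tag lists of a signature, `edgeTable()` the
#' edge data.frame of a network, `overlapP()` the discovery p-values of a
#' pattern set.
#'
#' @param x the object.
#' @return vector or data.frame matching the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("statistics", function(x) standardGeneric("statistics"))
#' @rdname accessors
#' @export
setMethod("statistics", "CoMiProfile", function(x) {
  setNames(x@statistic, .key(x@mirna, x@term))
})

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setMethod("pValues", "CoMiProfile", function(x) {
  setNames(x@pValue, .key(x@mirna, x@term))
})
#' @rdname accessors
#' @export
setMethod("pValues", "CoMiPatternSet", function(x) {
  setNames(x@overlapP, .key(x@mirna, x@term))
})

#' @rdname accessors
#' @export
setGeneric("conditionId", function(x) standardGeneric("conditionId"))
#' @rdname accessors
#' @export
setMethod("conditionId", "CoMiProfile", function(x) x@conditionId)

#' @rdname accessors
#' @export
setGeneric("directions", function(x) standardGeneric("directions"))
#' @rdname accessors
#' @export
setMethod("directions", "CoMiProfile", function(x) {
  setNames(x@direction, .key(x@mirna, x@term))
})

#' @rdname accessors
#' @export
setGeneric("upTags", function(x) standardGeneric("upTags"))
#' @rdname accessors
#' @export
setMethod("upTags", "CoMiSignature", function(x) x@upTags)

#' @rdname accessors
#' @export
setGeneric("downTags", function(x) standardGeneric("downTags"))
#' @rdname accessors
#' @export
setMethod("downTags", "CoMiSignature", function(x) x@downTags)

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setMethod("edgeTable", "CoMiNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("dspKs", function(x) standardGeneric("dspKs"))
#' @rdname accessors
#' @export
setMethod("dspKs", "DSPResult", function(x) x@ksScore)
#' @rdname accessors
#' @export
setMethod("dspKs", "DSPSweep", function(x) setNames(x@table$ks, x@table$k))

#' @rdname accessors
#' @export
setGeneric("dspP", function(x) standardGeneric("dspP"))
#' @rdname accessors
#' @export
setMethod("dspP", "DSPResult", function(x) x@pValue)
#' @rdname accessors
#' @export
setMethod("dspP", "DSPSweep", function(x) setNames(x@table$p, x@table$k))

#' @rdname accessors
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))
#' @rdname accessors
#' @export
setMethod("sweepTable", "DSPSweep", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("sweepSignatures", function(x) standardGeneric("sweepSignatures"))
#' @rdname accessors
#' @export
setMethod("sweepSignatures", "DSPSweep", function(x) x@signatures)

#' @rdname accessors
#' @export
setGeneric("meanAuc", function(x) standardGeneric("meanAuc"))
#' @rdname accessors
#' @export
setMethod("meanAuc", "PredictionReport", function(x) x@meanAuc)

#' @rdname accessors
#' @export
setGeneric("aucPerRepeat", function(x) standardGeneric("aucPerRepeat"))
#' @rdname accessors
#' @export
setMethod("aucPerRepeat", "PredictionReport", function(x) x@aucPerRepeat)

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setMethod("rocPoints", "PredictionReport", function(x) x@rocPoints)

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setMethod("selectedFeatures", "PredictionReport",
          function(x) x@selectedFeatures)

#' @rdname accessors
#' @export
setGeneric("instanceIds", function(x) standardGeneric("instanceIds"))
#' @rdname accessors
#' @export
setMethod("instanceIds", "DrugLibrary", function(x)
  vapply(x@instances, function(i) i@instanceId, character(1)))
#' @rdname accessors
#' @export
setMethod("instanceIds", "RankedDrugList", function(x) x@instanceIds)

#' @rdname accessors
#' @export
setGeneric("isPositive", function(x) standardGeneric("isPositive"))
#' @rdname accessors
#' @export
setMethod("isPositive", "DrugLibrary", function(x)
  vapply(x@instances, function(i) i@isPositive, logical(1)))
#' @rdname accessors
#' @export
setMethod("isPositive", "RankedDrugList", function(x) x@isPositive)

#' @rdname accessors
#' @export
setGeneric("instances", function(x) standardGeneric("instances"))
#' @rdname accessors
#' @export
setMethod("instances", "DrugLibrary", function(x) x@instances)

setMethod("length", "CoMiPatternSet", function(x) length(x@mirna))
setMethod("length", "CoMiProfile", function(x) length(x@mirna))
setMethod("length", "DrugLibrary", function(x) length(x@instances))

#' Subset a pattern set
#'
#' @param x a [CoMiPatternSet-class].
#' @param i index vector (integer, logical or pattern-key character).
#' @param j,...,drop ignored.
#' @return a CoMiPatternSet with the selected patterns.
#' @export
setMethod("[", "CoMiPatternSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, patternKeys(x))
  new("CoMiPatternSet",
      mirna = x@mirna[i], term = x@term[i],
      targetGenes = x@targetGenes[i], nontargetGenes = x@nontargetGenes[i],
      overlapP = x@overlapP[i], universeSize = x@universeSize,
      alpha = x@alpha)
})

setMethod("show", "CoMiPatternSet", function(object) {
  cat("CoMiPatternSet with", length(object), "patterns\n")
  cat("  miRNAs:", length(unique(object@mirna)),
      " terms:", length(unique(object@term)), "\n")
  cat("  universe size:", object@universeSize,
      " discovery alpha:", object@alpha, "\n")
})

setMethod("show", "CoMiProfile", function(object) {
  cat("CoMiProfile", sQuote(object@conditionId), "with", length(object),
      "indices\n")
  tab <- table(factor(object@direction,
                      c("target_up", "target_down", "null")))
  cat("  target_up:", tab[["target_up"]],
      " target_down:", tab[["target_down"]],
      " null:", tab[["null"]], "\n")
})

setMethod("show", "CoMiSignature", function(object) {
  cat("CoMiSignature (k =", object@k, ")\n")
  cat("  up-tag:  ", paste(head(object@upTags, 3), collapse = ", "),
      if (object@k > 3) "..." else "", "\n")
  cat("  down-tag:", paste(head(object@downTags, 3), collapse = ", "),
      if (object@k > 3) "..." else "", "\n")
})

setMethod("show", "CoMiNetwork", function(object) {
  cat("CoMiNetwork:", nrow(object@edges), "edges (alpha =", object@alpha,
      ")\n")
  cat("  miRNA nodes:", length(unique(object@edges$mirna)),
      " term nodes:", length(unique(object@edges$term)), "\n")
})

setMethod("show", "DrugLibrary", function(object) {
  pos <- sum(isPositive(object))
  cat("DrugLibrary with", length(object), "instances (", pos, "positive )\n")
})

setMethod("show", "RankedDrugList", function(object) {
  cat("RankedDrugList of", object@N, "instances,", object@nPos,
      "positives\n")
  cat("  top of list:", paste(head(object@instanceIds, 3), collapse = ", "),
      "\n")
})

setMethod("show", "DSPResult", function(object) {
  cat("DSPResult: KS =", format(object@ksScore, digits = 4),
      " p =", format(object@pValue, digits = 4),
      " (", object@nPerm, "permutations )\n")
})

setMethod("show", "DSPSweep", function(object) {
  cat("DSPSweep over", nrow(object@table), "window sizes\n")
  cat("  KS median", format(object@summary[["median"]], digits = 3),
      " IQR [", format(object@summary[["q1"]], digits = 3), ",",
      format(object@summary[["q3"]], digits = 3), "]\n")
})

setMethod("show", "PredictionReport", function(object) {
  cat("PredictionReport (", object@classifier, "):",
      "mean AUC", format(object@meanAuc, digits = 4),
      "over", object@nRepeats, "repeats of", object@nFolds, "-fold CV\n")
})

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec:", object@nGenes, "genes,", object@nMirnas, "miRNAs,",
      object@nTerms, "terms\n")
  cat("  cohorts:", object@nCase, "case /", object@nControl, "control,",
      object@nPatients, "patients (pCR fraction",
      format(object@pcrFraction, digits = 3), ")\n")
  cat("  drug library:", object@nTrueDrugs, "true drugs,", object@nDecoys,
      "decoys\n")
  cat("  planted effects:", nrow(object@plantedEffects), "\n")
})
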
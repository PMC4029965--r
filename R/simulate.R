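#' Construct a simulation specification
#'
#' The generator encodes the study design the method assumes: a paired
#' tumor/normal cohort in which planted miRNAs shift their target genes
#' inside specific gene sets, a drug library in which true treatments invert
#' those shifts among decoys, and an imbalanced patient cohort whose
#' responders carry the response-predictive shifts. Defaults mirror the
#' reference study's conditions at desk scale: 43 paired case/control
#' samples, a 26/178 responder fraction, 5 true drugs, and planted
#' repressions of -1 noise-SD on 20 targets inside 100-gene terms.
#'
#' @param nGenes,nMirnas,nTerms problem sizes.
#' @param termSizeRange min/max genes per term.
#' @param targetDensity per-gene probability of being a miRNA's target.
#' @param plantedEffects data.frame(mirna, term, shift, condition); condition
#'   in "disease", "drug", "response". Default plants one -1 SD disease
#'   repression and one +1 SD response effect.
#' @param noiseSd measurement noise SD (log2 scale).
#' @param nCase,nControl paired cohort sizes (equal for pairing).
#' @param nPatients patient cohort size.
#' @param pcrFraction responder fraction.
#' @param nTrueDrugs,nDecoys,instancesPerDrug drug library composition.
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(nGenes = 500L, nMirnas = 15L, nTerms = 40L,
                           termSizeRange = c(40L, 100L),
                           targetDensity = 0.08,
                           plantedEffects = NULL,
                           noiseSd = 1,
                           nCase = 43L, nControl = 43L,
                           nPatients = 178L, pcrFraction = 26 / 178,
                           nTrueDrugs = 5L, nDecoys = 50L,
                           instancesPerDrug = 1L) {
  if (is.null(plantedEffects))
    plantedEffects <- data.frame(
      mirna = c("mir-001", "mir-002"),
      term = c("term-001", "term-002"),
      shift = c(-1, 1),
      condition = c("disease", "response"),
      stringsAsFactors = FALSE)
  new("SimulationSpec",
      nGenes = as.integer(nGenes), nMirnas = as.integer(nMirnas),
      nTerms = as.integer(nTerms),
      termSizeRange = as.integer(termSizeRange),
      targetDensity = targetDensity, plantedEffects = plantedEffects,
      noiseSd = noiseSd, nCase = as.integer(nCase),
      nControl = as.integer(nControl), nPatients = as.integer(nPatients),
      pcrFraction = pcrFraction, nTrueDrugs = as.integer(nTrueDrugs),
      nDecoys = as.integer(nDecoys),
      instancesPerDrug = as.integer(instancesPerDrug))
}

.geneIds <- function(n) sprintf("g%04d", seq_len(n))
.mirIds <- function(n) sprintf("mir-%03d", seq_len(n))
.termIds <- function(n) sprintf("term-%03d", seq_len(n))

#' Generate a target map, gene set collection and universe
#'
#' Random target sets at `targetDensity`; terms drawn with sizes in
#' `termSizeRange`. Mirroring real functional annotation -- where a gene
#' set's members share regulators -- every term is built around a focal
#' miRNA whose targets make up a fifth of the term (at least 2 genes), so
#' each (focal miRNA, term) pair passes the hypergeometric gate at
#' alpha = 0.05 and a study-sized pattern collection is discoverable. Terms
#' named by a planted effect use that effect's miRNA as their focal miRNA.
#' The construction is verified and redrawn (bounded retries) if any planted
#' overlap fails the gate. Identical seeds give identical annotation.
#'
#' @param spec a [SimulationSpec-class].
#' @param seed RNG seed.
#' @return list with `targets` (named list), `sets` (named list),
#'   `universe` (character).
#' @export
generateAnnotation <- function(spec, seed = 1L) {
  stopifnot(is(spec, "SimulationSpec"))
  .withSeed(seed, {
    universe <- .geneIds(spec@nGenes)
    mirnas <- .mirIds(spec@nMirnas)
    terms <- .termIds(spec@nTerms)
    planted <- spec@plantedEffects
    if (nrow(planted)) {
      if (!all(planted$mirna %in% mirnas) || !all(planted$term %in% terms))
        stop("planted effects reference unknown miRNAs or terms")
    }
    for (attempt in 1:50) {
      targets <- lapply(mirnas, function(m) {
        tg <- universe[stats::runif(spec@nGenes) < spec@targetDensity]
        while (!length(tg)) tg <- sample(universe, 1L)
        tg
      })
      names(targets) <- mirnas
      # focal miRNA per term; planted terms get their planted miRNA
      focal <- sample(mirnas, spec@nTerms, replace = TRUE)
      names(focal) <- terms
      if (nrow(planted)) focal[planted$term] <- planted$mirna
      sets <- lapply(terms, function(te) {
        sz <- sample(seq(spec@termSizeRange[1], spec@termSizeRange[2]), 1L)
        m <- focal[[te]]
        K <- length(targets[[m]])
        # start at a fifth of the term and grow until the overlap clears
        # the discovery gate (keeping >= 2 non-targets)
        nT <- max(2L, min(K, sz - 2L, ceiling(sz / 5)))
        while (nT < min(K, sz - 2L) &&
               hypergeomOverlapP(nT, K, sz, spec@nGenes) > 0.05)
          nT <- nT + 1L
        tg <- sample(targets[[m]], nT)
        ng <- sample(setdiff(universe, targets[[m]]), sz - nT)
        sort(c(tg, ng), method = "radix")
      })
      names(sets) <- terms
      okAll <- TRUE
      for (i in seq_len(nrow(planted))) {
        m <- planted$mirna[i]; te <- planted$term[i]
        g <- sets[[te]]
        tg <- intersect(g, targets[[m]])
        ok <- length(tg) >= 2L && length(g) - length(tg) >= 2L &&
          hypergeomOverlapP(length(tg), length(targets[[m]]),
                            length(g), spec@nGenes) <= 0.05
        if (!ok) { okAll <- FALSE; break }
      }
      if (okAll)
        return(list(targets = targets, sets = sets, universe = universe))
    }
    stop("could not satisfy planted overlaps; spec infeasible")
  })
}

## genes shifted by each planted effect of a given condition: intersection of
## the miRNA's targets with the term's genes
.effectGenes <- function(spec, annotation, condition) {
  pe <- spec@plantedEffects
  pe <- pe[pe$condition == condition, , drop = FALSE]
  if (!nrow(pe)) return(list())
  lapply(seq_len(nrow(pe)), function(i) {
    list(genes = intersect(annotation$sets[[pe$term[i]]],
                           annotation$targets[[pe$mirna[i]]]),
         shift = pe$shift[i],
         mirna = pe$mirna[i], term = pe$term[i])
  })
}

#' Generate a paired case/control expression cohort
#'
#' Each pair shares a random baseline (pair effect, SD = `noiseSd`); case and
#' control add independent measurement noise of SD `noiseSd`. Every planted
#' "disease" effect adds its shift (in noise-SD units) to the case values of
#' the miRNA's target genes inside the planted term. Values are log2-scale.
#'
#' @param spec a [SimulationSpec-class] (requires `nCase == nControl`).
#' @param annotation output of [generateAnnotation()].
#' @param seed RNG seed.
#' @return list of SummarizedExperiments `case` and `control` with matched
#'   column order (pair i is column i of each).
#' @export
generateDiseaseCohort <- function(spec, annotation, seed = 1L) {
  stopifnot(is(spec, "SimulationSpec"))
  if (spec@nCase != spec@nControl)
    stop("paired design requires nCase == nControl")
  .withSeed(seed, {
    g <- annotation$universe
    n <- spec@nCase
    base <- matrix(stats::rnorm(length(g) * n, 0, spec@noiseSd),
                   length(g), n)
    ctrl <- base + matrix(stats::rnorm(length(g) * n, 0, spec@noiseSd),
                          length(g), n)
    case <- base + matrix(stats::rnorm(length(g) * n, 0, spec@noiseSd),
                          length(g), n)
    for (eff in .effectGenes(spec, annotation, "disease")) {
      rows <- match(eff$genes, g)
      case[rows, ] <- case[rows, ] + eff$shift * spec@noiseSd
    }
    dimnames(ctrl) <- list(g, sprintf("normal_%02d", seq_len(n)))
    dimnames(case) <- list(g, sprintf("tumor_%02d", seq_len(n)))
    mk <- function(m, cond) SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = m),
      colData = S4Vectors::DataFrame(condition = rep(cond, n),
                                     pair = seq_len(n),
                                     row.names = colnames(m)))
    list(case = mk(case, "case"), control = mk(ctrl, "control"))
  })
}

#' Generate a drug perturbation library
#'
#' True drugs (positives) get fold-change effects that are the negation of
#' the planted disease effects; decoys perturb one to three randomly chosen
#' patterns with random shifts. Every instance's fold-change vector carries
#' per-gene sampling noise matched to the disease cohort
#' (`noiseSd * sqrt(2 / nCase)`), and is converted to a [CoMiProfile-class]
#' over the supplied patterns. `instancesPerDrug` replicates each drug as
#' separate instances (different noise draws), mimicking multiple
#' dose/cell-line entries per compound.
#'
#' @param spec a [SimulationSpec-class].
#' @param annotation output of [generateAnnotation()].
#' @param patterns the discovered [CoMiPatternSet-class].
#' @param seed RNG seed.
#' @return a [DrugLibrary-class].
#' @export
generateDrugLibrary <- function(spec, annotation, patterns, seed = 1L) {
  stopifnot(is(spec, "SimulationSpec"), is(patterns, "CoMiPatternSet"))
  .withSeed(seed, {
    g <- annotation$universe
    fcSd <- spec@noiseSd * sqrt(2 / spec@nCase)
    disEff <- .effectGenes(spec, annotation, "disease")
    mkProfile <- function(fc, id) {
      names(fc) <- g
      computeProfile(patterns, fc, mode = "differential", conditionId = id)
    }
    insts <- list()
    for (d in seq_len(spec@nTrueDrugs)) {
      for (r in seq_len(spec@instancesPerDrug)) {
        fc <- stats::rnorm(length(g), 0, fcSd)
        for (eff in disEff) {
          rows <- match(eff$genes, g)
          fc[rows] <- fc[rows] - eff$shift * spec@noiseSd
        }
        id <- sprintf("true%02d_i%02d", d, r)
        insts[[length(insts) + 1L]] <- new("DrugInstance",
          instanceId = id, drugName = sprintf("truedrug%02d", d),
          cellLine = "sim", concentration = "1x",
          profile = mkProfile(fc, id), isPositive = TRUE)
      }
    }
    nPat <- length(patterns)
    for (d in seq_len(spec@nDecoys)) {
      for (r in seq_len(spec@instancesPerDrug)) {
        fc <- stats::rnorm(length(g), 0, fcSd)
        nEff <- sample(1:3, 1L)
        for (pi in sample.int(nPat, min(nEff, nPat))) {
          rows <- match(patterns@targetGenes[[pi]], g)
          fc[rows] <- fc[rows] + stats::rnorm(1, 0, spec@noiseSd)
        }
        id <- sprintf("decoy%03d_i%02d", d, r)
        insts[[length(insts) + 1L]] <- new("DrugInstance",
          instanceId = id, drugName = sprintf("decoy%03d", d),
          cellLine = "sim", concentration = "1x",
          profile = mkProfile(fc, id), isPositive = FALSE)
      }
    }
    new("DrugLibrary", instances = insts)
  })
}

#' Generate an imbalanced patient cohort of per-sample CoMi features
#'
#' Patient expression is i.i.d. noise on the log2 scale; responders
#' (label 1, `round(pcrFraction * nPatients)` of them) additionally carry
#' every planted "response" effect's shift on the predictive patterns'
#' target genes. The per-sample CoMi matrix over `patterns` is returned;
#' the `predictivePatterns` attribute records the planted pattern keys.
#'
#' @param spec a [SimulationSpec-class].
#' @param annotation output of [generateAnnotation()].
#' @param patterns the discovered [CoMiPatternSet-class].
#' @param seed RNG seed.
#' @return SummarizedExperiment with assay `"comi"` (patterns x patients),
#'   `colData()$label`, and metadata element `predictivePatterns`.
#' @export
generatePatientCohort <- function(spec, annotation, patterns, seed = 1L) {
  stopifnot(is(spec, "SimulationSpec"), is(patterns, "CoMiPatternSet"))
  .withSeed(seed, {
    g <- annotation$universe
    n <- spec@nPatients
    nPos <- round(spec@pcrFraction * n)
    labels <- c(rep(1L, nPos), rep(0L, n - nPos))
    labels <- labels[sample.int(n)]
    expr <- matrix(stats::rnorm(length(g) * n, 0, spec@noiseSd),
                   length(g), n,
                   dimnames = list(g, sprintf("pt_%03d", seq_len(n))))
    respEff <- .effectGenes(spec, annotation, "response")
    for (eff in respEff) {
      rows <- match(eff$genes, g)
      expr[rows, labels == 1L] <- expr[rows, labels == 1L] +
        eff$shift * spec@noiseSd
    }
    cohort <- comiMatrix(patterns, expr, labels = labels)
    S4Vectors::metadata(cohort)$predictivePatterns <-
      vapply(respEff, function(e) .key(e$mirna, e$term), character(1))
    cohort
  })
}
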
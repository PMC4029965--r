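## feature x sample matrix + 0/1 labels from a cohort container
.cohortParts <- function(cohort, labels = NULL) {
  if (is(cohort, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(cohort, "comi")
    if (is.null(labels))
      labels <- SummarizedExperiment::colData(cohort)$label
  } else {
    m <- cohort
  }
  labels <- as.integer(labels)
  if (length(labels) != ncol(m))
    stop("label count does not match sample count")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (!all(is.finite(m))) stop("non-finite cohort values")
  list(m = m, labels = labels)
}

#' Rank features by class-difference t-test
#'
#' Each feature (per-sample CoMi statistic) is tested between the two outcome
#' classes with the same Welch contrast used for CoMi indices; features are
#' ranked by ascending two-sided p-value, ties broken lexicographically by
#' key, and the top `nFeatures` returned.
#'
#' @param cohort SummarizedExperiment with assay `"comi"` and
#'   `colData()$label`, or a features x samples matrix.
#' @param nFeatures number of features to return.
#' @param labels 0/1 outcome vector (required when `cohort` is a matrix).
#' @return character vector of feature keys, best first.
#' @export
selectFeatures <- function(cohort, nFeatures, labels = NULL) {
  parts <- .cohortParts(cohort, labels)
  m <- parts$m; y <- parts$labels
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("each class needs >= 2 samples for feature selection")
  if (nFeatures > nrow(m))
    stop("nFeatures exceeds the number of features")
  pv <- vapply(seq_len(nrow(m)), function(i)
    .welch(m[i, y == 1L], m[i, y == 0L])[2], numeric(1))
  keys <- rownames(m)
  keys[.ord(pv, keys)][seq_len(nFeatures)]
}

#' Balance classes by under-sampling the majority
#'
#' Keeps every minority-class sample and a uniform random subset of the
#' majority class of equal size, as done when training on heavily imbalanced
#' response cohorts (e.g. 26 responders vs 152 non-responders keeps 52
#' samples).
#'
#' @param labels 0/1 vector.
#' @param seed RNG seed (caller's RNG state untouched).
#' @return sorted integer indices of retained samples.
#' @export
undersample <- function(labels, seed = 1L) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (!n1 || !n0) stop("both classes must be present")
  minority <- if (n1 <= n0) 1L else 0L
  keepMin <- which(labels == minority)
  maj <- which(labels != minority)
  keepMaj <- .withSeed(seed, sample(maj, length(keepMin)))
  sort.int(c(keepMin, keepMaj))
}

## classifier contracts: fit on (samples x features, 0/1 labels), return a
## numeric score per test sample oriented so larger = more likely class 1
.fitScore <- function(classifier, xtr, ytr, xte) {
  ytr <- factor(ytr, levels = c(0L, 1L))
  if (classifier == "logistic") {
    df <- data.frame(xtr, check.names = FALSE)
    fit <- suppressWarnings(stats::glm(ytr ~ ., data = cbind(ytr = ytr, df),
                                       family = stats::binomial()))
    unname(suppressWarnings(
      stats::predict(fit, newdata = data.frame(xte, check.names = FALSE),
                     type = "link")))
  } else if (classifier == "naive_bayes") {
    fit <- e1071::naiveBayes(x = data.frame(xtr, check.names = FALSE),
                             y = ytr)
    pr <- stats::predict(fit, data.frame(xte, check.names = FALSE),
                         type = "raw")
    unname(pr[, "1"])
  } else if (classifier == "svm") {
    fit <- e1071::svm(x = xtr, y = ytr, kernel = "linear", scale = TRUE)
    dv <- attr(stats::predict(fit, xte, decision.values = TRUE),
               "decision.values")
    s <- as.numeric(dv[, 1])
    # decision values are oriented toward the first class named in the
    # "A/B" column label; flip so larger always means class 1
    if (startsWith(colnames(dv)[1], "0")) s <- -s
    s
  } else stop("unknown classifier: ", classifier)
}

## trapezoidal AUC consistent with the rank (Mann-Whitney) definition,
## via pROC; scores oriented so larger = class 1
.auc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Repeated stratified cross-validated response prediction
#'
#' Each repeat draws a stratified `nFolds`-fold partition (each held-out fold
#' is ~1/nFolds of the cohort, i.e. an 80/20 split at the default 5 folds).
#' Within every training portion the pipeline under-samples the majority
#' class, ranks features by class-difference t-test, fits the chosen
#' classifier on the top `nFeatures`, and scores the held-out fold. Feature
#' selection never sees held-out samples. Held-out scores are pooled per
#' repeat into one AUC; the report's mean AUC averages over repeats.
#'
#' @param cohort SummarizedExperiment with assay `"comi"` and
#'   `colData()$label`, or a features x samples matrix plus `labels`.
#' @param classifier `"logistic"`, `"naive_bayes"` or `"svm"`.
#' @param nFeatures features selected per training portion (27 by default,
#'   the marker-panel size this workflow was designed around; tune per
#'   dataset).
#' @param nFolds folds per repeat (5).
#' @param nRepeats repeats (100).
#' @param labels 0/1 outcomes when `cohort` is a bare matrix.
#' @param seed base RNG seed; per-repeat and per-fold seeds derive from it.
#' @return a [PredictionReport-class].
#' @export
crossValidate <- function(cohort, classifier = c("logistic", "naive_bayes",
                                                 "svm"),
                          nFeatures = 27L, nFolds = 5L, nRepeats = 100L,
                          labels = NULL, seed = 1L) {
  classifier <- match.arg(classifier)
  parts <- .cohortParts(cohort, labels)
  m <- parts$m; y <- parts$labels
  if (nFolds < 2L) stop("nFolds must be >= 2")
  if (min(sum(y == 1L), sum(y == 0L)) < nFolds)
    stop("too few samples in the minority class for ", nFolds, " folds")
  nFeatures <- min(nFeatures, nrow(m))
  aucs <- numeric(nRepeats)
  pooledScores <- NULL; pooledLabels <- NULL
  selCount <- integer(nrow(m)); names(selCount) <- rownames(m)
  for (r in seq_len(nRepeats)) {
    folds <- .withSeed(seed + r, .stratifiedFolds(y, nFolds))
    scores <- numeric(length(y)); scored <- logical(length(y))
    for (f in seq_len(nFolds)) {
      te <- which(folds == f); tr <- which(folds != f)
      keep <- tr[undersample(y[tr], seed = seed + r * 131L + f)]
      feats <- selectFeatures(m[, keep, drop = FALSE], nFeatures,
                              labels = y[keep])
      selCount[feats] <- selCount[feats] + 1L
      sc <- .fitScore(classifier,
                      xtr = t(m[feats, keep, drop = FALSE]),
                      ytr = y[keep],
                      xte = t(m[feats, te, drop = FALSE]))
      scores[te] <- sc; scored[te] <- TRUE
    }
    stopifnot(all(scored))
    aucs[r] <- .auc(y, scores)
    pooledScores <- c(pooledScores, scores)
    pooledLabels <- c(pooledLabels, y)
  }
  roc <- pROC::roc(response = pooledLabels, predictor = pooledScores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  rp <- cbind(fpr = rev(1 - roc$specificities),
              tpr = rev(roc$sensitivities))
  topSel <- names(selCount)[.ord(-selCount, names(selCount))]
  new("PredictionReport",
      meanAuc = mean(aucs), aucPerRepeat = aucs, rocPoints = rp,
      selectedFeatures = topSel[seq_len(nFeatures)],
      classifier = classifier, nRepeats = as.integer(nRepeats),
      nFolds = as.integer(nFolds), seed = as.integer(seed))
}

## stratified fold assignment: within each class, shuffle and deal round-robin
.stratifiedFolds <- function(y, nFolds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  folds
}

#' Pearson correlation of features with the binary outcome
#'
#' @param cohort SummarizedExperiment with assay `"comi"` and
#'   `colData()$label`, or a matrix plus `labels`.
#' @param features subset of feature keys (default: all).
#' @param labels 0/1 outcomes when `cohort` is a bare matrix.
#' @return data.frame with columns `pattern_key`, `pearson_r`, `constant`
#'   (TRUE where the feature has zero variance and r is reported as 0).
#' @export
featureOutcomeCorrelation <- function(cohort, features = NULL,
                                      labels = NULL) {
  parts <- .cohortParts(cohort, labels)
  m <- parts$m; y <- parts$labels
  if (is.null(features)) features <- rownames(m)
  miss <- setdiff(features, rownames(m))
  if (length(miss)) stop("unknown features: ", paste(head(miss, 3),
                                                     collapse = ", "))
  r <- numeric(length(features)); const <- logical(length(features))
  for (i in seq_along(features)) {
    v <- m[features[i], ]
    if (stats::sd(v) == 0) {
      r[i] <- 0; const[i] <- TRUE
    } else {
      r[i] <- stats::cor(v, y)
    }
  }
  data.frame(pattern_key = features, pearson_r = r, constant = const,
             stringsAsFactors = FALSE)
}

#' Hypergeometric significance of the overlap of two feature lists
#'
#' Upper-tail hypergeometric p-value of observing at least the actual
#' overlap between two feature lists drawn from a declared universe, used to
#' ask whether independently derived marker lists are consistent.
#'
#' @param listA,listB character vectors (deduplicated internally).
#' @param universeSize size of the feature universe both lists were drawn
#'   from.
#' @return p-value in (0, 1].
#' @export
featureListOverlapP <- function(listA, listB, universeSize) {
  listA <- unique(listA); listB <- unique(listB)
  if (length(listA) > universeSize || length(listB) > universeSize)
    stop("list longer than the declared universe")
  hypergeomOverlapP(length(intersect(listA, listB)),
                    length(listA), length(listB), universeSize)
}
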
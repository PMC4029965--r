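mkCohort <- function(m, labels) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(comi = m),
    colData = S4Vectors::DataFrame(label = as.integer(labels),
                                   row.names = colnames(m)))
}

test_that("feature selection ranks a separating feature first", {
  set.seed(61)
  n0 <- 20L; n1 <- 10L
  labels <- c(rep(0L, n0), rep(1L, n1))
  m <- matrix(rnorm(51 * 30), 51, 30,
              dimnames = list(sprintf("f%02d", 1:51), sprintf("s%02d", 1:30)))
  m["f01", ] <- ifelse(labels == 1L, 1.5 + runif(30), -0.5 - runif(30))
  for (r in 1:20) {
    sub <- sample(30, 24)
    sel <- selectFeatures(m[, sub], 5, labels = labels[sub])
    expect_identical(sel[1], "f01")
  }
})

test_that("selecting all features returns a permutation ordered by the reference t-test", {
  set.seed(62)
  labels <- rep(c(0L, 1L), each = 8)
  m <- matrix(rnorm(10 * 16), 10, 16,
              dimnames = list(sprintf("f%02d", 1:10), sprintf("s%02d", 1:16)))
  sel <- selectFeatures(m, 10, labels = labels)
  expect_setequal(sel, rownames(m))
  pref <- vapply(rownames(m), function(f)
    refWelch(m[f, labels == 1L], m[f, labels == 0L])[["p"]], numeric(1))
  expect_identical(sel, names(sort(pref)))
  expect_error(selectFeatures(m, 11, labels = labels), "exceeds")
  expect_error(selectFeatures(m, 2, labels = rep(0L, 16)), "class")
})

test_that("under-sampling balances classes and keeps every minority sample", {
  labels <- c(rep(1L, 26), rep(0L, 152))
  keep <- undersample(labels, seed = 3)
  expect_length(keep, 52L)
  expect_true(all(which(labels == 1L) %in% keep))
  expect_equal(sum(labels[keep] == 0L), 26L)

  balanced <- rep(c(0L, 1L), each = 10)
  expect_identical(undersample(balanced, seed = 1), seq_along(balanced))

  expect_identical(undersample(labels, seed = 9), undersample(labels, 9))
  expect_false(identical(undersample(labels, seed = 9),
                         undersample(labels, seed = 10)))
  expect_error(undersample(rep(1L, 5)), "both classes")
})

test_that("a deterministic threshold on one feature gives AUC 1 for all classifiers", {
  set.seed(63)
  n <- 60L
  labels <- rep(c(0L, 1L), each = n / 2)
  m <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(sprintf("f%02d", 1:20), sprintf("s%02d", 1:n)))
  m["f01", ] <- ifelse(labels == 1L, 2 + runif(n), -2 - runif(n))
  cohort <- mkCohort(m, labels)
  for (clf in c("logistic", "naive_bayes", "svm")) {
    rep <- crossValidate(cohort, clf, nFeatures = 3, nRepeats = 3, seed = 5)
    expect_equal(meanAuc(rep), 1.0, tolerance = 1e-9,
                 label = paste("classifier", clf))
  }
})

test_that("AUC is invariant to monotone transformation of the scores", {
  set.seed(64)
  y <- rep(c(0, 1), each = 25)
  s <- rnorm(50) + y
  a1 <- comireg:::.auc(y, s)
  a2 <- comireg:::.auc(y, exp(s / 2))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("feature selection depends only on the training portion", {
  set.seed(65)
  n <- 40L
  labels <- rep(c(0L, 1L), each = n / 2)
  m <- matrix(rnorm(30 * n), 30, n,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:n)))
  folds <- comireg:::.withSeed(7, comireg:::.stratifiedFolds(labels, 5))
  train <- which(folds != 1L)
  test <- which(folds == 1L)
  selBefore <- selectFeatures(m[, train], 8, labels = labels[train])
  # shuffle the held-out labels; training-side selection must not move
  labels2 <- labels
  labels2[test] <- sample(labels2[test])
  selAfter <- selectFeatures(m[, train], 8, labels = labels2[train])
  expect_identical(selBefore, selAfter)
})

test_that("fold assignment is stratified and covers every sample", {
  labels <- c(rep(0L, 30), rep(1L, 10))
  folds <- comireg:::.withSeed(11, comireg:::.stratifiedFolds(labels, 5))
  expect_setequal(unique(folds), 1:5)
  for (f in 1:5) {
    expect_equal(sum(folds == f & labels == 1L), 2L)
    expect_equal(sum(folds == f & labels == 0L), 6L)
  }
})

test_that("feature-outcome correlation hits the exact poles and matches the formula", {
  labels <- c(1L, 0L, 1L, 0L, 0L, 1L)
  m <- rbind(asLabel = as.numeric(labels),
             antiLabel = 1 - as.numeric(labels),
             flat = rep(2, 6),
             noise = c(0.3, -1, 2, 0.5, -0.2, 1.1))
  colnames(m) <- paste0("s", 1:6)
  tab <- featureOutcomeCorrelation(mkCohort(m, labels))
  expect_equal(tab$pearson_r[tab$pattern_key == "asLabel"], 1)
  expect_equal(tab$pearson_r[tab$pattern_key == "antiLabel"], -1)
  expect_equal(tab$pearson_r[tab$pattern_key == "flat"], 0)
  expect_true(tab$constant[tab$pattern_key == "flat"])
  # direct formula recomputation
  v <- m["noise", ]; y <- labels
  rManual <- sum((v - mean(v)) * (y - mean(y))) /
    sqrt(sum((v - mean(v))^2) * sum((y - mean(y))^2))
  expect_equal(tab$pearson_r[tab$pattern_key == "noise"], rManual,
               tolerance = 1e-12)
  expect_error(featureOutcomeCorrelation(mkCohort(m, labels), "nope"),
               "unknown")
})

test_that("feature list overlap significance delegates to the hypergeometric tail", {
  idAB <- sprintf("f%02d", 1:5)
  p <- featureListOverlapP(idAB, idAB, universeSize = 100)
  # only one of the C(100,5) draws reaches overlap 5
  expect_equal(p, 1 / choose(100, 5), tolerance = 1e-12)
  expect_lt(p, 1e-3)
  disjoint <- featureListOverlapP(sprintf("a%d", 1:4), sprintf("b%d", 1:6),
                                  universeSize = 500)
  expect_equal(disjoint, 1.0)
  expect_error(featureListOverlapP(sprintf("f%d", 1:20), "x",
                                   universeSize = 10), "universe")
})
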
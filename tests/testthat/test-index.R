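test_that("fold changes follow the paired and unpaired definitions", {
  gn <- c("gA", "gB")
  case <- matrix(c(3, 0, 5, 2), 2, 2, dimnames = list(gn, c("c1", "c2")))
  ctrl <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(gn, c("n1", "n2")))
  fc <- foldChange(case, ctrl, paired = TRUE)
  expect_equal(unname(fc["gA"]), 3.0)  # mean of (2, 4)

  expect_equal(foldChange(case, case, paired = TRUE),
               setNames(c(0, 0), gn))

  # unpaired with unequal sample counts = difference of means
  ctrl3 <- cbind(ctrl, n3 = c(4, 0))
  fc2 <- foldChange(case, ctrl3, paired = FALSE)
  expect_equal(unname(fc2["gA"]), mean(case["gA", ]) - mean(ctrl3["gA", ]),
               tolerance = 1e-12)

  rownames(ctrl) <- c("gA", "gX")
  expect_error(foldChange(case, ctrl), "gene ids differ")
  rownames(ctrl) <- gn
  expect_error(foldChange(case, ctrl[, 1, drop = FALSE], paired = TRUE),
               "equal sample counts")
})

test_that("the CoMi index reproduces the Welch contrast on a worked example", {
  pat <- onePattern(paste0("t", 1:3), paste0("n", 1:3))
  v <- setNames(c(1, 2, 3, -1, 0, 1), c(paste0("t", 1:3), paste0("n", 1:3)))
  idx <- comiIndex(pat, v)
  expect_equal(idx$statistic, 2 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(idx$statistic, 2.449490, tolerance = 1e-6)
  expect_equal(idx$pValue, 0.0705, tolerance = 1e-3)
  ref <- refWelch(v[1:3], v[4:6])
  expect_equal(idx$statistic, ref[["statistic"]], tolerance = 1e-10)
  expect_equal(idx$pValue, ref[["p"]], tolerance = 1e-10)
  expect_equal(idx$direction, "target_up")
})

test_that("the CoMi index is antisymmetric and handles degenerate inputs", {
  set.seed(5)
  tg <- paste0("t", 1:4); ng <- paste0("n", 1:7)
  v <- setNames(rnorm(11), c(tg, ng))
  a <- comiIndex(onePattern(tg, ng), v)
  b <- comiIndex(onePattern(ng, tg), v)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  expect_equal(a$pValue, b$pValue, tolerance = 1e-12)

  # all equal values: null direction
  z <- setNames(rep(2, 11), c(tg, ng))
  idx <- comiIndex(onePattern(tg, ng), z)
  expect_equal(idx$statistic, 0)
  expect_equal(idx$pValue, 1)
  expect_equal(idx$direction, "null")

  # both subsets constant but unequal: capped, never infinite
  z2 <- setNames(c(rep(5, 4), rep(1, 7)), c(tg, ng))
  idx2 <- comiIndex(onePattern(tg, ng), z2)
  expect_equal(idx2$statistic, 1e6)
  expect_true(idx2$pValue > 0)
  expect_true(idx2$degenerate)

  # singleton target subset: statistic reported, p-value 1, flagged
  v1 <- setNames(c(10, rnorm(7)), c("t1", ng))
  idx3 <- comiIndex(onePattern("t1", ng), v1)
  expect_true(is.finite(idx3$statistic))
  expect_equal(idx3$pValue, 1)
  expect_true(idx3$degenerate)

  expect_error(comiIndex(onePattern(tg, ng), v[-1]), "missing")
})

test_that("the statistic is location invariant and scale invariant", {
  set.seed(8)
  tg <- paste0("t", 1:5); ng <- paste0("n", 1:9)
  v <- setNames(rnorm(14), c(tg, ng))
  pat <- onePattern(tg, ng)
  base <- comiIndex(pat, v)
  shifted <- comiIndex(pat, v + 7.5)
  scaled <- comiIndex(pat, v * 3.2)
  expect_equal(shifted$statistic, base$statistic, tolerance = 1e-10)
  expect_equal(shifted$pValue, base$pValue, tolerance = 1e-10)
  expect_equal(scaled$statistic, base$statistic, tolerance = 1e-10)
  expect_equal(scaled$pValue, base$pValue, tolerance = 1e-10)
})

test_that("per-sample values separate clearly shifted targets", {
  tg <- c("t1", "t2"); ng <- c("n1", "n2")
  v <- setNames(c(10, 10 + 1e-6, 2, 2 - 1e-6), c(tg, ng))
  idx <- comiIndex(onePattern(tg, ng), v)
  expect_gt(idx$statistic, 100)
  expect_equal(idx$direction, "target_up")
})

test_that("profiles drop uncovered patterns with a warning and error when empty", {
  ann <- generateAnnotation(tinySpec(), seed = 2)
  pats <- discoverPatterns(ann$targets, ann$sets, ann$universe, alpha = 0.2)
  set.seed(1)
  v <- setNames(rnorm(length(ann$universe)), ann$universe)
  prof <- computeProfile(pats, v, mode = "per_sample")
  expect_equal(length(prof), length(pats))

  # remove one pattern's gene from the input
  drop_gene <- pats@targetGenes[[1]][1]
  v2 <- v[setdiff(names(v), drop_gene)]
  expect_warning(prof2 <- computeProfile(pats, v2), "dropped")
  expect_lt(length(prof2), length(pats))

  expect_error(computeProfile(pats, v[1:2]), "no pattern")
  expect_error(computeProfile(pats[0], v), "empty pattern set")
})

test_that("a planted repression yields the most negative profile statistic", {
  sp <- tinySpec(plantedEffects = data.frame(
    mirna = "mir-001", term = "term-001", shift = -1.5,
    condition = "disease", stringsAsFactors = FALSE))
  hits <- 0L
  nRuns <- 60L
  ann <- generateAnnotation(sp, seed = 500)
  pats <- discoverPatterns(ann$targets, ann$sets, ann$universe, alpha = 0.05)
  expect_true("mir-001|term-001" %in% patternKeys(pats))
  for (r in seq_len(nRuns)) {
    co <- generateDiseaseCohort(sp, ann, seed = 1000 + r)
    fc <- foldChange(co$case, co$control, paired = TRUE)
    prof <- computeProfile(pats, fc, conditionId = "disease")
    s <- statistics(prof)
    if (names(which.min(s)) == "mir-001|term-001") hits <- hits + 1L
  }
  expect_gte(hits / nRuns, 0.95)
})

test_that("per-sample CoMi matrices line up patterns x samples", {
  ann <- generateAnnotation(tinySpec(), seed = 4)
  pats <- discoverPatterns(ann$targets, ann$sets, ann$universe, alpha = 0.2)
  set.seed(2)
  m <- matrix(rnorm(length(ann$universe) * 3), ncol = 3,
              dimnames = list(ann$universe, paste0("s", 1:3)))
  cm <- comiMatrix(pats, m, labels = c(1L, 0L, 0L))
  expect_equal(dim(cm), c(length(pats), 3L))
  expect_identical(rownames(cm), patternKeys(pats))
  # column j equals the per-sample profile of sample j
  p2 <- computeProfile(pats, setNames(m[, 2], rownames(m)),
                       mode = "per_sample")
  expect_equal(unname(SummarizedExperiment::assay(cm)[, 2]),
               unname(statistics(p2)), tolerance = 1e-12)
})
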
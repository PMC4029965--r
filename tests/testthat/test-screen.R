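test_that("signatures take the k extremes with deterministic tie-breaks", {
  stats <- mkStats(seq(7, -7))   # 15 statistics, descending 7..-7
  prof <- statProfile(stats)
  sig <- makeSignature(prof, 5)
  expect_equal(upTags(sig), names(sort(stats, decreasing = TRUE))[1:5])
  expect_equal(downTags(sig), names(sort(stats))[1:5])
  expect_length(intersect(upTags(sig), downTags(sig)), 0L)

  expect_silent(makeSignature(prof, floor(15 / 3)))
  expect_error(makeSignature(prof, floor(15 / 3) + 1), "k must lie")
  expect_error(makeSignature(prof, 4), "k must lie")

  # ties at the boundary resolve identically across calls
  tied <- statProfile(mkStats(c(rep(1, 8), rep(-1, 8))))
  s1 <- makeSignature(tied, 5); s2 <- makeSignature(tied, 5)
  expect_identical(upTags(s1), upTags(s2))
  expect_identical(downTags(s1), downTags(s2))
  expect_length(intersect(upTags(s1), downTags(s1)), 0L)
})

test_that("connectivity scores hit the exact-agreement and exact-reversal poles", {
  set.seed(31)
  stats <- mkStats(rnorm(18))
  disease <- statProfile(stats, "disease")
  sig <- makeSignature(disease, 5)
  expect_equal(connectivityScore(sig, disease, disease), 1)
  inverted <- statProfile(-stats, "drug")
  expect_equal(connectivityScore(sig, disease, inverted), -1)

  # unscorable when too few shared patterns
  tiny <- statProfile(stats[1:2], "drug")
  expect_warning(s <- connectivityScore(sig, disease, tiny), "unscorable")
  expect_true(is.na(s))
})

test_that("random drug statistics give near-zero mean connectivity", {
  set.seed(17)
  stats <- mkStats(rnorm(30))
  disease <- statProfile(stats, "disease")
  sig <- makeSignature(disease, 6)
  rhos <- replicate(1000, {
    connectivityScore(sig, disease, statProfile(mkStats(rnorm(30)), "d"))
  })
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("library ranking is ascending, deterministic, and places the inverter first", {
  set.seed(23)
  stats <- mkStats(rnorm(18))
  disease <- statProfile(stats, "disease")
  sig <- makeSignature(disease, 5)
  mkInst <- function(id, st, pos = FALSE)
    new("DrugInstance", instanceId = id, drugName = id, cellLine = "x",
        concentration = "1", profile = statProfile(st, id),
        isPositive = pos)
  inv <- mkInst("inverter", -stats, pos = TRUE)
  decoys <- lapply(1:6, function(i)
    mkInst(sprintf("decoy%d", i), mkStats(rnorm(18))))
  lib <- new("DrugLibrary", instances = c(list(inv), decoys))
  ranked <- rankLibrary(sig, disease, lib)
  expect_equal(instanceIds(ranked)[1], "inverter")
  expect_false(is.unsorted(ranked@scores))
  expect_equal(ranked@positivePositions, 1L)

  # invariance to library input order
  lib2 <- new("DrugLibrary", instances = rev(instances(lib)))
  ranked2 <- rankLibrary(sig, disease, lib2)
  expect_identical(instanceIds(ranked), instanceIds(ranked2))
})

test_that("the KS score reproduces hand-enumerated toys", {
  expect_equal(ksScore(c(1, 2), N = 10), 0.8, tolerance = 1e-12)
  expect_equal(ksScore(c(9, 10), N = 10), -0.9, tolerance = 1e-12)
  expect_error(ksScore(c(1, 1), N = 10), "duplicate")
  expect_error(ksScore(c(0, 2), N = 10), "outside")
  expect_error(ksScore(integer(0), N = 10), "at least one")
})

test_that("the KS score agrees with the running-walk oracle on all small cases", {
  for (N in c(8L, 10L)) {
    for (t in c(1L, 2L, 3L)) {
      combos <- utils::combn(N, t)
      for (j in seq_len(ncol(combos))) {
        pos <- combos[, j]
        expect_equal(ksScore(pos, N = N), walkKs(pos, N),
                     tolerance = 1e-12,
                     label = paste("N", N, "pos", paste(pos, collapse = ",")))
      }
    }
  }
})

test_that("top-concentrated positions score positive and flip sign under reversal", {
  # every 2-subset of the top half scores positive; its mirror image at the
  # bottom of the list scores negative
  N <- 10L
  combos <- utils::combn(5L, 2L)
  for (j in seq_len(ncol(combos))) {
    pos <- combos[, j]
    fwd <- ksScore(pos, N = N)
    bwd <- ksScore(sort(N + 1L - pos), N = N)
    expect_gt(fwd, 0)
    expect_lt(bwd, 0)
  }
})

test_that("DSP p-values are seeded, floored, and degenerate-safe", {
  res <- dspPvalue(list(positions = 1:10, N = 100), nPerm = 1000, seed = 5)
  expect_equal(dspP(res), 1 / 1001, tolerance = 1e-12)  # max attainable KS
  expect_equal(dspKs(res), ksScore(1:10, N = 100))

  res2 <- dspPvalue(list(positions = 1:10, N = 100), nPerm = 1000, seed = 5)
  expect_identical(dspP(res), dspP(res2))

  expect_warning(
    resAll <- dspPvalue(list(positions = 1:4, N = 4), nPerm = 100, seed = 1),
    "no null variability")
  expect_equal(dspP(resAll), 1)
})

test_that("a sweep over one k matches a direct dspPvalue call", {
  set.seed(41)
  stats <- mkStats(rnorm(24))
  disease <- statProfile(stats, "disease")
  mkInst <- function(id, st, pos = FALSE)
    new("DrugInstance", instanceId = id, drugName = id, cellLine = "x",
        concentration = "1", profile = statProfile(st, id),
        isPositive = pos)
  lib <- new("DrugLibrary", instances = c(
    list(mkInst("pos1", -stats, TRUE)),
    lapply(1:8, function(i) mkInst(sprintf("d%d", i),
                                   mkStats(rnorm(24))))))
  sw <- dspSweep(disease, lib, kValues = 6L, nPerm = 200, seed = 9)
  sig <- makeSignature(disease, 6L)
  ranked <- rankLibrary(sig, disease, lib)
  direct <- dspPvalue(ranked, nPerm = 200, seed = 9 + 1L)
  tab <- sweepTable(sw)
  expect_equal(tab$ks, dspKs(direct), tolerance = 1e-12)
  expect_equal(tab$p, dspP(direct), tolerance = 1e-12)
  expect_error(dspSweep(disease, lib, kValues = integer(0)), "empty k")
})

test_that("discriminative features collect the top signatures' tags", {
  set.seed(47)
  stats <- mkStats(rnorm(30))
  disease <- statProfile(stats, "disease")
  sig5 <- makeSignature(disease, 5)
  sig7 <- makeSignature(disease, 7)
  sweep <- new("DSPSweep",
               table = data.frame(k = c(5L, 7L), ks = c(0.9, -0.2),
                                  p = c(0.001, 0.6)),
               signatures = list(sig5, sig7),
               summary = c(q1 = 0, median = 0.35, q3 = 0.9))
  top <- discriminativeFeatures(sweep, topFraction = 0.5)
  expect_setequal(top, c(upTags(sig5), downTags(sig5)))
  all2 <- discriminativeFeatures(sweep, topFraction = 1.0)
  expect_setequal(all2, unique(c(upTags(sig5), downTags(sig5),
                                 upTags(sig7), downTags(sig7))))
  expect_error(discriminativeFeatures(sweep, 0), "topFraction")
})
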
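test_that("open-set splits are class-disjoint with floor arithmetic", {
  fed <- tinyFederation(61, nClasses = c(10, 12), samplesPerClass = 2)
  sp <- splitOpenSet(fed, 0.8, seed = 61)
  tr <- clientList(sp$train)[[1]]; te <- clientList(sp$test)[[1]]
  expect_length(unique(classLabels(tr)), 8)
  expect_length(unique(classLabels(te)), 2)
  expect_length(intersect(classLabels(tr), classLabels(te)), 0)
  ## all samples of a test class are reserved
  expect_equal(sum(table(classLabels(te))), 2 * 2)
  ## reproducible under the seed
  sp2 <- splitOpenSet(fed, 0.8, seed = 61)
  expect_identical(sp$assignment, sp2$assignment)
  ## the full-scale arithmetic: 636 classes -> 508 train / 128 test
  expect_equal(trainClassCounts(636), 508)
  expect_equal(636 - trainClassCounts(636), 128)
  ## a client that cannot form impostor pairs is rejected
  tiny <- tinyFederation(62, nClasses = c(4, 4), samplesPerClass = 2)
  expect_error(splitOpenSet(tiny, 0.8, seed = 1), "test class")
})

test_that("pair scoring partitions all C(n,2) pairs by label", {
  E <- fedvein:::withSeed(63, matrix(rnorm(4 * 8), 4, 8))
  sc <- scoreVerificationPairs(E, c("a", "a", "b", "b"))
  expect_length(genuineScores(sc), 2)
  expect_length(impostorScores(sc), 4)
  ## identical embeddings -> every score is 1
  E1 <- matrix(rep(1, 3 * 8), 3, 8, byrow = TRUE)
  sc1 <- scoreVerificationPairs(E1, c("a", "a", "b"))
  expect_equal(c(genuineScores(sc1), impostorScores(sc1)), rep(1, 3))
  ## counts are invariant to sample order
  ord <- c(3, 1, 4, 2)
  sc2 <- scoreVerificationPairs(E[ord, ], c("a", "a", "b", "b")[ord])
  expect_length(genuineScores(sc2), 2)
  expect_length(impostorScores(sc2), 4)
  ## bookkeeping on larger random instances
  set.seed(64)
  for (i in 1:5) {
    n <- sample(5:20, 1)
    labs <- sample(letters[1:4], n, replace = TRUE)
    if (length(unique(labs)) < 2 || max(table(labs)) < 2) next
    sc3 <- scoreVerificationPairs(matrix(rnorm(n * 6), n, 6), labs)
    expect_equal(length(genuineScores(sc3)) + length(impostorScores(sc3)),
                 choose(n, 2))
    expect_equal(length(genuineScores(sc3)),
                 sum(choose(table(labs), 2)))
  }
})

test_that("FAR/FRR at a threshold follow the accept-on-tie rule", {
  sc <- scoresOf(c(0.9, 0.8), c(0.3, 0.7))
  ## enumerating the four comparisons: at 0.75 no impostor is accepted and
  ## no genuine rejected; at 0.5 exactly one impostor (0.7) is accepted
  expect_equal(farFrrAt(sc, 0.75), c(FAR = 0, FRR = 0))
  expect_equal(farFrrAt(sc, 0.5), c(FAR = 50, FRR = 0))
  expect_equal(farFrrAt(sc, -2), c(FAR = 100, FRR = 0))
  expect_equal(farFrrAt(sc, 2), c(FAR = 0, FRR = 100))
  ## a tie at the threshold counts as accept
  expect_equal(farFrrAt(sc, 0.7), c(FAR = 50, FRR = 0))
  ## monotone sweep
  thr <- seq(-1, 1, by = 0.05)
  rates <- vapply(thr, function(t) farFrrAt(sc, t), numeric(2))
  expect_true(all(diff(rates["FAR", ]) <= 0))
  expect_true(all(diff(rates["FRR", ]) >= 0))
})

test_that("EER has its exact extreme identities and matches brute force", {
  ## perfect separation
  expect_equal(eer(scoresOf(c(0.8, 0.9, 0.95), c(0.1, 0.2))), 0)
  ## identical score multisets -> exactly 50
  s <- c(0.1, 0.4, 0.7)
  expect_equal(eer(scoresOf(s, s)), 50)
  set.seed(65)
  for (i in 1:100) {
    nG <- sample(3:30, 1); nI <- sample(3:30, 1)
    gen <- runif(nG, -0.2, 1); imp <- runif(nI, -1, 0.6)
    val <- eer(scoresOf(gen, imp))
    ref <- eerOracle(gen, imp)
    expect_lt(abs(val - ref), 100 / min(nG, nI) + 1e-9)
    expect_gte(val, 0); expect_lte(val, 50 + 1e-9)
  }
})

test_that("TAR at fixed FAR matches the conservative sweep oracle", {
  expect_equal(suppressWarnings(
    tarAtFar(scoresOf(c(0.8, 0.9), c(0.1, 0.2)))), 100)
  ## all scores identical: no threshold both separates and accepts
  expect_equal(suppressWarnings(tarAtFar(scoresOf(c(0.5, 0.5), c(0.5, 0.5)))), 0)
  set.seed(66)
  for (i in 1:100) {
    nG <- sample(5:40, 1); nI <- sample(100, 1) + 100
    gen <- rnorm(nG, 0.5, 0.2); imp <- rnorm(nI, -0.2, 0.2)
    gen <- pmin(pmax(gen, -1), 1); imp <- pmin(pmax(imp, -1), 1)
    sc <- scoresOf(gen, imp)
    expect_equal(suppressWarnings(tarAtFar(sc)), tarOracle(gen, imp))
  }
  expect_error(tarAtFar(scoresOf(0.5, numeric(0))), "impostor")
})

test_that("rank statistics are invariant to monotone score transforms", {
  set.seed(67)
  gen <- runif(25, -0.5, 1); imp <- runif(40, -1, 0.7)
  mono <- function(x) x^3          # strictly increasing on [-1, 1]
  e1 <- eer(scoresOf(gen, imp))
  e2 <- eer(scoresOf(mono(gen), mono(imp)))
  expect_equal(e1, e2, tolerance = 1e-6)
  t1 <- suppressWarnings(tarAtFar(scoresOf(gen, imp)))
  t2 <- suppressWarnings(tarAtFar(scoresOf(mono(gen), mono(imp))))
  expect_equal(t1, t2)
})

test_that("report arithmetic reproduces means and relative changes", {
  tab <- data.frame(dataset = c("d1", "d2", "d3"),
                    eer = c(1, 2, 3), tar = c(90, 95, 100))
  out <- summarizeVerification(tab)
  expect_equal(out$table$eer[4], 2)
  expect_equal(out$table$tar[4], 95)
  expect_equal(relReduction(0.5, 5.11), (5.11 - 0.5) / 5.11 * 100)
  expect_equal(relGain(3, 3), 0)
  ref <- list(other = data.frame(dataset = c("d1", "d2", "d3"),
                                 eer = c(2, 4, 6), tar = c(80, 85, 90)))
  cmp <- summarizeVerification(tab, ref)$comparison
  expect_equal(cmp$eer_reduction, relReduction(2, 4))
  expect_equal(cmp$tar_gain, relGain(95, 85))
})

test_that("dataset bookkeeping reproduces image totals and splits", {
  bk <- federationBookkeeping(c(220, 1680), c(2, 10))
  expect_equal(bk$n_images, c(440, 16800))
  expect_equal(bk$train_classes, c(176, 1344))
  expect_equal(bk$test_classes, c(44, 336))
})

test_that("end-to-end open-set evaluation produces per-client rows and a mean", {
  fed <- tinyFederation(71, nClasses = c(10, 10), samplesPerClass = 2)
  sp <- splitOpenSet(fed, 0.8, seed = 71)
  enc <- referenceEncoder(71, d = 16, inputShape = c(32, 32))
  rep1 <- suppressWarnings(evaluateOpenSet(enc, sp$test))
  expect_equal(rep1$client_id, c("client1", "client2", "mean"))
  expect_equal(rep1$eer[3], mean(rep1$eer[1:2]))
  expect_true(all(rep1$eer >= 0 & rep1$eer <= 50 + 1e-9))
  expect_true(all(rep1$tar >= 0 & rep1$tar <= 100))
  ## deterministic given the encoder and split
  rep2 <- suppressWarnings(evaluateOpenSet(enc, sp$test))
  expect_identical(rep1, rep2)
  ## contrast re-rendering changes the scores but keeps the contract
  rep3 <- suppressWarnings(evaluateOpenSet(enc, sp$test, contrastLevel = 0.6))
  expect_equal(dim(rep3), dim(rep1))
})
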
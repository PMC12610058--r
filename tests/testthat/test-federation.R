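test_that("model aggregation is a normalized sample-weighted mean", {
  v <- fedvein:::withSeed(1, rnorm(20))
  ## idempotence
  expect_equal(aggregateModels(list(v, v, v), c(5, 1, 3)), v)
  ## two clients, counts 1:3 -> 0.75 of the nonzero model
  expect_equal(aggregateModels(list(0 * v, v), c(1, 3)), 0.75 * v)
  ## weights sum to one for arbitrary positive counts
  set.seed(2)
  for (i in 1:10) {
    counts <- runif(4, 0.5, 20)
    agg <- aggregateModels(list(v, v, v, v), counts)
    expect_equal(agg, v)
  }
  ## affine equivariance: shifting every model shifts the aggregate
  ws <- lapply(1:3, function(i) fedvein:::withSeed(i, rnorm(20)))
  base <- aggregateModels(ws, c(2, 3, 5))
  shifted <- aggregateModels(lapply(ws, function(w) w + 7), c(2, 3, 5))
  expect_equal(shifted, base + 7)
  expect_error(aggregateModels(list(v, v[-1]), c(1, 1)), "shape")
  expect_error(aggregateModels(list(v, v), c(1, 0)), "positive")
  ## literal class-count weights are available for study
  expect_equal(aggregateModels(list(v, v), c(10, 30), literal = TRUE,
                               nTotalClasses = 50), v * 40 / 50)
})

test_that("prototype aggregation follows the ownership-weighted rule", {
  d <- 6
  pA <- makePrototypes(d, c("x", "s"), client = "A", seed = 3, nSamples = 4)
  pB <- makePrototypes(d, c("y", "s"), client = "B", seed = 4, nSamples = 4)
  agg <- aggregatePrototypes(list(pA, pB))
  ## count conservation
  expect_equal(ncol(prototypeVectors(agg)), 4)
  ## single-owner classes pass through exactly
  expect_identical(prototypeVectors(agg)[, 1], prototypeVectors(pA)[, 1])
  expect_identical(prototypeVectors(agg)[, 3], prototypeVectors(pB)[, 1])
  ## 50/50 shared class: literal rule gives (p + q) / 4
  p <- prototypeVectors(pA)[, 2]; q <- prototypeVectors(pB)[, 2]
  own <- prototypeOwnership(agg)
  sharedCols <- which(own$class_label == "s")
  for (j in sharedCols)
    expect_equal(prototypeVectors(agg)[, j], (p + q) / 4)
  ## normalized variant: weights sum to 1 -> (p + q) / 2
  agg2 <- aggregatePrototypes(list(pA, pB), normalized = TRUE)
  expect_equal(prototypeVectors(agg2)[, sharedCols[1]], (p + q) / 2)
  ## duplicate upload is rejected
  expect_error(aggregatePrototypes(list(pA, pA)), "duplicate")
})

test_that("a zero learning rate is a fixed point of the client update", {
  fed <- tinyFederation(41, nClasses = c(3, 3))
  cfg <- federationConfig(nRounds = 1, localEpochs = 1, batchSize = 4,
                          lr = 0, momentum = 0, d = 16, seed = 41)
  cl <- clientList(fed)[[1]]
  state <- fedvein:::initClientState(cl, cfg)
  enc <- referenceEncoder(1, d = 16, inputShape = c(32, 32))
  omega <- encoderParameters(enc)
  up <- clientUpdate(state, enc, omega, NULL, cfg)
  expect_equal(up$omega, omega)
  ## prototypes equal those of the unchanged encoder
  ref <- computePrototypes(enc, state$client)
  expect_equal(prototypeVectors(up$prototypes), prototypeVectors(ref))
  expect_error(federationConfig(localEpochs = 0), "localEpochs")
})

test_that("federated runs are deterministic and conserve structure", {
  fed <- tinyFederation(43, nClasses = c(3, 3), samplesPerClass = 3)
  cfg <- federationConfig(nRounds = 2, localEpochs = 1, batchSize = 4,
                          lr = 0.02, d = 16, seed = 43)
  run1 <- runFederation(fed, cfg)
  run2 <- runFederation(fed, cfg)
  expect_identical(run1$history, run2$history)
  expect_identical(encoderParameters(run1$encoder),
                   encoderParameters(run2$encoder))
  ## prototype count equals the total class count every round
  expect_equal(ncol(prototypeVectors(run1$prototypes)), 6)
  expect_equal(nrow(run1$history), 2 * 2)
  ## the local head never crosses the wire: uploaded state is encoder-sized
  expect_length(encoderParameters(run1$encoder),
                length(encoderParameters(
                  referenceEncoder(1, d = 16, inputShape = c(32, 32)))))
  ## per-client heads remain distinct, sized to their class counts
  for (st in run1$clientStates)
    expect_equal(ncol(st$Wk), length(st$labels))
})

test_that("round one bootstraps without prototypes, later rounds expand", {
  fed <- tinyFederation(47, nClasses = c(3, 4), samplesPerClass = 2)
  cfg <- federationConfig(nRounds = 1, localEpochs = 1, batchSize = 4,
                          lr = 0.02, d = 16, seed = 47)
  cl <- clientList(fed)[[1]]
  state <- fedvein:::initClientState(cl, cfg)
  enc <- referenceEncoder(2, d = 16, inputShape = c(32, 32))
  ## bootstrap: no prototypes -> the expansion is just Wk
  ewm <- expandWeightMatrix(state$Wk, state$labels, clientId(cl), NULL)
  expect_equal(ncol(weightMatrix(ewm)), 3)
  ## after one round the aggregated set covers all 7 classes, so another
  ## client's expansion has 7 columns (4 local + 3 prototype)
  run <- runFederation(fed, cfg)
  st2 <- run$clientStates[[2]]
  ewm2 <- expandWeightMatrix(st2$Wk, st2$labels, "client2", run$prototypes)
  expect_equal(ncol(weightMatrix(ewm2)), 7)
  expect_equal(sum(columnMap(ewm2)$is_local), 4)
})

test_that("single-client federation reduces to local margin training", {
  fed1 <- tinyFederation(53, nClasses = 4, samplesPerClass = 2)
  cfg <- federationConfig(nRounds = 2, localEpochs = 1, batchSize = 4,
                          lr = 0.02, d = 16, seed = 53)
  run <- runFederation(fed1, cfg)
  loc <- runLocalBaseline(fed1, cfg)
  expect_equal(run$history$loss, loc$history$loss)
  expect_equal(encoderParameters(run$encoder),
               encoderParameters(loc$encoders[[1]]))
})

test_that("exclude_own distribution strips a client's own prototypes", {
  d <- 6
  pA <- makePrototypes(d, c("x", "y"), client = "A", seed = 5)
  pB <- makePrototypes(d, "z", client = "B", seed = 6)
  global <- aggregatePrototypes(list(pA, pB))
  toA <- fedvein:::distributeTo(global, "A", "exclude_own")
  expect_equal(prototypeOwnership(toA)$client_id, "B")
  toAll <- fedvein:::distributeTo(global, "A", "all")
  expect_equal(ncol(prototypeVectors(toAll)), 3)
})

test_that("communication cost accounting matches the closed forms", {
  cc <- communicationCost(100, d = 512)
  expect_equal(cc$upload[1], 100 * 512 / 2^20)
  expect_equal(cc$download[1], 100 * 512 / 2^20)
  cc0 <- communicationCost(c(10, 20), d = 0)
  expect_equal(cc0$upload, rep(0, 3))
  expect_equal(cc0$download, rep(0, 3))
  ## exclude_own subtracts the client's own block from the download
  cc2 <- communicationCost(c(100, 50), d = 512,
                           distribution = "exclude_own")
  expect_equal(cc2$download[1:2], c(50, 100) * 512 / 2^20)
  expect_equal(trainClassCounts(c(636, 10)), c(508, 8))
})
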
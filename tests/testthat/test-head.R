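test_that("weight matrix expansion places blocks in client order", {
  d <- 8
  Wk <- fedvein:::withSeed(1, matrix(rnorm(d * 5), d, 5))
  ## single client: expansion is the identity
  e0 <- expandWeightMatrix(Wk, paste0("k", 1:5), "b", NULL)
  expect_identical(weightMatrix(e0), Wk)
  expect_true(all(columnMap(e0)$is_local))
  ## three clients with block widths 3 / 5 / 2, local client in the middle
  pA <- makePrototypes(d, paste0("a", 1:3), client = "a", seed = 2)
  pC <- makePrototypes(d, paste0("c", 1:2), client = "c", seed = 3)
  protos <- aggregatePrototypes(list(pA, pC))
  ewm <- expandWeightMatrix(Wk, paste0("k", 1:5), "b", protos)
  expect_equal(ncol(weightMatrix(ewm)), 10)
  expect_equal(columnMap(ewm)$client_id,
               c(rep("a", 3), rep("b", 5), rep("c", 2)))
  expect_equal(columnMap(ewm)$is_local,
               c(rep(FALSE, 3), rep(TRUE, 5), rep(FALSE, 2)))
  ## prototype columns are bitwise the server-sent vectors
  expect_identical(weightMatrix(ewm)[, 1:3], prototypeVectors(pA))
  expect_identical(weightMatrix(ewm)[, 9:10], prototypeVectors(pC))
  expect_identical(weightMatrix(ewm)[, 4:8], Wk)
  ## the client's own prototypes are dropped from the expansion
  pB <- makePrototypes(d, paste0("k", 1:5), client = "b", seed = 4)
  ewm2 <- expandWeightMatrix(Wk, paste0("k", 1:5), "b",
                             aggregatePrototypes(list(pA, pB, pC)))
  expect_equal(ncol(weightMatrix(ewm2)), 10)
  ## dimension mismatch is rejected
  expect_error(expandWeightMatrix(matrix(0, 4, 2), c("x", "y"), "b", protos),
               "dimension")
  expect_error(expandWeightMatrix(Wk, c("k1", "k1", "k3", "k4", "k5"),
                                  "b", NULL), "duplicate")
})

test_that("similarity entries are cosines in [-1, 1]", {
  d <- 8
  W <- fedvein:::withSeed(5, matrix(rnorm(d * 10), d, 10))
  Wn <- fedvein:::l2NormalizeCols(W)
  ## an embedding equal to a column scores 1 there
  S <- similarityMatrix(rbind(3 * Wn[, 4]), W)
  expect_equal(S[1, 4], 1)
  ## orthogonal pair scores 0
  U <- cbind(c(1, rep(0, 7)), c(0, 1, rep(0, 6)))
  expect_equal(similarityMatrix(rbind(U[, 1]), U)[1, 2], 0)
  E <- fedvein:::withSeed(6, matrix(rnorm(4 * d), 4, d))
  S2 <- similarityMatrix(E, W)
  expect_equal(dim(S2), c(4, 10))
  expect_true(all(S2 >= -1 - 1e-12 & S2 <= 1 + 1e-12))
})

test_that("quality margins interpolate between angular and additive forms", {
  expect_equal(marginsFromQuality(0, 0.4), list(g_angle = 0, g_add = 0.4))
  expect_equal(marginsFromQuality(-1, 0.4), list(g_angle = 0.4, g_add = 0))
  expect_equal(marginsFromQuality(1, 0.4), list(g_angle = -0.4, g_add = 0.8))
  expect_error(marginsFromQuality(1.5), "Qhat")
})

test_that("target logit evaluates its closed forms", {
  ## Qhat = 0 reduction: s (cos - m)
  expect_equal(targetLogit(0.9, 0, marginParams(0.4, 64)), 64 * (0.9 - 0.4))
  ## zero margin: plain scaled cosine, exactly
  cosv <- seq(-0.99, 0.99, by = 0.2)
  expect_equal(targetLogit(cosv, 0.3, marginParams(0, 16)), 16 * cosv,
               tolerance = 1e-6)
  ## Qhat = -1: pure angular margin, s cos(theta + m)
  th <- 60 * pi / 180
  expect_equal(targetLogit(cos(th), -1, marginParams(0.4, 16)),
               16 * cos(th + 0.4), tolerance = 1e-6)
  ## literal affine reading
  expect_equal(targetLogit(0.5, -1, marginParams(0.4, 16, literalEq13 = TRUE)),
               16 * (0.5 + 0.4 - 0))
})

test_that("loss equals an independent log-sum-exp oracle on random instances", {
  set.seed(42)
  for (rep in 1:100) {
    d <- 6; n <- 5; nLocal <- 3; nProto <- 5
    Z <- matrix(rnorm(n * d), n, d)
    Wk <- matrix(rnorm(d * nLocal), d, nLocal)
    protos <- makePrototypes(d, paste0("p", seq_len(nProto)), seed = rep)
    ewm <- expandWeightMatrix(Wk, paste0("L", seq_len(nLocal)), "me", protos)
    labels <- sample(paste0("L", seq_len(nLocal)), n, replace = TRUE)
    Qhat <- runif(n, -1, 1)
    params <- marginParams(0.4, 12)
    res <- fedpsfvLoss(Z, ewm, labels, Qhat, params)
    ## oracle: assemble the logit matrix independently and run plain CE
    En <- fedvein:::l2NormalizeRows(Z)
    Wn <- fedvein:::l2NormalizeCols(weightMatrix(ewm))
    C <- En %*% Wn
    tcol <- match(labels, columnMap(ewm)$class_label)
    L <- params$s * C
    for (i in 1:n) L[i, tcol[i]] <- targetLogit(C[i, tcol[i]], Qhat[i], params)
    expect_equal(res$loss, ceOracle(L, tcol), tolerance = 1e-6)
  }
})

test_that("loss gradients match central finite differences", {
  set.seed(7)
  d <- 6; n <- 4; nLocal <- 3
  Z <- matrix(rnorm(n * d), n, d)
  Wk <- matrix(rnorm(d * nLocal), d, nLocal)
  protos <- makePrototypes(d, c("p1", "p2"), seed = 8)
  labels <- sample(paste0("L", 1:nLocal), n, replace = TRUE)
  Qhat <- runif(n, -0.9, 0.9)
  params <- marginParams(0.4, 12)
  lossAt <- function(Zv, Wv) {
    ewm <- expandWeightMatrix(matrix(Wv, d, nLocal), paste0("L", 1:nLocal),
                              "me", protos)
    fedpsfvLoss(matrix(Zv, n, d), ewm, labels, Qhat, params)$loss
  }
  ewm0 <- expandWeightMatrix(Wk, paste0("L", 1:nLocal), "me", protos)
  res <- fedpsfvLoss(Z, ewm0, labels, Qhat, params)
  eps <- 1e-6
  for (i in sample(length(Z), 12)) {
    zp <- as.numeric(Z); zp[i] <- zp[i] + eps
    zm <- as.numeric(Z); zm[i] <- zm[i] - eps
    num <- (lossAt(zp, Wk) - lossAt(zm, Wk)) / (2 * eps)
    expect_lt(abs(num - res$gradEmbeddings[i]) /
                max(1e-8, abs(num) + abs(res$gradEmbeddings[i])), 1e-4)
  }
  for (i in sample(length(Wk), 12)) {
    wp <- as.numeric(Wk); wp[i] <- wp[i] + eps
    wm <- as.numeric(Wk); wm[i] <- wm[i] - eps
    num <- (lossAt(as.numeric(Z), wp) - lossAt(as.numeric(Z), wm)) / (2 * eps)
    expect_lt(abs(num - res$gradW[i]) /
                max(1e-8, abs(num) + abs(res$gradW[i])), 1e-4)
  }
})

test_that("loss reductions and structural properties hold", {
  d <- 8
  ## one client, one class: softmax over a single column -> loss 0
  W1 <- fedvein:::withSeed(9, matrix(rnorm(d), d, 1))
  e1 <- expandWeightMatrix(W1, "only", "me", NULL)
  Z1 <- fedvein:::withSeed(10, matrix(rnorm(d), 1, d))
  expect_equal(fedpsfvLoss(Z1, e1, "only", 0, marginParams())$loss, 0)
  ## empty prototype set reproduces the baseline margin loss
  Wk <- fedvein:::withSeed(11, matrix(rnorm(d * 3), d, 3))
  Z <- fedvein:::withSeed(12, matrix(rnorm(4 * d), 4, d))
  labs <- c("L1", "L2", "L3", "L1")
  base <- fedpsfvLoss(Z, expandWeightMatrix(Wk, paste0("L", 1:3), "me", NULL),
                      labs, 0, marginParams(0.4, 16))
  emptyP <- new("PrototypeSet", vectors = matrix(0, d, 0),
                ownership = data.frame(client_id = character(),
                                       class_label = character(),
                                       n_samples = numeric()))
  viaEmpty <- fedpsfvLoss(Z, expandWeightMatrix(Wk, paste0("L", 1:3), "me",
                                                emptyP),
                          labs, 0, marginParams(0.4, 16))
  expect_equal(base$loss, viaEmpty$loss)
  ## loss is non-negative and positive with >= 2 columns
  expect_gt(base$loss, 0)
  ## adding a prototype column never decreases the loss
  plus <- fedpsfvLoss(Z, expandWeightMatrix(Wk, paste0("L", 1:3), "me",
                                            makePrototypes(d, "px", seed = 13)),
                      labs, 0, marginParams(0.4, 16))
  expect_gte(plus$loss, base$loss)
  ## monotonicity: with all other cosines pinned at 0 (orthogonal columns),
  ## increasing the target cosine never increases the loss
  Worth <- diag(d)[, 1:3]
  pOrth <- new("PrototypeSet", vectors = diag(d)[, 4:5],
               ownership = data.frame(client_id = "other",
                                      class_label = c("p1", "p2"),
                                      n_samples = 2))
  ewmO <- expandWeightMatrix(Worth, paste0("L", 1:3), "me", pOrth)
  losses <- vapply(seq(-0.95, 0.95, by = 0.1), function(a) {
    z <- a * diag(d)[, 1] + sqrt(1 - a^2) * diag(d)[, 8]
    fedpsfvLoss(rbind(z), ewmO, "L1", 0, marginParams(0.4, 16))$loss
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-10))
  ## a label naming a prototype column is rejected
  ewm <- expandWeightMatrix(Wk, paste0("L", 1:3), "me",
                            makePrototypes(d, c("p1", "p2"), seed = 14))
  expect_error(fedpsfvLoss(Z, ewm, c("p1", "L1", "L2", "L3"), 0,
                           marginParams()), "local trainable column")
})

test_that("prototype columns are frozen through optimization steps", {
  d <- 8
  Wk <- fedvein:::withSeed(15, matrix(rnorm(d * 3), d, 3))
  protos <- makePrototypes(d, c("p1", "p2", "p3"), seed = 16)
  ewm <- expandWeightMatrix(Wk, paste0("L", 1:3), "me", protos)
  before <- weightMatrix(ewm)[, !columnMap(ewm)$is_local]
  Z <- fedvein:::withSeed(17, matrix(rnorm(5 * d), 5, d))
  labs <- sample(paste0("L", 1:3), 5, replace = TRUE)
  localCols <- which(columnMap(ewm)$is_local)
  for (step in 1:10) {
    res <- fedpsfvLoss(Z, ewm, labs, 0, marginParams(0.4, 16))
    Wk <- Wk - 0.1 * res$gradW
    ewm@W[, localCols] <- Wk
  }
  expect_identical(weightMatrix(ewm)[, !columnMap(ewm)$is_local], before)
  ## gradients exist only for the local block (shape check)
  expect_equal(dim(res$gradW), dim(Wk))
})

test_that("shared-label prototype columns are excluded from the denominator", {
  d <- 8
  Wk <- fedvein:::withSeed(18, matrix(rnorm(d * 2), d, 2))
  ## another client owns a prototype for local class L1
  protos <- makePrototypes(d, c("L1", "q"), client = "other", seed = 19)
  ewm <- expandWeightMatrix(Wk, c("L1", "L2"), "me", protos)
  Z <- fedvein:::withSeed(20, matrix(rnorm(1 * d), 1, d))
  withShared <- fedpsfvLoss(Z, ewm, "L1", 0, marginParams(0.4, 16))
  ## reference: drop the duplicate-label prototype column entirely
  protos2 <- makePrototypes(d, c("L1", "q"), client = "other", seed = 19)
  keep <- protos2@ownership$class_label != "L1"
  protos2 <- new("PrototypeSet",
                 vectors = protos2@vectors[, keep, drop = FALSE],
                 ownership = protos2@ownership[keep, , drop = FALSE])
  ewm2 <- expandWeightMatrix(Wk, c("L1", "L2"), "me", protos2)
  noShared <- fedpsfvLoss(Z, ewm2, "L1", 0, marginParams(0.4, 16))
  expect_equal(withShared$loss, noShared$loss)
})
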
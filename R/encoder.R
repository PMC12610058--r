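## Reference convolutional embedding encoder.
##
## A deliberately small network so that end-to-end federated training runs
## in minutes on one CPU: input mean-pool 2x2, then three 3x3 conv + ReLU +
## 2x2 mean-pool blocks, flatten, and a linear map to d dimensions. All
## forward/backward passes are expressed as BLAS matrix products via
## im2col, so training speed is acceptable in plain R. The encoder is a
## contract: anything exposing the same parameter-vector/embed/gradient
## surface (including heavyweight backbones) can stand in for it.

#' ReferenceEncoder: a small trainable convolutional embedding network
#'
#' @slot d embedding dimensionality.
#' @slot inputShape c(height, width); both must be multiples of 16.
#' @slot channels channel widths of the three conv blocks.
#' @slot params named list of parameter arrays (conv kernels and biases,
#'   final linear weight and bias).
#' @slot seed the initialization seed.
#'
#' @exportClass ReferenceEncoder
setClass("ReferenceEncoder",
  representation(d = "numeric", inputShape = "numeric",
                 channels = "numeric", params = "list", seed = "numeric"))

setMethod("show", "ReferenceEncoder", function(object) {
  cat(sprintf(
    "ReferenceEncoder: %dx%d input, conv channels %s, d = %d (%d parameters)\n",
    object@inputShape[1], object@inputShape[2],
    paste(object@channels, collapse = "/"), object@d,
    length(encoderParameters(object))))
})

#' Create a reference encoder
#'
#' Seeded He-normal initialization; two encoders built from the same seed,
#' shape and width are identical.
#'
#' @param seed integer initialization seed.
#' @param d embedding dimensionality (>= 8). 512 matches the prototype
#'   dimension used at full scale; tests use smaller values.
#' @param inputShape c(height, width) of the images the encoder accepts;
#'   each must be a multiple of 16.
#' @param channels integer vector of three conv channel widths.
#' @return A \linkS4class{ReferenceEncoder}.
#' @examples
#' enc <- referenceEncoder(1, d = 32, inputShape = c(64, 128))
#' enc
#' @export
referenceEncoder <- function(seed, d = 512, inputShape = c(64, 128),
                             channels = c(8, 16, 24)) {
  if (d < 8) stop("d must be >= 8")
  if (length(inputShape) != 2 || any(inputShape %% 16 != 0))
    stop("inputShape dimensions must be multiples of 16")
  if (length(channels) != 3) stop("three conv blocks are expected")
  cin <- c(1, channels[1], channels[2])
  cout <- channels
  ## input 2x2 pool, blocks 1-2 pooled, block 3 unpooled (keeps the spatial
  ## resolution that carries vein-position information)
  nf <- (inputShape[1] / 8) * (inputShape[2] / 8) * channels[3]
  params <- withSeed(seed, {
    p <- list()
    for (l in 1:3) {
      fanIn <- 9 * cin[l]
      p[[paste0("K", l)]] <- matrix(rnorm(fanIn * cout[l], sd = sqrt(2 / fanIn)),
                                    fanIn, cout[l])
      p[[paste0("b", l)]] <- numeric(cout[l])
    }
    p$Wl <- matrix(rnorm(nf * d, sd = sqrt(1 / nf)), nf, d)
    p$bl <- numeric(d)
    p
  })
  new("ReferenceEncoder", d = d, inputShape = as.numeric(inputShape),
      channels = as.numeric(channels), params = params, seed = seed)
}

#' Flat encoder parameter vector
#'
#' Get or set all trainable encoder parameters as one flat numeric vector
#' (the unit that crosses the wire in federated aggregation).
#'
#' @param object a \linkS4class{ReferenceEncoder}.
#' @param value flat numeric vector of the same total length.
#' @return Numeric vector, or the updated encoder for the setter.
#' @export
setGeneric("encoderParameters", function(object) standardGeneric("encoderParameters"))

#' @rdname encoderParameters
#' @export
setGeneric("encoderParameters<-",
           function(object, value) standardGeneric("encoderParameters<-"))

#' @rdname encoderParameters
setMethod("encoderParameters", "ReferenceEncoder", function(object) {
  unlist(object@params, use.names = FALSE)
})

#' @rdname encoderParameters
setMethod("encoderParameters<-", "ReferenceEncoder", function(object, value) {
  lens <- vapply(object@params, length, numeric(1))
  if (length(value) != sum(lens)) stop("parameter vector length mismatch")
  off <- 0
  for (nm in names(object@params)) {
    n <- lens[[nm]]
    chunk <- value[(off + 1):(off + n)]
    dim(chunk) <- dim(object@params[[nm]])
    object@params[[nm]] <- chunk
    off <- off + n
  }
  object
})

## im2col index matrix: rows = output positions of an HxW map, columns =
## the 9 kernel taps, entries = linear indices into the zero-padded
## (H+2)x(W+2) plane.
.convIndexCache <- new.env(parent = emptyenv())

convIndex <- function(H, W) {
  key <- paste(H, W)
  cached <- .convIndexCache[[key]]
  if (!is.null(cached)) return(cached)
  idx <- convIndexBuild(H, W)
  .convIndexCache[[key]] <- idx
  idx
}

convIndexBuild <- function(H, W) {
  Hp <- H + 2
  hw <- as.matrix(expand.grid(h = seq_len(H), w = seq_len(W)))
  idx <- matrix(0L, H * W, 9)
  k <- 0
  for (kw in 1:3) for (kh in 1:3) {
    k <- k + 1
    idx[, k] <- (hw[, "h"] + kh - 1L) + Hp * (hw[, "w"] + kw - 2L)
  }
  idx
}

padBatch <- function(X, H, W, C, B) {
  Xp <- array(0, c(H + 2, W + 2, C, B))
  Xp[2:(H + 1), 2:(W + 1), , ] <- X
  Xp
}

## One conv block forward: X (H,W,C,B) -> list(out, cache); the output is
## 2x2 mean-pooled when pool = TRUE, else kept at full resolution.
convBlockForward <- function(X, K, b, idx, pool = TRUE) {
  dims <- dim(X); H <- dims[1]; W <- dims[2]; C <- dims[3]; B <- dims[4]
  Cout <- ncol(K)
  Xp <- padBatch(X, H, W, C, B)
  M <- matrix(Xp, (H + 2) * (W + 2), C * B)
  A <- M[as.vector(idx), , drop = FALSE]
  dim(A) <- c(H * W, 9, C, B)
  P <- aperm(A, c(1, 4, 2, 3))
  dim(P) <- c(H * W * B, 9 * C)
  Z <- P %*% K
  Z <- Z + rep(b, each = nrow(Z))
  Arelu <- Z; Arelu[Arelu < 0] <- 0
  dim(Arelu) <- c(H, W, B, Cout)
  Y <- aperm(Arelu, c(1, 2, 4, 3))
  if (pool) {
    X5 <- array(Y, c(2, H / 2, 2, W / 2, Cout * B))
    Pool <- (X5[1, , 1, , ] + X5[2, , 1, , ] + X5[1, , 2, , ] + X5[2, , 2, , ]) / 4
    out <- array(Pool, c(H / 2, W / 2, Cout, B))
  } else out <- Y
  list(out = out, cache = list(P = P, Z = Z, dims = dims, Cout = Cout,
                               pool = pool))
}

## Backward through one conv block; dOut matches the block's output shape.
convBlockBackward <- function(dOut, K, idx, cache) {
  dims <- cache$dims; H <- dims[1]; W <- dims[2]; C <- dims[3]; B <- dims[4]
  Cout <- cache$Cout
  if (cache$pool) {
    ## un-pool: each input of a 2x2 cell receives dOut/4
    q <- array(dOut, c(H / 2, W / 2, Cout * B)) / 4
    dX5 <- array(0, c(2, H / 2, 2, W / 2, Cout * B))
    for (r in 1:2) for (s in 1:2) dX5[r, , s, , ] <- q
    dY <- array(dX5, c(H, W, Cout, B))
  } else dY <- dOut
  dA <- aperm(dY, c(1, 2, 4, 3))
  dim(dA) <- c(H * W * B, Cout)
  dZ <- dA
  dZ[cache$Z < 0] <- 0
  dK <- crossprod(cache$P, dZ)
  db <- colSums(dZ)
  dP <- dZ %*% t(K)
  dim(dP) <- c(H * W, B, 9, C)
  D <- aperm(dP, c(1, 3, 4, 2))
  dim(D) <- c(H * W, 9, C * B)
  Mg <- matrix(0, (H + 2) * (W + 2), C * B)
  for (k in 1:9) Mg[idx[, k], ] <- Mg[idx[, k], ] + D[, k, ]
  dXp <- array(Mg, c(H + 2, W + 2, C, B))
  list(dX = dXp[2:(H + 1), 2:(W + 1), , , drop = FALSE], dK = dK, db = db)
}

## Stack a list of HxW images into the encoder's input array: scale to
## [-0.5, 0.5] and mean-pool 2x2 once to halve the resolution.
encoderInput <- function(encoder, images) {
  H <- encoder@inputShape[1]; W <- encoder@inputShape[2]
  B <- length(images)
  X <- array(0, c(H, W, 1, B))
  for (i in seq_len(B)) {
    im <- images[[i]]
    if (!all(dim(im) == c(H, W)))
      stop(sprintf("image %d is %dx%d but the encoder expects %dx%d",
                   i, nrow(im), ncol(im), H, W))
    X[, , 1, i] <- im / 255 - 0.5
  }
  X5 <- array(X, c(2, H / 2, 2, W / 2, B))
  array((X5[1, , 1, , ] + X5[2, , 1, , ] + X5[1, , 2, , ] + X5[2, , 2, , ]) / 4,
        c(H / 2, W / 2, 1, B))
}

## Full forward pass; returns raw embeddings (B x d) and caches for backprop.
encoderForward <- function(encoder, images) {
  p <- encoder@params
  X <- encoderInput(encoder, images)
  caches <- vector("list", 3)
  idxs <- vector("list", 3)
  for (l in 1:3) {
    dims <- dim(X)
    idxs[[l]] <- convIndex(dims[1], dims[2])
    blk <- convBlockForward(X, p[[paste0("K", l)]], p[[paste0("b", l)]],
                            idxs[[l]], pool = l < 3)
    caches[[l]] <- blk$cache
    X <- blk$out
  }
  dims <- dim(X)
  nf <- prod(dims[1:3]); B <- dims[4]
  Fmat <- t(matrix(X, nf, B))
  Z <- Fmat %*% p$Wl + rep(p$bl, each = B)
  list(embeddings = Z, Fmat = Fmat, caches = caches, idxs = idxs,
       finalDims = dims)
}

## Backward pass from dL/dZ (B x d) to a flat parameter gradient.
encoderBackward <- function(encoder, fwd, dZ) {
  p <- encoder@params
  B <- nrow(dZ)
  g <- list()
  g$Wl <- crossprod(fwd$Fmat, dZ)
  g$bl <- colSums(dZ)
  dF <- dZ %*% t(p$Wl)
  dX <- array(t(dF), fwd$finalDims)
  for (l in 3:1) {
    bk <- convBlockBackward(dX, p[[paste0("K", l)]], fwd$idxs[[l]],
                            fwd$caches[[l]])
    g[[paste0("K", l)]] <- bk$dK
    g[[paste0("b", l)]] <- bk$db
    dX <- bk$dX
  }
  unlist(g[names(p)], use.names = FALSE)
}

#' Embed a batch of images
#'
#' Runs the encoder forward and returns one raw (unnormalized)
#' d-dimensional embedding per image. Deterministic given the encoder
#' parameters.
#'
#' @param encoder a \linkS4class{ReferenceEncoder}.
#' @param images list of numeric matrices matching the encoder input shape.
#' @return Numeric matrix, one row per image, \code{d} columns.
#' @export
setGeneric("embedBatch", function(encoder, images) standardGeneric("embedBatch"))

#' @rdname embedBatch
setMethod("embedBatch", "ReferenceEncoder", function(encoder, images) {
  if (length(images) == 0) stop("empty image batch")
  encoderForward(encoder, images)$embeddings
})

#' Compute per-class prototypes of a client
#'
#' Embeds every image, L2-normalizes the embeddings, averages within each
#' class and re-normalizes the mean to unit length, giving one prototype
#' per class. Prototypes live on the unit sphere because they later act as
#' classifier weight columns in cosine similarity. A class whose mean
#' embedding is (near-)zero has no well-defined direction and is an error.
#'
#' @param encoder a \linkS4class{ReferenceEncoder} (or contract-compatible
#'   encoder).
#' @param client a \linkS4class{VeinClient} whose images are already
#'   preprocessed as in training.
#' @param batchSize forward-pass batch size.
#' @return A \linkS4class{PrototypeSet} with one column per class.
#' @export
computePrototypes <- function(encoder, client, batchSize = 64) {
  labs <- unique(client@labels)
  if (length(client@images) == 0) stop("client has no images")
  E <- embedClient(encoder, client@images, batchSize)
  E <- l2NormalizeRows(E)
  d <- ncol(E)
  vectors <- matrix(0, d, length(labs))
  nSamples <- integer(length(labs))
  for (i in seq_along(labs)) {
    rows <- which(client@labels == labs[i])
    mu <- colMeans(E[rows, , drop = FALSE])
    nrm <- sqrt(sum(mu^2))
    if (nrm < 1e-8)
      stop("degenerate prototype: class '", labs[i],
           "' has a near-zero mean embedding")
    vectors[, i] <- mu / nrm
    nSamples[i] <- length(rows)
  }
  new("PrototypeSet", vectors = vectors,
      ownership = data.frame(client_id = client@clientId,
                             class_label = labs, n_samples = nSamples,
                             stringsAsFactors = FALSE))
}

## Batched embedding of an image list (keeps peak memory flat).
embedClient <- function(encoder, images, batchSize = 64) {
  n <- length(images)
  out <- NULL
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    E <- embedBatch(encoder, images[idx])
    if (is.null(out)) out <- matrix(0, n, ncol(E))
    out[idx, ] <- E
  }
  out
}

#' Save / load an encoder checkpoint
#'
#' Single-file serialization of the encoder (architecture description plus
#' parameters). A restored encoder produces bit-identical embeddings.
#'
#' @param encoder a \linkS4class{ReferenceEncoder}.
#' @param path file path.
#' @return \code{loadEncoder} returns the encoder; \code{saveEncoder}
#'   returns \code{path} invisibly.
#' @export
saveEncoder <- function(encoder, path) {
  saveRDS(list(format = "fedvein-encoder-v1",
               d = encoder@d, inputShape = encoder@inputShape,
               channels = encoder@channels, seed = encoder@seed,
               parameters = encoderParameters(encoder)), path)
  invisible(path)
}

#' @rdname saveEncoder
#' @export
loadEncoder <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "fedvein-encoder-v1"))
    stop("not a fedvein encoder checkpoint: ", path)
  enc <- referenceEncoder(x$seed, d = x$d, inputShape = x$inputShape,
                          channels = x$channels)
  encoderParameters(enc) <- x$parameters
  enc
}
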
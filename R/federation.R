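#' Federation run configuration
#'
#' Training configuration for the multi-round federated simulation.
#'
#' @param nRounds number of communication rounds (>= 1).
#' @param localEpochs local epochs per round (>= 1).
#' @param batchSize mini-batch size.
#' @param lr SGD step size.
#' @param momentum SGD momentum coefficient.
#' @param margin,scale,literalEq13 margin-loss hyperparameters (see
#'   \code{\link{marginParams}}).
#' @param d embedding/prototype dimensionality.
#' @param u quality-score steepness.
#' @param h quality-indicator scale.
#' @param gradientThreshold Sobel gradient threshold.
#' @param seed master seed for the run (initialization and batch order).
#' @param prototypeDistribution "all" (server sends the full global
#'   prototype set, the default, matching full-download accounting) or
#'   "exclude_own" (each client receives only other clients' prototypes).
#'   Either way a client only ever expands with other clients' prototypes.
#' @param prototypeSharing if FALSE, prototypes are never shared and each
#'   client trains on its local columns only (the no-prototype ablation).
#' @param qualityAdaptive if FALSE, images are used un-enhanced and the
#'   quality indicator is fixed at 0 (plain fixed-margin loss; the
#'   no-quality ablation).
#' @param literalAggregationWeights if TRUE, weight client models by
#'   \code{|D_k| / N} with N the total class count (a variant kept for
#'   study; the weights then do not sum to 1). Default: sample-count
#'   proportional weights normalized to 1.
#' @param normalizedPrototypeAggregation if TRUE, multi-owner prototype
#'   aggregation weights are normalized to sum to 1 instead of the literal
#'   \code{1/|CS_j|}-scaled form (inert for disjoint labels).
#' @param channels encoder conv widths.
#' @return An object of class \code{"FederationConfig"}.
#' @export
federationConfig <- function(nRounds = 15, localEpochs = 2, batchSize = 32,
                             lr = 0.05, momentum = 0.9,
                             margin = 0.4, scale = 16, literalEq13 = FALSE,
                             d = 64, u = 10, h = 0.33,
                             gradientThreshold = 100, seed = 1,
                             prototypeDistribution = c("all", "exclude_own"),
                             prototypeSharing = TRUE, qualityAdaptive = TRUE,
                             literalAggregationWeights = FALSE,
                             normalizedPrototypeAggregation = FALSE,
                             channels = c(8, 16, 24)) {
  if (nRounds < 1) stop("nRounds must be >= 1")
  if (localEpochs < 1) stop("localEpochs must be >= 1")
  if (batchSize < 1) stop("batchSize must be >= 1")
  structure(list(nRounds = nRounds, localEpochs = localEpochs,
                 batchSize = batchSize, lr = lr, momentum = momentum,
                 margin = margin, scale = scale, literalEq13 = literalEq13,
                 d = d, u = u, h = h,
                 gradientThreshold = gradientThreshold, seed = seed,
                 prototypeDistribution = match.arg(prototypeDistribution),
                 prototypeSharing = prototypeSharing,
                 qualityAdaptive = qualityAdaptive,
                 literalAggregationWeights = literalAggregationWeights,
                 normalizedPrototypeAggregation = normalizedPrototypeAggregation,
                 channels = channels),
            class = "FederationConfig")
}

#' @export
print.FederationConfig <- function(x, ...) {
  cat(sprintf(paste0(
    "FederationConfig: %d rounds x %d epoch(s), batch %d, lr %g, ",
    "momentum %g, m %g, s %g, d %d\n"),
    x$nRounds, x$localEpochs, x$batchSize, x$lr, x$momentum,
    x$margin, x$scale, x$d))
  invisible(x)
}

## Per-client training state: preprocessed images, quality records, the
## trainable local head and momentum buffers.
initClientState <- function(client, config) {
  sobel <- sobelConfig(client@orientation, config$gradientThreshold)
  if (config$qualityAdaptive) {
    quality <- clientQualityRecords(client, sobel, config$u)
    train <- enhanceClient(client, sobel)
  } else {
    quality <- NULL
    train <- client
  }
  labs <- unique(client@labels)
  wSeed <- deriveSeeds(config$seed, 1, salt = paste0("Wk:", client@clientId))
  Wk <- withSeed(wSeed, {
    l2NormalizeCols(matrix(rnorm(config$d * length(labs)), config$d,
                           length(labs)))
  })
  list(client = train, labels = labs, quality = quality, Wk = Wk,
       velEncoder = NULL, velW = 0 * Wk,
       nSamples = length(train@images))
}

## Per-sample quality indicator for a batch: class quality scores looked
## up from the preprocessing records, standardized within the batch.
batchQhat <- function(state, batchLabels, config) {
  if (!config$qualityAdaptive || is.null(state$quality))
    return(rep(0, length(batchLabels)))
  Q <- state$quality$Q[match(batchLabels, state$quality$class_label)]
  batchQualityIndicator(Q, config$h)
}

#' One client update (local training plus prototype computation)
#'
#' Installs the aggregated encoder parameters, expands the local weight
#' matrix with the received prototype blocks, runs the configured local
#' epochs of mini-batch SGD (with momentum) on the prototype-expanded
#' margin loss, and finally computes fresh class prototypes with the
#' updated encoder over the client's full training split. Prototype
#' columns are frozen throughout; only the encoder and the local weight
#' block are updated.
#'
#' @param state client state as built by \code{runFederation} (internal
#'   structure; see source).
#' @param encoder encoder template (defines architecture).
#' @param omega flat parameter vector to install before training.
#' @param prototypes \linkS4class{PrototypeSet} received from the server,
#'   or NULL in the bootstrap round.
#' @param config a \code{\link{federationConfig}}.
#' @param roundSeed seed governing this round's batch order.
#' @return list with the updated \code{state}, new flat parameters
#'   \code{omega}, the client's \linkS4class{PrototypeSet}
#'   \code{prototypes}, and \code{epochLosses}.
#' @export
clientUpdate <- function(state, encoder, omega, prototypes, config,
                         roundSeed = config$seed) {
  encoderParameters(encoder) <- omega
  params <- marginParams(config$margin, config$scale, config$literalEq13)
  ewm <- expandWeightMatrix(state$Wk, state$labels, state$client@clientId,
                            if (config$prototypeSharing) prototypes else NULL)
  localCols <- which(ewm@map$is_local)
  n <- length(state$client@images)
  if (n == 0) stop("client has an empty training split")
  if (is.null(state$velEncoder)) state$velEncoder <- 0 * omega
  epochLosses <- numeric(config$localEpochs)
  for (ep in seq_len(config$localEpochs)) {
    ord <- withSeed(deriveSeeds(roundSeed, 1,
                                salt = paste0("order:", state$client@clientId,
                                              ":", ep)),
                    sample.int(n))
    starts <- seq(1, n, by = config$batchSize)
    batchLoss <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      sel <- ord[starts[bi]:min(starts[bi] + config$batchSize - 1, n)]
      imgs <- state$client@images[sel]
      labs <- state$client@labels[sel]
      fwd <- encoderForward(encoder, imgs)
      res <- fedpsfvLoss(fwd$embeddings, ewm, labs,
                         batchQhat(state, labs, config), params)
      batchLoss[bi] <- res$loss
      gOmega <- encoderBackward(encoder, fwd, res$gradEmbeddings)
      state$velEncoder <- config$momentum * state$velEncoder - config$lr * gOmega
      omega <- encoderParameters(encoder) + state$velEncoder
      encoderParameters(encoder) <- omega
      state$velW <- config$momentum * state$velW - config$lr * res$gradW
      state$Wk <- state$Wk + state$velW
      ewm@W[, localCols] <- state$Wk
    }
    epochLosses[ep] <- mean(batchLoss)
  }
  protos <- computePrototypes(encoder, state$client,
                              batchSize = config$batchSize)
  list(state = state, omega = encoderParameters(encoder),
       prototypes = protos, epochLosses = epochLosses)
}

#' Aggregate client encoder parameters
#'
#' Sample-count weighted average of the clients' parameter vectors,
#' weights \code{|D_k| / sum |D_j|} (normalized to 1). The literal
#' variant divides by \code{nTotalClasses} instead, for study.
#'
#' @param omegaList list of flat parameter vectors, one per client.
#' @param counts positive per-client sample counts.
#' @param literal use the unnormalized class-count denominator.
#' @param nTotalClasses denominator for the literal variant.
#' @return Aggregated flat parameter vector.
#' @export
aggregateModels <- function(omegaList, counts, literal = FALSE,
                            nTotalClasses = NULL) {
  if (length(omegaList) != length(counts)) stop("one count per model required")
  if (any(counts <= 0)) stop("sample counts must be positive")
  lens <- vapply(omegaList, length, numeric(1))
  if (length(unique(lens)) != 1) stop("parameter vectors differ in shape")
  w <- if (literal) {
    if (is.null(nTotalClasses)) stop("literal weights need nTotalClasses")
    counts / nTotalClasses
  } else counts / sum(counts)
  out <- 0
  for (i in seq_along(omegaList)) out <- out + w[i] * omegaList[[i]]
  out
}

#' Aggregate prototypes across clients
#'
#' For every class j owned by the client set \code{CS_j}, the aggregated
#' prototype is \code{(1/|CS_j|) sum_k (|D_k^j| / N_j) S_k^j}, where
#' \code{N_j} is the total sample count of the class; each owning
#' client's entry is then replaced by the aggregate, so the total
#' prototype count is conserved. For a single-owner class the aggregate
#' equals the uploaded prototype exactly. The \code{normalized} variant
#' drops the leading \code{1/|CS_j|} so multi-owner weights sum to 1.
#'
#' @param protoList list of \linkS4class{PrototypeSet}, one per client.
#' @param normalized use weights that sum to 1 for multi-owner classes.
#' @return A \linkS4class{PrototypeSet} covering every uploaded
#'   (client, class) pair.
#' @export
aggregatePrototypes <- function(protoList, normalized = FALSE) {
  vectors <- do.call(cbind, lapply(protoList, function(p) p@vectors))
  ownership <- do.call(rbind, lapply(protoList, function(p) p@ownership))
  if (anyDuplicated(ownership[, c("client_id", "class_label")]))
    stop("duplicate (client, class) prototype upload")
  out <- vectors
  for (lab in unique(ownership$class_label)) {
    sel <- which(ownership$class_label == lab)
    if (length(sel) == 1) next
    Nj <- sum(ownership$n_samples[sel])
    w <- ownership$n_samples[sel] / Nj
    if (!normalized) w <- w / length(sel)
    agg <- vectors[, sel, drop = FALSE] %*% w
    out[, sel] <- matrix(agg, nrow(vectors), length(sel))
  }
  new("PrototypeSet", vectors = out, ownership = ownership)
}

## Prototype view a client receives under the configured distribution.
distributeTo <- function(global, clientId, distribution) {
  if (is.null(global)) return(NULL)
  if (distribution == "all") return(global)
  keep <- global@ownership$client_id != clientId
  new("PrototypeSet", vectors = global@vectors[, keep, drop = FALSE],
      ownership = global@ownership[keep, , drop = FALSE])
}

#' Run the federated training simulation
#'
#' Orchestrates the full multi-round loop: per round, every client
#' receives the global encoder parameters and the current prototype set,
#' trains locally on the prototype-expanded margin loss, and uploads its
#' updated encoder parameters and fresh prototypes; the server then
#' aggregates both. Round 1 trains with the plain (unexpanded) weight
#' matrix because no meaningful prototypes exist before any training;
#' prototypes first circulate in round 2. The local classifier block
#' never leaves its client (the personalization contract). Everything is
#' deterministic in the config seed.
#'
#' @param federation a \linkS4class{VeinFederation} of training splits.
#' @param config a \code{\link{federationConfig}}.
#' @return list with \code{encoder} (final aggregated global encoder),
#'   \code{history} (data.frame round/client_id/loss), \code{prototypes}
#'   (final global \linkS4class{PrototypeSet}), \code{clientStates}, and
#'   \code{config}.
#' @examples
#' \donttest{
#' fed <- generateFederation(federationSpec(nClasses = c(3, 3),
#'   samplesPerClass = 2, height = 32, width = 32, masterSeed = 5))
#' run <- runFederation(fed, federationConfig(nRounds = 2, d = 16,
#'   batchSize = 4, seed = 5))
#' head(run$history)
#' }
#' @export
runFederation <- function(federation, config = federationConfig()) {
  clients <- federation@clients
  if (length(clients) < 1) stop("at least one client is required")
  shape <- dim(clients[[1]]@images[[1]])
  encoder <- referenceEncoder(deriveSeeds(config$seed, 1, salt = "encoder"),
                              d = config$d, inputShape = shape,
                              channels = config$channels)
  omega <- encoderParameters(encoder)
  states <- lapply(clients, initClientState, config = config)
  names(states) <- vapply(clients, clientId, character(1))
  counts <- vapply(states, function(s) s$nSamples, numeric(1))
  global <- NULL
  history <- NULL
  roundSeeds <- deriveSeeds(config$seed, config$nRounds, salt = "rounds")
  for (t in seq_len(config$nRounds)) {
    omegaList <- vector("list", length(states))
    protoList <- vector("list", length(states))
    for (i in seq_along(states)) {
      up <- clientUpdate(states[[i]], encoder, omega,
                         distributeTo(global, names(states)[i],
                                      config$prototypeDistribution),
                         config, roundSeed = roundSeeds[t])
      states[[i]] <- up$state
      omegaList[[i]] <- up$omega
      protoList[[i]] <- up$prototypes
      history <- rbind(history,
                       data.frame(round = t, client_id = names(states)[i],
                                  loss = mean(up$epochLosses)))
    }
    omega <- aggregateModels(omegaList, counts,
                             literal = config$literalAggregationWeights,
                             nTotalClasses = sum(lengths(lapply(states,
                                                       `[[`, "labels"))))
    if (config$prototypeSharing)
      global <- aggregatePrototypes(protoList,
                                    normalized = config$normalizedPrototypeAggregation)
  }
  encoderParameters(encoder) <- omega
  list(encoder = encoder, history = history, prototypes = global,
       clientStates = states, config = config)
}

#' Train every client independently (local baseline)
#'
#' The non-federated reference: each client trains its own encoder from
#' the same seeded initialization for \code{nRounds * localEpochs} epochs
#' with the same loss but no prototype sharing and no aggregation.
#'
#' @param federation a \linkS4class{VeinFederation} of training splits.
#' @param config a \code{\link{federationConfig}}; \code{nRounds} rounds
#'   are re-interpreted as training segments so the optimization budget
#'   matches the federated run.
#' @return list with per-client \code{encoders} (named list),
#'   \code{history}, and \code{config}.
#' @export
runLocalBaseline <- function(federation, config = federationConfig()) {
  clients <- federation@clients
  shape <- dim(clients[[1]]@images[[1]])
  history <- NULL
  encoders <- list()
  roundSeeds <- deriveSeeds(config$seed, config$nRounds, salt = "rounds")
  for (cl in clients) {
    encoder <- referenceEncoder(deriveSeeds(config$seed, 1, salt = "encoder"),
                                d = config$d, inputShape = shape,
                                channels = config$channels)
    omega <- encoderParameters(encoder)
    state <- initClientState(cl, config)
    for (t in seq_len(config$nRounds)) {
      up <- clientUpdate(state, encoder, omega, NULL, config,
                         roundSeed = roundSeeds[t])
      state <- up$state
      omega <- up$omega
      history <- rbind(history,
                       data.frame(round = t, client_id = cl@clientId,
                                  loss = mean(up$epochLosses)))
    }
    encoderParameters(encoder) <- omega
    encoders[[cl@clientId]] <- encoder
  }
  list(encoders = encoders, history = history, config = config)
}

#' Training-split class counts under the open-set ratio
#'
#' @param nClasses integer vector of per-client class counts.
#' @param ratio training fraction by class count.
#' @return \code{floor(ratio * nClasses)}.
#' @export
trainClassCounts <- function(nClasses, ratio = 0.8) floor(ratio * nClasses)

#' Per-round prototype communication overhead
#'
#' Upload and download cost of prototype sharing, in units of \code{unit}
#' parameters (default 2^20, i.e. "M" of parameters). Each client uploads
#' one d-vector per training class; the download is the full global
#' prototype set under the "all" distribution, or the global set minus the
#' client's own prototypes under "exclude_own". The encoder parameter
#' count (the dominant, method-independent cost) can be reported
#' alongside.
#'
#' @param trainClasses integer vector: per-client training class counts.
#' @param d prototype dimensionality.
#' @param unit parameters per reported unit.
#' @param distribution "all" or "exclude_own".
#' @param encoderParams optional encoder parameter count to report.
#' @return data.frame with one row per client (upload, download) plus a
#'   "mean" row; attribute \code{"encoder"} carries the encoder cost.
#' @examples
#' communicationCost(trainClassCounts(c(636, 600, 492, 360, 220, 1680)))
#' @export
communicationCost <- function(trainClasses, d = 512, unit = 2^20,
                              distribution = c("all", "exclude_own"),
                              encoderParams = NULL) {
  distribution <- match.arg(distribution)
  upload <- trainClasses * d / unit
  total <- sum(trainClasses)
  download <- if (distribution == "all") rep(total * d / unit,
                                             length(trainClasses))
              else (total - trainClasses) * d / unit
  out <- data.frame(client = c(as.character(seq_along(trainClasses)), "mean"),
                    train_classes = c(trainClasses, mean(trainClasses)),
                    upload = c(upload, mean(upload)),
                    download = c(download, mean(download)))
  if (!is.null(encoderParams)) attr(out, "encoder") <- encoderParams / unit
  out
}
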
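#' Class-disjoint open-set split
#'
#' Splits every client's classes into training and test sets by class
#' count (default 8:2): \code{floor(ratio * n)} classes are chosen for
#' training by a seeded shuffle and the remaining classes — with all their
#' samples — are reserved for open-set testing, so test identities are
#' never seen in training.
#'
#' @param federation a \linkS4class{VeinFederation}.
#' @param ratio training fraction by class count.
#' @param seed split seed.
#' @return list with \code{train} and \code{test}
#'   \linkS4class{VeinFederation}s and an \code{assignment} data.frame
#'   (client_id, class_label, role).
#' @export
splitOpenSet <- function(federation, ratio = 0.8, seed = 1) {
  trainClients <- list(); testClients <- list(); assign <- NULL
  for (cl in federation@clients) {
    labs <- unique(cl@labels)
    if (length(labs) < 2) stop("client '", cl@clientId, "' has < 2 classes")
    nTrain <- floor(ratio * length(labs))
    nTest <- length(labs) - nTrain
    if (nTest < 2)
      stop("client '", cl@clientId, "' would have ", nTest,
           " test class(es); >= 2 are needed for impostor pairs")
    ord <- withSeed(deriveSeeds(seed, 1, salt = paste0("split:", cl@clientId)),
                    sample(labs))
    trainLabs <- ord[seq_len(nTrain)]
    sel <- cl@labels %in% trainLabs
    trainClients[[cl@clientId]] <-
      new("VeinClient", clientId = cl@clientId, images = cl@images[sel],
          labels = cl@labels[sel], orientation = cl@orientation)
    testClients[[cl@clientId]] <-
      new("VeinClient", clientId = cl@clientId, images = cl@images[!sel],
          labels = cl@labels[!sel], orientation = cl@orientation)
    assign <- rbind(assign,
                    data.frame(client_id = cl@clientId, class_label = labs,
                               role = ifelse(labs %in% trainLabs,
                                             "train", "test")))
  }
  list(train = new("VeinFederation", spec = federation@spec,
                   clients = unname(trainClients)),
       test = new("VeinFederation", spec = federation@spec,
                  clients = unname(testClients)),
       assignment = assign)
}

#' Genuine / impostor scores over all sample pairs
#'
#' Cosine similarity of every unordered pair of test-sample embeddings,
#' partitioned into genuine (same class) and impostor (different class)
#' score sets. Pair counts satisfy |genuine| + |impostor| = C(n, 2).
#'
#' @param embeddings n x d matrix of raw embeddings.
#' @param labels length-n class labels.
#' @return A \linkS4class{VerificationScores}.
#' @export
scoreVerificationPairs <- function(embeddings, labels) {
  n <- nrow(embeddings)
  if (n != length(labels)) stop("one label per embedding row is required")
  if (length(unique(labels)) < 2) stop(">= 2 classes are needed")
  if (max(table(labels)) < 2) stop(">= 1 class with >= 2 samples is needed")
  E <- l2NormalizeRows(embeddings)
  S <- E %*% t(E)
  S <- clip01(S, -1, 1)       # guard rounding just outside [-1, 1]
  ut <- upper.tri(S)
  same <- outer(labels, labels, "==")
  new("VerificationScores", genuine = S[ut & same], impostor = S[ut & !same])
}

#' Score a client's open-set split with an encoder
#'
#' Applies the same preprocessing as training (gradient enhancement when
#' enabled), embeds all test samples and scores all pairs.
#'
#' @param encoder a trained encoder.
#' @param client the client's test split.
#' @param qualityAdaptive apply gradient enhancement first (must match the
#'   training-time setting).
#' @param gradientThreshold Sobel threshold used for enhancement.
#' @param contrastLevel optional contrast re-rendering factor in (0, 1]
#'   applied to the raw test images before preprocessing (robustness
#'   protocol); NULL for native contrast.
#' @return A \linkS4class{VerificationScores}.
#' @export
scoreClient <- function(encoder, client, qualityAdaptive = TRUE,
                        gradientThreshold = 100, contrastLevel = NULL) {
  imgs <- client@images
  if (!is.null(contrastLevel))
    imgs <- lapply(imgs, applyContrast, contrastLevel = contrastLevel)
  if (qualityAdaptive) {
    cfg <- sobelConfig(client@orientation, gradientThreshold)
    imgs <- lapply(imgs, function(im) enhanceImage(im, sobelGradient(im, cfg)))
  }
  E <- embedClient(encoder, imgs)
  scoreVerificationPairs(E, client@labels)
}

#' False acceptance / false rejection rates at a threshold
#'
#' Acceptance rule: a pair is accepted when its score is >= the threshold
#' (ties accept). FAR is the percentage of impostor pairs accepted, FRR
#' the percentage of genuine pairs rejected.
#'
#' @param scores a \linkS4class{VerificationScores}.
#' @param threshold decision threshold.
#' @return Named numeric vector c(FAR, FRR), in percent.
#' @export
farFrrAt <- function(scores, threshold) {
  if (length(scores@genuine) == 0 || length(scores@impostor) == 0)
    stop("both score sets must be non-empty")
  c(FAR = 100 * mean(scores@impostor >= threshold),
    FRR = 100 * mean(scores@genuine < threshold))
}

## Step-function FAR/FRR at each candidate threshold (sorted union of the
## observed scores plus one point above the maximum where FAR = 0).
rocTable <- function(scores) {
  thr <- sort(unique(c(scores@genuine, scores@impostor)))
  thr <- c(thr, max(thr) + 1)
  far <- 100 * vapply(thr, function(t) mean(scores@impostor >= t), numeric(1))
  frr <- 100 * vapply(thr, function(t) mean(scores@genuine < t), numeric(1))
  data.frame(threshold = thr, FAR = far, FRR = frr)
}

#' Equal error rate
#'
#' Sweeps all candidate thresholds (the sorted union of observed scores),
#' locates the crossing of the non-increasing FAR and non-decreasing FRR
#' curves, and linearly interpolates between the bracketing thresholds to
#' return the common rate, in percent. Perfectly separated scores give 0;
#' identical genuine and impostor score sets give exactly 50.
#'
#' @param scores a \linkS4class{VerificationScores}.
#' @return EER in percent (in [0, 50]).
#' @export
eer <- function(scores) {
  if (length(scores@genuine) == 0 || length(scores@impostor) == 0)
    stop("both score sets must be non-empty")
  roc <- rocTable(scores)
  diff <- roc$FAR - roc$FRR
  hit <- which(diff == 0)
  if (length(hit) > 0) return(roc$FAR[hit[1]])
  i <- which(diff < 0)[1]    # first threshold where FRR exceeds FAR
  if (is.na(i)) return(roc$FAR[nrow(roc)])
  if (i == 1) return(roc$FAR[1])
  d1 <- diff[i - 1]; d2 <- diff[i]
  alpha <- d1 / (d1 - d2)
  roc$FAR[i - 1] + alpha * (roc$FAR[i] - roc$FAR[i - 1])
}

#' True acceptance rate at a fixed false acceptance rate
#'
#' Takes the smallest observed threshold whose empirical FAR does not
#' exceed the target (default FAR = 0.01, i.e. 1 percent) and reports
#' TAR = 100 - FRR there. The operating point is the conservative
#' empirical threshold: no credit is interpolated for FAR budget the
#' threshold does not actually spend (so degenerate all-equal scores give
#' TAR = 0). A warning is issued when the impostor set is too small for
#' the operating point to be well defined.
#'
#' @param scores a \linkS4class{VerificationScores}.
#' @param farTarget target false acceptance proportion (0.01 means 1\%).
#' @return TAR in percent.
#' @export
tarAtFar <- function(scores, farTarget = 0.01) {
  if (length(scores@impostor) == 0) stop("empty impostor score set")
  if (length(scores@impostor) < 1 / farTarget)
    warning(sprintf(
      "only %d impostor pairs; FAR = %g is below the empirical resolution",
      length(scores@impostor), farTarget))
  roc <- rocTable(scores)
  ok <- which(roc$FAR <= farTarget * 100)
  100 - roc$FRR[ok[1]]
}

#' Evaluate an open-set test federation
#'
#' Computes per-client EER and TAR at FAR = 0.01 with the given encoder
#' (one global encoder, or a named list of per-client encoders for the
#' local baseline), then appends the across-client mean row.
#'
#' @param encoder encoder or named list of encoders keyed by client id.
#' @param testFederation the test-split \linkS4class{VeinFederation}.
#' @param qualityAdaptive,gradientThreshold,contrastLevel passed to
#'   \code{\link{scoreClient}}.
#' @param farTarget operating FAR for the TAR metric.
#' @return data.frame with columns client_id, eer, tar (percent); last row
#'   is the mean.
#' @export
evaluateOpenSet <- function(encoder, testFederation, qualityAdaptive = TRUE,
                            gradientThreshold = 100, contrastLevel = NULL,
                            farTarget = 0.01) {
  rows <- NULL
  for (cl in testFederation@clients) {
    enc <- if (is.list(encoder)) encoder[[cl@clientId]] else encoder
    if (is.null(enc)) stop("no encoder for client ", cl@clientId)
    sc <- scoreClient(enc, cl, qualityAdaptive, gradientThreshold,
                      contrastLevel)
    rows <- rbind(rows, data.frame(client_id = cl@clientId,
                                   eer = eer(sc),
                                   tar = tarAtFar(sc, farTarget)))
  }
  rbind(rows, data.frame(client_id = "mean", eer = mean(rows$eer),
                         tar = mean(rows$tar)))
}

#' Relative change arithmetic for metric reports
#'
#' \code{relReduction(a, b)} is the percentage by which \code{a} is lower
#' than the reference \code{b} (used for error rates);
#' \code{relGain(a, b)} the percentage by which it is higher (used for
#' acceptance rates).
#'
#' @param a the method's value.
#' @param b the reference value.
#' @return Percentage change.
#' @export
relReduction <- function(a, b) (b - a) / b * 100

#' @rdname relReduction
#' @export
relGain <- function(a, b) (a - b) / b * 100

#' Summarize per-dataset verification metrics
#'
#' Appends the arithmetic mean row to a per-dataset metric table and, when
#' reference columns are supplied, the relative EER reduction and TAR gain
#' against each reference. Values are kept at full precision; rendering to
#' two decimals happens only in printed reports.
#'
#' @param metrics data.frame with columns \code{dataset}, \code{eer},
#'   \code{tar} (one row per dataset).
#' @param reference optional named list of data.frames with the same
#'   columns, the comparison methods.
#' @return list with \code{table} (metrics + mean row) and, if references
#'   were given, \code{comparison} (method, eer_reduction, tar_gain).
#' @export
summarizeVerification <- function(metrics, reference = NULL) {
  tab <- rbind(metrics,
               data.frame(dataset = "mean", eer = mean(metrics$eer),
                          tar = mean(metrics$tar)))
  out <- list(table = tab)
  if (!is.null(reference)) {
    cmp <- NULL
    for (nm in names(reference)) {
      refMean <- colMeans(reference[[nm]][, c("eer", "tar")])
      cmp <- rbind(cmp, data.frame(
        method = nm,
        eer_reduction = relReduction(mean(metrics$eer), refMean[["eer"]]),
        tar_gain = relGain(mean(metrics$tar), refMean[["tar"]])))
    }
    out$comparison <- cmp
  }
  out
}

#' Dataset bookkeeping for a federation
#'
#' Image totals and open-set split sizes implied by per-client class
#' counts and samples per class.
#'
#' @param nClasses integer vector of class counts.
#' @param samplesPerClass integer vector (recycled).
#' @param ratio open-set training fraction by class count.
#' @return data.frame with class counts, total images, and train/test
#'   class counts per client.
#' @examples
#' federationBookkeeping(c(220, 1680), c(2, 10))
#' @export
federationBookkeeping <- function(nClasses, samplesPerClass, ratio = 0.8) {
  spc <- rep_len(samplesPerClass, length(nClasses))
  data.frame(n_classes = nClasses, samples_per_class = spc,
             n_images = nClasses * spc,
             train_classes = trainClassCounts(nClasses, ratio),
             test_classes = nClasses - trainClassCounts(nClasses, ratio))
}
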
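#' Margin-loss hyperparameters
#'
#' @param m non-negative margin (typically 0.4).
#' @param s positive logit scale for the normalized-softmax loss. The
#'   scale is not dictated by the quality-adaptive construction; 64 is the
#'   conventional value for margin losses on unit embeddings.
#' @param literalEq13 if TRUE, use the purely affine target logit
#'   \code{s (cos(theta) + g_angle - g_add)} instead of the angular-space
#'   reading \code{s (cos(theta + g_angle) - g_add)} (see the methods
#'   vignette for why the angular reading is the default).
#' @return An object of class \code{"MarginParams"}.
#' @export
marginParams <- function(m = 0.4, s = 16, literalEq13 = FALSE) {
  if (m < 0) stop("margin m must be non-negative")
  if (s <= 0) stop("scale s must be positive")
  structure(list(m = m, s = s, literalEq13 = literalEq13),
            class = "MarginParams")
}

#' @export
print.MarginParams <- function(x, ...) {
  cat(sprintf("MarginParams: m = %g, s = %g%s\n", x$m, x$s,
              if (x$literalEq13) " (literal affine target logit)" else ""))
  invisible(x)
}

#' Expand a local classifier weight matrix with other clients' prototypes
#'
#' Concatenates the prototype blocks of the other clients with the
#' client's own trainable weight block, in ascending client order, to
#' form the d x N expanded classifier weight matrix. Prototype columns
#' are frozen (never updated); exactly the local block is trainable. Any
#' prototypes owned by the client itself are dropped from the expansion
#' (its own classes are already represented by the trainable block).
#'
#' @param Wk d x Nk local weight matrix.
#' @param localLabels class labels of the local columns (length Nk).
#' @param clientId the owning client's identifier.
#' @param prototypes a \linkS4class{PrototypeSet} of shared prototypes, or
#'   NULL for the bootstrap round (expansion is then just \code{Wk}).
#' @param clientOrder optional character vector fixing the client block
#'   order; defaults to sorted client ids.
#' @return An \linkS4class{ExpandedWeightMatrix}.
#' @examples
#' W <- matrix(rnorm(8 * 3), 8, 3)
#' ewm <- expandWeightMatrix(W, c("a", "b", "c"), "client1", NULL)
#' ewm
#' @export
expandWeightMatrix <- function(Wk, localLabels, clientId,
                               prototypes = NULL, clientOrder = NULL) {
  d <- nrow(Wk)
  if (length(localLabels) != ncol(Wk))
    stop("one label per local weight column is required")
  if (anyDuplicated(localLabels)) stop("duplicate local class labels")
  localMap <- data.frame(client_id = clientId, class_label = localLabels,
                         is_local = TRUE, stringsAsFactors = FALSE)
  if (is.null(prototypes) || ncol(prototypes@vectors) == 0) {
    return(new("ExpandedWeightMatrix", W = Wk, map = localMap,
               clientId = clientId))
  }
  own <- prototypes@ownership$client_id == clientId
  vec <- prototypes@vectors[, !own, drop = FALSE]
  ows <- prototypes@ownership[!own, , drop = FALSE]
  if (ncol(vec) > 0 && nrow(vec) != d)
    stop(sprintf("prototype dimension %d does not match weight dimension %d",
                 nrow(vec), d))
  clientOrder <- clientOrder %||% sort(unique(c(ows$client_id, clientId)))
  if (!clientId %in% clientOrder) stop("clientId missing from clientOrder")
  blocks <- list(); maps <- list()
  for (a in clientOrder) {
    if (a == clientId) {
      blocks[[a]] <- Wk; maps[[a]] <- localMap
    } else {
      sel <- which(ows$client_id == a)
      if (length(sel) == 0) next
      blocks[[a]] <- vec[, sel, drop = FALSE]
      maps[[a]] <- data.frame(client_id = a,
                              class_label = ows$class_label[sel],
                              is_local = FALSE, stringsAsFactors = FALSE)
    }
  }
  new("ExpandedWeightMatrix", W = do.call(cbind, unname(blocks)),
      map = do.call(rbind, unname(maps)), clientId = clientId)
}

#' Cosine similarity between embeddings and the expanded weight matrix
#'
#' Row-normalizes the embeddings, column-normalizes the weight matrix and
#' multiplies, so entry (i, j) is the cosine of the angle between
#' embedding i and class column j; all entries lie in [-1, 1].
#'
#' @param embeddings n x d matrix of (raw) embeddings.
#' @param ewm an \linkS4class{ExpandedWeightMatrix} (or plain d x N matrix).
#' @return n x N similarity matrix.
#' @export
similarityMatrix <- function(embeddings, ewm) {
  W <- if (is(ewm, "ExpandedWeightMatrix")) ewm@W else ewm
  S <- l2NormalizeRows(embeddings) %*% l2NormalizeCols(W)
  if (any(!is.finite(S))) stop("non-finite similarity values")
  S
}

#' Quality-adaptive margins
#'
#' Converts a batch quality indicator into the pair of margins applied to
#' the target logit: an angular-space margin \code{g_angle = -m Qhat} and
#' an additive cosine margin \code{g_add = m Qhat + m}. At \code{Qhat = 0}
#' this is the plain additive-cosine margin (0, m); at \code{Qhat = -1}
#' (low-quality classes) it shifts entirely into angular space (m, 0).
#'
#' @param Qhat quality indicator values in [-1, 1] (vectorized).
#' @param m margin.
#' @return list with numeric components \code{g_angle} and \code{g_add}.
#' @export
marginsFromQuality <- function(Qhat, m = 0.4) {
  if (any(Qhat < -1 | Qhat > 1)) stop("Qhat must lie in [-1, 1]")
  list(g_angle = -m * Qhat, g_add = m * Qhat + m)
}

## Safe arccos with derivative bookkeeping: inputs are clipped to
## [-1+eps, 1-eps] and the margin-shifted angle is clamped to [0, pi].
ACOS_EPS <- 1e-7

#' Target-class logit under the quality-adaptive margin
#'
#' For target columns the logit is
#' \code{s (cos(theta + g_angle) - g_add)} with \code{theta + g_angle}
#' clamped to [0, pi]; non-target logits are \code{s cos(theta)}. With
#' \code{m = 0} the logit reduces to \code{s cos(theta)} exactly.
#'
#' @param cosTheta cosine(s) of the target angle, in [-1, 1].
#' @param Qhat quality indicator(s) in [-1, 1].
#' @param params a \code{\link{marginParams}}.
#' @return Numeric vector of target logits.
#' @export
targetLogit <- function(cosTheta, Qhat, params = marginParams()) {
  g <- marginsFromQuality(Qhat, params$m)
  if (params$literalEq13)
    return(params$s * (cosTheta + g$g_angle - g$g_add))
  theta <- acos(clip01(cosTheta, -1 + ACOS_EPS, 1 - ACOS_EPS))
  ang <- clip01(theta + g$g_angle, 0, pi)
  params$s * (cos(ang) - g$g_add)
}

## Derivative of the target logit with respect to cos(theta).
targetLogitDCos <- function(cosTheta, Qhat, params) {
  if (params$literalEq13) return(rep(params$s, length(cosTheta)))
  g <- marginsFromQuality(Qhat, params$m)
  cc <- clip01(cosTheta, -1 + ACOS_EPS, 1 - ACOS_EPS)
  theta <- acos(cc)
  ang <- theta + g$g_angle
  out <- numeric(length(cosTheta))
  live <- cosTheta > -1 + ACOS_EPS & cosTheta < 1 - ACOS_EPS &
    ang > 0 & ang < pi
  ## d/dcos s cos(theta + ga) = s sin(theta + ga) / sin(theta)
  out[live] <- params$s * sin(ang[live]) / sin(theta[live])
  out
}

#' Prototype-expanded quality-adaptive margin loss
#'
#' The training loss of a client: normalized-softmax cross-entropy over
#' the expanded weight matrix, where the target logit carries the
#' quality-adaptive margins and the denominator includes both the other
#' local classes and the (frozen) prototype columns of the other clients.
#' Prototype columns sharing the sample's own class label (possible when
#' clients share identities) are excluded from the denominator. Returns
#' the batch-mean loss together with analytic gradients with respect to
#' the raw embeddings and the raw local weight block; prototype columns
#' receive no update.
#'
#' @param embeddings n x d matrix of raw (unnormalized) embeddings.
#' @param ewm an \linkS4class{ExpandedWeightMatrix} whose local block is
#'   the raw trainable \code{Wk}.
#' @param labels character vector of sample class labels; each must name a
#'   local (trainable) column.
#' @param Qhat per-sample quality indicator in [-1, 1] (scalar recycled).
#' @param params a \code{\link{marginParams}}.
#' @return list with \code{loss} (batch mean), \code{perSample},
#'   \code{gradEmbeddings} (n x d), \code{gradW} (d x Nk, local block).
#' @export
fedpsfvLoss <- function(embeddings, ewm, labels, Qhat = 0,
                        params = marginParams()) {
  map <- ewm@map
  n <- nrow(embeddings)
  Qhat <- rep_len(Qhat, n)
  localCols <- which(map$is_local)
  targetCol <- localCols[match(labels, map$class_label[localCols])]
  if (any(is.na(targetCol)))
    stop("every label must map to a local trainable column")
  E <- l2NormalizeRows(embeddings)
  Wn <- l2NormalizeCols(ewm@W)
  C <- E %*% Wn
  L <- params$s * C
  tIdx <- cbind(seq_len(n), targetCol)
  cosT <- C[tIdx]
  L[tIdx] <- targetLogit(cosT, Qhat, params)
  ## exclude prototype columns that duplicate the sample's own label
  protoSame <- outer(labels, ifelse(map$is_local, NA, map$class_label), "==")
  protoSame[is.na(protoSame)] <- FALSE
  L[protoSame] <- -Inf
  mx <- apply(L, 1, max)
  lse <- mx + log(rowSums(exp(L - mx)))
  perSample <- lse - L[tIdx]
  if (any(!is.finite(perSample))) stop("non-finite loss")
  P <- exp(L - lse)                      # softmax; masked columns get 0
  G <- P
  G[tIdx] <- G[tIdx] - 1
  dfdc <- targetLogitDCos(cosT, Qhat, params)
  Gc <- G * params$s
  Gc[tIdx] <- G[tIdx] * dfdc
  Gc <- Gc / n
  ## back through the cosine to raw embeddings (rows) and raw Wk (columns)
  dE <- Gc %*% t(Wn)
  zNorm <- sqrt(rowSums(embeddings^2))
  dZ <- (dE - E * rowSums(dE * E)) / zNorm
  GcL <- Gc[, localCols, drop = FALSE]
  dWn <- t(E) %*% GcL
  WL <- ewm@W[, localCols, drop = FALSE]
  wNorm <- sqrt(colSums(WL^2))
  WnL <- Wn[, localCols, drop = FALSE]
  dWk <- sweep(dWn - sweep(WnL, 2, colSums(dWn * WnL), "*"), 2, wNorm, "/")
  list(loss = mean(perSample), perSample = as.numeric(perSample),
       gradEmbeddings = dZ, gradW = dWk)
}
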
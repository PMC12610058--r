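#' Sobel gradient configuration
#'
#' Parameters of the gradient-based enhancement step: the finger
#' orientation (which decides whether the 3x3 Sobel stencil or its
#' transpose is applied) and the gradient threshold \code{T}. Gradient
#' responses whose magnitude exceeds \code{T} are zeroed, so every gradient
#' pixel lies in [0, T]; \code{T = 100} is the usual value.
#'
#' @param orientation "vertical" or "horizontal" finger axis.
#' @param threshold positive gradient threshold in intensity units.
#' @return An object of class \code{"SobelConfig"}.
#' @export
sobelConfig <- function(orientation = c("vertical", "horizontal"),
                        threshold = 100) {
  orientation <- match.arg(orientation)
  if (threshold <= 0) stop("threshold must be positive")
  structure(list(orientation = orientation, threshold = threshold),
            class = "SobelConfig")
}

#' @export
print.SobelConfig <- function(x, ...) {
  cat(sprintf("SobelConfig: %s orientation, threshold %g\n",
              x$orientation, x$threshold))
  invisible(x)
}

## The fixed 3x3 Sobel stencil for vertically oriented fingers; the
## horizontal case uses its transpose.
sobelKernel <- function(orientation) {
  G <- matrix(c(-1, 0, 1,
                -2, 0, 2,
                -1, 0, 1), nrow = 3, byrow = TRUE)
  if (orientation == "horizontal") t(G) else G
}

## 3x3 correlation with replicate padding so the output keeps the input
## shape; a direct shifted-sum is exact (no FFT round-off) and fast enough.
conv3x3Replicate <- function(img, G) {
  H <- nrow(img); W <- ncol(img)
  P <- img[c(1, seq_len(H), H), c(1, seq_len(W), W)]
  out <- matrix(0, H, W)
  for (i in 1:3) for (j in 1:3) {
    if (G[i, j] != 0)
      out <- out + G[i, j] * P[i:(i + H - 1), j:(j + W - 1), drop = FALSE]
  }
  out
}

#' Thresholded Sobel gradient image
#'
#' Computes the gradient magnitude \code{|G * I|} of a vein image with the
#' 3x3 Sobel stencil (transposed for horizontally oriented fingers),
#' replicate padding at the borders, then zeroes every pixel whose
#' magnitude exceeds the threshold \code{T}. The surviving responses trace
#' vein edges; the zeroing of strong responses suppresses finger-boundary
#' edges that would otherwise dominate both the enhancement and the edge
#' intensity.
#'
#' @param image numeric matrix (at least 3x3) of intensities in [0, 255].
#' @param config a \code{\link{sobelConfig}}.
#' @return Numeric matrix of the same shape with values in [0, T].
#' @examples
#' img <- matrix(100, 8, 8); img[, 5:8] <- 130
#' g <- sobelGradient(img, sobelConfig("vertical"))
#' range(g)
#' @export
sobelGradient <- function(image, config = sobelConfig()) {
  if (nrow(image) < 3 || ncol(image) < 3)
    stop("image must be at least 3x3 for the Sobel stencil")
  raw <- abs(conv3x3Replicate(image, sobelKernel(config$orientation)))
  raw[raw > config$threshold] <- 0
  raw
}

#' Gradient enhancement of a vein image
#'
#' Adds the thresholded gradient image to the original
#' (\code{I' = I + Ig}) and clips to the 8-bit range. Since the gradient
#' image is non-negative, no pixel is darkened.
#'
#' @param image numeric matrix in [0, 255].
#' @param gradient its gradient image from \code{\link{sobelGradient}}.
#' @return Enhanced image, clipped to [0, 255].
#' @export
enhanceImage <- function(image, gradient) {
  if (!all(dim(image) == dim(gradient)))
    stop("image and gradient shapes differ")
  clip01(image + gradient, 0, 255)
}

#' Edge intensity of a gradient image
#'
#' The sum of all (thresholded) gradient pixels: a scalar proxy for how
#' much resolvable vein edge structure the image carries, used downstream
#' as an image-quality signal.
#'
#' @param gradient gradient image from \code{\link{sobelGradient}}.
#' @return Non-negative scalar.
#' @export
edgeIntensity <- function(gradient) sum(gradient)

#' Per-class mean edge intensities of a client dataset
#'
#' Computes the edge intensity of every sample and averages within each
#' class, yielding the class-level edge intensity set \code{B_k}.
#'
#' @param client a \linkS4class{VeinClient}.
#' @param config a \code{\link{sobelConfig}}; defaults to the client's own
#'   orientation with threshold 100.
#' @return data.frame with columns \code{class_label}, \code{b}, ordered by
#'   first appearance of each class.
#' @export
classEdgeIntensities <- function(client, config = NULL) {
  config <- config %||% sobelConfig(client@orientation)
  if (length(client@images) == 0) stop("client has no images")
  b <- vapply(client@images,
              function(im) edgeIntensity(sobelGradient(im, config)),
              numeric(1))
  labs <- unique(client@labels)
  data.frame(class_label = labs,
             b = vapply(labs, function(l) mean(b[client@labels == l]),
                        numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Min-max normalization of class edge intensities
#'
#' Maps the class edge intensity set onto [0, 1] with the minimum at 0 and
#' the maximum at 1. In the degenerate cases (a single class, or all
#' classes equal) every value is set to the neutral 0.5 so the downstream
#' quality score is 50 and the margin reduces to the fixed-margin case.
#'
#' @param b numeric vector of class edge intensities.
#' @return Numeric vector in [0, 1].
#' @export
normalizeEdgeIntensities <- function(b) {
  if (length(b) == 0) stop("empty edge intensity set")
  rng <- range(b)
  if (diff(rng) == 0) return(rep(0.5, length(b)))
  (b - rng[1]) / diff(rng)
}

#' Quality score from normalized edge intensity
#'
#' Logistic mapping \code{Q = 100 / (1 + exp(-u (b' - 0.5)))} of the
#' normalized edge intensity onto (0, 100); \code{u} controls the
#' steepness (typically 10). Strictly increasing, with
#' \code{Q(b') + Q(1 - b') = 100} and \code{Q(0.5) = 50}.
#'
#' @param bPrime normalized edge intensity in [0, 1] (vectorized).
#' @param u positive steepness parameter.
#' @return Quality scores in (0, 100).
#' @export
qualityScore <- function(bPrime, u = 10) {
  if (u <= 0) stop("u must be positive")
  if (any(bPrime < 0 | bPrime > 1)) stop("bPrime must lie in [0, 1]")
  100 / (1 + exp(-u * (bPrime - 0.5)))
}

#' Batch quality indicator
#'
#' Standardizes the quality scores of the samples in a batch
#' (\code{(Q - mean) / (sd * h)}, population standard deviation, batch
#' statistics only) and clips to [-1, 1] for numerical stability. When the
#' batch has a single sample or zero spread the indicator is 0, which
#' recovers the plain fixed-margin loss downstream.
#'
#' @param Q numeric vector of per-sample quality scores (batch size >= 1).
#' @param h positive scale hyperparameter (typically 0.33).
#' @return Vector of indicators in [-1, 1].
#' @export
batchQualityIndicator <- function(Q, h = 0.33) {
  if (length(Q) == 0) stop("empty batch")
  if (h <= 0) stop("h must be positive")
  mu <- mean(Q)
  sigma <- sqrt(mean((Q - mu)^2))
  if (length(Q) == 1 || sigma == 0) return(rep(0, length(Q)))
  clip01((Q - mu) / (sigma * h), -1, 1)
}

#' Per-class quality records for a client
#'
#' The preprocessing pass over a client's training split: per-class edge
#' intensity \code{b}, its min-max normalization \code{b'}, and the
#' logistic quality score \code{Q}. Computed once before federated
#' training begins and looked up per batch.
#'
#' @param client a \linkS4class{VeinClient} (training split).
#' @param config optional \code{\link{sobelConfig}}.
#' @param u steepness of the quality-score logistic.
#' @return data.frame with columns \code{class_label}, \code{b},
#'   \code{b_prime}, \code{Q}.
#' @export
clientQualityRecords <- function(client, config = NULL, u = 10) {
  rec <- classEdgeIntensities(client, config)
  rec$b_prime <- normalizeEdgeIntensities(rec$b)
  rec$Q <- qualityScore(rec$b_prime, u)
  rec
}

#' Enhance every image of a client
#'
#' Applies \code{\link{sobelGradient}} + \code{\link{enhanceImage}} to each
#' image, returning a new client whose images are the enhanced ones.
#'
#' @param client a \linkS4class{VeinClient}.
#' @param config optional \code{\link{sobelConfig}}.
#' @return A \linkS4class{VeinClient} with enhanced images.
#' @export
enhanceClient <- function(client, config = NULL) {
  config <- config %||% sobelConfig(client@orientation)
  imgs <- lapply(client@images, function(im)
    enhanceImage(im, sobelGradient(im, config)))
  new("VeinClient", clientId = client@clientId, images = imgs,
      labels = client@labels, orientation = client@orientation)
}
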
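#' Construct a synthetic federation specification
#'
#' Builds a \linkS4class{FederationSpec} describing a heterogeneous
#' multi-client collection of finger-vein-like images. Heterogeneity knobs
#' (class counts, samples per class, orientation, contrast, noise,
#' illumination) mirror the ways real multi-organization vein datasets
#' differ: different acquisition devices produce different contrast and
#' noise floors, different protocols produce different class counts and
#' samples per class, and some devices image the finger vertically rather
#' than horizontally.
#'
#' @param nClasses integer vector, classes per client (each >= 2).
#' @param samplesPerClass integer vector (recycled), samples per class
#'   (each >= 2 so genuine pairs exist).
#' @param height,width image dimensions in pixels (recycled); must be
#'   at least 16.
#' @param orientation "vertical" or "horizontal" finger axis (recycled).
#' @param contrastLevel contrast factor in (0, 1] (recycled); 1 is the
#'   native device contrast.
#' @param noiseSd additive Gaussian pixel noise standard deviation in 8-bit
#'   intensity units (recycled).
#' @param illuminationOffset constant brightness offset in intensity units
#'   (recycled).
#' @param clientId character client identifiers (default "client1", ...).
#' @param sharedClassFraction fraction of classes drawn from a cross-client
#'   shared identity pool (default 0: all labels disjoint).
#' @param masterSeed integer master seed; the full federation is a pure
#'   function of the spec including this seed.
#' @return A \linkS4class{FederationSpec}.
#' @examples
#' spec <- federationSpec(nClasses = c(4, 3), samplesPerClass = 3,
#'                        masterSeed = 7)
#' spec
#' @export
federationSpec <- function(nClasses, samplesPerClass = 6,
                           height = 64, width = 128,
                           orientation = "horizontal",
                           contrastLevel = 1, noiseSd = 4,
                           illuminationOffset = 0,
                           clientId = NULL,
                           sharedClassFraction = 0,
                           masterSeed = 1) {
  m <- length(nClasses)
  if (m < 1) stop("at least one client is required")
  clientId <- clientId %||% paste0("client", seq_len(m))
  clients <- data.frame(
    client_id = as.character(clientId),
    n_classes = as.integer(nClasses),
    samples_per_class = as.integer(rep_len(samplesPerClass, m)),
    height = as.integer(rep_len(height, m)),
    width = as.integer(rep_len(width, m)),
    orientation = rep_len(orientation, m),
    contrast_level = rep_len(contrastLevel, m),
    noise_sd = rep_len(noiseSd, m),
    illumination_offset = rep_len(illuminationOffset, m),
    stringsAsFactors = FALSE)
  new("FederationSpec", clients = clients,
      sharedClassFraction = sharedClassFraction, masterSeed = masterSeed)
}

#' Generate a vein identity template
#'
#' Creates the renderable identity pattern for one finger: a set of smooth
#' dark curves (veins) threading a brighter finger-shaped region on a dark
#' background. The template stores curve control points and geometry, not
#' pixels; rendering happens in \code{\link{renderSample}}. Vein curves are
#' darker than the surrounding tissue, matching near-infrared transmission
#' imaging in which hemoglobin absorbs the illumination.
#'
#' @param seed integer seed; templates are deterministic in it.
#' @param shape c(height, width) in pixels, each >= 16.
#' @param nVeins number of vein curves (>= 1).
#' @param orientation "vertical" (finger axis along image rows) or
#'   "horizontal" (along columns).
#' @return An object of class \code{"veinTemplate"}.
#' @examples
#' tpl <- veinTemplate(1, shape = c(64, 64), nVeins = 4)
#' img <- renderSample(tpl)
#' range(img)
#' @export
veinTemplate <- function(seed, shape = c(64, 128), nVeins = 4,
                         orientation = "vertical") {
  if (length(shape) != 2 || any(shape < 16))
    stop("shape must be at least 16x16: vein curves are unresolvable below that")
  if (nVeins < 1) stop("nVeins must be >= 1")
  orientation <- match.arg(orientation, c("vertical", "horizontal"))
  ## canonical frame: finger axis along rows (length L), cross axis = cols
  if (orientation == "vertical") { L <- shape[1]; Wd <- shape[2] }
  else                          { L <- shape[2]; Wd <- shape[1] }
  nCtrl <- 7L
  withSeed(seed, {
    ## finger occupies the central band of the cross axis, edges wobbling
    margin <- 0.12 * Wd
    edgeWobble <- matrix(rnorm(2 * nCtrl, sd = 0.015 * Wd), nCtrl, 2)
    ## vein centers spread over the finger interior with jittered spacing
    span <- c(margin + 0.16 * Wd, Wd - margin - 0.16 * Wd)
    base <- seq(span[1], span[2], length.out = nVeins)
    ctrl <- matrix(0, nCtrl, nVeins)
    for (v in seq_len(nVeins)) {
      drift <- cumsum(rnorm(nCtrl, sd = 0.035 * Wd))
      ctrl[, v] <- base[v] + runif(1, -0.05, 0.05) * Wd + drift - mean(drift)
    }
    ctrl <- pmin(pmax(ctrl, margin + 2), Wd - margin - 2)
    structure(list(
      seed = seed, shape = shape, orientation = orientation,
      L = L, Wd = Wd, nVeins = nVeins, nCtrl = nCtrl,
      margin = margin, edgeWobble = edgeWobble,
      ctrl = ctrl,
      widths = runif(nVeins, 1.3, 2.6),
      depths = runif(nVeins, 60, 110),
      tissue = 185 + runif(1, -8, 8),
      background = 45), class = "veinTemplate")
  })
}

#' @export
print.veinTemplate <- function(x, ...) {
  cat(sprintf("veinTemplate: %d veins, %dx%d px, %s, seed %s\n",
              x$nVeins, x$shape[1], x$shape[2], x$orientation,
              format(x$seed)))
  invisible(x)
}

## Evaluate a control polygon as a smooth curve at nOut points via natural
## cubic spline interpolation.
splineCurve <- function(ctrl, nOut) {
  t <- seq(0, 1, length.out = length(ctrl))
  stats::spline(t, ctrl, xout = seq(0, 1, length.out = nOut))$y
}

## Clean canonical rendering of a template (double matrix, un-noised,
## unrounded), in the template's own image orientation.
renderCanvas <- function(template) {
  L <- template$L; Wd <- template$Wd
  x <- matrix(seq_len(Wd), L, Wd, byrow = TRUE)     # cross-axis coordinate
  left <- template$margin + splineCurve(template$edgeWobble[, 1], L)
  right <- Wd - template$margin + splineCurve(template$edgeWobble[, 2], L)
  mask <- stats::plogis((x - left) / 1.5) * stats::plogis((right - x) / 1.5)
  tissue <- template$tissue +
    18 * exp(-((x - (left + right) / 2)^2) / (2 * ((right - left) / 3.2)^2))
  veins <- matrix(0, L, Wd)
  for (v in seq_len(template$nVeins)) {
    center <- splineCurve(template$ctrl[, v], L)
    veins <- veins + template$depths[v] *
      exp(-(x - center)^2 / (2 * template$widths[v]^2))
  }
  canvas <- template$background + mask * (tissue - veins - template$background)
  if (template$orientation == "horizontal") canvas <- t(canvas)
  canvas
}

## Bilinear resampling under a rigid transform (rotation about the center
## plus translation), replicate border.
warpImage <- function(img, shift = c(0, 0), rotation = 0) {
  if (all(shift == 0) && rotation == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  th <- rotation * pi / 180
  cth <- cos(th); sth <- sin(th)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- matrix(seq_len(H), H, W) - cy
  gx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  ## inverse map: source = R^-1 (target - shift)
  ty <- gy - shift[1]; tx <- gx - shift[2]
  sy <- cth * ty + sth * tx + cy
  sx <- -sth * ty + cth * tx + cx
  sy <- pmin(pmax(sy, 1), H); sx <- pmin(pmax(sx, 1), W)
  y0 <- pmin(floor(sy), H - 1); x0 <- pmin(floor(sx), W - 1)
  fy <- sy - y0; fx <- sx - x0
  i00 <- cbind(as.vector(y0), as.vector(x0))
  v <- (1 - fy) * (1 - fx) * img[i00] +
       fy * (1 - fx) * img[i00 + c(1, 0)] +
       (1 - fy) * fx * img[i00 + c(0, 1)] +
       fy * fx * img[i00 + c(1, 1)]
  matrix(v, H, W)
}

#' Apply a contrast rescaling about mid-gray
#'
#' \code{x -> 127.5 + c (x - 127.5)}, clipped to [0, 255]; \code{c = 1} is
#' the identity. This is the transform behind the reduced-contrast
#' robustness protocol (levels such as 0.6, 0.8, 1.0).
#'
#' @param img numeric matrix in [0, 255].
#' @param contrastLevel contrast factor in (0, 1].
#' @return Matrix of the same shape in [0, 255].
#' @export
applyContrast <- function(img, contrastLevel) {
  if (contrastLevel <= 0 || contrastLevel > 1)
    stop("contrastLevel must lie in (0, 1]")
  clip01(127.5 + contrastLevel * (img - 127.5), 0, 255)
}

#' Render one sample image from an identity template
#'
#' Renders a template to pixels under sample-level jitter (sub-pixel shift,
#' small rotation, brightness offset), a client-level contrast factor and
#' additive Gaussian sensor noise, then clips to [0, 255] and rounds to
#' 8-bit integer intensities. With unit contrast, zero jitter and zero
#' noise the output equals the clean template rendering.
#'
#' @param template a \code{\link{veinTemplate}}.
#' @param jitter list with elements \code{shift} (length-2, pixels),
#'   \code{rotation} (degrees), \code{brightness} (intensity offset).
#' @param contrastLevel contrast factor in (0, 1].
#' @param noiseSd Gaussian noise standard deviation (intensity units).
#' @param seed optional seed for the noise draw; when \code{NULL} the
#'   current RNG stream is used (callers seed it).
#' @return Numeric matrix of integers in [0, 255].
#' @export
renderSample <- function(template,
                         jitter = list(shift = c(0, 0), rotation = 0,
                                       brightness = 0),
                         contrastLevel = 1, noiseSd = 0, seed = NULL) {
  if (contrastLevel <= 0 || contrastLevel > 1)
    stop("contrastLevel must lie in (0, 1]")
  doRender <- function() {
    img <- renderCanvas(template)
    img <- warpImage(img, shift = jitter$shift %||% c(0, 0),
                     rotation = jitter$rotation %||% 0)
    img <- img + (jitter$brightness %||% 0)
    img <- 127.5 + contrastLevel * (img - 127.5)
    if (noiseSd > 0) img <- img + rnorm(length(img), sd = noiseSd)
    round(clip01(img, 0, 255))
  }
  if (is.null(seed)) doRender() else withSeed(seed, doRender())
}

#' Generate a full heterogeneous federation of synthetic vein images
#'
#' Materializes every client of a \linkS4class{FederationSpec}. Class
#' labels are globally disjoint across clients by default (the setting of
#' distinct collaborating organizations); with
#' \code{sharedClassFraction > 0} a leading fraction of each client's
#' classes is drawn from a shared identity pool so that the same finger
#' appears at several clients (exercising multi-owner prototype
#' aggregation). Identical spec (including master seed) gives bit-identical
#' images.
#'
#' @param spec a \linkS4class{FederationSpec}.
#' @return A \linkS4class{VeinFederation}.
#' @examples
#' fed <- generateFederation(federationSpec(nClasses = c(3, 2),
#'   samplesPerClass = 2, height = 32, width = 32, masterSeed = 11))
#' fed
#' @export
generateFederation <- function(spec) {
  validObject(spec)
  cl <- spec@clients
  if (nrow(cl) < 1) stop("spec has no clients")
  clients <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    row <- cl[i, ]
    nShared <- floor(spec@sharedClassFraction * row$n_classes)
    labs <- c(if (nShared > 0) sprintf("shared_c%03d", seq_len(nShared)),
              sprintf("%s_c%03d", row$client_id,
                      seq_len(row$n_classes - nShared)))
    images <- vector("list", row$n_classes * row$samples_per_class)
    labels <- character(length(images))
    pos <- 0L
    for (lab in labs) {
      tplSeed <- deriveSeeds(spec@masterSeed, 1L,
                             salt = paste0("template:", lab))
      nVeins <- withSeed(tplSeed, sample(3:6, 1))
      tpl <- veinTemplate(tplSeed, shape = c(row$height, row$width),
                          nVeins = nVeins, orientation = row$orientation)
      sampleSeeds <- deriveSeeds(spec@masterSeed, row$samples_per_class,
                                 salt = paste0("samples:", row$client_id,
                                               ":", lab))
      for (s in seq_len(row$samples_per_class)) {
        img <- withSeed(sampleSeeds[s], {
          jit <- list(shift = runif(2, -2, 2),
                      rotation = runif(1, -4, 4),
                      brightness = rnorm(1, 0, 6) + row$illumination_offset)
          renderSample(tpl, jitter = jit,
                       contrastLevel = row$contrast_level,
                       noiseSd = row$noise_sd)
        })
        pos <- pos + 1L
        images[[pos]] <- img
        labels[pos] <- lab
      }
    }
    clients[[i]] <- new("VeinClient", clientId = row$client_id,
                        images = images, labels = labels,
                        orientation = row$orientation)
  }
  new("VeinFederation", spec = spec, clients = clients)
}

emptySpec <- function() {
  new("FederationSpec",
      clients = data.frame(client_id = character(), n_classes = integer(),
                           samples_per_class = integer(), height = integer(),
                           width = integer(), orientation = character(),
                           contrast_level = numeric(), noise_sd = numeric(),
                           illumination_offset = numeric(),
                           stringsAsFactors = FALSE),
      sharedClassFraction = 0, masterSeed = 0)
}

#' Write / read a federation in the class-per-directory layout
#'
#' \code{writeDataset} writes \code{root/<client>/<class>/<sample>.png}
#' (lossless 8-bit grayscale PNG) plus a per-client \code{_meta.yaml}
#' carrying the orientation tag; \code{readDataset} reads the same layout
#' back (and so also reads any user-supplied dataset organized this way).
#' The round trip is lossless for labels and pixels.
#'
#' @param federation a \linkS4class{VeinFederation}.
#' @param root dataset root directory.
#' @return \code{writeDataset} returns \code{root} invisibly;
#'   \code{readDataset} returns a \linkS4class{VeinFederation}.
#' @export
writeDataset <- function(federation, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (cl in federation@clients) {
    cdir <- file.path(root, cl@clientId)
    dir.create(cdir, showWarnings = FALSE)
    yaml::write_yaml(list(orientation = cl@orientation),
                     file.path(cdir, "_meta.yaml"))
    counters <- list()
    for (i in seq_along(cl@images)) {
      lab <- cl@labels[i]
      ldir <- file.path(cdir, lab)
      dir.create(ldir, showWarnings = FALSE)
      counters[[lab]] <- (counters[[lab]] %||% 0L) + 1L
      png::writePNG(cl@images[[i]] / 255,
                    file.path(ldir, sprintf("s%03d.png", counters[[lab]])))
    }
  }
  invisible(root)
}

#' @rdname writeDataset
#' @export
readDataset <- function(root) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  clientDirs <- list.dirs(root, recursive = FALSE)
  if (length(clientDirs) == 0) stop("no client directories under ", root)
  clients <- vector("list", length(clientDirs))
  for (i in seq_along(clientDirs)) {
    cdir <- clientDirs[i]
    metaFile <- file.path(cdir, "_meta.yaml")
    orientation <- if (file.exists(metaFile))
      yaml::read_yaml(metaFile)$orientation %||% "vertical" else "vertical"
    classDirs <- list.dirs(cdir, recursive = FALSE)
    if (length(classDirs) == 0)
      stop("client directory has no class subdirectories: ", cdir)
    images <- list(); labels <- character()
    for (ldir in classDirs) {
      files <- sort(list.files(ldir, full.names = TRUE))
      if (length(files) == 0) stop("empty class directory: ", ldir)
      for (f in files) {
        if (!grepl("\\.png$", f, ignore.case = TRUE))
          stop("non-PNG file in dataset tree: ", f)
        px <- tryCatch(png::readPNG(f),
                       error = function(e) stop("unreadable image file: ", f))
        if (length(dim(px)) == 3) px <- px[, , 1]
        images[[length(images) + 1L]] <- round(px * 255)
        labels <- c(labels, basename(ldir))
      }
    }
    clients[[i]] <- new("VeinClient", clientId = basename(cdir),
                        images = images, labels = labels,
                        orientation = orientation)
  }
  new("VeinFederation", spec = emptySpec(), clients = clients)
}
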
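## Central S4 containers. Per-operation results (quality tables, metric rows)
## stay plain data.frames, as is usual for light tabular returns.

#' FederationSpec: configuration of a synthetic multi-client federation
#'
#' Describes a heterogeneous federation of clients, one row per client:
#' class count, samples per class, image geometry, finger orientation,
#' contrast level, noise level and illumination offset. Together with
#' \code{masterSeed} the spec fully determines the generated dataset:
#' identical spec + seed give bit-identical images.
#'
#' @slot clients data.frame with columns \code{client_id}, \code{n_classes},
#'   \code{samples_per_class}, \code{height}, \code{width},
#'   \code{orientation} ("vertical" or "horizontal"), \code{contrast_level}
#'   in (0,1], \code{noise_sd} and \code{illumination_offset} in 8-bit
#'   intensity units.
#' @slot sharedClassFraction fraction of each client's classes drawn from a
#'   pool shared across clients (default 0: disjoint labels, the setting of
#'   distinct collaborating organizations). Positive values exercise the
#'   multi-owner prototype aggregation branch.
#' @slot masterSeed integer master seed.
#'
#' @exportClass FederationSpec
setClass("FederationSpec",
  representation(clients = "data.frame",
                 sharedClassFraction = "numeric",
                 masterSeed = "numeric"))

setValidity("FederationSpec", function(object) {
  cl <- object@clients
  need <- c("client_id", "n_classes", "samples_per_class", "height", "width",
            "orientation", "contrast_level", "noise_sd", "illumination_offset")
  if (!all(need %in% names(cl)))
    return(paste("clients table must have columns:", paste(need, collapse = ", ")))
  ## zero rows allowed as a placeholder for datasets read back from disk
  if (nrow(cl) == 0) return(TRUE)
  if (anyDuplicated(cl$client_id)) return("client_id values must be unique")
  if (any(cl$n_classes < 2)) return("every client needs >= 2 classes")
  if (any(cl$samples_per_class < 2))
    return("samples_per_class must be >= 2 (open-set pairing needs >= 2 genuine samples)")
  if (any(cl$height < 16 | cl$width < 16)) return("images must be at least 16x16")
  if (any(cl$contrast_level <= 0 | cl$contrast_level > 1))
    return("contrast_level must lie in (0, 1]")
  if (any(cl$noise_sd < 0)) return("noise_sd must be non-negative")
  if (!all(cl$orientation %in% c("vertical", "horizontal")))
    return("orientation must be 'vertical' or 'horizontal'")
  if (object@sharedClassFraction < 0 || object@sharedClassFraction > 1)
    return("sharedClassFraction must lie in [0, 1]")
  TRUE
})

#' VeinClient: one client's image collection
#'
#' @slot clientId character client identifier.
#' @slot images list of numeric matrices, intensities in [0, 255].
#' @slot labels character vector of class labels, parallel to \code{images}.
#' @slot orientation finger orientation tag ("vertical" or "horizontal").
#'
#' @exportClass VeinClient
setClass("VeinClient",
  representation(clientId = "character", images = "list",
                 labels = "character", orientation = "character"))

setValidity("VeinClient", function(object) {
  if (length(object@images) != length(object@labels))
    return("images and labels must have equal length")
  for (im in object@images) {
    if (!is.matrix(im)) return("every image must be a matrix")
    if (any(im < 0 | im > 255)) return("pixel intensities must lie in [0, 255]")
  }
  if (!object@orientation %in% c("vertical", "horizontal"))
    return("orientation must be 'vertical' or 'horizontal'")
  TRUE
})

#' VeinFederation: a set of client datasets
#'
#' @slot spec the generating \linkS4class{FederationSpec} (may be a
#'   zero-row placeholder for datasets read from disk).
#' @slot clients list of \linkS4class{VeinClient}.
#'
#' @exportClass VeinFederation
setClass("VeinFederation",
  representation(spec = "FederationSpec", clients = "list"))

#' PrototypeSet: per-class embedding prototypes with ownership metadata
#'
#' Columns are unit-norm d-dimensional class prototypes; the ownership
#' table records which client computed each prototype from how many samples.
#'
#' @slot vectors d x n numeric matrix, one unit-norm column per prototype.
#' @slot ownership data.frame with columns \code{client_id},
#'   \code{class_label}, \code{n_samples}, parallel to the columns.
#'
#' @exportClass PrototypeSet
setClass("PrototypeSet",
  representation(vectors = "matrix", ownership = "data.frame"))

setValidity("PrototypeSet", function(object) {
  if (ncol(object@vectors) != nrow(object@ownership))
    return("one ownership row per prototype column is required")
  if (nrow(object@ownership) > 0) {
    need <- c("client_id", "class_label", "n_samples")
    if (!all(need %in% names(object@ownership)))
      return("ownership needs columns client_id, class_label, n_samples")
    if (anyDuplicated(object@ownership[, c("client_id", "class_label")]))
      return("duplicate (client_id, class_label) prototype")
    if (!all(is.finite(object@vectors))) return("prototype entries must be finite")
  }
  TRUE
})

#' ExpandedWeightMatrix: prototype-expanded classifier weight matrix
#'
#' The d x N concatenation of the other clients' prototype blocks with the
#' client's own trainable weight block in client order, plus the global
#' column map. Prototype columns are frozen; exactly the local block is
#' trainable.
#'
#' @slot W d x N numeric matrix (raw local block; unit prototype columns).
#' @slot map data.frame with columns \code{client_id}, \code{class_label},
#'   \code{is_local}, parallel to the columns of \code{W}.
#' @slot clientId the owning client.
#'
#' @exportClass ExpandedWeightMatrix
setClass("ExpandedWeightMatrix",
  representation(W = "matrix", map = "data.frame", clientId = "character"))

setValidity("ExpandedWeightMatrix", function(object) {
  if (ncol(object@W) != nrow(object@map))
    return("column map must have one row per column of W")
  need <- c("client_id", "class_label", "is_local")
  if (!all(need %in% names(object@map)))
    return("map needs columns client_id, class_label, is_local")
  if (anyDuplicated(object@map[, c("client_id", "class_label")]))
    return("duplicate (client_id, class_label) column")
  TRUE
})

#' VerificationScores: genuine and impostor similarity scores
#'
#' Cosine similarities of all unordered sample pairs of an open-set test
#' split, partitioned by label equality.
#'
#' @slot genuine numeric vector of same-class pair similarities.
#' @slot impostor numeric vector of cross-class pair similarities.
#'
#' @exportClass VerificationScores
setClass("VerificationScores",
  representation(genuine = "numeric", impostor = "numeric"))

setValidity("VerificationScores", function(object) {
  s <- c(object@genuine, object@impostor)
  if (length(s) && (any(!is.finite(s)) || any(s < -1 - 1e-9 | s > 1 + 1e-9)))
    return("scores must be finite cosine similarities in [-1, 1]")
  TRUE
})

setMethod("show", "FederationSpec", function(object) {
  cat(sprintf("FederationSpec: %d client(s), master seed %s\n",
              nrow(object@clients), format(object@masterSeed)))
  print(object@clients, row.names = FALSE)
})

setMethod("show", "VeinClient", function(object) {
  cat(sprintf("VeinClient '%s': %d images, %d classes, %s orientation\n",
              object@clientId, length(object@images),
              length(unique(object@labels)), object@orientation))
})

setMethod("show", "VeinFederation", function(object) {
  cat(sprintf("VeinFederation: %d client(s)\n", length(object@clients)))
  for (cl in object@clients)
    cat(sprintf("  %s: %d images, %d classes (%s)\n", cl@clientId,
                length(cl@images), length(unique(cl@labels)), cl@orientation))
})

setMethod("show", "PrototypeSet", function(object) {
  cat(sprintf("PrototypeSet: %d prototype(s) of dimension %d from %d client(s)\n",
              ncol(object@vectors), nrow(object@vectors),
              length(unique(object@ownership$client_id))))
})

setMethod("show", "ExpandedWeightMatrix", function(object) {
  cat(sprintf(
    "ExpandedWeightMatrix for '%s': d = %d, %d columns (%d local trainable, %d prototype)\n",
    object@clientId, nrow(object@W), ncol(object@W),
    sum(object@map$is_local), sum(!object@map$is_local)))
})

setMethod("show", "VerificationScores", function(object) {
  cat(sprintf("VerificationScores: %d genuine, %d impostor pairs\n",
              length(object@genuine), length(object@impostor)))
})
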
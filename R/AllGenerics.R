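#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers: client
#' identifier, class labels, image list, prototype vectors and ownership
#' table, genuine/impostor score vectors.
#'
#' @param object an S4 object from this package.
#' @return The underlying slot value (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("clientId", function(object) standardGeneric("clientId"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("imageList", function(object) standardGeneric("imageList"))

#' @rdname accessors
#' @export
setGeneric("clientList", function(object) standardGeneric("clientList"))

#' @rdname accessors
#' @export
setGeneric("prototypeVectors", function(object) standardGeneric("prototypeVectors"))

#' @rdname accessors
#' @export
setGeneric("prototypeOwnership", function(object) standardGeneric("prototypeOwnership"))

#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(object) standardGeneric("weightMatrix"))

#' @rdname accessors
#' @export
setGeneric("columnMap", function(object) standardGeneric("columnMap"))

#' @rdname accessors
#' @export
setGeneric("genuineScores", function(object) standardGeneric("genuineScores"))

#' @rdname accessors
#' @export
setGeneric("impostorScores", function(object) standardGeneric("impostorScores"))

#' @rdname accessors
setMethod("clientId", "VeinClient", function(object) object@clientId)
#' @rdname accessors
setMethod("classLabels", "VeinClient", function(object) object@labels)
#' @rdname accessors
setMethod("imageList", "VeinClient", function(object) object@images)
#' @rdname accessors
setMethod("clientList", "VeinFederation", function(object) object@clients)
#' @rdname accessors
setMethod("prototypeVectors", "PrototypeSet", function(object) object@vectors)
#' @rdname accessors
setMethod("prototypeOwnership", "PrototypeSet", function(object) object@ownership)
#' @rdname accessors
setMethod("weightMatrix", "ExpandedWeightMatrix", function(object) object@W)
#' @rdname accessors
setMethod("columnMap", "ExpandedWeightMatrix", function(object) object@map)
#' @rdname accessors
setMethod("genuineScores", "VerificationScores", function(object) object@genuine)
#' @rdname accessors
setMethod("impostorScores", "VerificationScores", function(object) object@impostor)
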
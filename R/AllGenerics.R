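#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers. Slot access in
#' user code should always go through these rather than `@`.
#'
#' @param object an object of one of the package's S4 classes.
#' @param x an object of one of the package's S4 classes.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("dpi", function(object) standardGeneric("dpi"))

#' @rdname accessors
#' @export
setGeneric("scanChannel", function(object) standardGeneric("scanChannel"))

#' @rdname accessors
#' @export
setGeneric("scanRole", function(object) standardGeneric("scanRole"))

#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("netOD", function(object) standardGeneric("netOD"))

#' @rdname accessors
#' @export
setGeneric("netODSigma", function(object) standardGeneric("netODSigma"))

#' @rdname accessors
#' @export
setGeneric("profileMeta", function(object) standardGeneric("profileMeta"))

#' @rdname accessors
#' @export
setGeneric("coefA", function(object) standardGeneric("coefA"))

#' @rdname accessors
#' @export
setGeneric("coefB", function(object) standardGeneric("coefB"))

#' @rdname accessors
#' @export
setGeneric("coefN", function(object) standardGeneric("coefN"))

#' @rdname accessors
#' @export
setGeneric("sigmaA", function(object) standardGeneric("sigmaA"))

#' @rdname accessors
#' @export
setGeneric("sigmaB", function(object) standardGeneric("sigmaB"))

#' @rdname accessors
#' @export
setGeneric("netODDomain", function(object) standardGeneric("netODDomain"))

#' @rdname accessors
#' @export
setGeneric("doseRel", function(object) standardGeneric("doseRel"))

#' @rdname accessors
#' @export
setGeneric("attenuationCAX", function(object) standardGeneric("attenuationCAX"))

#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
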
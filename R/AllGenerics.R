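#' Accessor generics
#'
#' Small accessor family for the package's S4 classes: `coords()` and
#' `frames()` read a [LocalizationTable]; `centroids()`, `clusterSizes()` and
#' `membership()` read an [EmitterClusterSet] (or the cluster set inside an
#' [OrigamiObject]); `distances()` and `expansionFactor()` read an
#' [NNDistanceSet]; `nnDistances()` builds one.
#'
#' @param object,x an object of the documented class.
#' @param ... passed on to methods.
#' @return the slot contents (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(object) standardGeneric("clusterSizes"))

#' @rdname accessors
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' @rdname accessors
#' @export
setGeneric("distances", function(object) standardGeneric("distances"))

#' @rdname accessors
#' @export
setGeneric("expansionFactor", function(object) standardGeneric("expansionFactor"))

#' @rdname nnDistances
#' @export
setGeneric("nnDistances", function(x, ...) standardGeneric("nnDistances"))
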
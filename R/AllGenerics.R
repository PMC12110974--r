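#' Accessor generics
#'
#' Small accessor family for the result classes: `vaf()` returns the variant
#' allele fraction, `vafPercent()` the same in percent, `concentration()` the
#' copies/uL estimate, `lob()`, `lod95()` and `loq()` the detection limits,
#' `rSquared()` the linearity coefficient, `clusterCounts()` the four-quadrant
#' tallies as a named vector, and `nDroplets()` the droplet count of a well.
#'
#' @param object a DuplexDrops result object.
#' @return the scalar or named vector documented for each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vaf", function(object) standardGeneric("vaf"))

#' @rdname accessors
#' @export
setGeneric("vafPercent", function(object) standardGeneric("vafPercent"))

#' @rdname accessors
#' @export
setGeneric("concentration", function(object) standardGeneric("concentration"))

#' @rdname accessors
#' @export
setGeneric("lob", function(object) standardGeneric("lob"))

#' @rdname accessors
#' @export
setGeneric("lod95", function(object) standardGeneric("lod95"))

#' @rdname accessors
#' @export
setGeneric("loq", function(object) standardGeneric("loq"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("clusterCounts", function(object) standardGeneric("clusterCounts"))

#' @rdname accessors
#' @export
setGeneric("nDroplets", function(object) standardGeneric("nDroplets"))

#' @rdname accessors
#' @export
setGeneric("rankPosition", function(object) standardGeneric("rankPosition"))
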
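#' @include refltriage-package.R
NULL

#' Accessor generics for refltriage objects
#'
#' Small family of accessors shared by the container classes:
#' `unitCell()` returns the [UnitCell-class] of an object, `spaceGroup()`
#' its [SpaceGroup-class], `reflections()` the reflection table
#' (a `data.frame`), and `isMerged()` / `isAnomalous()` the container flags.
#'
#' @param x a refltriage object
#' @return the slot value; see the class documentation for details
#' @name accessors
#' @aliases unitCell spaceGroup reflections isMerged isAnomalous
NULL

#' @rdname accessors
#' @export
setGeneric("unitCell", function(x) standardGeneric("unitCell"))

#' @rdname accessors
#' @export
setGeneric("spaceGroup", function(x) standardGeneric("spaceGroup"))

#' @rdname accessors
#' @export
setGeneric("reflections", function(x) standardGeneric("reflections"))

#' @rdname accessors
#' @export
setGeneric("isMerged", function(x) standardGeneric("isMerged"))

#' @rdname accessors
#' @export
setGeneric("isAnomalous", function(x) standardGeneric("isAnomalous"))
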
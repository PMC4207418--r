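#' Accessors for package classes
#'
#' Small accessor generics so user code never reaches into slots:
#' `atoms()` / `bonds()` return the per-atom and per-bond data.frames of
#' a [Molecule-class], `moleculeId()` its identifier, `isPrepared()` its
#' preparation state; `trainIds()`, `testIds()` and `externalIds()`
#' return the partitions of a [SplitResult-class].
#'
#' @param object a package object.
#' @return The slot contents (data.frame, character or logical).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("bonds", function(object) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setGeneric("moleculeId", function(object) standardGeneric("moleculeId"))
#' @rdname accessors
#' @export
setGeneric("isPrepared", function(object) standardGeneric("isPrepared"))
#' @rdname accessors
#' @export
setGeneric("trainIds", function(object) standardGeneric("trainIds"))
#' @rdname accessors
#' @export
setGeneric("testIds", function(object) standardGeneric("testIds"))
#' @rdname accessors
#' @export
setGeneric("externalIds", function(object) standardGeneric("externalIds"))

#' @rdname accessors
setMethod("atoms", "Molecule", function(object) object@atoms)
#' @rdname accessors
setMethod("bonds", "Molecule", function(object) object@bonds)
#' @rdname accessors
setMethod("moleculeId", "Molecule", function(object) object@id)
#' @rdname accessors
setMethod("isPrepared", "Molecule", function(object) object@prepared)
#' @rdname accessors
setMethod("trainIds", "SplitResult", function(object) object@trainIds)
#' @rdname accessors
setMethod("testIds", "SplitResult", function(object) object@testIds)
#' @rdname accessors
setMethod("externalIds", "SplitResult", function(object) object@externalIds)
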
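#' @name SnpHapPower-generics
#' @title Accessor generics
#' @description Accessor generics for the package's S4 classes.
#' @param x An object.
#' @param ... Additional arguments passed to methods.
#' @keywords internal
NULL

#' @rdname SnpHapPower-generics
#' @export
setGeneric("animalIds", function(x, ...) standardGeneric("animalIds"))

#' @rdname SnpHapPower-generics
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname SnpHapPower-generics
#' @export
setGeneric("markerMap", function(x, ...) standardGeneric("markerMap"))

#' @rdname SnpHapPower-generics
#' @export
setGeneric("nAnimals", function(x, ...) standardGeneric("nAnimals"))

#' @rdname SnpHapPower-generics
#' @export
setGeneric("nSnps", function(x, ...) standardGeneric("nSnps"))

#' @rdname SnpHapPower-generics
#' @export
setGeneric("isFounder", function(x, ...) standardGeneric("isFounder"))

#' @rdname SnpHapPower-generics
#' @export
setGeneric("generations", function(x, ...) standardGeneric("generations"))

#' @rdname SnpHapPower-generics
#' @export
setGeneric("heritability", function(x, ...) standardGeneric("heritability"))

#' @rdname SnpHapPower-generics
#' @export
setGeneric("varianceComponents", function(x, ...) standardGeneric("varianceComponents"))

#' @rdname SnpHapPower-generics
#' @export
setGeneric("adjustedPhenotypes", function(x, ...) standardGeneric("adjustedPhenotypes"))

#' @rdname SnpHapPower-generics
#' @export
setGeneric("ancestralDosages", function(x, position, ...) standardGeneric("ancestralDosages"))

#' @rdname SnpHapPower-generics
#' @export
setGeneric("powerTable", function(x, ...) standardGeneric("powerTable"))

#' @rdname SnpHapPower-generics
#' @export
setGeneric("keptSnps", function(x, ...) standardGeneric("keptSnps"))

#' @rdname SnpHapPower-generics
#' @export
setGeneric("keptAnimals", function(x, ...) standardGeneric("keptAnimals"))
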
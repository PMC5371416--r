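#' @include attCfold-package.R
NULL

#' @title Accessor generics
#' @description Accessor generics for the package's S4 classes; see the
#'   class pages (\linkS4class{AttCSite}, \linkS4class{ConstraintSet},
#'   \linkS4class{FoldOutcome}, \linkS4class{ReplichoreMap},
#'   \linkS4class{IntegronRecord}) for the methods.
#' @param x object to access.
#' @name accessors
#' @keywords internal
NULL

#' @rdname accessors
#' @export
setGeneric("siteId", function(x) standardGeneric("siteId"))

#' @rdname accessors
#' @export
setGeneric("topStrand", function(x) standardGeneric("topStrand"))

#' @rdname accessors
#' @export
setGeneric("bottomStrand", function(x) standardGeneric("bottomStrand"))

#' @rdname accessors
#' @export
setGeneric("boxes", function(x) standardGeneric("boxes"))

#' @rdname accessors
#' @param value replacement value.
#' @export
setGeneric("boxes<-", function(x, value) standardGeneric("boxes<-"))

#' @rdname accessors
#' @export
setGeneric("originClass", function(x) standardGeneric("originClass"))

#' @rdname accessors
#' @export
setGeneric("forcedPairs", function(x) standardGeneric("forcedPairs"))

#' @rdname accessors
#' @export
setGeneric("strandLabel", function(x) standardGeneric("strandLabel"))

#' @rdname accessors
#' @export
setGeneric("mfeStructure", function(x) standardGeneric("mfeStructure"))

#' @rdname accessors
#' @export
setGeneric("mfeEnergy", function(x) standardGeneric("mfeEnergy"))

#' @rdname accessors
#' @export
setGeneric("ensembleEnergy", function(x) standardGeneric("ensembleEnergy"))

#' @rdname accessors
#' @export
setGeneric("pfoldValue", function(x) standardGeneric("pfoldValue"))

#' @rdname accessors
#' @export
setGeneric("oriC", function(x) standardGeneric("oriC"))

#' @rdname accessors
#' @export
setGeneric("terminus", function(x) standardGeneric("terminus"))

#' @rdname accessors
#' @export
setGeneric("attcSites", function(x) standardGeneric("attcSites"))

#' @rdname accessors
#' @export
setGeneric("elementClass", function(x) standardGeneric("elementClass"))
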
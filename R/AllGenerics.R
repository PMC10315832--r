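#' @name proteoMR-generics
#' @title Accessor generics
#'
#' @description Accessor generics for the S4 containers in this package.
#' Slot access via `@` is not part of the supported interface; use these.
#'
#' @param x an object of the documented class.
#' @param ids character vector of variant identifiers.
#' @param alpha significance level.
#' @param ... passed to methods.
#' @return The accessed component; see the class documentation.
NULL

#' @rdname proteoMR-generics
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))

#' @rdname proteoMR-generics
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))

#' @rdname proteoMR-generics
#' @export
setGeneric("genomeBuild", function(x) standardGeneric("genomeBuild"))

#' @rdname proteoMR-generics
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname proteoMR-generics
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname proteoMR-generics
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname proteoMR-generics
#' @export
setGeneric("subsetVariants", function(x, ids) standardGeneric("subsetVariants"))

#' @rdname proteoMR-generics
#' @export
setGeneric("exposureId", function(x) standardGeneric("exposureId"))

#' @rdname proteoMR-generics
#' @export
setGeneric("outcomeId", function(x) standardGeneric("outcomeId"))

#' @rdname proteoMR-generics
#' @export
setGeneric("instrumentTable", function(x) standardGeneric("instrumentTable"))

#' @rdname proteoMR-generics
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))

#' @rdname proteoMR-generics
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @rdname proteoMR-generics
#' @export
setGeneric("pleiotropyFlags", function(x) standardGeneric("pleiotropyFlags"))

#' @rdname proteoMR-generics
#' @export
setGeneric("isPleiotropic", function(x) standardGeneric("isPleiotropic"))

#' @rdname proteoMR-generics
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))

#' @rdname proteoMR-generics
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))

#' @rdname proteoMR-generics
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))

#' @rdname proteoMR-generics
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname proteoMR-generics
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname proteoMR-generics
#' @export
setGeneric("oddsRatio", function(x, ...) standardGeneric("oddsRatio"))

#' @rdname proteoMR-generics
#' @export
setGeneric("isSignificant", function(x, alpha = 0.05) standardGeneric("isSignificant"))

#' @rdname proteoMR-generics
#' @export
setGeneric("isTestable", function(x) standardGeneric("isTestable"))

#' @rdname proteoMR-generics
#' @export
setGeneric("steigerVerdict", function(x) standardGeneric("steigerVerdict"))

#' @rdname proteoMR-generics
#' @export
setGeneric("correctDirection", function(x) standardGeneric("correctDirection"))

#' @rdname proteoMR-generics
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))

#' @rdname proteoMR-generics
#' @export
setGeneric("isColocalized", function(x) standardGeneric("isColocalized"))

#' @rdname proteoMR-generics
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @rdname proteoMR-generics
#' @export
setGeneric("screenDetails", function(x) standardGeneric("screenDetails"))
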
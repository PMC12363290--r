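#' Genotype identifiers of an object
#'
#' Ordered genotype identifiers carried by a \linkS4class{MarkerMatrix},
#' \linkS4class{RelationshipKernel} or \linkS4class{PedigreeTable}.
#'
#' @param x an object with genotype identifiers.
#' @return Character vector of genotype ids, in the object's storage order.
#' @export
setGeneric("genotypeIds", function(x) standardGeneric("genotypeIds"))

#' Kernel matrix accessor
#'
#' @param x a \linkS4class{RelationshipKernel}.
#' @return The underlying symmetric numeric matrix with id dimnames.
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))

#' Kernel kind accessor
#'
#' @param x a \linkS4class{RelationshipKernel}.
#' @return One of \code{"A"}, \code{"G"}, \code{"K"}, \code{"C"}, \code{"P"},
#'   \code{"custom"}.
#' @export
setGeneric("kernelKind", function(x) standardGeneric("kernelKind"))

#' Posterior variance-component summary of a fit
#'
#' @param object a fitted model object.
#' @return A data.frame of posterior means and standard deviations, one row
#'   per variance component (each kernel plus the residual).
#' @export
setGeneric("varianceComponents", function(object) {
  standardGeneric("varianceComponents")
})

#' Posterior-mean genetic effect vectors of a fit
#'
#' @param object a fitted model object.
#' @return A numeric matrix, one column per kernel, rows indexed by genotype
#'   (single-environment fits) or by phenotype record (multi-environment
#'   fits).
#' @export
setGeneric("geneticEffects", function(object) {
  standardGeneric("geneticEffects")
})

#' Posterior-mean predictions of a fit
#'
#' @param object a fitted model object.
#' @return Numeric vector of posterior-mean predicted values for every
#'   genotype (or phenotype record), observed and masked alike.
#' @export
setGeneric("fittedValues", function(object) standardGeneric("fittedValues"))
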
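#' Accessors for fitted objects
#'
#' `parameterMaps()` returns the per-voxel parameter estimates of a fit,
#' `lossHistory()` the per-iteration objective values, and
#' `terminationReason()` the stopping criterion that ended the optimisation
#' (`"tol"`, `"max_iter"` or `"converged"`).
#'
#' @param object a [FitResult-class] (or, for `parameterMaps()`, any object
#'   carrying parameter maps).
#' @return `parameterMaps()`: a [ParameterMaps-class]; `lossHistory()`: a
#'   numeric vector; `terminationReason()`: a length-one character.
#' @aliases parameterMaps lossHistory terminationReason
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("parameterMaps", function(object) standardGeneric("parameterMaps"))

#' @rdname fit-accessors
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))

#' @rdname fit-accessors
#' @export
setGeneric("terminationReason", function(object) standardGeneric("terminationReason"))

#' Accessors for posterior objects
#'
#' `chainSamples()` returns the retained posterior draws of a [ChainStore-class]
#' as a (voxel, parameter, sample) array; `acceptanceRate()` the per-voxel
#' acceptance fraction; `posteriorMean()`, `posteriorSd()` and `posteriorIqr()`
#' the per-parameter summary vectors of a [PosteriorSummary-class].
#'
#' @param object a [ChainStore-class] or [PosteriorSummary-class].
#' @return See each function's description.
#' @aliases chainSamples acceptanceRate posteriorMean posteriorSd posteriorIqr
#' @name posterior-accessors
NULL

#' @rdname posterior-accessors
#' @export
setGeneric("chainSamples", function(object) standardGeneric("chainSamples"))

#' @rdname posterior-accessors
#' @export
setGeneric("acceptanceRate", function(object) standardGeneric("acceptanceRate"))

#' @rdname posterior-accessors
#' @export
setGeneric("posteriorMean", function(object) standardGeneric("posteriorMean"))

#' @rdname posterior-accessors
#' @export
setGeneric("posteriorSd", function(object) standardGeneric("posteriorSd"))

#' @rdname posterior-accessors
#' @export
setGeneric("posteriorIqr", function(object) standardGeneric("posteriorIqr"))

#' Names of the parameters of a model or map collection
#'
#' @param object a [ForwardModel-class], [ParameterMaps-class],
#'   [ChainStore-class] or [PosteriorSummary-class].
#' @return character vector of parameter names.
#' @export
setGeneric("modelParameters", function(object) standardGeneric("modelParameters"))
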
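#' @include AllGenerics.R
NULL

setClassUnion("functionOrNULL", c("function", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' Acquisition-parameter grid
#'
#' Named arrays of acquisition parameters (echo times in ms, b-values in
#' ms/um^2, ...). Each entry must be finite and broadcastable against the
#' measurement dimensions of the signal it is used with: its length must be 1,
#' equal to one of the measurement dimensions, or equal to their product.
#'
#' @slot values named list of finite numeric vectors/arrays.
#' @seealso [acquisitionGrid()]
#' @export
setClass("AcquisitionGrid", representation(values = "list"))

setValidity("AcquisitionGrid", function(object) {
    v <- object@values
    if (length(v) == 0L) return("grid must contain at least one parameter array")
    if (is.null(names(v)) || any(!nzchar(names(v))))
        return("every grid entry must be named")
    for (nm in names(v)) {
        x <- v[[nm]]
        if (!(is.numeric(x) || is.complex(x) || is.logical(x)))
            return(sprintf("grid entry '%s' is not numeric/complex/logical", nm))
        if (!all(is.finite(x)))
            return(sprintf("grid entry '%s' contains non-finite values", nm))
    }
    TRUE
})

#' Construct an acquisition grid
#'
#' @param ... named numeric vectors of acquisition parameters, e.g.
#'   `echo_times = seq(2, 24, by = 2)`.
#' @return an [AcquisitionGrid-class].
#' @examples
#' grid <- acquisitionGrid(echo_times = seq(2, 24, by = 2))
#' grid[["echo_times"]]
#' @export
acquisitionGrid <- function(...) {
    new("AcquisitionGrid", values = list(...))
}

#' @describeIn AcquisitionGrid extract one parameter array by name.
#' @param x,i object and entry name.
#' @export
setMethod("[[", "AcquisitionGrid", function(x, i) {
    if (!i %in% names(x@values))
        stop(sprintf("grid has no entry '%s' (available: %s)", i,
                     paste(names(x@values), collapse = ", ")))
    x@values[[i]]
})

#' @describeIn AcquisitionGrid names of the stored parameter arrays.
#' @export
setMethod("names", "AcquisitionGrid", function(x) names(x@values))

setMethod("show", "AcquisitionGrid", function(object) {
    cat("AcquisitionGrid with", length(object@values), "parameter array(s)\n")
    for (nm in names(object@values)) {
        v <- object@values[[nm]]
        cat(sprintf("  %s: length %d, range [%g, %g]\n", nm, length(v), min(v), max(v)))
    }
})

#' Named, box-bounded parameter maps
#'
#' Holds one array per model parameter, all sharing one spatial (or flat list)
#' shape, together with the finite box bounds each parameter must respect.
#' Values may be `NA` outside the fitted mask; all non-`NA` values lie within
#' their bounds.
#'
#' @slot maps named list of numeric arrays with a common shape.
#' @slot lower,upper named numeric vectors of finite per-parameter bounds,
#'   `lower < upper`.
#' @seealso [parameterMapsList()]
#' @export
setClass("ParameterMaps",
         representation(maps = "list", lower = "numeric", upper = "numeric"))

setValidity("ParameterMaps", function(object) {
    m <- object@maps
    if (length(m) == 0L) return("at least one parameter map is required")
    if (is.null(names(m))) return("maps must be named")
    d0 <- dim(m[[1]]); if (is.null(d0)) d0 <- length(m[[1]])
    for (nm in names(m)) {
        d <- dim(m[[nm]]); if (is.null(d)) d <- length(m[[nm]])
        if (!identical(d, d0)) return("all parameter maps must share one shape")
    }
    if (!setequal(names(object@lower), names(m)) || !setequal(names(object@upper), names(m)))
        return("bounds must name exactly the map parameters")
    for (nm in names(m)) {
        lb <- object@lower[[nm]]; ub <- object@upper[[nm]]
        if (!is.finite(lb) || !is.finite(ub)) return(sprintf("bounds for '%s' must be finite", nm))
        if (lb >= ub) return(sprintf("lower bound must be below upper bound for '%s'", nm))
        x <- m[[nm]]
        if (any(!is.na(x) & (x < lb | x > ub)))
            return(sprintf("map '%s' has values outside its bounds [%g, %g]", nm, lb, ub))
    }
    TRUE
})

#' Construct parameter maps
#'
#' @param maps named list of numeric arrays (one per parameter, common shape).
#' @param lower,upper named numeric vectors of finite per-parameter box bounds.
#' @return a [ParameterMaps-class].
#' @export
parameterMapsList <- function(maps, lower, upper) {
    new("ParameterMaps", maps = maps,
        lower = lower[names(maps)], upper = upper[names(maps)])
}

#' @describeIn ParameterMaps extract one parameter map by name.
#' @param x,i object and parameter name.
#' @export
setMethod("[[", "ParameterMaps", function(x, i) {
    if (!i %in% names(x@maps))
        stop(sprintf("no parameter map '%s' (available: %s)", i,
                     paste(names(x@maps), collapse = ", ")))
    x@maps[[i]]
})

setMethod("modelParameters", "ParameterMaps", function(object) names(object@maps))

setMethod("show", "ParameterMaps", function(object) {
    d <- dim(object@maps[[1]]); if (is.null(d)) d <- length(object@maps[[1]])
    cat("ParameterMaps over shape", paste(d, collapse = " x "), "\n")
    for (nm in names(object@maps)) {
        x <- object@maps[[nm]]
        cat(sprintf("  %s in [%g, %g]: median %g (%d NA)\n", nm,
                    object@lower[[nm]], object@upper[[nm]],
                    stats::median(x, na.rm = TRUE), sum(is.na(x))))
    }
})

#' Forward signal model
#'
#' The pluggable contract shared by both solvers: a deterministic function
#' mapping named parameter arrays and an acquisition grid to a predicted
#' signal array shaped exactly like the measured data. An optional analytic
#' Jacobian (one derivative array per parameter, each shaped like the signal)
#' makes gradient-based fitting exact; without it the solver falls back to a
#' vectorised central-difference Jacobian, valid for voxel-separable models.
#'
#' @slot name registry name.
#' @slot parameters parameter names, in canonical order.
#' @slot lower,upper named finite default box bounds per parameter.
#' @slot init named default initial values (inside the bounds).
#' @slot fun `function(theta, grid)` with `theta` a named list of parameter
#'   arrays; returns the predicted signal with the parameter shape as leading
#'   dimension(s) and the measurement dimension(s) trailing.
#' @slot jacobian optional `function(theta, grid)` returning a named list of
#'   derivative arrays, each shaped like `fun`'s output.
#' @seealso [forwardModel()], [registerModel()], [getModel()]
#' @export
setClass("ForwardModel",
         representation(name = "character", parameters = "character",
                        lower = "numeric", upper = "numeric", init = "numeric",
                        fun = "function", jacobian = "functionOrNULL"))

setValidity("ForwardModel", function(object) {
    p <- object@parameters
    if (length(p) == 0L) return("model must declare at least one parameter")
    for (s in list(object@lower, object@upper, object@init))
        if (!setequal(names(s), p)) return("lower/upper/init must name every parameter")
    for (nm in p) {
        lb <- object@lower[[nm]]; ub <- object@upper[[nm]]
        if (!is.finite(lb) || !is.finite(ub) || lb >= ub)
            return(sprintf("bounds for '%s' must be finite with lower < upper", nm))
        x0 <- object@init[[nm]]
        if (!is.finite(x0) || x0 <= lb || x0 >= ub)
            return(sprintf("init for '%s' must lie strictly inside its bounds", nm))
    }
    TRUE
})

setMethod("modelParameters", "ForwardModel", function(object) object@parameters)

setMethod("show", "ForwardModel", function(object) {
    cat(sprintf("ForwardModel '%s' (%d parameter%s)\n", object@name,
                length(object@parameters), if (length(object@parameters) > 1) "s" else ""))
    for (nm in object@parameters)
        cat(sprintf("  %s in [%g, %g], init %g\n", nm,
                    object@lower[[nm]], object@upper[[nm]], object@init[[nm]]))
    cat(if (is.null(object@jacobian)) "  Jacobian: central differences (fallback)\n"
        else "  Jacobian: analytic\n")
})

#' Result of a whole-volume gradient fit
#'
#' @slot maps final [ParameterMaps-class] (inside bounds; `NA` outside mask).
#' @slot lossHistory total objective per retained iteration.
#' @slot dataLoss data-fidelity part of the final loss.
#' @slot termination one of `"tol"`, `"max_iter"`, `"converged"`, `"aborted"`.
#' @slot iterations iterations actually used (equals `length(lossHistory)`).
#' @export
setClass("FitResult",
         representation(maps = "ParameterMaps", lossHistory = "numeric",
                        dataLoss = "numeric", termination = "character",
                        iterations = "integer"))

setValidity("FitResult", function(object) {
    if (!object@termination %in% c("tol", "max_iter", "converged", "aborted"))
        return("unknown termination reason")
    if (length(object@lossHistory) != object@iterations)
        return("loss history length must equal iterations used")
    TRUE
})

setMethod("parameterMaps", "FitResult", function(object) object@maps)
setMethod("lossHistory", "FitResult", function(object) object@lossHistory)
setMethod("terminationReason", "FitResult", function(object) object@termination)
setMethod("modelParameters", "FitResult", function(object) names(object@maps@maps))

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult: %d iteration(s), terminated by '%s'\n",
                object@iterations, object@termination))
    cat(sprintf("  final loss %g (data term %g)\n",
                utils::tail(object@lossHistory, 1), object@dataLoss))
    show(object@maps)
})

#' Retained posterior samples
#'
#' Samples kept after burn-in and thinning, indexed (voxel, parameter,
#' sample). `chainId` records which independent chain (Metropolis-Hastings) or
#' walker (ensemble) produced each retained sample; within one chain, samples
#' are stored in iteration order.
#'
#' @slot samples numeric array `(n_voxels, n_parameters, n_samples)`.
#' @slot parameters parameter names (second dimension).
#' @slot chainId integer vector of length `n_samples`.
#' @slot algorithm `"mh"` or `"ensemble"`.
#' @slot lower,upper the bounds the sampler enforced.
#' @slot acceptance per-voxel per-chain acceptance fraction (matrix).
#' @slot seed the master seed used.
#' @export
setClass("ChainStore",
         representation(samples = "array", parameters = "character",
                        chainId = "integer", algorithm = "character",
                        lower = "numeric", upper = "numeric",
                        acceptance = "matrix", seed = "integer"))

setValidity("ChainStore", function(object) {
    d <- dim(object@samples)
    if (length(d) != 3L) return("samples must be a (voxel, parameter, sample) array")
    if (d[2] != length(object@parameters)) return("parameter dimension mismatch")
    if (d[3] != length(object@chainId)) return("chainId must index the sample dimension")
    for (p in seq_along(object@parameters)) {
        x <- object@samples[, p, ]
        lb <- object@lower[[object@parameters[p]]]
        ub <- object@upper[[object@parameters[p]]]
        if (any(x < lb - 1e-12 | x > ub + 1e-12))
            return(sprintf("retained samples for '%s' escape the bounds", object@parameters[p]))
    }
    TRUE
})

setMethod("chainSamples", "ChainStore", function(object) object@samples)
setMethod("acceptanceRate", "ChainStore", function(object) object@acceptance)
setMethod("modelParameters", "ChainStore", function(object) object@parameters)

setMethod("show", "ChainStore", function(object) {
    d <- dim(object@samples)
    cat(sprintf("ChainStore (%s): %d voxel(s), %d parameter(s), %d retained sample(s)\n",
                object@algorithm, d[1], d[2], d[3]))
    cat(sprintf("  %d chain(s)/walker(s), mean acceptance %.3f\n",
                length(unique(object@chainId)), mean(object@acceptance)))
})

#' Posterior summary maps
#'
#' Per-voxel, per-parameter sample mean and unbiased standard deviation (and
#' interquartile range) of the retained posterior draws.
#'
#' @slot mean,sd,iqr named lists of per-voxel numeric vectors.
#' @slot parameters parameter names.
#' @export
setClass("PosteriorSummary",
         representation(mean = "list", sd = "list", iqr = "list",
                        parameters = "character"))

setMethod("posteriorMean", "PosteriorSummary", function(object) object@mean)
setMethod("posteriorSd", "PosteriorSummary", function(object) object@sd)
setMethod("posteriorIqr", "PosteriorSummary", function(object) object@iqr)
setMethod("modelParameters", "PosteriorSummary", function(object) object@parameters)

setMethod("show", "PosteriorSummary", function(object) {
    cat("PosteriorSummary over", length(object@mean[[1]]), "voxel(s)\n")
    for (nm in object@parameters)
        cat(sprintf("  %s: mean of means %g, median sd %g\n", nm,
                    mean(object@mean[[nm]]), stats::median(object@sd[[nm]])))
})

#' Graph adjacency for surface/vertex regularisation
#'
#' Undirected vertex adjacency stored as unique unordered edges (1-based
#' internally; edge-list files on disk are strictly 0-based). No self-edges.
#'
#' @slot nVertices vertex count.
#' @slot edges integer matrix with two columns, each row one undirected edge.
#' @seealso [graphAdjacency()], [readEdgeList()]
#' @export
setClass("GraphAdjacency",
         representation(nVertices = "integer", edges = "matrix"))

setValidity("GraphAdjacency", function(object) {
    e <- object@edges
    if (ncol(e) != 2L) return("edges must have two columns")
    if (nrow(e) > 0L) {
        if (!is.integer(e)) return("edge indices must be integers")
        if (any(e < 1L) || any(e > object@nVertices)) return("edge index out of range")
        if (any(e[, 1] == e[, 2])) return("self-edges are not allowed")
    }
    TRUE
})

setMethod("show", "GraphAdjacency", function(object) {
    cat(sprintf("GraphAdjacency: %d vertices, %d undirected edges\n",
                object@nVertices, nrow(object@edges)))
})

#' Construct a graph adjacency from an edge list
#'
#' Edges are symmetrised and deduplicated: each unordered pair is stored once.
#'
#' @param edges two-column matrix (or data frame) of 1-based vertex index
#'   pairs.
#' @param nVertices vertex count; defaults to the largest index seen.
#' @return a [GraphAdjacency-class].
#' @examples
#' tri <- graphAdjacency(rbind(c(1, 2), c(1, 3), c(2, 3)))
#' tvGraph(c(0, 1, 2), tri)  # 8: each edge counted from both endpoints
#' @export
graphAdjacency <- function(edges, nVertices = NULL) {
    e <- as.matrix(edges)
    storage.mode(e) <- "integer"
    if (nrow(e) > 0L) {
        if (any(e[, 1] == e[, 2])) stop("self-edges are not allowed")
        e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
        e <- unique(e)
    }
    if (is.null(nVertices)) nVertices <- if (nrow(e)) max(e) else 0L
    new("GraphAdjacency", nVertices = as.integer(nVertices), edges = e)
}
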
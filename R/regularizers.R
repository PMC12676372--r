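#' @include AllClasses.R core.R
NULL

# index a single axis of an array, all other axes untouched
.axisSlice <- function(x, axis, idx) {
    args <- rep(list(quote(expr = )), length(dim(x)))
    args[[axis]] <- idx
    do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

.axisAssignAdd <- function(x, axis, idx, val) {
    args <- rep(list(quote(expr = )), length(dim(x)))
    args[[axis]] <- idx
    cur <- do.call(`[`, c(list(x), args, list(drop = FALSE)))
    do.call(`[<-`, c(list(x), args, list(cur + val)))
}

#' Anisotropic volumetric total variation
#'
#' The mean absolute forward difference of a parameter map along each of the
#' first `ndims` spatial axes (anisotropic, L1-of-gradient TV). Differences
#' with either endpoint outside the mask or crossing the image edge are
#' excluded, so the penalty never smooths across tissue/air boundaries. The
#' 2D variant penalises in-plane differences only, i.e. is computed
#' slice-wise along the third axis. A map that is constant on the mask (or a
#' single-voxel mask, which has no valid differences) scores 0.
#'
#' The mean (rather than sum) normalisation keeps the regularisation weight
#' `lambda` comparable across volume sizes, mirroring the mean-normalised
#' data loss.
#'
#' @param map numeric array of spatial rank at least `ndims`.
#' @param mask logical array like `map`, or `NULL` for all-`TRUE`.
#' @param ndims 2 or 3: number of leading axes to difference along.
#' @return nonnegative scalar.
#' @examples
#' m <- array(0, c(2, 1, 1)); m[2, 1, 1] <- 3
#' tvSpatial(m)            # one valid difference of 3
#' @export
tvSpatial <- function(map, mask = NULL, ndims = 3L) {
    d <- dim(map)
    if (is.null(d)) d <- length(map)
    if (!ndims %in% c(2L, 3L)) stop("ndims must be 2 or 3")
    if (ndims > length(d)) stop("ndims exceeds the array rank")
    if (is.null(mask)) mask <- array(TRUE, d)
    total <- 0; count <- 0L
    for (a in seq_len(ndims)) {
        if (d[a] < 2L) next
        hi <- .axisSlice(map, a, 2:d[a]); lo <- .axisSlice(map, a, 1:(d[a] - 1L))
        ok <- .axisSlice(mask, a, 2:d[a]) & .axisSlice(mask, a, 1:(d[a] - 1L))
        total <- total + sum(abs(hi - lo)[ok])
        count <- count + sum(ok)
    }
    if (count == 0L) 0 else total / count
}

# gradient of tvSpatial w.r.t. the map; subgradient 0 at ties (sign(0) = 0)
.tvSpatialGrad <- function(map, mask = NULL, ndims = 3L) {
    d <- dim(map)
    if (is.null(mask)) mask <- array(TRUE, d)
    count <- 0L
    for (a in seq_len(ndims)) {
        if (d[a] < 2L) next
        count <- count + sum(.axisSlice(mask, a, 2:d[a]) & .axisSlice(mask, a, 1:(d[a] - 1L)))
    }
    g <- array(0, d)
    if (count == 0L) return(g)
    for (a in seq_len(ndims)) {
        if (d[a] < 2L) next
        hi <- .axisSlice(map, a, 2:d[a]); lo <- .axisSlice(map, a, 1:(d[a] - 1L))
        ok <- .axisSlice(mask, a, 2:d[a]) & .axisSlice(mask, a, 1:(d[a] - 1L))
        s <- sign(hi - lo) * ok
        g <- .axisAssignAdd(g, a, 2:d[a], s)
        g <- .axisAssignAdd(g, a, 1:(d[a] - 1L), -s)
    }
    g / count
}

#' Graph (surface) total variation
#'
#' The per-vertex sum `sum_i sum_{j in N(i)} |theta_i - theta_j|` over a
#' vertex adjacency, as used for cortical-surface fitting where neighbourhood
#' is mesh connectivity rather than Euclidean distance. Each undirected edge
#' contributes twice (once from each endpoint), matching the per-vertex
#' double sum as written; a single edge with values `(a, b)` scores
#' `2 * |a - b|`.
#'
#' @param values numeric vector, one value per vertex.
#' @param adjacency a [GraphAdjacency-class].
#' @return nonnegative scalar.
#' @export
tvGraph <- function(values, adjacency) {
    stopifnot(methods::is(adjacency, "GraphAdjacency"))
    if (length(values) != adjacency@nVertices)
        stop(sprintf("values has length %d but the graph has %d vertices",
                     length(values), adjacency@nVertices))
    e <- adjacency@edges
    if (nrow(e) == 0L) return(0)
    2 * sum(abs(values[e[, 1]] - values[e[, 2]]))
}

.tvGraphGrad <- function(values, adjacency) {
    e <- adjacency@edges
    g <- numeric(length(values))
    if (nrow(e) == 0L) return(g)
    s <- sign(values[e[, 1]] - values[e[, 2]])
    g2 <- g
    # accumulate per endpoint (edges may repeat vertices)
    gi <- tapply(2 * s, e[, 1], sum); g[as.integer(names(gi))] <- gi
    gj <- tapply(-2 * s, e[, 2], sum); g2[as.integer(names(gj))] <- gj
    g + g2
}

#' Prior-based penalty
#'
#' Mean over masked voxels of `|theta - mu| / sigma`, penalising departures
#' of a parameter map from an externally derived mean map `mu` in units of
#' its standard deviation map `sigma` (e.g. ROI statistics from a high-SNR
#' cohort, used to stabilise low-SNR fits).
#'
#' @param theta parameter map (array or vector).
#' @param mu,sigma prior mean and standard deviation, shaped like `theta`
#'   (scalars are broadcast); `sigma > 0` within the mask.
#' @param mask logical array like `theta`, or `NULL` for all-`TRUE`.
#' @return nonnegative scalar; 0 iff `theta == mu` on the mask.
#' @export
priorPenalty <- function(theta, mu, sigma, mask = NULL) {
    if (is.null(mask)) mask <- array(TRUE, .dimOf(theta))
    mu <- array(mu, .dimOf(theta)); sigma <- array(sigma, .dimOf(theta))
    if (any(sigma[mask] <= 0)) stop("sigma must be strictly positive inside the mask")
    mean((abs(theta - mu) / sigma)[mask])
}

.priorPenaltyGrad <- function(theta, mu, sigma, mask = NULL) {
    if (is.null(mask)) mask <- array(TRUE, .dimOf(theta))
    mu <- array(mu, .dimOf(theta)); sigma <- array(sigma, .dimOf(theta))
    g <- array(0, .dimOf(theta))
    g[mask] <- sign(theta[mask] - mu[mask]) / sigma[mask] / sum(mask)
    g
}

#' Regularisation terms for the gradient solver
#'
#' Constructors for the weighted penalty terms a fit can carry:
#' `tvTerm()` for volumetric TV on one parameter map, `graphTvTerm()` for
#' surface/graph TV (list-layout fits), `priorTerm()` for the prior penalty,
#' and `customTerm()` for any user penalty returning a finite scalar (supply
#' `grad` — the derivative with respect to the map — to use it with the
#' gradient solver).
#'
#' @param parameter name of the parameter map the term acts on.
#' @param lambda nonnegative regularisation weight.
#' @param ndims 2 (slice-wise) or 3 for volumetric TV.
#' @param adjacency a [GraphAdjacency-class] (graph TV). The default weight
#'   used in the surface demo is `1e-5`.
#' @param mu,sigma prior mean/SD maps (prior term).
#' @param fn `function(map, mask)` returning a finite scalar (custom term).
#' @param grad optional `function(map, mask)` returning the derivative array.
#' @param label name used in error messages.
#' @return a regulariser term for [composeRegularizers()] /
#'   [fitGradient()].
#' @name regularizer-terms
NULL

.regTerm <- function(parameter, lambda, value, grad, label) {
    if (lambda < 0) stop("lambda must be nonnegative")
    structure(list(parameter = parameter, lambda = lambda,
                   value = value, grad = grad, label = label),
              class = "regTerm")
}

#' @rdname regularizer-terms
#' @export
tvTerm <- function(parameter, lambda, ndims = 3L) {
    .regTerm(parameter, lambda,
             value = function(map, mask) tvSpatial(map, mask, ndims),
             grad = function(map, mask) .tvSpatialGrad(map, mask, ndims),
             label = sprintf("tv%dd(%s)", ndims, parameter))
}

#' @rdname regularizer-terms
#' @export
graphTvTerm <- function(parameter, lambda = 1e-5, adjacency) {
    .regTerm(parameter, lambda,
             value = function(map, mask) tvGraph(as.vector(map), adjacency),
             grad = function(map, mask) .tvGraphGrad(as.vector(map), adjacency),
             label = sprintf("graphTv(%s)", parameter))
}

#' @rdname regularizer-terms
#' @export
priorTerm <- function(parameter, lambda, mu, sigma) {
    .regTerm(parameter, lambda,
             value = function(map, mask) priorPenalty(map, mu, sigma, mask),
             grad = function(map, mask) .priorPenaltyGrad(map, mu, sigma, mask),
             label = sprintf("prior(%s)", parameter))
}

#' @rdname regularizer-terms
#' @export
customTerm <- function(fn, lambda, parameter, grad = NULL, label = "custom") {
    .regTerm(parameter, lambda, value = fn, grad = grad, label = label)
}

#' Compose weighted regularisation terms
#'
#' Combines a list of terms into one object evaluating
#' `sum_k lambda_k R_k(theta)`. Terms with `lambda = 0` contribute exactly 0
#' and are skipped. A custom term returning a non-scalar or non-finite value
#' raises an error naming the term.
#'
#' @param terms list of terms from [tvTerm()], [graphTvTerm()],
#'   [priorTerm()], [customTerm()] (a single term is accepted).
#' @return an object with `$value(maps, mask)` returning the weighted total
#'   and `$grad(maps, mask)` returning a named list of gradient arrays (one
#'   per regularised parameter). An empty term list evaluates to 0.
#' @examples
#' reg <- composeRegularizers(list(tvTerm("R2star", lambda = 0.01)))
#' reg$value(list(R2star = array(1, c(3, 3, 3))), NULL)   # constant map: 0
#' @export
composeRegularizers <- function(terms = list()) {
    if (inherits(terms, "regTerm")) terms <- list(terms)
    stopifnot(all(vapply(terms, inherits, logical(1), "regTerm")))
    active <- terms[vapply(terms, function(tm) tm$lambda > 0, logical(1))]
    value <- function(maps, mask = NULL) {
        tot <- 0
        for (tm in active) {
            v <- tm$value(maps[[tm$parameter]], mask)
            if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
                stop(sprintf("regulariser '%s' did not return a finite scalar", tm$label))
            tot <- tot + tm$lambda * v
        }
        tot
    }
    grad <- function(maps, mask = NULL) {
        g <- list()
        for (tm in active) {
            if (is.null(tm$grad))
                stop(sprintf("regulariser '%s' has no gradient; supply grad= to use it with the gradient solver",
                             tm$label))
            gt <- tm$lambda * tm$grad(maps[[tm$parameter]], mask)
            g[[tm$parameter]] <- if (is.null(g[[tm$parameter]])) gt else g[[tm$parameter]] + gt
        }
        g
    }
    structure(list(value = value, grad = grad, terms = active),
              class = "regularizerSet")
}
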
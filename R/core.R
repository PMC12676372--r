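#' @include AllClasses.R
NULL

.dimOf <- function(x) {
    d <- dim(x)
    if (is.null(d)) length(x) else d
}

#' Gather masked voxels into list layout
#'
#' Extracts the voxels where `mask` is `TRUE` from a volume whose leading
#' dimensions are spatial, producing a list-layout array with the masked
#' voxels along the first dimension and the measurement dimensions trailing.
#' Voxels are ordered by the column-major linear index of the spatial grid
#' (R's native array order), so the layout is identical across runs;
#' `scatterVoxels()` inverts it exactly.
#'
#' @param volume numeric (or complex) array; leading dims match `dim(mask)`.
#' @param mask logical array over the spatial dimensions with at least one
#'   `TRUE` element.
#' @return array `(n_masked, measurement dims...)`; a plain vector when the
#'   volume has no measurement dimensions.
#' @examples
#' v <- array(seq_len(4 * 4 * 4 * 3), c(4, 4, 4, 3))
#' m <- array(FALSE, c(4, 4, 4)); m[1:2, 1, 1] <- TRUE
#' gatherVoxels(v, m)
#' @seealso [scatterVoxels()]
#' @export
gatherVoxels <- function(volume, mask) {
    dm <- .dimOf(mask)
    dv <- .dimOf(volume)
    ns <- length(dm)
    if (length(dv) < ns || !identical(as.integer(dv[seq_len(ns)]), as.integer(dm)))
        stop("mask spatial shape does not match the volume's leading dimensions")
    idx <- which(as.vector(mask))
    if (length(idx) == 0L) stop("mask selects no voxels")
    measDim <- if (length(dv) > ns) dv[-seq_len(ns)] else integer(0)
    vm <- volume
    dim(vm) <- c(prod(dm), max(1L, prod(measDim)))
    out <- vm[idx, , drop = FALSE]
    if (length(measDim)) dim(out) <- c(length(idx), measDim) else out <- as.vector(out)
    out
}

#' Scatter list-layout values back into a volume
#'
#' Places the rows of a list-layout array at the `TRUE` positions of `mask`
#' (in `gatherVoxels()`'s column-major order) and fills everything else with
#' `fill`. `gatherVoxels(scatterVoxels(x, m), m)` recovers `x` exactly.
#'
#' @param flat vector or array whose first dimension equals the mask
#'   cardinality.
#' @param mask logical spatial array.
#' @param fill scalar placed outside the mask (default 0; use `NA` for maps).
#' @return array of shape `(dim(mask), trailing dims of flat)`.
#' @export
scatterVoxels <- function(flat, mask, fill = 0) {
    dm <- .dimOf(mask)
    idx <- which(as.vector(mask))
    df <- .dimOf(flat)
    if (df[1] != length(idx))
        stop(sprintf("flat has %d rows but the mask selects %d voxels", df[1], length(idx)))
    measDim <- if (length(df) > 1L) df[-1] else integer(0)
    fm <- flat
    dim(fm) <- c(df[1], max(1L, prod(measDim)))
    out <- matrix(as.vector(fill)[1], nrow = prod(dm), ncol = ncol(fm))
    if (is.complex(flat)) storage.mode(out) <- "complex"
    out[idx, ] <- fm
    dim(out) <- c(dm, measDim)
    out
}

#' Map bounded parameters to and from unconstrained space
#'
#' The gradient solver optimises in an unconstrained space and enforces box
#' bounds through the scaled-logit map `theta = lb + (ub - lb) * plogis(z)`:
#' strictly monotone, differentiable, and mapping the whole real line onto
#' `(lb, ub)`, so bound violations are impossible mid-optimisation. The
#' midpoint of the bounds corresponds to `z = 0`. Values on or outside the
#' bounds are clamped just inside (with a warning) before the forward
#' transform.
#'
#' @param theta numeric array strictly inside `(lower, upper)`.
#' @param z unconstrained numeric array.
#' @param lower,upper finite bounds (scalars or arrays broadcastable against
#'   `theta`), `lower < upper`.
#' @return `toUnconstrained()`: the unconstrained array `z`;
#'   `fromUnconstrained()`: the bounded array `theta`.
#' @examples
#' toUnconstrained(0.5, 0, 1)          # 0 at the midpoint
#' fromUnconstrained(100, 0, 1)        # approaches the upper bound
#' @export
toUnconstrained <- function(theta, lower, upper) {
    if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
        stop("bounds must be finite with lower < upper")
    eps <- 1e-9 * (upper - lower)
    lo <- lower + eps; hi <- upper - eps
    if (any(theta < lo | theta > hi)) {
        warning("parameter values on or outside the bounds were clamped inside")
        theta <- pmin(pmax(theta, lo), hi)
    }
    stats::qlogis((theta - lower) / (upper - lower))
}

#' @rdname toUnconstrained
#' @export
fromUnconstrained <- function(z, lower, upper) {
    lower + (upper - lower) * stats::plogis(z)
}

# d theta / d z of the scaled-logit map, used by the gradient chain rule
.boundTransformDeriv <- function(z, lower, upper) {
    s <- stats::plogis(z)
    (upper - lower) * s * (1 - s)
}

#' Validate a fitting input bundle
#'
#' Checks the measured signal, mask, weights and acquisition grid for mutual
#' consistency and returns a normalised bundle. In `"volume"` layout the
#' first three dimensions are spatial; in `"list"` layout the first dimension
#' indexes samples. A missing mask becomes all-`TRUE`; missing weights become
#' all-ones. `NaN`/`NA` signal values are rejected inside the mask and
#' ignored outside it. Input values inside the mask are never modified.
#'
#' @param signal numeric or complex array with at least one measurement
#'   dimension.
#' @param mask logical spatial array, or `NULL`.
#' @param weights nonnegative array broadcastable to the signal (scalar,
#'   spatial, or full shape), or `NULL` for all-ones.
#' @param grid an [AcquisitionGrid-class] (or named list coerced to one), or
#'   `NULL`.
#' @param layout `"volume"` or `"list"`.
#' @return list with elements `signal`, `mask`, `weights` (full signal
#'   shape), `grid`, `spatialDim`, `measDim`, `nVoxels`.
#' @export
validateInputs <- function(signal, mask = NULL, weights = NULL, grid = NULL,
                           layout = c("volume", "list")) {
    layout <- match.arg(layout)
    dv <- .dimOf(signal)
    ns <- if (layout == "volume") 3L else 1L
    if (length(dv) <= ns)
        stop("signal: needs at least one measurement dimension beyond the ",
             if (layout == "volume") "3 spatial dims" else "sample dim")
    spatialDim <- as.integer(dv[seq_len(ns)])
    measDim <- as.integer(dv[-seq_len(ns)])
    if (is.null(mask)) {
        mask <- array(TRUE, spatialDim)
    } else {
        if (!is.logical(mask)) mask <- mask != 0
        if (!identical(as.integer(.dimOf(mask)), spatialDim))
            stop("mask: shape does not equal the signal's spatial shape")
        if (!any(mask)) stop("mask: contains no TRUE element")
    }
    sigFlat <- signal; dim(sigFlat) <- c(prod(spatialDim), prod(measDim))
    inMask <- as.vector(mask)
    if (anyNA(sigFlat[inMask, ]) || any(is.nan(Re(sigFlat[inMask, ]))))
        stop("signal: NaN/NA values inside the mask")
    if (is.null(weights)) {
        weights <- array(1, dv)
    } else {
        if (any(weights < 0, na.rm = TRUE)) stop("weights: negative values")
        weights <- .broadcastToSignal(weights, spatialDim, measDim, "weights")
        wFlat <- weights; dim(wFlat) <- c(prod(spatialDim), prod(measDim))
        if (anyNA(wFlat[inMask, ])) stop("weights: NA values inside the mask")
    }
    if (!is.null(grid)) {
        if (!methods::is(grid, "AcquisitionGrid")) grid <- do.call(acquisitionGrid, as.list(grid))
        for (nm in names(grid)) {
            n <- length(grid[[nm]])
            if (!(n == 1L || n %in% measDim || n == prod(measDim)))
                stop(sprintf("grid: entry '%s' (length %d) is not broadcastable against the measurement dims (%s)",
                             nm, n, paste(measDim, collapse = " x ")))
        }
    }
    list(signal = signal, mask = mask, weights = weights, grid = grid,
         spatialDim = spatialDim, measDim = measDim, nVoxels = sum(mask))
}

# expand scalar / spatial-shaped / full-shaped input to the full signal shape
.broadcastToSignal <- function(x, spatialDim, measDim, what) {
    dv <- c(spatialDim, measDim)
    dx <- .dimOf(x)
    if (length(x) == 1L) return(array(as.vector(x), dv))
    if (identical(as.integer(dx), as.integer(dv))) return(x)
    if (identical(as.integer(dx), as.integer(spatialDim)))
        return(array(rep(as.vector(x), times = prod(measDim)), dv))
    stop(sprintf("%s: shape is not broadcastable to the signal shape", what))
}

# subset the last dimension of an array, keeping shape
.sliceLast <- function(a, i) {
    d <- dim(a)
    m <- a; dim(m) <- c(prod(d[-length(d)]), d[length(d)])
    out <- m[, i]
    dim(out) <- d[-length(d)]
    out
}
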
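#' @include core.R models.R
NULL

#' Per-voxel bounded nonlinear least-squares reference
#'
#' The conventional voxel-wise estimator: an independent box-bounded
#' Levenberg-Marquardt least-squares fit per masked voxel, run sequentially.
#' Serves as the comparison oracle for the whole-volume gradient solver —
#' with no regularisation and an `"l2"` loss the two share the same per-voxel
#' optimum.
#'
#' @inheritParams fitGradient
#' @return list with `maps` (named list of parameter arrays in the native
#'   spatial shape, `NA` outside the mask), `exitCode` (per-voxel
#'   `minpack.lm` termination code array; codes 1-4 indicate convergence,
#'   others flag non-convergent voxels — never silently filled), and
#'   `nNotConverged`.
#' @examples
#' sim <- genMonoexpVolume(shape = c(4, 4, 4), snr = 1e9, seed = 2)
#' fit <- nllsOracle("monoexp_r2s", sim$signalNoisy, sim$mask, grid = sim$grid)
#' fit$nNotConverged
#' @export
nllsOracle <- function(model, signal, mask = NULL, grid, init = NULL,
                       bounds = NULL, layout = c("volume", "list")) {
    layout <- match.arg(layout)
    model <- .resolveModel(model)
    bundle <- validateInputs(signal, mask, NULL, grid, layout)
    pn <- model@parameters; np <- length(pn)
    lb <- if (!is.null(bounds)) bounds$lower[pn] else model@lower
    ub <- if (!is.null(bounds)) bounds$upper[pn] else model@upper
    nv <- bundle$nVoxels; nm <- prod(bundle$measDim)
    if (nm < np)
        stop(sprintf("per-voxel measurement count (%d) below parameter count (%d)", nm, np))
    Y <- gatherVoxels(bundle$signal, bundle$mask); dim(Y) <- c(nv, nm)
    init0 <- numeric(np); names(init0) <- pn
    initMat <- matrix(0, nv, np, dimnames = list(NULL, pn))
    for (p in pn) {
        v <- if (!is.null(init) && !is.null(init[[p]])) init[[p]] else model@init[[p]]
        initMat[, p] <- if (length(v) == 1L) rep(v, nv)
                        else gatherVoxels(array(v, bundle$spatialDim), bundle$mask)
    }
    est <- matrix(NA_real_, nv, np, dimnames = list(NULL, pn))
    code <- integer(nv)
    for (v in seq_len(nv)) {
        yv <- Y[v, ]
        resid <- function(par) {
            tl <- as.list(par); names(tl) <- pn
            as.vector(model@fun(tl, bundle$grid)) - yv
        }
        fit <- minpack.lm::nls.lm(par = initMat[v, ], lower = lb, upper = ub,
                                  fn = resid,
                                  control = minpack.lm::nls.lm.control(maxiter = 200))
        est[v, ] <- fit$par
        code[v] <- fit$info
    }
    maps <- lapply(pn, function(p) scatterVoxels(est[, p], bundle$mask, fill = NA_real_))
    names(maps) <- pn
    codeMap <- scatterVoxels(as.numeric(code), bundle$mask, fill = NA_real_)
    list(maps = maps, exitCode = codeMap, nNotConverged = sum(!code %in% 1:4))
}

#' Least-squares reconstruction baseline (conjugate gradients)
#'
#' Solves the Tikhonov-regularised linear reconstruction
#' `argmin_I ||k - E I||^2 + lambda ||I||^2` for the SENSE/CAIPI encoding
#' operator `E` by conjugate gradients on the Hermitian normal equations
#' `(E^H E + lambda) I = E^H k`. Deterministic given its inputs; aborts with
#' diagnostics if the residual norm increases over 10 consecutive
#' iterations.
#'
#' @param kSpace complex multi-channel k-space `(spatial..., coils, echoes)`.
#' @param coils complex coil sensitivities `(spatial..., coils)`.
#' @param samplingMask logical per-echo sampling pattern.
#' @param lambda Tikhonov weight (>= 0).
#' @param maxIter conjugate-gradient iteration cap.
#' @param tol relative residual tolerance for early stopping.
#' @return list with `image` (complex `(spatial..., echoes)`), `residuals`
#'   (normal-equation residual norms per iteration) and `iterations`.
#' @export
lsqrBaseline <- function(kSpace, coils, samplingMask, lambda = 0,
                         maxIter = 100L, tol = 1e-9) {
    b <- senseAdjoint(kSpace, coils, samplingMask)
    A <- function(x) senseAdjoint(senseForward(x, coils, samplingMask),
                                  coils, samplingMask) + lambda * x
    x <- array(0 + 0i, dim(b))
    r <- b
    p <- r
    rs <- sum(Mod(r)^2)
    rs0 <- rs
    hist <- numeric(0)
    rising <- 0L
    it <- 0L
    while (it < maxIter && rs > tol^2 * rs0) {
        it <- it + 1L
        Ap <- A(p)
        alpha <- rs / Re(sum(Conj(p) * Ap))
        x <- x + alpha * p
        r <- r - alpha * Ap
        rsNew <- sum(Mod(r)^2)
        hist <- c(hist, sqrt(rsNew))
        rising <- if (length(hist) > 1L && rsNew > rs) rising + 1L else 0L
        if (rising >= 10L)
            stop(sprintf("conjugate gradients diverging: residual increased over 10 iterations (last %g)",
                         sqrt(rsNew)))
        beta <- rsNew / rs
        p <- r + beta * p
        rs <- rsNew
    }
    list(image = x, residuals = hist, iterations = it)
}

#' Normalised root-mean-square error
#'
#' `||x - reference|| / ||reference||` over all elements (complex modulus).
#'
#' @param x,reference arrays of one shape.
#' @return nonnegative scalar.
#' @export
nrmse <- function(x, reference) {
    sqrt(sum(Mod(x - reference)^2) / sum(Mod(reference)^2))
}
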
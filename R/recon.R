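#' @include fit-gradient.R sense.R oracle.R
NULL

# anisotropic in-plane (2D) TV on a complex image stack: modulus of complex
# forward differences along the first two axes, mean-normalised; echoes and
# slices are penalised independently
.tvComplex2d <- function(I) {
    d <- dim(I)
    tot <- 0; cnt <- 0L
    for (a in 1:2) {
        if (d[a] < 2L) next
        df <- .axisSlice(I, a, 2:d[a]) - .axisSlice(I, a, 1:(d[a] - 1L))
        tot <- tot + sum(Mod(df))
        cnt <- cnt + length(df)
    }
    if (cnt == 0L) 0 else tot / cnt
}

.tvComplex2dGrad <- function(I) {
    d <- dim(I)
    cnt <- 0L
    for (a in 1:2) if (d[a] >= 2L) cnt <- cnt + prod(d[-a]) * (d[a] - 1L)
    g <- array(0 + 0i, d)
    if (cnt == 0L) return(g)
    for (a in 1:2) {
        if (d[a] < 2L) next
        df <- .axisSlice(I, a, 2:d[a]) - .axisSlice(I, a, 1:(d[a] - 1L))
        u <- df / pmax(Mod(df), 1e-12)   # phase; subgradient 0 at ties
        u[Mod(df) == 0] <- 0 + 0i
        g <- .axisAssignAdd(g, a, 2:d[a], u)
        g <- .axisAssignAdd(g, a, 1:(d[a] - 1L), -u)
    }
    g / cnt
}

#' Model-based parallel-imaging reconstruction by gradient descent
#'
#' Reconstructs the complex multi-echo image stack from undersampled
#' multi-channel k-space by minimising
#' `mean |k - E I|_(l1|l2) + lambdaTv * TV2D(I) + lambdaL2 * mean |I|^2`
#' with the same first-order optimisers as [fitGradient()] (the image is
#' parameterised by its real and imaginary parts; gradients use the exact
#' adjoint of the encoding operator). The `"l2"` loss with `lambdaTv = 0`
#' targets the same least-squares objective as [lsqrBaseline()]; the `"l1"`
#' loss with in-plane TV gives the noise-robust variant.
#'
#' @param kSpace,coils,samplingMask as in [senseForward()].
#' @param lambdaTv weight of the anisotropic in-plane complex TV.
#' @param lambdaL2 Tikhonov weight (on `mean |I|^2`).
#' @param init complex starting image; defaults to the adjoint
#'   reconstruction `E^H k`.
#' @param options a [fitOptions()] list (loss, optimiser, learning rate,
#'   stopping criteria; default 500 iterations).
#' @return list with `image` (complex `(spatial..., echoes)`),
#'   `lossHistory`, `termination`, `iterations`.
#' @export
reconGradient <- function(kSpace, coils, samplingMask, lambdaTv = 0,
                          lambdaL2 = 0, init = NULL,
                          options = fitOptions(iteration = 500L,
                                               initialLearnRate = 0.01,
                                               lossFunction = "l2")) {
    opts <- options
    dk <- dim(kSpace)
    nSampled <- sum(samplingMask) * dk[length(dk) - 1L]
    I <- if (is.null(init)) senseAdjoint(kSpace, coils, samplingMask) else init
    dI <- dim(I)
    nvI <- length(I)
    step <- .optimStep(opts)
    state <- NULL
    loss <- numeric(opts$iteration)
    termination <- "max_iter"
    it <- 0L
    Z <- array(0, c(dI, 2))
    Z[seq_len(nvI)] <- Re(I)
    Z[nvI + seq_len(nvI)] <- Im(I)
    repeat {
        it <- it + 1L
        I <- array(complex(real = Z[seq_len(nvI)], imaginary = Z[nvI + seq_len(nvI)]), dI)
        r <- senseForward(I, coils, samplingMask) - kSpace
        if (opts$lossFunction == "l2") {
            Ld <- sum(Mod(r)^2) / nSampled
            gI <- 2 * senseAdjoint(r, coils, samplingMask) / nSampled
        } else {
            Ld <- sum(Mod(r)) / nSampled
            u <- r / pmax(Mod(r), 1e-12); u[Mod(r) == 0] <- 0 + 0i
            gI <- senseAdjoint(u, coils, samplingMask) / nSampled
        }
        L <- Ld
        if (lambdaTv > 0) {
            L <- L + lambdaTv * .tvComplex2d(I)
            gI <- gI + lambdaTv * .tvComplex2dGrad(I)
        }
        if (lambdaL2 > 0) {
            L <- L + lambdaL2 * sum(Mod(I)^2) / nvI
            gI <- gI + lambdaL2 * 2 * I / nvI
        }
        loss[it] <- L
        G <- array(0, c(dI, 2))
        G[seq_len(nvI)] <- Re(gI)
        G[nvI + seq_len(nvI)] <- Im(gI)
        if (any(!is.finite(G))) stop(sprintf("non-finite gradient at iteration %d", it))
        upd <- step(Z, G, state)
        Z <- upd$z; state <- upd$state
        if (L < opts$tol) { termination <- "tol"; break }
        if (it >= opts$iteration) { termination <- "max_iter"; break }
        sl <- convergenceSlope(loss[seq_len(it)], opts$convergenceWindow)
        if (!is.na(sl) && abs(sl) < opts$convergenceValue) { termination <- "converged"; break }
    }
    I <- array(complex(real = Z[seq_len(nvI)], imaginary = Z[nvI + seq_len(nvI)]), dI)
    list(image = I, lossHistory = loss[seq_len(it)], termination = termination,
         iterations = it)
}
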
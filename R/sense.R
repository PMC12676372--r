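#' @include models.R
NULL

# unitary multi-dimensional FFT pair: with the 1/sqrt(N) normalisation the
# adjoint of the (sampled) forward FFT is exactly the (masked) inverse FFT
.fftU <- function(x) stats::fft(x) / sqrt(length(x))
.ifftU <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# batched unitary FFT over the leading `ns` (spatial) dims of x, the
# trailing dims being the batch; one mvfft pass per spatial axis
.fftBatch <- function(x, ns, inverse = FALSE) {
    d <- dim(x)
    nsp <- prod(d[seq_len(ns)])
    for (a in seq_len(ns)) {
        dim(x) <- c(d[1], prod(d[-1]))
        x <- stats::mvfft(x, inverse = inverse)
        dim(x) <- d
        perm <- c(seq_len(ns)[-1], 1L, seq_along(d)[-seq_len(ns)])
        x <- aperm(x, perm)
        d <- d[perm]
    }
    # ns cyclic shifts of the spatial axes restore the original order
    x / sqrt(nsp)
}

.senseDims <- function(I, C, samplingMask) {
    dC <- .dimOf(C); dI <- .dimOf(I)
    ns <- length(dC) - 1L
    if (length(dI) != ns + 1L || !identical(as.integer(dI[seq_len(ns)]), as.integer(dC[seq_len(ns)])))
        stop("coil map and image must share one spatial shape")
    if (!identical(as.integer(.dimOf(samplingMask)), as.integer(dI)))
        stop("sampling mask shape must equal the per-echo k-space shape")
    list(spatial = as.integer(dI[seq_len(ns)]), nCoils = dC[ns + 1L], nEchoes = dI[ns + 1L])
}

#' SENSE/CAIPI encoding operator and its adjoint
#'
#' The parallel-imaging forward operator `E`: per coil `c` and echo `e`, the
#' coil-weighted image is transformed to k-space with a unitary FFT and masked
#' by the per-echo undersampling pattern,
#' `k[.., c, e] = M_u[.., e] * F(C[.., c] * I[.., e])`.
#' `senseAdjoint()` applies the exact adjoint
#' `E^H k = sum_c conj(C_c) * F^{-1}(M_u * k_c)` per echo; with the unitary
#' FFT convention the pair satisfies `<E x, y> = <x, E^H y>` to machine
#' precision, and with coils normalised to `sum_c |C_c|^2 = 1` per voxel a
#' fully sampled acquisition is exactly invertible.
#'
#' @param I complex image stack, shape `(spatial..., n_echoes)`.
#' @param kSpace complex k-space, shape `(spatial..., n_coils, n_echoes)`.
#' @param C complex coil sensitivities, shape `(spatial..., n_coils)`.
#' @param samplingMask logical per-echo k-space sampling pattern, shape
#'   `(spatial..., n_echoes)`.
#' @return `senseForward()`: complex k-space `(spatial..., n_coils,
#'   n_echoes)`, zero where unsampled; `senseAdjoint()`: complex image stack
#'   `(spatial..., n_echoes)`.
#' @seealso [genPhantomRecon()], [lsqrBaseline()], [reconGradient()]
#' @export
senseForward <- function(I, C, samplingMask) {
    dd <- .senseDims(I, C, samplingMask)
    ns <- length(dd$spatial)
    nv <- prod(dd$spatial)
    nc <- dd$nCoils; ne <- dd$nEchoes
    Cm <- C; dim(Cm) <- c(nv, nc)
    Im <- I; dim(Im) <- c(nv, ne)
    Mm <- samplingMask; dim(Mm) <- c(nv, ne)
    CI <- matrix(0 + 0i, nv, nc * ne)
    for (e in seq_len(ne))
        CI[, (e - 1L) * nc + seq_len(nc)] <- Cm * Im[, e]
    dim(CI) <- c(dd$spatial, nc * ne)
    km <- .fftBatch(CI, ns)
    dim(km) <- c(nv, nc * ne)
    for (e in seq_len(ne))
        km[, (e - 1L) * nc + seq_len(nc)] <- km[, (e - 1L) * nc + seq_len(nc)] * Mm[, e]
    dim(km) <- c(dd$spatial, nc, ne)
    km
}

#' @rdname senseForward
#' @export
senseAdjoint <- function(kSpace, C, samplingMask) {
    dk <- .dimOf(kSpace)
    nEchoes <- dk[length(dk)]
    nCoils <- dk[length(dk) - 1L]
    spatial <- as.integer(dk[seq_len(length(dk) - 2L)])
    if (!identical(as.integer(.dimOf(C)), c(spatial, as.integer(nCoils))))
        stop("coil map shape does not match the k-space spatial/coil shape")
    if (!identical(as.integer(.dimOf(samplingMask)), c(spatial, as.integer(nEchoes))))
        stop("sampling mask shape must equal the per-echo k-space shape")
    ns <- length(spatial)
    nv <- prod(spatial)
    km <- kSpace; dim(km) <- c(nv, nCoils * nEchoes)
    Cm <- C; dim(Cm) <- c(nv, nCoils)
    Mm <- samplingMask; dim(Mm) <- c(nv, nEchoes)
    masked <- matrix(0 + 0i, nv, nCoils * nEchoes)
    for (e in seq_len(nEchoes))
        masked[, (e - 1L) * nCoils + seq_len(nCoils)] <-
            km[, (e - 1L) * nCoils + seq_len(nCoils)] * Mm[, e]
    dim(masked) <- c(spatial, nCoils * nEchoes)
    img <- .fftBatch(masked, ns, inverse = TRUE)
    dim(img) <- c(nv, nCoils * nEchoes)
    out <- matrix(0 + 0i, nv, nEchoes)
    for (e in seq_len(nEchoes))
        out[, e] <- rowSums(Conj(Cm) * img[, (e - 1L) * nCoils + seq_len(nCoils)])
    dim(out) <- c(spatial, nEchoes)
    out
}

# registry entry: the encoding operator as a forward model over the real and
# imaginary parts of the image stack (grid carries coils + sampling mask)
.senseModel <- function() {
    forwardModel(
        name = "sense",
        parameters = c("I_real", "I_imag"),
        lower = c(I_real = -1e6, I_imag = -1e6),
        upper = c(I_real = 1e6, I_imag = 1e6),
        init = c(I_real = 0, I_imag = 0),
        fun = function(theta, grid) {
            senseForward(theta$I_real + 1i * theta$I_imag,
                         grid[["coils"]], grid[["sampling_mask"]])
        })
}
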
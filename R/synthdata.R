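#' @include core.R models.R sense.R
NULL

# ellipsoid mask inscribed in the volume (background voxels carry zero
# signal, so they provide pure-noise samples for SNR checks)
.ellipsoidMask <- function(shape, frac = 0.45) {
    ctr <- (shape + 1) / 2
    r <- pmax(frac * shape, 0.5)
    g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
    d2 <- ((g$x - ctr[1]) / r[1])^2 + ((g$y - ctr[2]) / r[2])^2 + ((g$z - ctr[3]) / r[3])^2
    array(d2 <= 1, shape)
}

# smoothly varying field in [0, 1]: product of shifted sinusoids with
# seeded random phases
.smoothField <- function(shape, phase) {
    ax <- lapply(seq_along(shape), function(a)
        0.5 + 0.5 * sin(2 * pi * (seq_len(shape[a]) / shape[a]) + phase[a]))
    f <- array(1, shape)
    fx <- ax[[1]]; fy <- ax[[2]]; fz <- ax[[3]]
    f <- outer(outer(fx, fy), fz)
    (f - min(f)) / max(1e-12, diff(range(f)))
}

# piecewise-constant field: nested concentric boxes, one drawn value each
.piecewiseField <- function(shape, nLevels, draw) {
    f <- array(draw[1], shape)
    for (l in 2:nLevels) {
        m <- floor((l - 1) / (2 * nLevels) * shape)
        f[(1 + m[1]):(shape[1] - m[1]),
          (1 + m[2]):(shape[2] - m[2]),
          (1 + m[3]):(shape[3] - m[3])] <- draw[l]
    }
    f
}

.rangeField <- function(shape, rng, fieldType, nLevels = 4L) {
    if (diff(rng) <= 0) stop("degenerate parameter range")
    if (fieldType == "smooth") {
        ph <- stats::runif(3, 0, 2 * pi)
        rng[1] + diff(rng) * .smoothField(shape, ph)
    } else {
        rng[1] + diff(rng) * .piecewiseField(shape, nLevels, stats::runif(nLevels))
    }
}

#' Synthetic mono-exponential multi-echo volume
#'
#' Generates ground-truth S0 and R2* maps (piecewise-constant or smoothly
#' varying) over an ellipsoidal signal mask, the noise-free multi-echo
#' gradient-echo signal, and a noisy copy with additive Gaussian noise.
#' SNR is anchored at the reference measurement: the noise SD equals the
#' mean noise-free first-echo signal inside the mask divided by `snr`, so
#' background voxels (zero signal) sample pure noise. A Rician magnitude
#' option is available but off by default; the Gaussian law matches the
#' samplers' Gaussian likelihood.
#'
#' @param shape 3-vector of spatial dimensions.
#' @param s0Range,r2sRange truth ranges for S0 (signal units) and R2*
#'   (1/ms).
#' @param echoTimes echo times in ms.
#' @param snr signal-to-noise ratio at the first echo (> 0).
#' @param seed RNG seed; every output is a pure function of seed + settings.
#' @param fieldType `"smooth"` or `"piecewise"` truth maps.
#' @param rician add noise in quadrature (magnitude data) instead of plain
#'   additive Gaussian.
#' @return list with `truth` ([ParameterMaps-class]), `signalClean`,
#'   `signalNoisy` (arrays `shape x echoes`), `mask`, `grid`
#'   ([AcquisitionGrid-class]), `noiseSd`, `snr`, `seed`.
#' @export
genMonoexpVolume <- function(shape = c(8, 8, 8), s0Range = c(500, 2000),
                             r2sRange = c(0.01, 0.05),
                             echoTimes = seq(2, 24, length.out = 12),
                             snr = 50, seed = 1, fieldType = c("smooth", "piecewise"),
                             rician = FALSE) {
    fieldType <- match.arg(fieldType)
    if (snr <= 0) stop("snr must be positive")
    set.seed(seed)
    S0 <- .rangeField(shape, s0Range, fieldType)
    R2s <- .rangeField(shape, r2sRange, fieldType)
    mask <- .ellipsoidMask(shape)
    S0[!mask] <- 0
    clean <- monoexpSignal(S0, R2s, echoTimes)
    noiseSd <- mean(.sliceLast(clean, 1L)[mask]) / snr
    noise <- array(stats::rnorm(length(clean), sd = noiseSd), dim(clean))
    noisy <- if (rician) {
        noise2 <- array(stats::rnorm(length(clean), sd = noiseSd), dim(clean))
        sqrt((clean + noise)^2 + noise2^2)
    } else clean + noise
    truth <- parameterMapsList(list(S0 = S0, R2star = R2s),
                               lower = c(S0 = 0, R2star = 0),
                               upper = c(S0 = max(s0Range) * 2, R2star = max(r2sRange) * 4))
    list(truth = truth, signalClean = clean, signalNoisy = noisy, mask = mask,
         grid = acquisitionGrid(echo_times = echoTimes), noiseSd = noiseSd,
         snr = snr, seed = seed)
}

#' Synthetic two-pool multi-echo volume
#'
#' Same mechanism as [genMonoexpVolume()] with the two-pool gradient-echo
#' model: piecewise-constant by default, which is the truthful target for
#' total-variation regularisation experiments.
#'
#' @inheritParams genMonoexpVolume
#' @param fRange fast-pool fraction range.
#' @param r2aRange,r2bRange fast/slow pool rate ranges (1/ms).
#' @return as [genMonoexpVolume()], with truth maps `S0`, `f`, `R2a`,
#'   `R2b`.
#' @export
genTwopoolVolume <- function(shape = c(12, 12, 4), s0Range = c(800, 1200),
                             fRange = c(0.1, 0.4), r2aRange = c(0.10, 0.15),
                             r2bRange = c(0.010, 0.02),
                             echoTimes = seq(1, 60, length.out = 20),
                             snr = 100, seed = 1,
                             fieldType = c("piecewise", "smooth")) {
    fieldType <- match.arg(fieldType)
    if (snr <= 0) stop("snr must be positive")
    set.seed(seed)
    S0 <- .rangeField(shape, s0Range, fieldType)
    f <- .rangeField(shape, fRange, fieldType)
    R2a <- .rangeField(shape, r2aRange, fieldType)
    R2b <- .rangeField(shape, r2bRange, fieldType)
    mask <- .ellipsoidMask(shape)
    S0[!mask] <- 0
    clean <- twopoolSignal(S0, f, R2a, R2b, echoTimes)
    noiseSd <- mean(.sliceLast(clean, 1L)[mask]) / snr
    noisy <- clean + array(stats::rnorm(length(clean), sd = noiseSd), dim(clean))
    truth <- parameterMapsList(list(S0 = S0, f = f, R2a = R2a, R2b = R2b),
                               lower = c(S0 = 0, f = 0, R2a = 0, R2b = 0),
                               upper = c(S0 = max(s0Range) * 2, f = 1,
                                         R2a = max(r2aRange) * 4, R2b = max(r2bRange) * 4))
    list(truth = truth, signalClean = clean, signalNoisy = noisy, mask = mask,
         grid = acquisitionGrid(echo_times = echoTimes), noiseSd = noiseSd,
         snr = snr, seed = seed)
}

#' CAIPI undersampling pattern
#'
#' Boolean per-echo k-space sampling mask for kz-undersampled multi-echo
#' acquisition with CAIPIRINHA shifting: the readout (first) axis is fully
#' sampled, each ky row shifts the sampled kz comb by `zShift`, and the
#' whole pattern rotates by `zTEShift` kz positions from echo to echo. The
#' sampling fraction is exactly `1/Rz` per echo.
#'
#' @param shape spatial k-space dimensions `(kx, ky, kz)`.
#' @param nEchoes echo count.
#' @param Rz kz acceleration factor (must divide `shape[3]`).
#' @param zShift CAIPI kz shift per ky row (< `Rz`).
#' @param zTEShift kz shift per echo (< `Rz`).
#' @return logical array `(shape, nEchoes)`.
#' @export
caipiMask <- function(shape, nEchoes, Rz, zShift, zTEShift) {
    if (shape[3] %% Rz != 0) stop("Rz must divide the kz dimension")
    if (zShift >= Rz || zTEShift >= Rz) stop("CAIPI shifts must be smaller than Rz")
    m <- array(FALSE, c(shape, nEchoes))
    ky <- seq_len(shape[2]) - 1L
    kz <- seq_len(shape[3]) - 1L
    for (e in seq_len(nEchoes)) {
        off <- ((e - 1L) * zTEShift) %% Rz
        sampled <- outer(ky, kz, function(y, z) (z - zShift * y - off) %% Rz == 0)
        m[, , , e] <- rep(sampled, each = shape[1])
    }
    m
}

#' Synthetic parallel-imaging phantom with CAIPI undersampling
#'
#' A piecewise-constant complex multi-echo phantom (mono-exponential
#' magnitude decay, smooth phase), smooth synthetic coil profiles normalised
#' to `sum_c |C_c|^2 = 1` per voxel (so the fully sampled acquisition is
#' exactly invertible by [senseAdjoint()]), the CAIPI sampling mask, and the
#' noisy undersampled multi-channel k-space.
#'
#' @param shape spatial matrix size `(x, y, z)`; `Rz` must divide
#'   `shape[3]`, and for the CAIPI shift pattern to tile k-space as a lattice
#'   `shape[2]` should be a multiple of `Rz / gcd(zShift, Rz)` (the default
#'   24 is, for `Rz = 9`, `zShift = 3`).
#' @param nCoils synthetic coil count; with `Rz`-fold kz undersampling at
#'   least `Rz` coils are needed for a unique least-squares reconstruction
#'   (default 16, with centres spread over the full z extent so coil
#'   profiles can separate the CAIPI aliasing replicas).
#' @param Rz,zShift,zTEShift CAIPI pattern, see [caipiMask()].
#' @param nEchoes,echoTimes echo train (ms).
#' @param noiseSd complex Gaussian k-space noise SD (per real/imaginary
#'   channel), relative to a unit-magnitude phantom.
#' @param seed RNG seed.
#' @return list with `imageTruth` (complex `(shape, nEchoes)`), `coils`,
#'   `samplingMask`, `kSpace`, `grid`, `noiseSd`, `seed`.
#' @export
genPhantomRecon <- function(shape = c(8, 24, 18), nCoils = 16, Rz = 9,
                            zShift = 3, zTEShift = 2, nEchoes = 6,
                            echoTimes = c(3, 8, 13, 18, 23, 28),
                            noiseSd = 0.002, seed = 1) {
    stopifnot(length(echoTimes) == nEchoes)
    set.seed(seed)
    mag <- .piecewiseField(shape, 4L, c(0.4, 1.0, 0.7, 0.9))
    r2s <- .piecewiseField(shape, 4L, c(0.01, 0.03, 0.02, 0.05))
    g <- expand.grid(x = seq_len(shape[1]) / shape[1],
                     y = seq_len(shape[2]) / shape[2],
                     z = seq_len(shape[3]) / shape[3])
    phase <- array(2 * pi * (0.3 * g$x + 0.2 * g$y - 0.1 * g$z), shape)
    I <- array(0 + 0i, c(shape, nEchoes))
    for (e in seq_len(nEchoes))
        I[, , , e] <- mag * exp(-echoTimes[e] * r2s) * exp(1i * phase)
    # smooth coil profiles: Gaussian lobes centred around the FOV boundary
    ang <- 2 * pi * (seq_len(nCoils) - 1) / nCoils
    C <- array(0 + 0i, c(shape, nCoils))
    cx <- 0.5 + 0.75 * cos(ang); cy <- 0.5 + 0.75 * sin(ang)
    cz <- (seq_len(nCoils) - 0.5) / nCoils
    for (cc in seq_len(nCoils)) {
        d2 <- (g$x - cx[cc])^2 + (g$y - cy[cc])^2 + (g$z - cz[cc])^2
        C[, , , cc] <- array(exp(-d2 / (2 * 0.25^2)) * exp(1i * 2 * pi * 0.2 * (g$x * cos(ang[cc]) + g$y * sin(ang[cc]))), shape)
    }
    ssq <- sqrt(apply(abs(C)^2, 1:3, sum))
    for (cc in seq_len(nCoils)) C[, , , cc] <- C[, , , cc] / ssq
    Mu <- caipiMask(shape, nEchoes, Rz, zShift, zTEShift)
    k <- senseForward(I, C, Mu)
    n <- array(complex(real = stats::rnorm(length(k), sd = noiseSd),
                       imaginary = stats::rnorm(length(k), sd = noiseSd)), dim(k))
    # noise only on acquired samples
    maskCoil <- aperm(array(Mu, c(shape, nEchoes, nCoils)), c(1, 2, 3, 5, 4))
    k <- k + n * maskCoil
    list(imageTruth = I, coils = C, samplingMask = Mu, kSpace = k,
         grid = acquisitionGrid(echo_times = echoTimes), noiseSd = noiseSd,
         seed = seed)
}

#' Conjugate-Gaussian toy problem for sampler validation
#'
#' `nObs` observations `y_i = theta + N(0, sigma^2)` per voxel with the
#' identity forward model (predicted signal = theta replicated), flat prior
#' inside wide bounds. The posterior is Gaussian in closed form: mean
#' `ybar`, SD `sigma / sqrt(nObs)` — the ground truth the samplers are
#' checked against.
#'
#' @param nObs observations per voxel (>= 2).
#' @param thetaTrue true parameter value.
#' @param sigma observation noise SD.
#' @param nVoxels independent voxels.
#' @param seed RNG seed.
#' @return list with `signal` (matrix `nVoxels x nObs`), `model` (identity
#'   [ForwardModel-class] with bounds `thetaTrue +/- 25 sigma`), `grid`,
#'   `posteriorMean` (per voxel), `posteriorSd` (scalar `sigma/sqrt(nObs)`),
#'   `thetaTrue`, `sigma`, `seed`.
#' @export
genGaussianToy <- function(nObs = 100, thetaTrue = 0, sigma = 1, nVoxels = 1,
                           seed = 1) {
    if (nObs < 2) stop("nObs must be at least 2")
    set.seed(seed)
    y <- matrix(thetaTrue + stats::rnorm(nVoxels * nObs, sd = sigma), nVoxels, nObs)
    half <- 25 * sigma
    model <- forwardModel(
        name = "identity_gaussian",
        parameters = "theta",
        lower = c(theta = thetaTrue - half), upper = c(theta = thetaTrue + half),
        init = c(theta = thetaTrue + 0.5 * sigma),
        fun = function(theta, grid) {
            n <- grid[["n_obs"]]
            matrix(theta$theta, length(theta$theta), n)
        },
        jacobian = function(theta, grid) {
            n <- grid[["n_obs"]]
            list(theta = matrix(1, length(theta$theta), n))
        })
    list(signal = y, model = model, grid = acquisitionGrid(n_obs = nObs),
         posteriorMean = rowMeans(y), posteriorSd = sigma / sqrt(nObs),
         thetaTrue = thetaTrue, sigma = sigma, seed = seed)
}
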
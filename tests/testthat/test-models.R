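test_that("mono-exponential signal matches the closed form", {
    expect_equal(monoexpSignal(2, 0.05, 20), 2 * exp(-1), tolerance = 1e-12)
    t <- seq(0, 30, by = 3)
    expect_equal(monoexpSignal(3, 0, t), rep(3, length(t)))   # R2* = 0
    expect_equal(monoexpSignal(5, 0.1, 0), 5)                 # t = 0
    expect_error(monoexpSignal(1, 0.1, -1), "nonnegative")
    # strictly decreasing in t for positive S0 and R2*
    s <- monoexpSignal(100, 0.07, seq(1, 40, by = 1))
    expect_true(all(diff(s) < 0))
    # array broadcasting over voxels
    S0 <- array(runif(8, 100, 200), c(2, 2, 2))
    R2 <- array(runif(8, 0.01, 0.1), c(2, 2, 2))
    out <- monoexpSignal(S0, R2, c(2, 4))
    expect_equal(dim(out), c(2, 2, 2, 2))
    expect_equal(out[1, 2, 1, 2], S0[1, 2, 1] * exp(-4 * R2[1, 2, 1]))
})

test_that("two-pool signal: closed form, degenerate pools, validation", {
    expect_equal(twopoolSignal(1, 0.2, 0.1, 0.02, 10),
                 0.2 * exp(-1) + 0.8 * exp(-0.2), tolerance = 1e-12)
    t <- seq(2, 24, by = 2)
    # f = 1 collapses to mono-exponential with the fast rate
    expect_equal(twopoolSignal(50, 1, 0.08, 0.01, t), monoexpSignal(50, 0.08, t))
    # equal rates collapse for any fraction
    expect_equal(twopoolSignal(50, 0.3, 0.05, 0.05, t), monoexpSignal(50, 0.05, t))
    expect_error(twopoolSignal(1, 1.2, 0.1, 0.02, t), "\\[0, 1\\]")
})

test_that("model registry registers, retrieves and refuses duplicates", {
    expect_setequal(intersect(listModels(), c("monoexp_r2s", "twopool_gre", "sense")),
                    c("monoexp_r2s", "twopool_gre", "sense"))
    m <- forwardModel("tmp_model_xyz", "a", c(a = 0), c(a = 1),
                      fun = function(theta, grid) theta$a)
    registerModel(m)
    expect_identical(getModel("tmp_model_xyz")@name, "tmp_model_xyz")
    expect_error(registerModel(m), "already registered")
    expect_error(getModel("no_such_model"), "available")
    rm(list = "tmp_model_xyz", envir = qmrfit:::.modelRegistry)
})

test_that("registered models return measurement-shaped output for random shapes", {
    set.seed(4)
    for (rep in 1:5) {
        d <- sample(2:5, 3, replace = TRUE)
        nt <- sample(3:8, 1)
        t <- sort(runif(nt, 1, 30))
        th <- list(S0 = array(runif(prod(d), 100, 500), d),
                   R2star = array(runif(prod(d), 0.01, 0.1), d))
        out <- getModel("monoexp_r2s")@fun(th, acquisitionGrid(echo_times = t))
        expect_equal(dim(out), c(d, nt))
        th2 <- c(th[1], list(f = array(runif(prod(d)), d),
                             R2a = array(runif(prod(d), 0.05, 0.2), d),
                             R2b = array(runif(prod(d), 0.001, 0.03), d)))
        out2 <- getModel("twopool_gre")@fun(th2, acquisitionGrid(echo_times = t))
        expect_equal(dim(out2), c(d, nt))
    }
})

test_that("analytic model Jacobians match central differences", {
    set.seed(5)
    t <- seq(2, 24, by = 2)
    grid <- acquisitionGrid(echo_times = t)
    for (nm in c("monoexp_r2s", "twopool_gre")) {
        mod <- getModel(nm)
        n <- 7
        th <- lapply(mod@parameters, function(p)
            runif(n, mod@lower[[p]] + 0.1 * (mod@upper[[p]] - mod@lower[[p]]),
                  mod@upper[[p]] - 0.1 * (mod@upper[[p]] - mod@lower[[p]])))
        names(th) <- mod@parameters
        J <- mod@jacobian(th, grid)
        for (p in mod@parameters) {
            h <- 1e-6 * (mod@upper[[p]] - mod@lower[[p]])
            tp <- th; tp[[p]] <- th[[p]] + h
            tm <- th; tm[[p]] <- th[[p]] - h
            Jnum <- (mod@fun(tp, grid) - mod@fun(tm, grid)) / (2 * h)
            expect_equal(as.vector(J[[p]]), as.vector(Jnum), tolerance = 1e-5)
        }
    }
})

test_that("SENSE forward/adjoint satisfy the adjoint identity and linearity", {
    ph <- genPhantomRecon(shape = c(6, 6, 6), nCoils = 4, Rz = 2, zShift = 1,
                          zTEShift = 1, nEchoes = 2, echoTimes = c(3, 8), seed = 8)
    dI <- dim(ph$imageTruth); dk <- dim(ph$kSpace)
    set.seed(9)
    x <- rcomplex(prod(dI), dI)
    y <- rcomplex(prod(dk), dk)
    Ex <- senseForward(x, ph$coils, ph$samplingMask)
    EHy <- senseAdjoint(y, ph$coils, ph$samplingMask)
    relErr <- Mod(sum(Conj(Ex) * y) - sum(Conj(x) * EHy)) /
        (sqrt(sum(Mod(x)^2)) * sqrt(sum(Mod(y)^2)))
    expect_lt(relErr, 1e-10)
    # zero maps to zero; masked entries are zero
    expect_true(all(senseForward(x * 0, ph$coils, ph$samplingMask) == 0))
    expect_true(all(Ex[!aperm(array(ph$samplingMask, c(dI, dk[4])), c(1, 2, 3, 5, 4))] == 0))
})

test_that("fully sampled SENSE with unit-norm coils is exactly invertible", {
    ph <- genPhantomRecon(shape = c(6, 6, 4), nCoils = 5, Rz = 1, zShift = 0,
                          zTEShift = 0, nEchoes = 2, echoTimes = c(3, 8),
                          noiseSd = 0, seed = 10)
    expect_equal(mean(ph$samplingMask), 1)
    rec <- senseAdjoint(ph$kSpace, ph$coils, ph$samplingMask)
    expect_lt(nrmse(rec, ph$imageTruth), 1e-12)
    # single uniform coil, full sampling: forward is the unitary FFT itself
    I <- rcomplex(6 * 6 * 4 * 1, c(6, 6, 4, 1))
    C1 <- array(1 + 0i, c(6, 6, 4, 1))
    Mu <- array(TRUE, c(6, 6, 4, 1))
    k <- senseForward(I, C1, Mu)
    expect_equal(as.vector(k), as.vector(stats::fft(I[, , , 1]) / sqrt(6 * 6 * 4)),
                 tolerance = 1e-12)
})
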
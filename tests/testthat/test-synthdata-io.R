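test_that("generators are pure functions of seed and settings", {
    a <- genMonoexpVolume(shape = c(5, 5, 5), snr = 40, seed = 7)
    b <- genMonoexpVolume(shape = c(5, 5, 5), snr = 40, seed = 7)
    expect_identical(a$signalNoisy, b$signalNoisy)
    expect_identical(a$truth[["R2star"]], b$truth[["R2star"]])
    c2 <- genMonoexpVolume(shape = c(5, 5, 5), snr = 40, seed = 8)
    expect_false(identical(a$signalNoisy, c2$signalNoisy))
    t1 <- genGaussianToy(nObs = 30, thetaTrue = 2, sigma = 0.5, nVoxels = 4, seed = 3)
    t2 <- genGaussianToy(nObs = 30, thetaTrue = 2, sigma = 0.5, nVoxels = 4, seed = 3)
    expect_identical(t1$signal, t2$signal)
})

test_that("empirical noise SD matches the SNR definition at the first echo", {
    sim <- genMonoexpVolume(shape = c(24, 24, 24), snr = 50, seed = 9)
    # background voxels (outside the ellipsoid) carry pure noise
    bg <- !sim$mask
    noise <- (sim$signalNoisy - sim$signalClean)[array(bg, dim(sim$signalNoisy))]
    expect_gt(length(noise), 1e4)
    expect_equal(sd(noise), sim$noiseSd, tolerance = 0.02)
    expect_equal(sim$noiseSd,
                 mean(sim$signalClean[, , , 1][sim$mask]) / 50, tolerance = 1e-12)
})

test_that("two-pool generator reduces to mono-exponential at f = 1", {
    g <- genTwopoolVolume(shape = c(4, 4, 4), fRange = c(1 - 1e-12, 1),
                          r2aRange = c(0.03, 0.06), snr = 1e9, seed = 10,
                          fieldType = "smooth")
    ref <- monoexpSignal(g$truth[["S0"]], g$truth[["R2a"]], g$grid[["echo_times"]])
    expect_equal(g$signalClean, ref, tolerance = 1e-9)
})

test_that("Gaussian toy exposes the correct closed-form posterior", {
    toy <- genGaussianToy(nObs = 100, thetaTrue = 3, sigma = 1, nVoxels = 2, seed = 11)
    expect_equal(toy$posteriorSd, 0.1)
    expect_equal(toy$posteriorMean, rowMeans(toy$signal))
    big <- genGaussianToy(nObs = 20000, thetaTrue = 3, sigma = 1, seed = 12)
    expect_lt(abs(big$posteriorMean - 3), 0.05)   # consistency at large n
    expect_error(genGaussianToy(nObs = 1), "at least 2")
})

test_that("CAIPI mask: sampling fraction, shift pattern, validation", {
    m <- caipiMask(c(4, 12, 18), nEchoes = 6, Rz = 9, zShift = 3, zTEShift = 2)
    # exactly 1/Rz sampled per echo, per ky row
    expect_equal(apply(m, 4, mean), rep(1 / 9, 6))
    for (y in 1:12) expect_equal(mean(m[1, y, , 1]), 1 / 9)
    # 3 consecutive ky rows cover 3 distinct kz offsets
    offs <- lapply(1:3, function(y) which(m[1, y, , 1]) %% 9)
    expect_length(unique(unlist(offs)), 3)
    # echo-to-echo rotation by zTEShift
    expect_equal(which(m[1, 1, , 2])[1] - which(m[1, 1, , 1])[1], 2)
    expect_error(caipiMask(c(4, 12, 16), 6, 9, 3, 2), "divide")
    expect_error(caipiMask(c(4, 12, 18), 6, 9, 9, 2), "smaller")
})

test_that("recon phantom is exactly invertible when fully sampled", {
    ph <- genPhantomRecon(shape = c(6, 6, 6), nCoils = 4, Rz = 1, zShift = 0,
                          zTEShift = 0, nEchoes = 2, echoTimes = c(3, 8),
                          noiseSd = 0, seed = 13)
    rec <- senseAdjoint(ph$kSpace, ph$coils, ph$samplingMask)
    expect_lt(nrmse(rec, ph$imageTruth), 1e-12)
    # coil normalisation: sum of squared magnitudes is 1 per voxel
    ssq <- apply(abs(ph$coils)^2, 1:3, sum)
    expect_equal(as.vector(ssq), rep(1, length(ssq)), tolerance = 1e-12)
})

test_that("NLLS oracle solves noiseless voxels exactly and flags nothing", {
    sim <- genMonoexpVolume(shape = c(4, 4, 4), snr = 1e9, seed = 14)
    orc <- nllsOracle("monoexp_r2s", sim$signalNoisy, sim$mask, grid = sim$grid)
    expect_identical(orc$nNotConverged, 0L)
    m <- sim$mask
    for (p in c("S0", "R2star")) {
        rel <- abs(orc$maps[[p]][m] - sim$truth[[p]][m]) / sim$truth[[p]][m]
        expect_lt(max(rel), 1e-6)
        expect_true(all(is.na(orc$maps[[p]][!m])))
    }
    expect_error(nllsOracle("monoexp_r2s", sim$signalNoisy[, , , 1, drop = FALSE],
                            sim$mask, grid = list(echo_times = 2)), "count")
})

test_that("two-pool oracle recovers the pool fraction at high SNR", {
    g <- genTwopoolVolume(snr = 100, seed = 15)     # ~240 masked voxels
    orc <- nllsOracle("twopool_gre", g$signalNoisy, g$mask, grid = g$grid)
    bias <- mean(orc$maps$f[g$mask] - g$truth[["f"]][g$mask])
    expect_lt(abs(bias), 0.05)
})

test_that("conjugate-gradient baseline: exact recovery and Tikhonov limit", {
    ph <- genPhantomRecon(shape = c(6, 6, 6), nCoils = 6, Rz = 1, zShift = 0,
                          zTEShift = 0, nEchoes = 2, echoTimes = c(3, 8),
                          noiseSd = 0, seed = 16)
    cg <- lsqrBaseline(ph$kSpace, ph$coils, ph$samplingMask, lambda = 0,
                       maxIter = 100, tol = 1e-10)
    expect_lt(nrmse(cg$image, ph$imageTruth), 1e-6)
    # very large Tikhonov weight shrinks the solution towards zero
    cgBig <- lsqrBaseline(ph$kSpace, ph$coils, ph$samplingMask, lambda = 1e6,
                          maxIter = 50)
    expect_lt(sqrt(sum(Mod(cgBig$image)^2)) / sqrt(sum(Mod(ph$imageTruth)^2)), 1e-3)
})

test_that("NIfTI, complex pair and edge-list round trips preserve the data", {
    tmp <- withr::local_tempdir()
    v <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
    p <- file.path(tmp, "vol.nii.gz")
    writeVolume(v, p)
    expect_equal(readVolume(p), v, tolerance = 1e-6)
    z <- array(complex(real = rnorm(24), imaginary = rnorm(24)), c(2, 3, 4))
    writeComplexVolume(z, file.path(tmp, "k"))
    expect_equal(readComplexVolume(file.path(tmp, "k")), z, tolerance = 1e-6)
    adj <- graphAdjacency(rbind(c(1, 2), c(2, 3), c(1, 3)))
    ep <- file.path(tmp, "edges.txt")
    writeEdgeList(adj, ep)
    back <- readEdgeList(ep)
    expect_identical(back@edges, adj@edges)
    # strict 0-based convention: negative indices rejected
    writeLines(c("-1 0", "0 1"), ep)
    expect_error(readEdgeList(ep), "0-based")
})

test_that("YAML configs are schema-checked with the offending key named", {
    tmp <- withr::local_tempdir()
    gp <- file.path(tmp, "grid.yaml")
    writeLines("echo_times: [2, 4, 6]", gp)
    g <- readAcquisitionConfig(gp)
    expect_equal(g[["echo_times"]], c(2, 4, 6))
    fp <- file.path(tmp, "fit.yaml")
    writeLines(c("iteration: 10", "learnRate: 0.1"), fp)
    expect_error(readFitConfig(fp), "learnRate")
    writeLines(c("iteration: 10", "initialLearnRate: 0.1"), fp)
    expect_identical(readFitConfig(fp)$iteration, 10L)
})
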